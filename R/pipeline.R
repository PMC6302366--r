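#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. All randomness downstream
#' derives from the single `seed`.
#'
#' @param expression Path to the expression TSV (genes x samples), or an
#'   expression matrix.
#' @param phenotype Path to the phenotype TSV (sample_id, label), or a
#'   [group_labels()] tibble.
#' @param output_dir Directory for artifact files.
#' @param value_scale Scale of the input expression values.
#' @param control_label,case_label Phenotype labels mapped to the two
#'   groups (used only when `phenotype` is a path).
#' @param alpha,fc_hi,fc_lo Volcano thresholds.
#' @param use_voom_weights Use precision weights in the DE fit.
#' @param k_min,k_max Candidate cluster-number range (`k_max = NULL` uses
#'   the [objective_matrix()] default).
#' @param R Bootstrap replicates per objective cell.
#' @param folds,repeats Cross-validation shape for signature validation.
#' @param n_delta Shrinkage-grid size for the NSC threshold search.
#' @param seed Root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, phenotype, output_dir = ".",
                            value_scale = "counts",
                            control_label = "control", case_label = "case",
                            alpha = 0.05, fc_hi = 2, fc_lo = 0.5,
                            use_voom_weights = FALSE,
                            k_min = 2, k_max = NULL, R = 50,
                            folds = 10, repeats = 10, n_delta = 30,
                            seed = 1) {
  stopifnot(alpha > 0, fc_hi > 0, fc_lo > 0, k_min >= 2, R >= 2,
            folds >= 2, repeats >= 1)
  cfg <- list(expression = expression, phenotype = phenotype,
              output_dir = output_dir, value_scale = value_scale,
              control_label = control_label, case_label = case_label,
              alpha = alpha, fc_hi = fc_hi, fc_lo = fc_lo,
              use_voom_weights = use_voom_weights,
              k_min = k_min, k_max = k_max, R = R,
              folds = folds, repeats = repeats, n_delta = n_delta,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @param ... Overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full signature-discovery pipeline
#'
#' Executes, in order: prefilter, log-CPM (counts input) or pass-through
#' (pre-normalized input, with a warning), the moderated DE test with the
#' volcano bi-filter, gene-wise standardization of the DEG matrix,
#' bootstrap-stability objective matrix over candidate K, Pareto ranking
#' and K selection, k-means module extraction at the selected K, module
#' scoring by average pairwise Spearman correlation, signature selection,
#' and repeated cross-validated NSC validation. Every intermediate table
#' is written to `output_dir`, along with a run manifest (JSON) recording
#' parameters, seeds and stage-by-stage counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results (`de`, `degs`,
#'   `objectives`, `pareto`, `partition`, `module_scores`, `signature`,
#'   `cv`, `manifest`) and the vector of written `artifact` paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  X <- if (is.character(config$expression)) {
    read_expression(config$expression, config$value_scale)
  } else config$expression
  groups <- if (is.character(config$phenotype)) {
    read_groups(config$phenotype, config$control_label, config$case_label)
  } else config$phenotype

  aligned <- align_samples(X, groups)
  X <- aligned$expression
  groups <- aligned$groups

  pf <- prefilter(X)
  if (value_scale(pf$expression) == "counts") {
    Y <- log_cpm(pf$expression)
  } else {
    warning("input is not on the counts scale; skipping log-CPM and using values as-is")
    Y <- pf$expression
  }
  weights <- if (isTRUE(config$use_voom_weights)) {
    voom_weights(Y, groups)
  } else NULL

  de <- moderated_de(Y, groups, weights = weights, alpha = config$alpha,
                     fc_hi = config$fc_hi, fc_lo = config$fc_lo)
  readr::write_tsv(tibble::as_tibble(de), out("de_table.tsv"), progress = FALSE)
  degs <- volcano_filter(de, config$alpha, config$fc_hi, config$fc_lo)
  deg_ids <- de$gene_id[de$status != "ns"]
  if (length(deg_ids) < 2 * config$k_min) {
    stop("stage de_test: only ", length(deg_ids),
         " DEGs; too few to cluster", call. = FALSE)
  }
  Z <- standardize_genes(Y[deg_ids, , drop = FALSE])
  report <- pf$report
  report$n_dropped_constant <- attr(Z, "n_dropped_constant")
  jsonlite::write_json(as.list(report), out("preprocess_report.json"),
                       auto_unbox = TRUE)

  objectives <- objective_matrix(Z, k_min = config$k_min,
                                 k_max = config$k_max, R = config$R,
                                 seed = config$seed)
  readr::write_tsv(tibble::as_tibble(objectives), out("objective_matrix.tsv"),
                   progress = FALSE)
  pareto <- pareto_rank(objectives)
  jsonlite::write_json(list(pareto_k = pareto$pareto_k,
                            rank_key = pareto$rank_key,
                            dominance_counts = pareto$dominance_counts,
                            selected_k = pareto$selected_k),
                       out("pareto.json"), auto_unbox = TRUE, digits = NA)

  part <- cluster_kmeans(Z, pareto$selected_k, seed = config$seed)
  readr::write_tsv(tibble::as_tibble(part), out("partition.tsv"),
                   progress = FALSE)
  scores <- score_modules(Z, part, de)
  readr::write_tsv(tibble::as_tibble(scores), out("module_scores.tsv"),
                   progress = FALSE)
  sig <- pick_signature(scores, part)
  write_signature(sig, out("signature.tsv"))

  cv <- evaluate_signature(Y[sig$gene_ids, , drop = FALSE], groups,
                           repeats = config$repeats, folds = config$folds,
                           seed = config$seed, n_delta = config$n_delta)
  readr::write_tsv(dplyr::bind_rows(
    cv$per_repeat,
    tibble::tibble(repeat_id = NA_integer_, tp = NA_integer_,
                   fp = NA_integer_, tn = NA_integer_, fn = NA_integer_,
                   sensitivity = cv$summary$mean[1],
                   specificity = cv$summary$mean[2],
                   precision = cv$summary$mean[3],
                   accuracy = cv$summary$mean[4],
                   delta_median = NA_real_)),
    out("cv_report.tsv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("paretosig")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("expression", "phenotype"))],
    counts = list(
      n_samples = ncol(X),
      n_control = sum(groups$group == "control"),
      n_case = sum(groups$group == "case"),
      preprocess = as.list(report),
      n_deg = length(deg_ids),
      n_up = length(degs$up),
      n_down = length(degs$down),
      selected_k = pareto$selected_k,
      signature_size = length(sig$gene_ids),
      signature_cluster = sig$source_cluster
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  artifacts <- c("de_table.tsv", "preprocess_report.json",
                 "objective_matrix.tsv", "pareto.json", "partition.tsv",
                 "module_scores.tsv", "signature.tsv", "cv_report.tsv",
                 "manifest.json")
  invisible(list(de = de, degs = degs, objectives = objectives,
                 pareto = pareto, partition = part, module_scores = scores,
                 signature = sig, cv = cv, manifest = manifest,
                 artifacts = out(artifacts)))
}
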