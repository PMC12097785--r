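## Orchestration: cohort -> connectivity -> metrics -> cognition ->
## associations, with a descriptives table, a sensory-motor negative
## control, and reproducible delimited outputs stamped with a config hash.

#' Pipeline run configuration
#'
#' @param cohort a `synthetic_cohort`, or a path to a cohort directory
#'   written by [write_cohort()], or NULL to simulate from `spec`.
#' @param spec a [cohort_spec()] used when `cohort` is NULL.
#' @param covariates covariate column names used in partial correlations
#'   (default site and cortical thickness, as in the study design).
#' @param alpha FDR level.
#' @param gamma_detect Louvain resolution for data-driven relabeling.
#' @param n_factors factors extracted from the battery.
#' @param seed seed for the community-detection restarts.
#' @param out_dir optional output directory for delimited tables.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = NULL, spec = cohort_spec(),
                       covariates = c("site", "cortical_thickness"),
                       alpha = 0.05, gamma_detect = 1.2, n_factors = 5,
                       seed = 1L, out_dir = NULL) {
  structure(list(cohort = cohort, spec = spec, covariates = covariates,
                 alpha = alpha, gamma_detect = gamma_detect,
                 n_factors = n_factors, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

## FNV-1a hash of the serialized config, for output provenance stamps
config_hash_ <- function(config) {
  cfg <- config
  cfg$cohort <- NULL
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(lapply(unclass(cfg), function(x)
    if (inherits(x, "cohort_spec")) unclass(x[setdiff(names(x), "atlas")]) else x),
    auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # xor low byte, then multiply by the FNV prime mod 2^32 without
    # exceeding double precision
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_stamped_ <- function(d, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Descriptive statistics table
#'
#' Mean, SD and range per metric column, mirroring the layout of the
#' descriptive tables of a cohort report.
#'
#' @param data `data.frame` of numeric metric columns (non-numeric columns
#'   are dropped).
#' @return `data.frame`: variable, mean, sd, min, max.
#' @export
descriptives <- function(data) {
  num <- data[vapply(data, is.numeric, logical(1))]
  out <- data.frame(
    variable = names(num),
    mean = vapply(num, mean, numeric(1)),
    sd = vapply(num, stats::sd, numeric(1)),
    min = vapply(num, min, numeric(1)),
    max = vapply(num, max, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

resolve_cohort_ <- function(config) {
  if (inherits(config$cohort, "synthetic_cohort")) return(config$cohort)
  if (is.character(config$cohort)) return(read_cohort(config$cohort))
  simulate_cohort(config$spec)
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a cohort, computes per-subject connectivity and graph
#' metrics, derives factor scores and overall cognition from the test
#' battery, and relates network metrics to cognition with covariate-adjusted
#' partial correlations under one BH-FDR family. Also produces the
#' descriptives table and the sensory-motor negative-control rows.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `metrics`, `cognition` (table),
#'   `cognition_fit`, `associations`, `control`, `descriptives`, `joined`,
#'   `config_hash`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  cohort <- resolve_cohort_(config)
  metrics <- metrics_table(cohort)
  cog <- fit_cognition(cohort$tests, n_factors = config$n_factors)
  joined <- merge(metrics, cog$table, by = "subject_id")
  joined <- merge(joined,
                  cohort$subjects[, c("subject_id", "site",
                                      "cortical_thickness")],
                  by = "subject_id")
  joined <- joined[order(joined$subject_id), ]
  rownames(joined) <- NULL

  preds <- intersect(c("system_segregation", "modularity_Q",
                       "mean_within_connectivity",
                       "participation_coefficient",
                       "seg_DMN", "seg_FPN", "seg_CON"),
                     names(joined))
  assoc <- associate(joined, preds, "overall_cognition",
                     covariates = config$covariates, alpha = config$alpha)
  control <- negative_control_(joined, config)
  res <- structure(list(
    metrics = metrics, cognition = cog$table, cognition_fit = cog,
    associations = assoc, control = control,
    descriptives = descriptives(
      joined[, c(preds, "overall_cognition"), drop = FALSE]),
    joined = joined, config_hash = config_hash_(config), config = config,
    cohort = cohort), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- res$config_hash
    write_stamped_(metrics, file.path(config$out_dir, "metrics.tsv"), h)
    write_stamped_(cog$table, file.path(config$out_dir, "cognition.tsv"), h)
    write_stamped_(assoc, file.path(config$out_dir, "associations.tsv"), h)
    write_stamped_(control, file.path(config$out_dir, "negative_control.tsv"), h)
    write_stamped_(res$descriptives,
                   file.path(config$out_dir, "descriptives.tsv"), h)
  }
  res
}

negative_control_ <- function(joined, config) {
  associate(joined, "sm_segregation", "overall_cognition",
            covariates = config$covariates, alpha = config$alpha)
}

#' Sensory-motor negative control
#'
#' Repeats the association analysis with sensory-motor system segregation as
#' the predictor. In cohorts where cognition is tied only to
#' association-system segregation these rows behave as planted nulls.
#'
#' @param config a [run_config()], or a `pipeline_result` whose control rows
#'   are returned directly.
#' @return association `data.frame`.
#' @export
negative_control <- function(config) {
  if (inherits(config, "pipeline_result")) return(config$control)
  run_pipeline(config)$control
}

#' Cross-parcellation robustness check
#'
#' Reruns the segregation-cognition association twice on the same result:
#' once with the atlas labels and once with labels regenerated by Louvain
#' community detection (at `gamma_detect`) on the group-average positive
#' connectivity matrix. Returns both rows so the sign of the association can
#' be compared across parcellations.
#'
#' @param result a `pipeline_result`.
#' @return `data.frame` with rows `atlas` and `louvain`.
#' @export
parcellation_robustness <- function(result) {
  cohort <- result$cohort
  config <- result$config
  # group-average z matrix over subjects
  zs <- lapply(cohort$timeseries, function(m) connectivity(m)$z)
  G <- Reduce(`+`, zs) / length(zs)
  diag(G) <- 0
  gm <- positive_part(conn_matrix(G, node_ids = colnames(G)))
  atlas2 <- louvain_atlas(gm, cohort$atlas, gamma = config$gamma_detect,
                          seed = config$seed)
  metrics2 <- metrics_table(cohort, atlas = atlas2)
  joined2 <- merge(metrics2[, c("subject_id", "system_segregation")],
                   result$joined[, c("subject_id", "overall_cognition")],
                   by = "subject_id")
  r_atlas <- pearson_with_p(result$joined$system_segregation,
                            result$joined$overall_cognition,
                            "segregation_atlas", "overall_cognition")
  r_louv <- pearson_with_p(joined2$system_segregation,
                           joined2$overall_cognition,
                           "segregation_louvain", "overall_cognition")
  out <- rbind(r_atlas, r_louv)
  out$parcellation <- c("atlas", "louvain")
  out
}
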