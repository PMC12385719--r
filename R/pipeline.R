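#' Pipeline run configuration
#'
#' Validates the knobs of a full evaluation run. Either `input` (path to a
#' trait-table CSV/TSV) or `synthetic` (a [synthetic_config()]; default
#' [default_config()] seeded from `seed`) supplies the panel.
#'
#' @param input Optional path to a trait table file.
#' @param synthetic Optional [synthetic_config()] used when `input` is NULL.
#' @param alpha Significance level for all tests, in (0, 1).
#' @param kaiser Eigenvalue retention threshold, > 0.
#' @param proportion Elite fraction, in (0, 1].
#' @param k Cluster count, >= 1.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; sub-seeds for each stochastic stage are derived
#'   from it by a counter split.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, alpha = 0.05,
                            kaiser = 1.0, proportion = 0.05, k = 4,
                            out_dir = tempfile("cottoneval_run_"),
                            seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(kaiser) || kaiser < 0) {
    stop("kaiser threshold must be non-negative", call. = FALSE)
  }
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1) {
    stop("proportion must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  if (is.null(input) && is.null(synthetic)) {
    synthetic <- default_config(seed = .subseed(seed, 11L))
  }
  structure(list(input = input, synthetic = synthetic, alpha = alpha,
                 kaiser = kaiser, proportion = proportion, k = as.integer(k),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields of [pipeline_config()] are read from the file; a
#' `synthetic: n_accessions/seed` block selects a sized [default_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  syn <- NULL
  if (!is.null(cfg$synthetic)) {
    syn <- default_config(
      n_accessions = cfg$synthetic$n_accessions %||% 259,
      seed = cfg$synthetic$seed %||% cfg$seed %||% 1L)
  }
  pipeline_config(input = cfg$input, synthetic = syn,
                  alpha = cfg$alpha %||% 0.05,
                  kaiser = cfg$kaiser %||% 1.0,
                  proportion = cfg$proportion %||% 0.05,
                  k = cfg$k %||% 4,
                  out_dir = cfg$out_dir %||% tempfile("cottoneval_run_"),
                  seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full evaluation pipeline
#'
#' Executes every stage in order - acquire panel (read or simulate),
#' descriptive summary, origin and period group comparisons, the full
#' correlation matrix, the PCA-FMF comprehensive evaluation, clustering and
#' cluster profiling - writing each stage's CSV next to a machine-readable
#' JSON summary (`summary.json`, schema-versioned) and a plain-text log.
#' Identical configuration (including seed) produces byte-identical JSON.
#' Any stage failure aborts the run with the stage name in the error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   summary written to JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("cottoneval pipeline | seed = ", config$seed,
      " | alpha = ", config$alpha)

  tab <- stage("input", {
    if (!is.null(config$input)) {
      say("reading trait table from ", config$input)
      read_trait_table(config$input)
    } else {
      say("generating synthetic panel (n = ",
          config$synthetic$n_accessions, ", seed = ",
          config$synthetic$seed, ")")
      panel <- generate_germplasm(config$synthetic)
      write_trait_table(panel$table,
                        file.path(config$out_dir, "panel.csv"))
      panel$table
    }
  })

  summ <- stage("summarize", summarize_table(tab))
  utils::write.csv(summ$traits, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)

  cmp_origin <- stage("compare-origin",
                      compare_groups(tab, "origin", alpha = config$alpha))
  cmp_period <- stage("compare-period",
                      compare_groups(tab, "period", alpha = config$alpha))
  for (nm in c("origin", "period")) {
    cmp <- if (nm == "origin") cmp_origin else cmp_period
    out <- cbind(cmp$results,
                 as.data.frame(cmp$letters, stringsAsFactors = FALSE))
    utils::write.csv(out,
                     file.path(config$out_dir, paste0("anova_", nm, ".csv")),
                     row.names = FALSE)
  }
  say("significant nutritional traits: origin ", cmp_origin$n_significant,
      "/26, period ", cmp_period$n_significant, "/26")

  corr <- stage("correlate", pearson_matrix(tab))
  long <- data.frame(
    trait_a = rownames(corr$r_matrix)[row(corr$r_matrix)[upper.tri(corr$r_matrix)]],
    trait_b = colnames(corr$r_matrix)[col(corr$r_matrix)[upper.tri(corr$r_matrix)]],
    r = corr$r_matrix[upper.tri(corr$r_matrix)],
    p = corr$p_matrix[upper.tri(corr$p_matrix)],
    stars = corr$star_matrix[upper.tri(corr$star_matrix)],
    stringsAsFactors = FALSE)
  utils::write.csv(long, file.path(config$out_dir, "correlations.csv"),
                   row.names = FALSE)

  fit <- stage("evaluate",
               pcafmf(tab, kaiser = config$kaiser,
                      proportion = config$proportion))
  scores_df <- data.frame(accession_id = names(fit$F), F = unname(fit$F),
                          rank = unname(fit$rank),
                          elite = unname(fit$elite),
                          fit$membership,
                          fit$scores[, fit$retained, drop = FALSE],
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(scores_df, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)
  say("retained ", length(fit$retained), " components; elite k = ", fit$k)

  clus <- stage("cluster", hierarchical_cluster(tab, k = config$k))
  utils::write.csv(data.frame(accession_id = names(clus$cluster),
                              cluster = unname(clus$cluster)),
                   file.path(config$out_dir, "clusters.csv"),
                   row.names = FALSE)
  write_dendrogram(clus, file.path(config$out_dir, "dendrogram.nwk"))
  prof <- stage("profile-clusters",
                profile_clusters(tab, clus, alpha = config$alpha))

  summary_json <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_accessions = length(tab$accession_id),
    trait_summaries = summ$traits,
    aggregates = as.list(summ$aggregates),
    significant_traits = list(origin = cmp_origin$n_significant,
                              period = cmp_period$n_significant),
    top_correlations = utils::head(long[order(-abs(long$r)), ], 10),
    retained_eigenvalues = fit$eigenvalues[fit$retained],
    weights = as.list(fit$weights),
    F_quantiles = as.list(stats::quantile(fit$F,
                                          c(0, 0.25, 0.5, 0.75, 1))),
    F_mean = mean(fit$F),
    elite = names(sort(fit$rank)[seq_len(fit$k)]),
    cluster_sizes = clus$sizes,
    cluster_significant_traits = prof$n_significant)
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  say("outputs written to ", config$out_dir)
  invisible(list(table = tab, summary = summ, origin = cmp_origin,
                 period = cmp_period, correlation = corr, fit = fit,
                 clusters = clus, profile = prof, json = summary_json))
}
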