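#' Descriptive summary of a single trait
#'
#' Mean, sample SD (n-1 denominator), coefficient of variation
#' (100 * sd / mean), range, and a Shapiro-Wilk normality screen when the
#' sample is large enough. The CV is the panel's diversity measure; it is
#' scale-invariant and reported in percent.
#'
#' @param values Finite numeric vector, length >= 2.
#' @param trait_code Optional trait code recorded in the output.
#' @return A one-row data.frame with columns `trait_code`, `n`, `mean`,
#'   `sd`, `cv_percent` (NA with a warning if the mean is 0), `min`, `max`,
#'   `normality_p` (NA when n < 8 or the vector is constant).
#' @export
summarize_trait <- function(values, trait_code = NA_character_) {
  if (length(values) < 2) {
    stop("need at least 2 values to summarize", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  cv <- if (m == 0) {
    warning("zero mean: CV undefined", call. = FALSE)
    NA_real_
  } else {
    100 * s / m
  }
  normp <- NA_real_
  if (length(values) >= 8 && s > 0) {
    normp <- stats::shapiro.test(values)$p.value
  }
  data.frame(trait_code = trait_code, n = length(values), mean = m, sd = s,
             cv_percent = cv, min = min(values), max = max(values),
             normality_p = normp, stringsAsFactors = FALSE)
}

#' Descriptive summary of every trait in a table
#'
#' One [summarize_trait()] row per registry trait, in registry order, plus
#' the derived aggregates the panel is usually described by: the combined
#' protein + oil mean, and the means of the per-accession saturated
#' (C14:0 + C16:0 + C18:0 + C20:0) and unsaturated
#' (C16:1 + C18:1 + C18:2 + C18:3) fatty-acid sums.
#'
#' @param table A [trait_table()].
#' @return A list with `traits` (data.frame of 34 summaries) and
#'   `aggregates` (named numeric: `protein_oil_mean`, `sfa_mean`,
#'   `ufa_mean`).
#' @export
summarize_table <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  v <- table$values
  out <- do.call(rbind, lapply(colnames(v), function(tr) {
    summarize_trait(v[, tr], trait_code = tr)
  }))
  reg <- table$registry
  agg <- c(
    protein_oil_mean = mean(v[, "protein"]) + mean(v[, "oil"]),
    sfa_mean = mean(rowSums(v[, family_codes("sfa", reg), drop = FALSE])),
    ufa_mean = mean(rowSums(v[, family_codes("ufa", reg), drop = FALSE]))
  )
  list(traits = out, aggregates = agg)
}

#' Shapiro-Wilk normality screen
#'
#' Advisory check that a trait's panel distribution is compatible with
#' normality; it never gates the pipeline.
#'
#' @param values Finite numeric vector, n >= 8, non-constant.
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p`, and `pass` (`p >= alpha`).
#' @export
check_normality <- function(values, alpha = 0.05) {
  if (length(values) < 8) {
    stop("normality screen needs n >= 8", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("constant vector: normality test undefined", call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       pass = ht$p.value >= alpha)
}

#' Freedman-Diaconis histogram breaks
#'
#' Bin rule used by the report histograms.
#'
#' @param values Numeric vector.
#' @return Breakpoints suitable for [graphics::hist()].
#' @keywords internal
fd_breaks <- function(values) {
  h <- 2 * stats::IQR(values) / length(values)^(1 / 3)
  if (h <= 0) return(3)
  max(1L, ceiling(diff(range(values)) / h))
}
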