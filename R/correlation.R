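#' Pearson correlation matrix with per-pair significance
#'
#' Full pairwise Pearson correlation over the 34 traits with two-sided
#' p-values from the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))`
#' on n - 2 degrees of freedom, and the conventional significance stars
#' (`**` for p < 0.01, `*` for 0.01 <= p < 0.05). No correction is applied
#' across the 561 pairs; stars are raw, as in standard trait-correlation
#' heatmaps.
#'
#' @param table A [trait_table()], n >= 3, all trait columns non-constant.
#' @return Object of class `correlation_result`: list with `r_matrix`,
#'   `p_matrix`, `star_matrix` and `n`.
#' @export
pearson_matrix <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  v <- table$values
  n <- nrow(v)
  if (n < 3) stop("need at least 3 accessions", call. = FALSE)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(v)
  r[r > 1] <- 1
  r[r < -1] <- -1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(r_matrix = r, p_matrix = p, star_matrix = stars, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Pearson correlation over", ncol(x$r_matrix), "traits, n =", x$n, "\n")
  off <- x$p_matrix[upper.tri(x$p_matrix)]
  cat("  pairs:", length(off), "| p<0.05:", sum(off < 0.05),
      "| p<0.01:", sum(off < 0.01), "\n")
  invisible(x)
}

#' Cross-family correlation report
#'
#' All trait pairs between two registry families (or within one, taking
#' distinct unordered pairs), sorted by |r| descending with ties broken by
#' registry order.
#'
#' @param result A [pearson_matrix()] result.
#' @param block_a,block_b Family names accepted by [family_codes()].
#' @param registry Trait registry.
#' @return data.frame with `trait_a`, `trait_b`, `r`, `p`, `stars`.
#' @export
cross_block_report <- function(result, block_a, block_b,
                               registry = trait_registry()) {
  stopifnot(inherits(result, "correlation_result"))
  a <- family_codes(block_a, registry)
  b <- family_codes(block_b, registry)
  if (identical(sort(a), sort(b))) {
    pairs <- t(utils::combn(a, 2))
  } else {
    pairs <- as.matrix(expand.grid(trait_a = a, trait_b = b,
                                   stringsAsFactors = FALSE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  }
  out <- data.frame(trait_a = pairs[, 1], trait_b = pairs[, 2],
                    r = result$r_matrix[pairs],
                    p = result$p_matrix[pairs],
                    stars = result$star_matrix[pairs],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}
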