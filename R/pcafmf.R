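#' Standardize trait columns to zero mean and unit variance
#'
#' Column-wise z-scoring with the sample SD (n - 1 denominator); the first
#' step of correlation-matrix PCA on traits with heterogeneous units.
#'
#' @param x A [trait_table()] or a numeric matrix with trait columns.
#' @return List with `z` (standardized matrix), `means`, `sds`.
#' @export
standardize_traits <- function(x) {
  v <- if (inherits(x, "trait_table")) x$values else as.matrix(x)
  if (nrow(v) < 3) stop("need at least 3 rows to standardize", call. = FALSE)
  mu <- colMeans(v)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait column(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(v, 2, mu, "-"), 2, sds, "/")
  list(z = z, means = mu, sds = sds)
}

#' Principal component analysis of standardized traits
#'
#' Eigendecomposition of the p x p sample correlation matrix (so p > n is
#' allowed). Eigenvalues are returned in descending order; each loading
#' column carries a deterministic sign fixed by [orient_loadings()];
#' scores are `z %*% loadings` and contribution rates are
#' `eigenvalue / p`.
#'
#' @param z Standardized matrix from [standardize_traits()].
#' @param registry Optional trait registry supplying the desirability
#'   orientation for the sign convention; when `NULL` (or when column names
#'   do not match the registry) the fallback convention is used: the
#'   largest-magnitude loading in each column is made positive.
#' @return List of class `pca_model` with `eigenvalues`, `loadings`,
#'   `scores`, `contribution_rates`, `n`, `p`.
#' @export
fit_pca <- function(z, registry = NULL) {
  z <- as.matrix(z)
  R <- stats::cor(z)
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  V <- orient_loadings(e$vectors, colnames(z), registry)
  rownames(V) <- colnames(z)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- z %*% V
  structure(
    list(eigenvalues = lam, loadings = V, scores = scores,
         contribution_rates = lam / ncol(z), n = nrow(z), p = ncol(z)),
    class = "pca_model")
}

#' Deterministic sign convention for loading columns
#'
#' A principal component's sign is arbitrary, but the fuzzy-membership
#' composite is not sign-invariant, so orientation must be fixed. Each
#' column is flipped, if necessary, so that the sum of its loadings on
#' `higher_better` traits minus the sum on `lower_better` traits is
#' non-negative; this points every retained axis "toward quality" (the
#' first component ends up positively associated with protein and the
#' amino acids, negatively with oil). Exact ties - and columns of traits
#' absent from the registry - fall back to making the largest-magnitude
#' loading positive (first such entry on a further tie).
#'
#' @param V Matrix of loading columns.
#' @param trait_codes Row names of `V` / trait codes.
#' @param registry Trait registry or NULL.
#' @return `V` with signs fixed.
#' @export
orient_loadings <- function(V, trait_codes = rownames(V), registry = NULL) {
  w <- numeric(nrow(V))
  if (!is.null(registry) && !is.null(trait_codes) &&
      all(trait_codes %in% registry$code)) {
    des <- registry$desirability[match(trait_codes, registry$code)]
    w <- (des == "higher_better") - (des == "lower_better")
  }
  for (j in seq_len(ncol(V))) {
    s <- sum(w * V[, j])
    if (s < 0) {
      V[, j] <- -V[, j]
    } else if (s == 0) {
      imax <- which.max(abs(V[, j]))[1]
      if (V[imax, j] < 0) V[, j] <- -V[, j]
    }
  }
  V
}

#' Retain components by the Kaiser rule
#'
#' Keeps components whose eigenvalue strictly exceeds `threshold`
#' (default 1: more variance than a single standardized trait).
#'
#' @param model A `pca_model` from [fit_pca()], or a numeric vector of
#'   eigenvalues.
#' @param threshold Eigenvalue cutoff.
#' @return Integer indices of retained components.
#' @export
select_components <- function(model, threshold = 1.0) {
  lam <- if (inherits(model, "pca_model")) model$eigenvalues else model
  keep <- which(lam > threshold)
  if (!length(keep)) {
    stop("no eigenvalue exceeds ", threshold,
         "; lower the threshold to retain at least one component",
         call. = FALSE)
  }
  keep
}

#' Contribution-rate weights over retained components
#'
#' `W_i = CR_i / sum(CR_retained) = lambda_i / sum(lambda_retained)`; the
#' normalization makes the choice of CR denominator (all components or
#' retained only) irrelevant.
#'
#' @param model A `pca_model` or numeric eigenvalues.
#' @param retained Indices from [select_components()].
#' @return Numeric weights summing to 1.
#' @export
compute_weights <- function(model, retained) {
  lam <- if (inherits(model, "pca_model")) model$eigenvalues else model
  if (!length(retained)) stop("no retained components", call. = FALSE)
  w <- lam[retained] / sum(lam[retained])
  stats::setNames(w, paste0("PC", retained))
}

#' Fuzzy membership normalization of component scores
#'
#' Min-max rescaling per component: `U = (X - Xmin) / (Xmax - Xmin)`, so
#' each retained component contributes on a common \[0, 1\] scale with the
#' worst accession at 0 and the best at 1.
#'
#' @param scores Accession x component numeric matrix (or vector).
#' @param degenerate One of `"error"` (default; a zero-range component is
#'   an error) or `"half"` (map a zero-range component to 0.5 everywhere).
#' @return Matrix of memberships in \[0, 1\].
#' @export
membership_normalize <- function(scores, degenerate = c("error", "half")) {
  degenerate <- match.arg(degenerate)
  X <- as.matrix(scores)
  if (nrow(X) < 2) stop("need at least 2 accessions", call. = FALSE)
  U <- X
  for (j in seq_len(ncol(X))) {
    rng <- range(X[, j])
    if (rng[1] == rng[2]) {
      if (degenerate == "error") {
        stop("degenerate component ", j, ": max score equals min score ",
             "(use degenerate = 'half' to map it to 0.5)", call. = FALSE)
      }
      U[, j] <- 0.5
    } else {
      U[, j] <- (X[, j] - rng[1]) / (rng[2] - rng[1])
    }
  }
  U
}

#' Weighted composite score
#'
#' `F = sum_i U_i W_i`: the membership matrix combined with the
#' contribution-rate weights. Lies in \[0, 1\].
#'
#' @param U Membership matrix from [membership_normalize()].
#' @param W Weights from [compute_weights()]; must align with `U` columns.
#' @return Numeric vector of composite scores.
#' @export
composite_score <- function(U, W) {
  U <- as.matrix(U)
  if (ncol(U) != length(W)) {
    stop("U has ", ncol(U), " columns but W has length ", length(W),
         call. = FALSE)
  }
  drop(U %*% W)
}

#' Rank accessions and select the elite fraction
#'
#' Descending sort by composite score with ties broken by accession id
#' (ascending); the elite count is `ceiling(proportion * n)`, so a 5%
#' selection from 259 accessions yields exactly 13.
#'
#' @param F_values Numeric composite scores.
#' @param proportion Top fraction to select, in (0, 1].
#' @param ids Accession identifiers (default names of `F_values` or
#'   indices).
#' @return List with `rank` (1 = best, a permutation of 1..n), `elite`
#'   (logical), `k` (elite count) and `order` (ids best-first).
#' @export
rank_and_select <- function(F_values, proportion = 0.05, ids = NULL) {
  n <- length(F_values)
  if (n < 1) stop("need at least one accession", call. = FALSE)
  if (proportion <= 0 || proportion > 1) {
    stop("proportion must be in (0, 1]", call. = FALSE)
  }
  if (is.null(ids)) ids <- names(F_values)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(-F_values, ids)
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  k <- as.integer(ceiling(proportion * n))
  list(rank = rk, elite = rk <= k, k = k, order = ids[ord])
}

#' Fit the PCA fuzzy-membership composite evaluation model
#'
#' The package's core procedure for comprehensive germplasm evaluation:
#' standardize the 34 traits, eigendecompose their correlation matrix,
#' retain components with eigenvalue > `kaiser`, weight them by their
#' contribution rates, min-max normalize each retained component score to a
#' \[0, 1\] fuzzy membership, and combine into a composite
#' `F = sum(U_i * W_i)` per accession. Accessions are ranked by F and the
#' top `proportion` (ceiling rule) flagged as elite germplasm.
#'
#' @param table A [trait_table()] (or plain numeric matrix; the registry
#'   sign convention then falls back to largest-loading-positive).
#' @param kaiser Eigenvalue retention threshold (strict inequality).
#' @param proportion Elite fraction (default 0.05).
#' @return Object of class `pcafmf` with components `eigenvalues`,
#'   `loadings`, `scores`, `contribution_rates`, `retained`, `weights`,
#'   `membership`, `F` (named by accession), `rank`, `elite`, `k`,
#'   `score_range` (training min/max per retained component), plus the
#'   standardization parameters.
#' @seealso [predict.pcafmf()], [plot.pcafmf()], [rank_and_select()]
#' @examples
#' panel <- generate_germplasm(default_config(seed = 7))
#' fit <- pcafmf(panel$table)
#' fit
#' head(summary(fit)$top)
#' @export
pcafmf <- function(table, kaiser = 1.0, proportion = 0.05) {
  registry <- if (inherits(table, "trait_table")) table$registry else NULL
  ids <- if (inherits(table, "trait_table")) {
    table$accession_id
  } else {
    rownames(table)
  }
  std <- standardize_traits(table)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(std$z)))
  model <- fit_pca(std$z, registry)
  retained <- select_components(model, kaiser)
  W <- compute_weights(model, retained)
  X <- model$scores[, retained, drop = FALSE]
  U <- membership_normalize(X)
  Fv <- stats::setNames(composite_score(U, W), ids)
  sel <- rank_and_select(Fv, proportion, ids)
  structure(
    list(call = match.call(),
         eigenvalues = model$eigenvalues,
         loadings = model$loadings,
         scores = model$scores,
         contribution_rates = model$contribution_rates,
         retained = retained, weights = W,
         membership = U, F = Fv,
         rank = stats::setNames(sel$rank, ids),
         elite = stats::setNames(sel$elite, ids),
         k = sel$k, order = sel$order,
         kaiser = kaiser, proportion = proportion,
         score_range = apply(X, 2, range),
         trait_means = std$means, trait_sds = std$sds,
         registry = registry),
    class = "pcafmf")
}

#' @export
print.pcafmf <- function(x, digits = 3, ...) {
  cat("PCA-FMF comprehensive evaluation\n")
  cat("  accessions:", length(x$F), "| traits:", length(x$trait_means), "\n")
  cat("  retained components (eigenvalue >", x$kaiser, "):",
      length(x$retained), "\n")
  cr <- sum(x$contribution_rates[x$retained])
  cat("  cumulative contribution of retained PCs:",
      sprintf("%.2f%%", 100 * cr), "\n")
  cat("  F range:", paste(sprintf("%.*f", digits, range(x$F)),
                          collapse = " - "),
      "| mean:", sprintf("%.*f", digits, mean(x$F)), "\n")
  cat("  elite (top ", sprintf("%g%%", 100 * x$proportion), "): ",
      x$k, " accessions\n", sep = "")
  invisible(x)
}

#' @export
summary.pcafmf <- function(object, ...) {
  lam <- object$eigenvalues
  comp <- data.frame(
    component = paste0("PC", seq_along(lam)),
    eigenvalue = lam,
    contribution_pct = 100 * object$contribution_rates,
    cumulative_pct = 100 * cumsum(object$contribution_rates),
    retained = seq_along(lam) %in% object$retained)
  ord <- order(object$rank)
  tab <- data.frame(accession_id = names(object$F)[ord],
                    F = unname(object$F[ord]),
                    rank = unname(object$rank[ord]),
                    elite = unname(object$elite[ord]),
                    stringsAsFactors = FALSE)
  out <- list(components = comp, weights = object$weights,
              top = utils::head(tab, object$k), ranking = tab,
              F_mean = mean(object$F),
              pct_above_mean = 100 * mean(object$F > mean(object$F)))
  class(out) <- "summary.pcafmf"
  out
}

#' @export
print.summary.pcafmf <- function(x, ...) {
  cat("Retained components:\n")
  print(x$components[x$components$retained, c("component", "eigenvalue",
                                              "contribution_pct")],
        row.names = FALSE, digits = 4)
  cat("Weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("Mean F: %.3f (%.2f%% of accessions above the mean)\n",
              x$F_mean, x$pct_above_mean))
  cat("Elite accessions:\n")
  print(x$top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.pcafmf <- function(object, ...) object$weights

#' @export
fitted.pcafmf <- function(object, ...) object$F

#' Score new accessions with a fitted PCA-FMF model
#'
#' Applies the training standardization, loadings, membership ranges and
#' weights to new trait data. Memberships of accessions outside the
#' training score range fall outside \[0, 1\] (and so may F); this is
#' deliberate - it flags accessions beyond the evaluated panel rather than
#' silently clamping them.
#'
#' @param object A fitted [pcafmf()] model.
#' @param newdata A [trait_table()] or numeric matrix with the same trait
#'   columns.
#' @param ... Unused.
#' @return List with `scores`, `membership` and `F`.
#' @export
predict.pcafmf <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "trait_table")) newdata$values else
    as.matrix(newdata)
  v <- v[, names(object$trait_means), drop = FALSE]
  z <- sweep(sweep(v, 2, object$trait_means, "-"), 2, object$trait_sds, "/")
  X <- z %*% object$loadings[, object$retained, drop = FALSE]
  rng <- object$score_range
  U <- sweep(sweep(X, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
  list(scores = X, membership = U,
       F = stats::setNames(composite_score(U, object$weights), rownames(v)))
}

#' Diagnostic plots for a PCA-FMF fit
#'
#' Three base-graphics panels: the eigenvalue scree with the Kaiser
#' threshold, the distribution of composite F values with the elite cut,
#' and the accessions on the first two components.
#'
#' @param x A fitted [pcafmf()] model.
#' @param which Subset of `1:3` selecting panels.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.pcafmf <- function(x, which = 1:3, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::plot(x$eigenvalues, type = "b", pch = 19,
                   xlab = "Component", ylab = "Eigenvalue",
                   main = "Scree", ...)
    graphics::abline(h = x$kaiser, lty = 2)
  }
  if (2 %in% which) {
    graphics::hist(x$F, breaks = fd_breaks(x$F), xlab = "Composite F",
                   main = "F distribution", col = "grey85", ...)
    cut <- min(x$F[x$elite])
    graphics::abline(v = cut, lty = 2, col = "red3")
  }
  if (3 %in% which && ncol(x$scores) >= 2) {
    graphics::plot(x$scores[, 1], x$scores[, 2],
                   col = ifelse(x$elite, "red3", "grey40"),
                   pch = ifelse(x$elite, 19, 1),
                   xlab = sprintf("PC1 (%.1f%%)",
                                  100 * x$contribution_rates[1]),
                   ylab = sprintf("PC2 (%.1f%%)",
                                  100 * x$contribution_rates[2]),
                   main = "Accessions", ...)
  }
  invisible(x)
}
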