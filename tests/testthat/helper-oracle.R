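# Independent straight-line oracle for the PCA fuzzy-membership composite.
# Deliberately shares no code with the package: standardization by explicit
# loops, eigenstructure through the SVD of the standardized matrix (the
# package eigendecomposes the correlation matrix), and the same documented
# sign convention re-derived from scratch.
pcafmf_oracle <- function(values, registry = NULL, kaiser = 1,
                          proportion = 0.05) {
  v <- as.matrix(values)
  n <- nrow(v)
  p <- ncol(v)
  z <- matrix(0, n, p)
  for (j in seq_len(p)) {
    m <- sum(v[, j]) / n
    s <- sqrt(sum((v[, j] - m)^2) / (n - 1))
    z[, j] <- (v[, j] - m) / s
  }
  sv <- svd(z)
  lam <- sv$d^2 / (n - 1)
  V <- sv$v
  # orientation: quality-weighted loading sum non-negative, else largest
  # |loading| positive
  w <- rep(0, p)
  if (!is.null(registry) && !is.null(colnames(v)) &&
      all(colnames(v) %in% registry$code)) {
    d <- registry$desirability[match(colnames(v), registry$code)]
    w <- ifelse(d == "higher_better", 1, ifelse(d == "lower_better", -1, 0))
  }
  for (j in seq_len(ncol(V))) {
    s <- sum(w * V[, j])
    flip <- if (s < 0) TRUE else if (s > 0) FALSE else {
      V[which.max(abs(V[, j]))[1], j] < 0
    }
    if (flip) V[, j] <- -V[, j]
  }
  keep <- which(lam > kaiser)
  Wts <- lam[keep] / sum(lam[keep])
  X <- z %*% V[, keep, drop = FALSE]
  U <- X
  for (j in seq_along(keep)) {
    lo <- min(X[, j]); hi <- max(X[, j])
    U[, j] <- (X[, j] - lo) / (hi - lo)
  }
  Fv <- as.numeric(U %*% Wts)
  list(eigenvalues = lam, retained = keep, weights = Wts, scores = X,
       membership = U, F = Fv)
}
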