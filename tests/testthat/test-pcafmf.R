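test_that("standardization meets its contract and is idempotent", {
  m <- matrix(c(1, 2, 3, 5, 5.5, 9), 3, 2)
  std <- standardize_traits(m)
  expect_equal(std$z[, 1], c(-1, 0, 1))
  expect_lt(max(abs(colMeans(std$z))), 1e-12)
  expect_lt(max(abs(apply(std$z, 2, sd) - 1)), 1e-12)
  expect_equal(standardize_traits(std$z)$z, std$z, tolerance = 1e-12)
  mm <- cbind(m, c(4, 4, 4))
  colnames(mm) <- c("a", "b", "c")
  expect_error(standardize_traits(mm), "c")
})

test_that("2x2 correlation PCA has closed-form eigenvalues 1 +/- r", {
  set.seed(8)
  x <- rnorm(200)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(200)
  z <- standardize_traits(cbind(x, y))$z
  r <- cor(z)[1, 2]
  model <- fit_pca(z)
  expect_equal(model$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-10)
  # independent columns: eigenvalues both near 1
  z2 <- standardize_traits(matrix(rnorm(4000), 2000, 2))$z
  expect_equal(fit_pca(z2)$eigenvalues, c(1, 1), tolerance = 0.1)
})

test_that("trace identity and basic invariants hold on the full panel", {
  tab <- generate_germplasm(default_config(seed = 2))$table
  fit <- pcafmf(tab)
  expect_equal(sum(fit$eigenvalues), 34, tolerance = 1e-8)
  expect_equal(sum(fit$contribution_rates), 1, tolerance = 1e-10)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  expect_equal(unname(apply(fit$membership, 2, min)), rep(0, length(fit$retained)))
  expect_equal(unname(apply(fit$membership, 2, max)), rep(1, length(fit$retained)))
  expect_true(all(fit$F >= 0 & fit$F <= 1))
  expect_setequal(fit$rank, seq_along(fit$F))
  # loadings orthonormal; scores centred
  G <- crossprod(fit$loadings)
  expect_equal(G, diag(34), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(fit$scores))), 1e-10)
})

test_that("component selection is strict and degenerate-safe", {
  expect_equal(select_components(c(2.5, 1.2, 0.9, 0.4)), c(1L, 2L))
  expect_equal(select_components(c(2.5, 1.0, 0.5)), 1L)   # exactly 1 excluded
  expect_error(select_components(c(1.0)), "threshold")
  expect_equal(select_components(c(0.8, 0.7), threshold = 0.5), c(1L, 2L))
})

test_that("weights, membership and composite follow the formulas", {
  expect_equal(unname(compute_weights(c(3, 1), 1:2)), c(0.75, 0.25))
  expect_equal(unname(compute_weights(c(5, 2, 2), 1)), 1.0)
  w <- compute_weights(c(2.2, 1.6, 1.1), 1:3)
  expect_equal(unname(w), c(2.2, 1.6, 1.1) / 4.9, tolerance = 1e-12)

  expect_equal(membership_normalize(cbind(c(1, 3, 5)))[, 1], c(0, 0.5, 1))
  expect_equal(membership_normalize(cbind(c(-2, 0, 2)))[, 1], c(0, 0.5, 1))
  expect_error(membership_normalize(cbind(c(2, 2, 2))), "degenerate")
  expect_equal(membership_normalize(cbind(c(2, 2, 2)),
                                    degenerate = "half")[, 1],
               rep(0.5, 3))

  expect_equal(composite_score(rbind(c(1, 1)), c(0.6, 0.4)), 1.0)
  expect_equal(composite_score(rbind(c(0, 0)), c(0.6, 0.4)), 0.0)
  expect_equal(composite_score(rbind(c(0.5, 0.25)), c(0.75, 0.25)), 0.4375)
  expect_error(composite_score(rbind(c(1, 1)), c(1)), "columns")
})

test_that("ranking uses the ceiling rule with id tie-breaks", {
  expect_equal(rank_and_select(runif(259), 0.05)$k, 13L)
  expect_equal(rank_and_select(runif(100), 0.05)$k, 5L)
  expect_equal(rank_and_select(runif(10), 0.05)$k, 1L)
  sel <- rank_and_select(c(a2 = 0.5, a1 = 0.5, b = 0.9), 1 / 3)
  expect_equal(sel$order, c("b", "a1", "a2"))
  expect_equal(sel$rank, c(3L, 2L, 1L))
  expect_error(rank_and_select(numeric(0)), "at least one")
  expect_error(rank_and_select(1:3, proportion = 0), "proportion")
})

test_that("full evaluation matches the independent straight-line oracle", {
  # random small tables, plain matrices (fallback sign convention)
  for (seed in 1:25) {
    set.seed(seed)
    v <- matrix(rnorm(30 * 8, 50, 5), 30, 8)
    fit <- pcafmf(v)
    orc <- pcafmf_oracle(v)
    expect_equal(unname(fit$F), orc$F, tolerance = 1e-8,
                 info = paste("seed", seed))
    expect_equal(fit$eigenvalues[fit$retained],
                 orc$eigenvalues[orc$retained], tolerance = 1e-8)
  }
  # and with the registry sign convention on full 34-trait tables
  for (seed in 26:30) {
    tab <- generate_germplasm(default_config(n_accessions = 40,
                                             seed = seed))$table
    fit <- pcafmf(tab)
    orc <- pcafmf_oracle(tab$values, registry = tab$registry)
    expect_equal(unname(fit$F), orc$F, tolerance = 1e-8,
                 info = paste("table seed", seed))
  }
})

test_that("evaluation is deterministic and affine-invariant", {
  tab <- generate_germplasm(default_config(seed = 7))$table
  f1 <- pcafmf(tab)
  f2 <- pcafmf(tab)
  expect_identical(f1$F, f2$F)

  # positive per-trait rescaling and shifts leave F unchanged; applied on
  # the raw matrix (no [0,100] validator) so every trait can be transformed
  set.seed(1)
  scl <- runif(34, 0.5, 1.6)
  sft <- runif(34, -5, 5)
  v2 <- sweep(sweep(tab$values, 2, scl, "*"), 2, sft, "+")
  f_raw <- pcafmf(tab$values)
  f_aff <- pcafmf(v2)
  expect_equal(unname(f_aff$F), unname(f_raw$F), tolerance = 1e-10)
})

test_that("an accession dominating every quality-oriented trait ranks first", {
  set.seed(14)
  cfg <- default_config(n_accessions = 60, seed = 14)
  tab <- generate_germplasm(cfg)$table
  reg <- tab$registry
  hi <- reg$desirability == "higher_better"
  lo <- reg$desirability == "lower_better"
  v <- tab$values
  v[1, hi] <- apply(v[, hi, drop = FALSE], 2, max) * 1.05
  v[1, lo] <- apply(v[, lo, drop = FALSE], 2, min) * 0.95
  v <- pmin(v, 100)
  tab$values <- v
  fit <- pcafmf(tab)
  expect_equal(unname(fit$rank[1]), 1L)
  expect_true(fit$elite[1])
})

test_that("the sign convention is pinned: flipping a component flips U", {
  tab <- generate_germplasm(default_config(seed = 9))$table
  std <- standardize_traits(tab)
  model <- fit_pca(std$z, tab$registry)
  # PC1 oriented toward quality: positive on protein, negative on oil
  expect_gt(model$loadings["protein", 1], 0)
  expect_lt(model$loadings["oil", 1], 0)
  retained <- select_components(model)
  X <- model$scores[, retained, drop = FALSE]
  U <- membership_normalize(X)
  Xf <- X
  Xf[, 1] <- -Xf[, 1]
  Uf <- membership_normalize(Xf)
  expect_equal(Uf[, 1], 1 - U[, 1], tolerance = 1e-12)
  W <- compute_weights(model, retained)
  expect_false(isTRUE(all.equal(composite_score(U, W),
                                composite_score(Uf, W))))
})

test_that("model methods expose the fit coherently", {
  tab <- generate_germplasm(default_config(seed = 4))$table
  fit <- pcafmf(tab)
  expect_equal(coef(fit), fit$weights)
  expect_equal(fitted(fit), fit$F)
  s <- summary(fit)
  expect_equal(nrow(s$top), fit$k)
  expect_equal(s$ranking$F, sort(fit$F, decreasing = TRUE),
               ignore_attr = TRUE)
  pr <- predict(fit, tab)
  expect_equal(pr$F, fit$F, tolerance = 1e-12)
  out <- capture.output(print(fit))
  expect_true(any(grepl("elite", out)))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
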