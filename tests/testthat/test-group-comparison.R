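test_that("one-way ANOVA matches its defining identities", {
  # no between-group variance
  av <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(av$f_statistic, 0)
  expect_equal(av$p_value, 1)

  # k = 2 balanced: F equals the squared pooled t statistic
  set.seed(21)
  x <- rnorm(30); y <- rnorm(30, 0.8)
  av2 <- one_way_anova(c(x, y), rep(c("a", "b"), each = 30))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(av2$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av2$p_value, tt$p.value, tolerance = 1e-10)

  # agreement with the stock aov fit on unbalanced noisy groups
  set.seed(22)
  g <- factor(rep(c("a", "b", "c"), times = c(7, 12, 5)))
  v <- rnorm(24) + as.integer(g)
  av3 <- one_way_anova(v, g)
  ref <- summary(stats::aov(v ~ g))[[1]]
  expect_equal(av3$f_statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(av3$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # huge planted shift is essentially always detected
  set.seed(23)
  v4 <- c(rnorm(20, 0), rnorm(20, 10))
  expect_lt(one_way_anova(v4, rep(c("a", "b"), each = 20))$p_value, 1e-4)

  expect_error(one_way_anova(1:5, c("a", "a", "a", "a", "b")), "fewer than 2")
  expect_error(one_way_anova(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("ANOVA F is location-invariant and scale-invariant", {
  set.seed(31)
  v <- rnorm(45)
  g <- rep(c("a", "b", "c"), each = 15)
  f0 <- one_way_anova(v, g)$f_statistic
  expect_equal(one_way_anova(v + 100, g)$f_statistic, f0, tolerance = 1e-9)
  expect_equal(one_way_anova(v * 7.3, g)$f_statistic, f0, tolerance = 1e-9)
})

test_that("Tukey HSD reduces to the two-sample t test at k = 2", {
  set.seed(41)
  x <- rnorm(18); y <- rnorm(13, 0.5)   # deliberately unbalanced
  tk <- tukey_hsd(c(x, y), rep(c("a", "b"), times = c(18, 13)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk$p_matrix["a", "b"], tt$p.value, tolerance = 1e-6)
  expect_equal(tk$p_matrix, t(tk$p_matrix))
  expect_equal(diag(tk$p_matrix), c(a = 1, b = 1))
})

test_that("Tukey p-values behave across identical and separated groups", {
  tk0 <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_gte(min(tk0$p_matrix), 0.999)

  # monotone: p non-increasing in mean separation, all else fixed
  base <- rnorm(30)
  ps <- vapply(c(0.5, 1, 2, 4), function(d) {
    tukey_hsd(c(base, base + d), rep(c("a", "b"), each = 30))$p_matrix["a", "b"]
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))

  # 3 groups at 0/0/5: only the pairs with group c separate
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    v <- c(rnorm(30), rnorm(30), rnorm(30, 5))
    g <- rep(c("a", "b", "c"), each = 30)
    sig <- tukey_hsd(v, g)$significant
    sig["a", "c"] && sig["b", "c"] && !sig["a", "b"]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("compact letter display shares letters exactly with non-significance", {
  no_sig <- matrix(FALSE, 3, 3, dimnames = list(c("x", "y", "z"),
                                                c("x", "y", "z")))
  expect_equal(unname(compact_letter_display(no_sig, c(x = 3, y = 2, z = 1))),
               c("a", "a", "a"))

  all_sig <- !diag(3) == 1
  dimnames(all_sig) <- dimnames(no_sig)
  expect_equal(unname(compact_letter_display(all_sig, c(x = 3, y = 2, z = 1))),
               c("a", "b", "c"))

  chain <- no_sig
  chain["x", "z"] <- chain["z", "x"] <- TRUE
  expect_equal(unname(compact_letter_display(chain, c(x = 3, y = 2, z = 1))),
               c("a", "ab", "b"))

  expect_error(compact_letter_display(matrix(c(FALSE, TRUE, FALSE, FALSE),
                                             2, 2)),
               "symmetric")
})

test_that("letter sharing matches the input matrix on exhaustive random cases", {
  share_letter <- function(a, b) {
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  }
  set.seed(99)
  for (trial in 1:60) {
    k <- sample(3:6, 1)
    sig <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(sig))
    sig[pairs] <- runif(length(pairs)) < 0.4
    sig <- sig | t(sig)
    dimnames(sig) <- list(paste0("L", 1:k), paste0("L", 1:k))
    means <- setNames(rnorm(k), rownames(sig))
    ltr <- compact_letter_display(sig, means)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        expect_identical(share_letter(ltr[i], ltr[j]), !sig[i, j],
                         info = sprintf("trial %d pair %d-%d", trial, i, j))
      }
    }
  }
})

test_that("ANOVA/Tukey type-I error is calibrated near alpha", {
  set.seed(7)
  rejections <- 0L
  n_tests <- 200L
  for (i in seq_len(n_tests)) {
    v <- rnorm(60)
    g <- rep(c("a", "b", "c"), each = 20)
    if (one_way_anova(v, g)$p_value < 0.05) rejections <- rejections + 1L
  }
  # binomial(200, 0.05): mean 10, sd ~3.1
  expect_gte(rejections, 2)
  expect_lte(rejections, 21)
})

test_that("significant-trait counting recovers a planted 23-of-26 pattern", {
  nut <- family_codes("nutritional")
  null_traits <- c("C14_0", "C18_0", "C16_1")
  affected <- setdiff(nut, null_traits)
  res <- vapply(1:8, function(seed) {
    cfg <- default_config(seed = seed)
    sds <- cfg$trait_means * cfg$trait_cvs / 100
    cfg$origin_effects[] <- 0
    cfg$period_effects[] <- 0
    cfg$origin_effects["NIR", affected] <- sds[affected]
    cfg$origin_effects["FOR", affected] <- -0.5 * sds[affected]
    tab <- generate_germplasm(cfg)$table
    flags <- count_significant_traits(tab, "origin")$flags
    c(planted = sum(flags[affected]), false = sum(flags[null_traits]))
  }, numeric(2))
  # every planted 1-SD shift is recovered; the unshifted traits fire only
  # at the type-I rate
  expect_gte(mean(res["planted", ] == 23), 0.95)
  expect_lte(mean(res["false", ]), 3 * 0.05 * 4)

  # null calibration: with no effects the expected count is ~26 * alpha
  null_counts <- vapply(1:30, function(seed) {
    cfg <- default_config(seed = 100 + seed)
    cfg$origin_effects[] <- 0
    cfg$period_effects[] <- 0
    count_significant_traits(generate_germplasm(cfg)$table, "origin")$count
  }, numeric(1))
  expect_lt(abs(mean(null_counts) - 26 * 0.05), 2)

  tab1 <- generate_germplasm(default_config(seed = 1))$table
  expect_error(count_significant_traits(tab1, grouping = rep("g", 259)),
               "at least 2 groups")
})

test_that("compare_groups assembles results with letters per level", {
  tab <- generate_germplasm(default_config(seed = 3))$table
  cmp <- compare_groups(tab, "origin")
  expect_equal(nrow(cmp$results), 26)
  expect_equal(colnames(cmp$letters), levels(droplevels(tab$origin)))
  expect_true(all(nchar(cmp$letters) >= 1))
  expect_equal(cmp$n_significant, sum(cmp$results$p_value < 0.05))
})
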