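#' One-way ANOVA for a single trait across groups
#'
#' Classic fixed-effects one-way ANOVA: F is the between/within mean-square
#' ratio with (k - 1, N - k) degrees of freedom. The degenerate case of zero
#' between-group variance (identical group means with zero within-group
#' spread included) is reported as F = 0, p = 1 rather than NaN.
#'
#' @param values Numeric vector.
#' @param groups Vector/factor of group labels; every group must have at
#'   least 2 observations and there must be at least 2 groups.
#' @return List with `f_statistic`, `p_value`, `df` (c(k-1, N-k)) and
#'   `group_means`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  .check_groups(values, groups)
  N <- length(values)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_between <- sum(tabulate(groups) * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df1 <- k - 1
  df2 <- N - k
  if (ss_between <= .Machine$double.eps * max(1, sum(values^2))) {
    f <- 0
    p <- 1
  } else if (ss_within == 0) {
    f <- Inf
    p <- 0
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(f_statistic = f, p_value = p, df = c(df1, df2),
       group_means = gm)
}

.check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  if (nlevels(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  cnt <- table(groups)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise adjusted p-values from the studentized-range distribution,
#' using the Tukey-Kramer correction for unequal group sizes (the origin
#' groups of a germplasm panel are rarely balanced). Implemented through
#' [stats::aov()] + [stats::TukeyHSD()].
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level used for the `significant` matrix.
#' @return List with `p_matrix` (symmetric, diagonal 1 by convention),
#'   `significant` (logical matrix, `p < alpha`), `group_means`, `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  .check_groups(values, groups)
  lev <- levels(groups)
  k <- length(lev)
  # hyphen-free placeholder levels so TukeyHSD pair labels parse cleanly
  safe <- factor(paste0("g", as.integer(groups)),
                 levels = paste0("g", seq_len(k)))
  fit <- stats::aov(values ~ safe, data = data.frame(values, safe))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$safe
  pm <- matrix(1, k, k, dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- as.integer(sub("^g", "", pairs[[i]][1]))
    b <- as.integer(sub("^g", "", pairs[[i]][2]))
    pm[a, b] <- pm[b, a] <- tk[i, "p adj"]
  }
  # constant-data degeneracy: TukeyHSD yields NaN when all values coincide
  pm[is.nan(pm)] <- 1
  list(p_matrix = pm, significant = pm < alpha,
       group_means = tapply(values, groups, mean), alpha = alpha)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-absorb algorithm: start from a single letter shared by all
#' levels; for each significantly different pair, split every letter column
#' that still contains both; absorb columns that become subsets of others.
#' Letters are then ordered so that levels with larger means receive
#' earlier letters, making the display deterministic. Two levels share a
#' letter if and only if they are not significantly different.
#'
#' @param significant Symmetric logical matrix (TRUE = significantly
#'   different), dimnames giving the level names.
#' @param means Optional named numeric vector of level means used to order
#'   letters (defaults to reverse input order weights of zero, i.e. input
#'   order).
#' @return Named character vector of letter strings, one per level.
#' @examples
#' m <- matrix(FALSE, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' m["a", "c"] <- m["c", "a"] <- TRUE
#' compact_letter_display(m, c(a = 3, b = 2, c = 1))
#' @export
compact_letter_display <- function(significant, means = NULL) {
  stopifnot(is.matrix(significant), nrow(significant) == ncol(significant))
  if (!isTRUE(all.equal(significant, t(significant)))) {
    stop("significance matrix must be symmetric", call. = FALSE)
  }
  lev <- rownames(significant)
  if (is.null(lev)) lev <- as.character(seq_len(nrow(significant)))
  k <- length(lev)
  if (is.null(means)) means <- stats::setNames(rev(seq_len(k)), lev)
  cols <- list(lev)                      # each column = set of levels sharing a letter
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!significant[i, j]) next
      for (c_idx in seq_along(cols)) {
        col <- cols[[c_idx]]
        if (all(c(lev[i], lev[j]) %in% col)) {
          cols[[c_idx]] <- setdiff(col, lev[i])
          cols[[length(cols) + 1]] <- setdiff(col, lev[j])
        }
      }
      # absorb: drop columns contained in another column
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[b] &&
              all(cols[[a]] %in% cols[[b]]) &&
              (length(cols[[a]]) < length(cols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order letters: a column's rank is the best (largest) mean it contains
  best <- vapply(cols, function(col) max(means[col]), numeric(1))
  cols <- cols[order(-best)]
  letters_out <- stats::setNames(character(k), lev)
  for (c_idx in seq_along(cols)) {
    ch <- .letter_label(c_idx)
    for (l in cols[[c_idx]]) {
      letters_out[l] <- paste0(letters_out[l], ch)
    }
  }
  letters_out
}

.letter_label <- function(i) {
  if (i <= 26) return(letters[i])
  paste0(letters[((i - 1) %/% 26)], letters[((i - 1) %% 26) + 1])
}

#' Per-trait group comparison with Tukey letters
#'
#' Runs [one_way_anova()] and [tukey_hsd()] for each trait across the
#' chosen grouping variable and attaches a compact letter display ordered
#' by descending group mean.
#'
#' @param table A [trait_table()].
#' @param grouping `"origin"` or `"period"`, or a custom factor of length
#'   n accessions (e.g. cluster labels).
#' @param traits Trait codes to test (default: the 26 nutritional traits).
#' @param alpha Significance level for both the ANOVA flag and the letters.
#' @return Object of class `group_comparison`: list with `results`
#'   (data.frame: trait_code, f_statistic, p_value, significant),
#'   `letters` (trait x level letter matrix), `group_means` (trait x level),
#'   `grouping`, `alpha`, and `n_significant`.
#' @export
compare_groups <- function(table, grouping = c("origin", "period"),
                           traits = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "trait_table"))
  if (is.character(grouping) && length(grouping) == 1) {
    grouping <- match.arg(grouping)
    g <- table[[grouping]]
    gname <- grouping
  } else {
    g <- as.factor(grouping)
    gname <- "custom"
  }
  g <- droplevels(g)
  if (is.null(traits)) traits <- family_codes("nutritional", table$registry)
  lev <- levels(g)
  res <- data.frame(trait_code = traits, f_statistic = NA_real_,
                    p_value = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  letter_m <- matrix(NA_character_, length(traits), length(lev),
                     dimnames = list(traits, lev))
  mean_m <- matrix(NA_real_, length(traits), length(lev),
                   dimnames = list(traits, lev))
  for (i in seq_along(traits)) {
    v <- table$values[, traits[i]]
    av <- one_way_anova(v, g)
    res$f_statistic[i] <- av$f_statistic
    res$p_value[i] <- av$p_value
    res$significant[i] <- av$p_value < alpha
    tk <- tukey_hsd(v, g, alpha = alpha)
    letter_m[i, ] <- compact_letter_display(tk$significant, av$group_means)
    mean_m[i, ] <- av$group_means[lev]
  }
  structure(
    list(results = res, letters = letter_m, group_means = mean_m,
         grouping = gname, alpha = alpha,
         n_significant = sum(res$significant)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison by ", x$grouping, " (alpha = ", x$alpha, ")\n",
      sep = "")
  cat(x$n_significant, "of", nrow(x$results),
      "traits significantly different\n")
  invisible(x)
}

#' Count traits differing significantly across groups
#'
#' Runs a per-trait one-way ANOVA (no multiple-testing correction, matching
#' standard germplasm-panel reporting) and counts traits with p below
#' `alpha`.
#'
#' @inheritParams compare_groups
#' @return List with `count` and `flags` (named logical per trait).
#' @export
count_significant_traits <- function(table, grouping = c("origin", "period"),
                                     traits = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "trait_table"))
  if (is.character(grouping) && length(grouping) == 1) {
    grouping <- match.arg(grouping)
    g <- table[[grouping]]
  } else {
    g <- as.factor(grouping)
  }
  g <- droplevels(g)
  if (is.null(traits)) traits <- family_codes("nutritional", table$registry)
  flags <- vapply(traits, function(tr) {
    one_way_anova(table$values[, tr], g)$p_value < alpha
  }, logical(1))
  list(count = sum(flags), flags = flags)
}
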