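#' Hierarchical clustering of accessions on standardized traits
#'
#' Agglomerative clustering (Ward by default, on Euclidean distance over
#' standardized traits) cut at `k` groups. Cluster labels are canonical:
#' clusters are renumbered by decreasing size, ties broken by the smallest
#' member accession id, so the same data always yields the same labels
#' regardless of input row order.
#'
#' @param table A [trait_table()] (standardized internally) or an already
#'   standardized numeric matrix.
#' @param k Number of clusters (default 4); must satisfy 1 <= k <= n.
#' @param linkage `"ward"` (Ward D2), `"average"` or `"complete"`.
#' @return Object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector), `k`, `sizes`, `linkage`, `hclust` (the tree)
#'   and `cophenetic` (distances retained for audit).
#' @export
hierarchical_cluster <- function(table, k = 4,
                                 linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  z <- if (inherits(table, "trait_table")) {
    standardize_traits(table)$z
  } else {
    as.matrix(table)
  }
  n <- nrow(z)
  if (k > n) stop("k = ", k, " exceeds the ", n, " accessions", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  ids <- rownames(z)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  d <- stats::dist(z)
  hc <- stats::hclust(d, method = method)
  raw <- stats::cutree(hc, k = k)
  cl <- .relabel_clusters(raw, ids)
  structure(
    list(cluster = stats::setNames(cl, ids), k = k,
         sizes = as.integer(table(cl)), linkage = linkage, hclust = hc,
         cophenetic = stats::cophenetic(hc)),
    class = "cluster_assignment")
}

# canonical labels: decreasing size, ties by smallest member id
.relabel_clusters <- function(raw, ids) {
  sizes <- table(raw)
  first_id <- tapply(ids, raw, function(x) min(sort(x)))
  ord <- order(-as.integer(sizes), first_id[names(sizes)])
  map <- stats::setNames(seq_along(ord), names(sizes)[ord])
  as.integer(map[as.character(raw)])
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, "): k = ", x$k, "\n", sep = "")
  cat("  sizes:", paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Export a cluster dendrogram in Newick format
#'
#' @param assignment A [hierarchical_cluster()] result.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_dendrogram <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ape::write.tree(ape::as.phylo(assignment$hclust), file = path)
  invisible(path)
}

#' Per-trait profiling of cluster differences
#'
#' Re-uses the group-comparison machinery with the cluster labels as the
#' grouping factor: per-trait one-way ANOVA with Tukey letters over all 34
#' traits, plus the count of traits differing at `alpha`.
#'
#' @param table The [trait_table()] that was clustered.
#' @param assignment A [hierarchical_cluster()] result.
#' @param alpha Significance level.
#' @return A [compare_groups()] object (grouping `"cluster"`), with the
#'   cluster sizes attached.
#' @export
profile_clusters <- function(table, assignment, alpha = 0.05) {
  stopifnot(inherits(table, "trait_table"),
            inherits(assignment, "cluster_assignment"))
  cl <- assignment$cluster[table$accession_id]
  singles <- names(table(cl))[table(cl) < 2]
  if (length(singles)) {
    stop("cluster(s) with a single accession cannot be profiled: ",
         paste(singles, collapse = ", "), call. = FALSE)
  }
  out <- compare_groups(table, grouping = factor(cl),
                        traits = table$registry$code, alpha = alpha)
  out$grouping <- "cluster"
  out$sizes <- assignment$sizes
  out
}
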