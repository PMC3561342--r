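#' Spearman correlation matrix between sample profiles
#'
#' Pairwise Spearman correlation of sample expression profiles (ties get
#' average ranks). A sample with a constant profile has no defined rank
#' correlation and yields `NA` entries.
#'
#' @param x An [expr_matrix()] with at least 2 samples and 2 genes.
#' @return Symmetric samples-by-samples correlation matrix, unit diagonal.
#' @export
spearman_matrix <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2 || nrow(x$values) < 2)
    stop_input("need at least 2 samples and 2 genes")
  rho <- suppressWarnings(stats::cor(x$values, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Hierarchical clustering of samples from a correlation matrix
#'
#' Agglomerates samples on distance `1 - rho` with the chosen linkage
#' (average/UPGMA by default). Samples are processed in lexicographic id
#' order so tie-breaks are deterministic.
#'
#' @param corr Correlation matrix from [spearman_matrix()].
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(corr, linkage = c("average", "complete",
                                                   "single")) {
  linkage <- match.arg(linkage)
  if (anyNA(corr)) {
    bad <- unique(rownames(corr)[which(is.na(corr), arr.ind = TRUE)[, 1]])
    stop_input("undefined correlations involving sample(s): %s",
               paste(bad, collapse = ", "))
  }
  ord <- order(rownames(corr))
  d <- stats::as.dist(1 - corr[ord, ord])
  stats::hclust(d, method = linkage)
}

#' Cut a sample dendrogram into k clusters and score label purity
#'
#' Purity is the fraction of samples whose cluster's majority label matches
#' their own label.
#'
#' @param tree `hclust` tree from [hierarchical_cluster()].
#' @param k Number of clusters, `1 <= k <=` number of samples.
#' @param labels Named character vector, sample id -> group label.
#' @return List with `partition` (named cluster ids) and `purity`.
#' @export
cut_k <- function(tree, k, labels) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop_input("k must be in [1, %d]", n)
  part <- stats::cutree(tree, k = k)
  lab <- labels[names(part)]
  agree <- vapply(split(lab, part), function(g) max(table(g)), numeric(1))
  list(partition = part, purity = sum(agree) / n)
}

#' Export a sample dendrogram as newick
#' @param tree `hclust` tree.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
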