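#' Expression breadth of every gene within one group
#'
#' Breadth is the number of a group's samples in which the gene's expression
#' strictly exceeds the background threshold.
#'
#' @param x An [expr_matrix()].
#' @param threshold Background threshold (RPKM).
#' @param group `"normal"` or `"cancer"`.
#' @return Named integer vector, gene -> breadth in `[0, group size]`.
#' @export
expression_breadth <- function(x, threshold, group) {
  if (threshold < 0) stop_input("threshold must be >= 0")
  gv <- group_values(x, group)
  rowSums(gv > threshold)
}

#' Housekeeping genes of one group
#'
#' A gene is HK for a group when it is expressed above background in every
#' sample of that group (breadth = group size; strict ubiquity).
#'
#' @inheritParams expression_breadth
#' @param min_breadth_fraction Required fraction of the group's samples
#'   (default 1, i.e. all of them).
#' @return Character vector of HK gene ids.
#' @export
define_hk <- function(x, threshold, group, min_breadth_fraction = 1) {
  b <- expression_breadth(x, threshold, group)
  size <- sum(x$samples$group == group)
  names(b)[b >= ceiling(min_breadth_fraction * size)]
}

#' Five-type housekeeping classification
#'
#' Given the two groups' HK sets, partitions all genes into `shared`
#' (HK in both), `normal_unique` (HK only in normal), `cancer_associated`
#' (HK only in cancer) and `non_HK`. The two derived sets of the five-type
#' scheme are `normal_HK = shared + normal_unique` and
#' `cancer_HK = shared + cancer_associated`.
#'
#' @param normal_hk,cancer_hk Character vectors of HK gene ids per group.
#' @param all_genes Character vector of every gene id.
#' @return An `hk_catalog`: list with per-gene `class` (named character),
#'   the four base sets, the two derived sets, and per-class `counts`.
#' @export
classify_five_types <- function(normal_hk, cancer_hk, all_genes) {
  if (!all(normal_hk %in% all_genes) || !all(cancer_hk %in% all_genes))
    stop_input("HK sets must be subsets of all_genes")
  shared <- intersect(normal_hk, cancer_hk)
  normal_unique <- setdiff(normal_hk, cancer_hk)
  cancer_associated <- setdiff(cancer_hk, normal_hk)
  non_hk <- setdiff(all_genes, union(normal_hk, cancer_hk))
  cls <- setNames(rep("non_HK", length(all_genes)), all_genes)
  cls[shared] <- "shared"
  cls[normal_unique] <- "normal_unique"
  cls[cancer_associated] <- "cancer_associated"
  structure(list(
    class = cls,
    shared = shared,
    normal_unique = normal_unique,
    cancer_associated = cancer_associated,
    non_HK = non_hk,
    normal_HK = normal_hk,
    cancer_HK = cancer_hk,
    counts = c(shared = length(shared),
               normal_unique = length(normal_unique),
               cancer_associated = length(cancer_associated),
               non_HK = length(non_hk),
               normal_HK = length(normal_hk),
               cancer_HK = length(cancer_hk))
  ), class = "hk_catalog")
}

#' Catalog accounting over a locus total
#'
#' Per-class counts with percentages of `total_loci`, rounded half-up to
#' integer percent (the convention behind headline fractions like "47%").
#'
#' @param catalog An `hk_catalog`.
#' @param total_loci Total number of loci the percentages refer to.
#' @return `data.frame` with columns `set`, `count`, `pct_of_loci`.
#' @export
catalog_accounting <- function(catalog, total_loci) {
  stopifnot(inherits(catalog, "hk_catalog"))
  if (total_loci < length(catalog$class))
    stop_input("total_loci smaller than the number of classified genes")
  counts <- catalog$counts
  data.frame(
    set = names(counts),
    count = as.integer(counts),
    pct_of_loci = round_half_up(100 * counts / total_loci),
    row.names = NULL
  )
}
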