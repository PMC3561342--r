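#' FPR/FNR curves between exonic and intergenic expression
#'
#' For every candidate threshold `t` (the sorted unique union of observed
#' values plus 0), counts the negative-set values above `t` (false positives)
#' and the positive-set values at or below `t` (false negatives):
#' `FPR(t) = FP / (FP + TN)`, `FNR(t) = FN / (FN + TP)`. "Expressed" always
#' means strictly greater than the threshold. FPR is non-increasing and FNR
#' non-decreasing along the candidates.
#'
#' @param positive_values Expression of genes (exonic signal), non-negative.
#' @param negative_values Expression of intergenic regions, non-negative.
#' @return A `background_model` list: `candidates`, `fpr`, `fnr`, and the
#'   per-candidate confusion counts `fp`, `tn`, `fn`, `tp`.
#' @export
fpr_fnr_curve <- function(positive_values, negative_values) {
  if (length(positive_values) == 0) stop_input("positive set is empty")
  if (length(negative_values) == 0) stop_input("negative set is empty")
  if (any(positive_values < 0) || any(negative_values < 0))
    stop_input("expression values must be non-negative")
  cand <- sort(unique(c(0, positive_values, negative_values)))
  # #{negative > t} via counts of negatives <= t
  tn <- vapply(cand, function(t) sum(negative_values <= t), numeric(1))
  fn <- vapply(cand, function(t) sum(positive_values <= t), numeric(1))
  fp <- length(negative_values) - tn
  tp <- length(positive_values) - fn
  structure(list(
    candidates = cand,
    fpr = fp / (fp + tn),
    fnr = fn / (fn + tp),
    fp = fp, tn = tn, fn = fn, tp = tp
  ), class = "background_model")
}

#' Background threshold coordinating FPR and FNR
#'
#' Picks the candidate minimising `|FPR - FNR|` (the balanced-error
#' crossing); ties break toward the smaller threshold.
#'
#' @param model A `background_model` from [fpr_fnr_curve()].
#' @return The selected threshold (a candidate value).
#' @export
select_background_threshold <- function(model) {
  stopifnot(inherits(model, "background_model"))
  d <- abs(model$fpr - model$fnr)
  model$candidates[which.min(d)]  # which.min returns the first (smallest) argmin
}

#' Unified background threshold across samples
#'
#' The cross-sample median of per-sample thresholds (mean of the two middle
#' order statistics for an even count).
#'
#' @param per_sample_thresholds Numeric vector of per-sample thresholds.
#' @return Median threshold.
#' @export
unified_background <- function(per_sample_thresholds) {
  if (length(per_sample_thresholds) == 0) stop_input("no thresholds given")
  stats::median(per_sample_thresholds)
}

#' Per-sample background thresholds for a whole matrix
#'
#' Runs [fpr_fnr_curve()] + [select_background_threshold()] per sample,
#' using each sample's gene values as the positive set against a common
#' intergenic negative set, then unifies by the median.
#'
#' @param x An [expr_matrix()].
#' @param intergenic Numeric vector of intergenic expression densities.
#' @return List with `per_sample` (named vector) and `unified` (median).
#' @export
background_thresholds <- function(x, intergenic) {
  stopifnot(inherits(x, "expr_matrix"))
  per <- vapply(seq_len(ncol(x$values)), function(j) {
    select_background_threshold(fpr_fnr_curve(x$values[, j], intergenic))
  }, numeric(1))
  names(per) <- x$samples$sample_id
  list(per_sample = per, unified = unified_background(per))
}
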