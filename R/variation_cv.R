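#' Rank expression values as low / moderate / high
#'
#' Every expressed cell gets rank 1 (at or below the unified low threshold),
#' 2 (between low and high, boundary inclusive) or 3 (above high). Cells at
#' or below the background threshold are not expressed and stay `NA`.
#'
#' @param x An [expr_matrix()].
#' @param unified_low,unified_high Unified tri-level thresholds.
#' @param background Background threshold; must satisfy
#'   `background < unified_low < unified_high`.
#' @return Integer matrix (genes x samples) in `{1, 2, 3}` with `NA` for
#'   unexpressed cells.
#' @export
assign_ranks <- function(x, unified_low, unified_high, background) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!(background < unified_low && unified_low < unified_high))
    stop_input("need background < unified_low < unified_high (got %g, %g, %g)",
               background, unified_low, unified_high)
  v <- x$values
  r <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  r[v > background] <- 1L
  r[v > unified_low] <- 2L
  r[v > unified_high] <- 3L
  r
}

#' Rank-based coefficient of variation of one gene
#'
#' CV = sigma / mu over the gene's expression ranks, with mu the arithmetic
#' mean and sigma the population standard deviation (square root of the
#' arithmetic mean of squared deviations). Ranks replace raw values so that
#' high-expression genes do not dominate the variation estimate.
#'
#' @param ranks Integer vector of ranks in `{1, 2, 3}`; `NA`s (masked,
#'   unexpressed samples) make the CV undefined.
#' @return List with `mu`, `sigma`, `cv` (all `NA` when undefined) and
#'   `defined`.
#' @export
rank_cv <- function(ranks) {
  if (anyNA(ranks) || length(ranks) < 2)
    return(list(mu = NA_real_, sigma = NA_real_, cv = NA_real_,
                defined = FALSE))
  mu <- mean(ranks)
  sigma <- sqrt(mean((ranks - mu)^2))
  list(mu = mu, sigma = sigma, cv = sigma / mu, defined = TRUE)
}

#' CV values for a set of genes from a rank matrix
#'
#' @param rank_matrix Output of [assign_ranks()].
#' @param genes Gene ids (default all rows).
#' @param group Optional group restriction (`"normal"`/`"cancer"`) applied by
#'   column-name prefix match against `samples`.
#' @param samples Sample sheet, required when `group` is given.
#' @return Named numeric vector of CVs (`NA` where undefined).
#' @export
cv_values <- function(rank_matrix, genes = rownames(rank_matrix),
                      group = NULL, samples = NULL) {
  m <- rank_matrix[genes, , drop = FALSE]
  if (!is.null(group)) {
    if (is.null(samples)) stop_input("'samples' needed to select a group")
    m <- m[, samples$group == group, drop = FALSE]
  }
  apply(m, 1, function(r) rank_cv(r)$cv)
}

#' Constant/variable CV cutoffs from the control group
#'
#' First and third quartiles (linear interpolation, quantile type 7) of the
#' control (normal-group) CV distribution; these become the status cutoffs
#' for both conditions.
#'
#' @param cv Numeric CV values (NAs dropped).
#' @return Named vector `c(q1 = ..., q3 = ...)`.
#' @export
cv_thresholds <- function(cv) {
  cv <- cv[!is.na(cv)]
  if (length(cv) < 4) stop_input("need at least 4 defined CV values")
  q <- stats::quantile(cv, c(0.25, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' Variation status from CV values
#'
#' `constant` for `CV <= q1` (including CV = 0), `moderate_variable` for
#' `q1 < CV <= q3`, `variable` above `q3`.
#'
#' @param cv Numeric CV values.
#' @param q1,q3 Status cutoffs (defaults 0.14 and 0.26, the reference
#'   normal-group quartiles).
#' @return Character vector of statuses (`NA` where CV is `NA`).
#' @export
variation_status <- function(cv, q1 = 0.14, q3 = 0.26) {
  if (!(q1 <= q3)) stop_input("q1 must be <= q3")
  out <- rep(NA_character_, length(cv))
  out[!is.na(cv) & cv <= q1] <- "constant"
  out[!is.na(cv) & cv > q1 & cv <= q3] <- "moderate_variable"
  out[!is.na(cv) & cv > q3] <- "variable"
  names(out) <- names(cv)
  out
}

#' Status transition matrix between conditions
#'
#' Cross-tabulates per-gene variation status in the normal condition against
#' the cancer condition over a common gene set (typically the shared HK
#' genes). Rows are normal statuses, columns cancer statuses.
#'
#' @param status_normal,status_cancer Named character vectors over the same
#'   genes.
#' @return 3x3 integer matrix with dimnames
#'   `constant`/`moderate_variable`/`variable`.
#' @export
transition_matrix <- function(status_normal, status_cancer) {
  if (!setequal(names(status_normal), names(status_cancer)))
    stop_input("status maps cover different gene sets")
  status_cancer <- status_cancer[names(status_normal)]
  lv <- c("constant", "moderate_variable", "variable")
  keep <- !is.na(status_normal) & !is.na(status_cancer)
  table(factor(status_normal[keep], levels = lv),
        factor(status_cancer[keep], levels = lv),
        dnn = c("normal", "cancer"))
}
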