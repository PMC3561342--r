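#' Per-gene expression extremes within each group
#'
#' For every gene, the maximum and the minimum *positive* expression value
#' within the normal and cancer samples. Genes with no positive value in a
#' group get `NA` extremes and an `only_on_*` flag for the other group.
#'
#' @param x An [expr_matrix()].
#' @return `data.frame`: `gene_id`, `max_n`, `min_n`, `max_c`, `min_c`,
#'   `only_on_in_cancer`, `only_on_in_normal`.
#' @export
group_extremes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  ext <- function(v) {
    pos <- v[v > 0]
    if (length(pos) == 0) c(NA_real_, NA_real_) else c(max(pos), min(pos))
  }
  en <- t(apply(group_values(x, "normal"), 1, ext))
  ec <- t(apply(group_values(x, "cancer"), 1, ext))
  data.frame(
    gene_id = rownames(x$values),
    max_n = en[, 1], min_n = en[, 2],
    max_c = ec[, 1], min_c = ec[, 2],
    only_on_in_cancer = is.na(en[, 1]) & !is.na(ec[, 1]),
    only_on_in_normal = is.na(ec[, 1]) & !is.na(en[, 1]),
    stringsAsFactors = FALSE
  )
}

#' MD and AD: span-width and mid-level differences of log2 group extremes
#'
#' MA-plot-style statistics over the group extremes:
#' `MD = log2(max_n/min_n) - log2(max_c/min_c)` (difference of log2
#' expression span widths) and
#' `AD = (log2 max_n + log2 min_n)/2 - (log2 max_c + log2 min_c)/2`
#' (difference of log2 mid-levels). `MD < 0` means the cancer span is wider;
#' `AD < 0` means the cancer relative average level is higher. Genes with a
#' non-positive or missing extreme get `NA` (flagged, excluded from tests).
#'
#' @param extremes Output of [group_extremes()].
#' @return The `extremes` data.frame with `MD` and `AD` columns appended.
#' @export
mdad <- function(extremes) {
  ok <- with(extremes, !is.na(max_n) & !is.na(min_n) &
               !is.na(max_c) & !is.na(min_c) &
               max_n > 0 & min_n > 0 & max_c > 0 & min_c > 0)
  MD <- AD <- rep(NA_real_, nrow(extremes))
  MD[ok] <- with(extremes[ok, ], log2(max_n / min_n) - log2(max_c / min_c))
  AD[ok] <- with(extremes[ok, ],
                 (log2(max_n) + log2(min_n)) / 2 -
                   (log2(max_c) + log2(min_c)) / 2)
  extremes$MD <- MD
  extremes$AD <- AD
  extremes
}

#' maxR and minR: normal-to-cancer extreme-value ratios
#'
#' `maxR = max_n / max_c` and `minR = min_n / min_c`. A ratio of 0 marks a
#' gene only switched on in cancer; values in `[0, 1]` mean the normal
#' extreme is smaller; `Inf` marks a gene only on in normal. Genes off in
#' both groups get `NA`.
#'
#' @param extremes Output of [group_extremes()].
#' @return The `extremes` data.frame with `maxR` and `minR` appended.
#' @export
ratios <- function(extremes) {
  num_max <- ifelse(is.na(extremes$max_n), 0, extremes$max_n)
  num_min <- ifelse(is.na(extremes$min_n), 0, extremes$min_n)
  maxR <- ifelse(is.na(extremes$max_c), Inf, num_max / extremes$max_c)
  minR <- ifelse(is.na(extremes$min_c), Inf, num_min / extremes$min_c)
  both_off <- is.na(extremes$max_n) & is.na(extremes$max_c)
  maxR[both_off] <- NA_real_
  minR[both_off] <- NA_real_
  extremes$maxR <- maxR
  extremes$minR <- minR
  extremes
}

#' Paired Wilcoxon signed-rank test against a zero-median null
#'
#' Tests whether paired differences (here, per-gene MD or AD values) come
#' from a distribution with median zero. Exact zeros are dropped; ties share
#' average ranks. For `n <= exact_max_n` nonzero values the p-value is exact
#' (full sign-assignment distribution of the positive-rank sum, computed by
#' convolution over the tied ranks); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. The reported Z
#' always carries the sign of `W - n(n+1)/4`, so negative Z means the values
#' lean negative.
#'
#' @param values Numeric vector of paired differences.
#' @param mu0 Hypothesised median (default 0).
#' @param alpha Rejection level for the `reject` flag.
#' @param exact_max_n Largest `n` for the exact path (default 20).
#' @return List: `defined`, `n_used`, `W`, `Z`, `p_value`, `reject`,
#'   `method` (`"exact"`/`"normal"`).
#' @export
wilcoxon_signed_rank <- function(values, mu0 = 0, alpha = 0.05,
                                 exact_max_n = 20) {
  d <- values[!is.na(values)] - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(defined = FALSE, n_used = 0L, W = NA_real_, Z = NA_real_,
                p_value = NA_real_, reject = NA, method = "none"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  sigma <- sqrt(sigma2)
  cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
  Z <- if (sigma > 0) (W - mu - cc) / sigma else 0
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))  # doubled ranks are integers even with ties
    maxs <- sum(r2)
    pmf <- numeric(maxs + 1)
    pmf[1] <- 1
    for (ri in r2)
      pmf <- (pmf + c(rep(0, ri), pmf[seq_len(maxs + 1 - ri)])) / 2
    w2 <- as.integer(round(2 * W))
    p_le <- sum(pmf[seq_len(w2 + 1)])
    p_ge <- sum(pmf[(w2 + 1):(maxs + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
    method <- "normal"
  }
  list(defined = TRUE, n_used = n, W = W, Z = Z, p_value = p,
       reject = p <= alpha, method = method)
}

#' MDAD test summary per variation-status subtype
#'
#' Runs the paired Wilcoxon signed-rank test on MD and AD over all genes and
#' within each variation-status subtype, mirroring the per-type summary
#' tables (columns: type, gene count, reject flag, p-value, Z).
#'
#' @param records Output of [mdad()] (and optionally [ratios()]).
#' @param status Named character vector of variation statuses for
#'   `records$gene_id` (may contain `NA`).
#' @param alpha Rejection level.
#' @return `data.frame` with one row per type
#'   (`MD`, `AD`, `MD_<status>`, `AD_<status>`).
#' @export
mdad_test_summary <- function(records, status = NULL, alpha = 0.05) {
  groups <- list(all = records)
  if (!is.null(status)) {
    st <- status[records$gene_id]
    for (s in c("constant", "moderate_variable", "variable"))
      groups[[s]] <- records[!is.na(st) & st == s, , drop = FALSE]
  }
  rows <- list()
  for (g in names(groups)) {
    for (stat in c("MD", "AD")) {
      vals <- groups[[g]][[stat]]
      vals <- vals[!is.na(vals)]
      wt <- wilcoxon_signed_rank(vals, alpha = alpha)
      label <- if (g == "all") stat else paste0(stat, "_", g)
      rows[[label]] <- data.frame(
        type = label, gene_count = length(vals),
        reject = as.integer(isTRUE(wt$reject)),
        p_value = wt$p_value, Z = wt$Z, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accumulated gene fraction with extreme ratios below a cutoff
#'
#' Percentage of genes with `minR <= cutoff` and with `maxR <= cutoff`,
#' overall and per variation-status subtype (genes with undefined ratios are
#' excluded from their column's denominator).
#'
#' @param records Output of [ratios()].
#' @param status Named character vector of statuses for `records$gene_id`,
#'   or `NULL` for the overall row only.
#' @param cutoff Ratio cutoff (default 1).
#' @return `data.frame`: `type`, `gene_count`, `minR_le_pct`, `maxR_le_pct`
#'   (percentages, 2 decimal places).
#' @export
accumulated_ratio_table <- function(records, status = NULL, cutoff = 1) {
  pct <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    round_half_up(100 * mean(v <= cutoff), 2)
  }
  make_row <- function(label, df)
    data.frame(type = label, gene_count = nrow(df),
               minR_le_pct = pct(df$minR), maxR_le_pct = pct(df$maxR),
               stringsAsFactors = FALSE)
  rows <- list(make_row("all", records))
  if (!is.null(status)) {
    st <- status[records$gene_id]
    for (s in c("constant", "moderate_variable", "variable"))
      rows[[s]] <- make_row(s, records[!is.na(st) & st == s, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
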