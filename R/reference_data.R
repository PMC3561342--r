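#' Bundled reference tables
#'
#' Small plain-text reference tables from a published 12-normal-tissue /
#' 9-cancer-cell-line RNA-Seq survey, bundled as worked-example inputs:
#'
#' * `reference_trilevel_thresholds()` — per-sample LEG/MEG/HEG gene counts
#'   and low/high thresholds (RPKM) of the 12 normal samples.
#' * `reference_hk_counts()` — headline set sizes (normal/cancer HK, shared,
#'   locus total) and variation-subtype counts, as a named numeric vector.
#' * `reference_sample_sheet()` — the 21-sample sheet (group labels and
#'   library sizes).
#'
#' @return A `data.frame` (thresholds, sample sheet) or named numeric vector
#'   (counts).
#' @name reference_data
NULL

#' @rdname reference_data
#' @export
reference_trilevel_thresholds <- function() {
  utils::read.delim(system.file("extdata", "reference_trilevel_thresholds.tsv",
                                package = "hkatlas"), check.names = TRUE)
}

#' @rdname reference_data
#' @export
reference_hk_counts <- function() {
  df <- utils::read.delim(system.file("extdata", "reference_hk_counts.tsv",
                                      package = "hkatlas"))
  setNames(df$value, df$quantity)
}

#' @rdname reference_data
#' @export
reference_sample_sheet <- function() {
  utils::read.delim(system.file("extdata", "reference_sample_sheet.tsv",
                                package = "hkatlas"))
}
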