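#' @keywords internal
"_PACKAGE"

# Weighted median taking the lower-middle data value: the smallest x whose
# cumulative weight reaches ceiling(W/2). Always returns an observed value,
# never an average of two values.
weighted_median_lower <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= ceiling(sum(w) / 2))[1L]]
}

# Round half away from zero, so 37.5 -> 38 (base round() is half-to-even).
# The tiny relative epsilon counters binary representation of decimal halves
# (1.055 is stored just below 1.055 and must still report as 1.06).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
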