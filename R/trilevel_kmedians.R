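#' Compressive transform of expression values
#'
#' Working transform applied before clustering: `log2(x + n)` with transform
#' factor `n` (default 1). Strictly increasing, so it only compresses the
#' heavy right tail of RPKM values; thresholds are always reported on the
#' original scale.
#'
#' @param x Positive expression value(s).
#' @param n Transform factor (pseudocount).
#' @return Transformed value(s).
#' @examples
#' transform_expression(1) # 1
#' transform_expression(3) # 2
#' @export
transform_expression <- function(x, n = 1) {
  if (any(x <= 0)) stop_input("transform requires x > 0")
  log2(x + n)
}

# deterministic init: data values at the weighted 1/6, 3/6, 5/6 quantiles
seed_quantile_centroids <- function(x, w, K) {
  cw <- cumsum(w) / sum(w)
  probs <- (2 * seq_len(K) - 1) / (2 * K)
  cents <- vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
  if (length(unique(cents)) < K) {  # collapse: fall back to spread-out values
    cents <- x[unique(round(seq(1, length(x), length.out = K)))]
    if (length(unique(cents)) < K)
      cents <- sort(unique(x))[seq_len(K)]
  }
  sort(cents)
}

#' One-dimensional weighted k-medians over (value, count) points
#'
#' Clusters expressed genes represented as weighted points `(x, y)` — `x` an
#' expression value, `y` the number of genes at that value. Each point is
#' assigned to the nearest centroid; a centroid is the expression value of
#' the middle gene of its cluster (weighted median, lower-middle on even
#' total weight) — an observed value, never an arithmetic mean. Distances
#' are taken between transformed values (`log2(x + n)`) by default;
#' `distance_space = "raw"` uses original values. Iteration stops when the
#' assignment no longer changes. Initialisation is deterministic (weighted
#' quantile seeding); `restarts > 0` adds random restarts under `seed` and
#' keeps the solution with the lowest weighted L1 objective.
#'
#' @param x Distinct expression values (> 0).
#' @param w Positive integer weights (gene counts per value).
#' @param K Number of clusters (default 3: LEG/MEG/HEG).
#' @param n Transform factor, see [transform_expression()].
#' @param distance_space `"transformed"` (default) or `"raw"`.
#' @param restarts Number of extra random initialisations.
#' @param seed Seed for the random restarts.
#' @param max_iter Iteration cap per start.
#' @return A `cluster_state`: `x`, `w`, ascending `centroids`, per-point
#'   `assignment` (1 = LEG ... K = HEG), `objective` (weighted L1 deviation
#'   in distance space), `iterations`, `converged`.
#' @export
weighted_kmedians_1d <- function(x, w = rep(1L, length(x)), K = 3, n = 1,
                                 distance_space = c("transformed", "raw"),
                                 restarts = 0, seed = 1L, max_iter = 100) {
  distance_space <- match.arg(distance_space)
  if (length(x) != length(w)) stop_input("x and w lengths differ")
  if (any(w < 1)) stop_input("weights must be positive")
  o <- order(x)
  x <- x[o]; w <- w[o]
  if (anyDuplicated(x)) {  # merge duplicate values
    w <- as.numeric(tapply(w, match(x, unique(x)), sum))
    x <- unique(x)
  }
  if (length(x) < K)
    stop_input("need at least K = %d distinct values, got %d", K, length(x))
  tf <- function(v) if (distance_space == "transformed")
    transform_expression(v, n) else v
  tx <- tf(x)

  run_from <- function(cents) {
    assignment <- rep(0L, length(x))
    converged <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      tc <- tf(cents)
      d <- abs(outer(tx, tc, "-"))
      new_assign <- max.col(-d, ties.method = "first")
      # empty-cluster repair: reseed at the point farthest from its centroid
      for (k in which(tabulate(new_assign, K) == 0)) {
        far <- which.max(d[cbind(seq_along(x), new_assign)])
        cents[k] <- x[far]
        tc <- tf(cents)
        d <- abs(outer(tx, tc, "-"))
        new_assign <- max.col(-d, ties.method = "first")
      }
      if (identical(new_assign, assignment)) { converged <- TRUE; break }
      assignment <- new_assign
      cents <- vapply(seq_len(K), function(k) {
        m <- assignment == k
        weighted_median_lower(x[m], w[m])
      }, numeric(1))
      # keep centroid order tied to cluster index so labels stay sorted
      ord <- order(cents)
      cents <- cents[ord]
      assignment <- match(assignment, ord)
    }
    obj <- sum(w * abs(tx - tf(cents)[assignment]))
    list(centroids = cents, assignment = assignment, objective = obj,
         iterations = it, converged = converged)
  }

  best <- run_from(seed_quantile_centroids(x, w, K))
  if (restarts > 0) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      init <- sort(sample(x, K, prob = w / sum(w)))
      while (length(unique(init)) < K)
        init <- sort(sample(x, K, prob = w / sum(w)))
      cand <- run_from(init)
      if (cand$objective < best$objective) best <- cand
    }
  }
  structure(c(best, list(x = x, w = w, K = K, n = n,
                         distance_space = distance_space)),
            class = "cluster_state")
}

#' Low/high thresholds from a converged tri-level clustering
#'
#' The low threshold is the average of the maximum expression in LEG and the
#' minimum in MEG; the high threshold averages the maximum of MEG and the
#' minimum of HEG — on the original expression scale.
#'
#' @param state A `cluster_state` with `K = 3`.
#' @return Named vector `c(low = ..., high = ...)`.
#' @export
extract_thresholds <- function(state) {
  stopifnot(inherits(state, "cluster_state"))
  if (state$K != 3) stop_input("threshold extraction requires K = 3")
  if (any(tabulate(state$assignment, 3) == 0)) stop_input("empty cluster")
  leg <- state$x[state$assignment == 1]
  meg <- state$x[state$assignment == 2]
  heg <- state$x[state$assignment == 3]
  c(low = (max(leg) + min(meg)) / 2, high = (max(meg) + min(heg)) / 2)
}

#' Unified tri-level thresholds across samples
#'
#' Componentwise medians of per-sample (low, high) thresholds; an even
#' sample count takes the mean of the two middle order statistics.
#'
#' @param per_sample Matrix or data.frame with columns `low` and `high`,
#'   one row per sample.
#' @return Named vector `c(low = ..., high = ...)`.
#' @export
unify_thresholds <- function(per_sample) {
  per_sample <- as.data.frame(per_sample)
  if (nrow(per_sample) == 0) stop_input("no per-sample thresholds")
  if (!all(c("low", "high") %in% names(per_sample)))
    stop_input("need columns 'low' and 'high'")
  c(low = stats::median(per_sample$low), high = stats::median(per_sample$high))
}

#' Tri-level partition of one sample's expressed genes
#'
#' Takes all of a sample's values above background, collapses them to
#' weighted `(value, gene count)` points, clusters with
#' [weighted_kmedians_1d()], and reports thresholds and LEG/MEG/HEG counts.
#'
#' @param values Numeric vector of one sample's expression values.
#' @param background Background threshold; only values strictly above it are
#'   clustered.
#' @param ... Passed to [weighted_kmedians_1d()].
#' @return List with `state`, `thresholds` and `counts`
#'   (`low`/`moderate`/`high` gene counts plus `total`).
#' @export
trilevel_sample <- function(values, background, ...) {
  expressed <- sort(values[values > background])
  if (length(expressed) < 3) stop_input("fewer than 3 expressed genes")
  r <- rle(expressed)
  state <- weighted_kmedians_1d(r$values, r$lengths, K = 3, ...)
  counts <- vapply(1:3, function(k) sum(state$w[state$assignment == k]),
                   numeric(1))
  list(state = state,
       thresholds = extract_thresholds(state),
       counts = c(low = counts[1], moderate = counts[2], high = counts[3],
                  total = sum(counts)))
}

#' Per-sample tri-level thresholds for a whole matrix
#'
#' Runs [trilevel_sample()] on every sample and unifies thresholds as the
#' medians over the normal group (the control standard applied to all
#' samples).
#'
#' @param x An [expr_matrix()].
#' @param background Background threshold.
#' @param ... Passed to [weighted_kmedians_1d()].
#' @return List with `per_sample` (`data.frame`: sample, group, low/moderate/
#'   high counts, thresholds, total) and `unified` (`c(low, high)` medians
#'   over normal samples).
#' @export
trilevel_matrix <- function(x, background, ...) {
  stopifnot(inherits(x, "expr_matrix"))
  rows <- lapply(seq_len(ncol(x$values)), function(j) {
    ts <- trilevel_sample(x$values[, j], background, ...)
    data.frame(sample_id = x$samples$sample_id[j],
               group = x$samples$group[j],
               low_count = ts$counts[["low"]],
               low = ts$thresholds[["low"]],
               moderate_count = ts$counts[["moderate"]],
               high_count = ts$counts[["high"]],
               high = ts$thresholds[["high"]],
               total = ts$counts[["total"]])
  })
  per_sample <- do.call(rbind, rows)
  normal <- per_sample[per_sample$group == "normal", ]
  list(per_sample = per_sample, unified = unify_thresholds(normal))
}
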