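test_that("the working transform is log2(x + n) and strictly increasing", {
  expect_equal(transform_expression(1), 1)
  expect_equal(transform_expression(3), 2)
  expect_error(transform_expression(0), "x > 0")
  set.seed(8)
  x <- sort(rlnorm(50, 0, 2))
  expect_true(all(diff(transform_expression(x)) > 0))
})

test_that("K = n puts every point in its own cluster", {
  st <- weighted_kmedians_1d(c(1, 10, 100), K = 3)
  expect_equal(sort(unique(st$assignment)), 1:3)
  expect_equal(st$centroids, c(1, 10, 100))
  expect_error(weighted_kmedians_1d(c(1, 1, 1), K = 3), "distinct")
})

test_that("converged clusters are contiguous and are fixed points", {
  set.seed(9)
  for (i in 1:15) {
    x <- sort(round(rlnorm(sample(5:60, 1), 1, 1.5), 4))
    x <- unique(x)
    if (length(x) < 3) next
    w <- sample(1:20, length(x), replace = TRUE)
    st <- weighted_kmedians_1d(x, w)
    expect_true(st$converged)
    # contiguity: assignment is non-decreasing along sorted x
    expect_true(all(diff(st$assignment) >= 0))
    # fixed point: reassigning to the nearest centroid changes nothing
    tx <- transform_expression(st$x)
    tc <- transform_expression(st$centroids)
    again <- max.col(-abs(outer(tx, tc, "-")), ties.method = "first")
    expect_identical(again, st$assignment)
  }
})

test_that("objective never beats the exact DP optimum and matches it when tiny", {
  set.seed(10)
  for (i in 1:30) {
    m <- sample(5:50, 1)
    x <- sort(unique(round(rlnorm(m, 1, 1.5), 3)))
    if (length(x) < 3) next
    w <- sample(1:30, length(x), replace = TRUE)
    st <- weighted_kmedians_1d(x, w, restarts = 20, seed = i)
    # the DP optimum is a true lower bound for any contiguous clustering
    expect_gte(st$objective, dp_kmedians_objective(x, w) - 1e-9)
  }
  # on tiny instances the iterative algorithm attains the optimum exactly
  for (i in 1:10) {
    x <- sort(unique(round(rlnorm(8, 1, 1.5), 2)))
    if (length(x) < 4) next
    w <- sample(1:5, length(x), replace = TRUE)
    st <- weighted_kmedians_1d(x, w, restarts = 20, seed = i)
    expect_equal(st$objective, dp_kmedians_objective(x, w), tolerance = 1e-9)
  }
})

test_that("thresholds average boundary genes on the original scale", {
  # threshold arithmetic on a given converged partition
  make_state <- function(x, assignment)
    structure(list(x = x, w = rep(1L, length(x)), K = 3,
                   assignment = assignment,
                   centroids = tapply(x, assignment, min)),
              class = "cluster_state")
  st <- make_state(c(0.5, 1.0, 2.0, 8.0, 20), c(1L, 1L, 2L, 2L, 3L))
  thr <- extract_thresholds(st)
  expect_equal(unname(thr["low"]), 1.5)
  expect_equal(unname(thr["high"]), 14.0)
  st2 <- weighted_kmedians_1d(c(1, 2, 4), K = 3)
  expect_equal(unname(extract_thresholds(st2)), c(1.5, 3.0))
  expect_error(extract_thresholds(make_state(c(1, 2, 3), c(1L, 1L, 2L))),
               "empty cluster")
  # low < high over random converged states
  set.seed(11)
  for (i in 1:10) {
    x <- sort(unique(round(rlnorm(40, 1, 1.5), 3)))
    thr <- extract_thresholds(weighted_kmedians_1d(x))
    expect_lt(thr[["low"]], thr[["high"]])
  }
})

test_that("distance space is transformed by default but thresholds stay raw", {
  x <- c(0.5, 1, 2, 4, 8, 16, 64, 128)
  st_t <- weighted_kmedians_1d(x, distance_space = "transformed")
  st_r <- weighted_kmedians_1d(x, distance_space = "raw")
  # thresholds are averages of raw boundary values in both spaces
  for (st in list(st_t, st_r)) {
    thr <- extract_thresholds(st)
    leg_max <- max(st$x[st$assignment == 1])
    meg_min <- min(st$x[st$assignment == 2])
    expect_equal(unname(thr["low"]), (leg_max + meg_min) / 2)
  }
})

test_that("unified thresholds are componentwise medians across samples", {
  ref <- reference_trilevel_thresholds()
  uni <- unify_thresholds(ref[, c("low", "high")])
  expect_equal(unname(uni["low"]), 1.055)
  expect_equal(unname(uni["high"]), 12.72)
  expect_equal(unname(unify_thresholds(data.frame(low = 1, high = 2))), c(1, 2))
  expect_error(unify_thresholds(data.frame(low = numeric(0),
                                           high = numeric(0))), "no per-sample")
})

test_that("tri-level partition recovers boundaries between planted modes", {
  cfg <- sim_config(seed = 0)
  modes <- exp(cfg$level_meanlog)
  ok <- 0
  for (r in 1:25) {
    set.seed(100 + r)
    comp <- sample(1:3, 2000, replace = TRUE, prob = cfg$level_weights)
    x <- rlnorm(2000, cfg$level_meanlog[comp], cfg$level_sdlog[comp])
    thr <- trilevel_sample(x, background = 0.25)$thresholds
    if (thr[["low"]] > modes[1] && thr[["low"]] < modes[2] &&
        thr[["high"]] > modes[2] && thr[["high"]] < modes[3]) ok <- ok + 1
  }
  expect_gte(ok, 24)  # >= 95%
})
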