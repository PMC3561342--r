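test_that("Spearman matrix is rank-based, symmetric and unit-diagonal", {
  set.seed(18)
  v <- matrix(rlnorm(40, 0, 1), 10, 4,
              dimnames = list(paste0("g", 1:10), NULL))
  v[, 2] <- v[, 1]                 # duplicated sample
  v[, 3] <- v[, 1]^3 + 1           # strictly monotone transform
  m <- toy_matrix(v, c("normal", "normal", "cancer", "cancer"))
  rho <- spearman_matrix(m)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 4))
  expect_equal(unname(rho[1, 2]), 1)
  expect_equal(unname(rho[1, 3]), 1)
})

test_that("a single discordant pair matches the closed form", {
  # profiles over 3 genes: ranks (1,2,3) vs (1,3,2) -> d = (0,1,1)
  v <- matrix(c(1, 2, 3, 1, 3, 2), 3, 2,
              dimnames = list(paste0("g", 1:3), NULL))
  m <- toy_matrix(v, c("normal", "cancer"))
  rho <- spearman_matrix(m)
  expect_equal(unname(rho[1, 2]), 1 - 6 * 2 / (3 * (9 - 1)))
})

test_that("constant profiles are reported as undefined and block clustering", {
  v <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
              dimnames = list(paste0("g", 1:3), NULL))
  m <- toy_matrix(v, c("normal", "cancer"))
  rho <- spearman_matrix(m)
  expect_true(anyNA(rho))
  expect_error(hierarchical_cluster(rho), "s02")
})

test_that("merge order equals brute-force average-linkage agglomeration", {
  set.seed(19)
  v <- matrix(rlnorm(60, 0, 1), 15, 4,
              dimnames = list(paste0("g", 1:15), NULL))
  v[, 2] <- v[, 1] * 2 + rlnorm(15, 0, 0.05)  # near-identical pair
  m <- toy_matrix(v, c("normal", "normal", "cancer", "cancer"))
  rho <- spearman_matrix(m)
  tree <- hierarchical_cluster(rho)
  ref <- brute_average_linkage(as.dist(1 - rho))
  expect_equal(ref[[1]]$members, c(1, 2))  # identical pair merges first
  got_heights <- sort(tree$height)
  ref_heights <- sort(vapply(ref, `[[`, numeric(1), "height"))
  expect_equal(got_heights, ref_heights, tolerance = 1e-12)
})

test_that("dendrogram is invariant to input sample order", {
  f <- medium_sim()
  x <- f$sim$matrix
  perm <- rev(seq_len(ncol(x$values)))
  xp <- expr_matrix(x$values[, perm], x$samples[perm, ])
  t1 <- hierarchical_cluster(spearman_matrix(x))
  t2 <- hierarchical_cluster(spearman_matrix(xp))
  expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-12)
  labels <- setNames(x$samples$group, x$samples$sample_id)
  p1 <- cut_k(t1, 2, labels)$partition
  p2 <- cut_k(t2, 2, labels)$partition
  expect_true(all(vapply(split(names(p1), p1), function(ids)
    length(unique(p2[ids])) == 1, logical(1))))
})

test_that("cutting recovers purity extremes and the planted two groups", {
  f <- medium_sim()
  x <- f$sim$matrix
  tree <- hierarchical_cluster(spearman_matrix(x))
  labels <- setNames(x$samples$group, x$samples$sample_id)
  n <- ncol(x$values)
  expect_equal(cut_k(tree, n, labels)$purity, 1)
  expect_equal(cut_k(tree, 1, labels)$purity,
               max(table(labels)) / n)
  expect_equal(cut_k(tree, 2, labels)$purity, 1)
  expect_error(cut_k(tree, 0, labels), "k must be")
})

test_that("newick export round-trips through ape", {
  f <- medium_sim()
  tree <- hierarchical_cluster(spearman_matrix(f$sim$matrix))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, f$sim$matrix$samples$sample_id)
})
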