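test_that("group extremes use positive entries only and flag off genes", {
  m <- toy_matrix(rbind(g1 = c(2, 8, 0, 4, 16),
                        g2 = c(0, 0, 0, 1, 2),
                        g3 = c(5, 0, 0, 7, 0)),
                  c("normal", "normal", "normal", "cancer", "cancer"))
  ext <- group_extremes(m)
  expect_equal(ext$max_n[1], 8); expect_equal(ext$min_n[1], 2)
  expect_equal(ext$max_c[1], 16); expect_equal(ext$min_c[1], 4)
  expect_true(ext$only_on_in_cancer[2])
  expect_equal(ext$max_n[3], ext$min_n[3])  # single positive value
})

test_that("MD and AD are log2 span and midpoint differences", {
  m <- toy_matrix(rbind(g1 = c(2, 8, 4, 16),
                        g2 = c(3, 3, 3, 3),
                        g3 = c(4, 8, 1, 64)),
                  c("normal", "normal", "cancer", "cancer"))
  rec <- mdad(group_extremes(m))
  expect_equal(rec$MD[1], 0)       # spans 2 vs 2 on log2 scale
  expect_equal(rec$AD[1], -1)      # midpoints 2 vs 3 on log2 scale
  expect_equal(rec$MD[2], 0); expect_equal(rec$AD[2], 0)
  expect_lt(rec$MD[3], 0)          # cancer span strictly wider
})

test_that("maxR and minR encode on/off direction", {
  m <- toy_matrix(rbind(g1 = c(8, 8, 16, 16),
                        g2 = c(0, 0, 2, 4),
                        g3 = c(2, 4, 0, 0),
                        g4 = c(0, 0, 0, 0)),
                  c("normal", "normal", "cancer", "cancer"))
  rec <- ratios(group_extremes(m))
  expect_equal(rec$maxR[1], 0.5)
  expect_equal(rec$minR[1], 0.5)
  expect_equal(rec$maxR[2], 0)     # only on in cancer
  expect_equal(rec$maxR[3], Inf)   # only on in normal
  expect_true(is.na(rec$maxR[4]))  # off in both groups
  m2 <- toy_matrix(rbind(g1 = c(3, 3)), c("normal", "cancer"))
  expect_equal(ratios(group_extremes(m2))$maxR, 1)
})

test_that("swapping group labels negates MD/AD and inverts the ratios", {
  set.seed(14)
  v <- matrix(rlnorm(60, 1, 1), 10, 6,
              dimnames = list(paste0("g", 1:10), NULL))
  g <- c("normal", "normal", "normal", "cancer", "cancer", "cancer")
  a <- ratios(mdad(group_extremes(toy_matrix(v, g))))
  b <- ratios(mdad(group_extremes(toy_matrix(v, rev(g)))))
  expect_equal(a$MD, -b$MD)
  expect_equal(a$AD, -b$AD)
  expect_equal(a$maxR, 1 / b$maxR)
  expect_equal(a$minR, 1 / b$minR)
})

test_that("MD and AD are invariant to global rescaling of the matrix", {
  set.seed(15)
  v <- matrix(rlnorm(50, 0, 1.5), 10, 5,
              dimnames = list(paste0("g", 1:10), NULL))
  g <- c("normal", "normal", "cancer", "cancer", "cancer")
  a <- mdad(group_extremes(toy_matrix(v, g)))
  b <- mdad(group_extremes(toy_matrix(v * 7.3, g)))
  expect_equal(a$MD, b$MD)
  expect_equal(a$AD, b$AD)
})

test_that("signed-rank test matches brute-force enumeration and stats oracles", {
  expect_false(wilcoxon_signed_rank(c(0, 0, 0))$defined)
  w <- wilcoxon_signed_rank(c(-1, -2, -3))
  expect_equal(w$p_value, 0.25)
  expect_lt(w$Z, 0)

  set.seed(16)
  for (i in 1:10) {
    d <- round(rnorm(sample(4:10, 1)), sample(0:2, 1))  # rounding makes ties
    d <- d[d != 0]
    if (length(d) < 2) next
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p_value, brute_signed_rank_p(d), tolerance = 1e-12)
  }
  # untied case against the closed-form null distribution in stats
  for (i in 1:10) {
    d <- rnorm(10)
    got <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(got$p_value, ref, tolerance = 1e-12)
    r <- rank(abs(d)); W <- sum(r[d > 0])
    p_cf <- min(1, 2 * min(stats::psignrank(W, 10),
                           1 - stats::psignrank(W - 1, 10)))
    expect_equal(got$p_value, p_cf, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p-values agree near the cutover", {
  set.seed(17)
  for (i in 1:10) {
    d <- rnorm(15, mean = 0.3)
    d <- d[d != 0]
    p_exact <- wilcoxon_signed_rank(d, exact_max_n = 20)$p_value
    p_norm <- wilcoxon_signed_rank(d, exact_max_n = 0)$p_value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("Z carries the sign of the rank-sum displacement", {
  up <- wilcoxon_signed_rank(rep(c(1, 2, 3), 10))
  dn <- wilcoxon_signed_rank(rep(c(-1, -2, -3), 10))
  expect_gt(up$Z, 0)
  expect_lt(dn$Z, 0)
  expect_equal(up$Z, -dn$Z)
  expect_true(dn$reject)
})

test_that("accumulated ratio table counts genes at or below the cutoff", {
  rec <- data.frame(gene_id = paste0("g", 1:4),
                    minR = c(0.5, 0.9, 1.2, 2.0),
                    maxR = c(1, 1, 1, 1))
  tab <- accumulated_ratio_table(rec)
  expect_equal(tab$minR_le_pct[tab$type == "all"], 50.00)
  expect_equal(tab$maxR_le_pct[tab$type == "all"], 100.00)
})

test_that("planted up-regulation pushes minR mass below 1, monotonically", {
  pct_le1 <- vapply(c(0.5, 1.5), function(fc) {
    cfg <- sim_config(n_genes = 800, cancer_upregulation_log2fc = fc,
                      upregulated_fraction = 1, seed = 33)
    sim <- simulate_expression(cfg)
    sh <- sim$truth$gene_id[sim$truth$class == "shared"]
    rec <- ratios(group_extremes(sim$matrix))
    rec <- rec[rec$gene_id %in% sh, ]
    100 * mean(rec$minR <= 1, na.rm = TRUE)
  }, numeric(1))
  expect_gt(pct_le1[1], 50)
  expect_gt(pct_le1[2], pct_le1[1])
})

test_that("MDAD summary rejects AD with negative Z under planted up-regulation", {
  f <- medium_sim()
  res <- medium_pipeline()
  sm <- res$mdad_summary_shared
  ad <- sm[sm$type == "AD", ]
  expect_equal(ad$reject, 1)
  expect_lt(ad$Z, 0)
  expect_equal(sum(sm$gene_count[sm$type %in%
    c("MD_constant", "MD_moderate_variable", "MD_variable")]),
    sm$gene_count[sm$type == "MD"] -
      sum(is.na(res$status$normal[res$catalog$shared])))
})
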