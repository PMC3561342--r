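test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 200, seed = 9)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_intergenic(cfg, 100), simulate_intergenic(cfg, 100))
  expect_error(simulate_intergenic(cfg, 0), "positive")
})

test_that("config validation rejects malformed designs", {
  expect_error(sim_config(class_fractions = c(shared = 0.5, normal_unique = 0.2,
                                              cancer_associated = 0.2,
                                              tissue_specific = 0.2)), "sum to 1")
  expect_error(sim_config(n_genes = 3), "n_genes")
  expect_error(sim_config(cancer_upregulation_log2fc = -1), ">= 0")
})

test_that("planted GC shift in cancer-associated genes is recoverable", {
  cfg0 <- sim_config(n_genes = 5000, at_rich_shift = 0, seed = 5)
  ann0 <- simulate_annotation(cfg0)
  gap0 <- mean(ann0$gc[ann0$class != "cancer_associated"]) -
    mean(ann0$gc[ann0$class == "cancer_associated"])
  expect_lt(abs(gap0), 0.01)

  cfg1 <- sim_config(n_genes = 5000, at_rich_shift = 0.10, seed = 5)
  ann1 <- simulate_annotation(cfg1)
  gap1 <- mean(ann1$gc[ann1$class != "cancer_associated"]) -
    mean(ann1$gc[ann1$class == "cancer_associated"])
  expect_lt(abs(gap1 - 0.10), 0.01)
})

test_that("every truth label is consistent with the generated on/off pattern", {
  f <- medium_sim()
  v <- f$sim$matrix$values
  grp <- f$sim$matrix$samples$group
  on <- v > f$cfg$min_on_rpkm  # generator guarantee: on-cells exceed the floor
  for (cl in unique(f$sim$truth$class)) {
    rows <- which(f$sim$truth$class == cl)
    on_n <- rowSums(on[rows, grp == "normal", drop = FALSE])
    on_c <- rowSums(on[rows, grp == "cancer", drop = FALSE])
    nn <- sum(grp == "normal"); nc <- sum(grp == "cancer")
    if (cl == "shared") {
      expect_true(all(on_n == nn & on_c == nc))
    } else if (cl == "normal_unique") {
      expect_true(all(on_n == nn & on_c < nc))
    } else if (cl == "cancer_associated") {
      expect_true(all(on_c == nc & on_n < nn))
    } else {
      expect_true(all(on_n < nn & on_c < nc))
    }
  }
})

test_that("degenerate all-shared config yields a pure shared catalog", {
  cfg <- sim_config(n_genes = 100,
                    class_fractions = c(shared = 1, normal_unique = 0,
                                        cancer_associated = 0,
                                        tissue_specific = 0),
                    dropout_rate = 0, force_zero = TRUE, seed = 3)
  sim <- simulate_expression(cfg)
  normal_hk <- define_hk(sim$matrix, 0.25, "normal")
  cancer_hk <- define_hk(sim$matrix, 0.25, "cancer")
  cat <- classify_five_types(normal_hk, cancer_hk, rownames(sim$matrix$values))
  expect_equal(unname(cat$counts["shared"]), 100)
  expect_equal(unname(cat$counts["non_HK"]), 0)
})

test_that("intergenic density sits well below the low expression mode", {
  cfg <- sim_config(n_genes = 500, seed = 8)
  ig <- simulate_intergenic(cfg, 5000)
  expect_lt(stats::quantile(ig, 0.5), exp(cfg$level_meanlog[1]))
  sim <- simulate_expression(cfg)
  thr <- background_thresholds(sim$matrix, ig)
  expect_true(all(thr$per_sample > 0))
  expect_lt(thr$unified, cfg$min_on_rpkm)
})
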