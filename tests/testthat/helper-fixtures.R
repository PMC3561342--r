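# Small shared fixtures, built once per test file.

toy_matrix <- function(values, groups) {
  n <- length(groups)
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = groups,
    total_mapped_reads = rep(1e7, n)
  )
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  expr_matrix(values, samples)
}

# medium synthetic study reused across files (memoised per R session)
.fixture_env <- new.env(parent = emptyenv())
medium_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(n_genes = 2000, seed = 42)
    .fixture_env$cfg <- cfg
    .fixture_env$sim <- simulate_expression(cfg)
    .fixture_env$intergenic <- simulate_intergenic(cfg, 4000)
  }
  list(cfg = .fixture_env$cfg, sim = .fixture_env$sim,
       intergenic = .fixture_env$intergenic)
}
medium_pipeline <- function() {
  if (is.null(.fixture_env$res)) {
    f <- medium_sim()
    .fixture_env$res <- run_pipeline(f$sim$matrix, f$intergenic)
  }
  .fixture_env$res
}

# the full-size study (default design: 10,000 genes, 12 + 9 samples),
# shared between the recovery tests and the acceptance suite
full_study <- function() {
  if (is.null(.fixture_env$full)) {
    cfg <- sim_config(seed = 101)
    sim <- simulate_expression(cfg)
    intergenic <- simulate_intergenic(cfg, 10000)
    res <- run_pipeline(sim$matrix, intergenic,
                        annotation = simulate_annotation(cfg))
    .fixture_env$full <- list(cfg = cfg, sim = sim, intergenic = intergenic,
                              res = res)
  }
  .fixture_env$full
}
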