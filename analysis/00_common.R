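# Shared paths and study configuration for the analysis scripts.
# Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate.R && Rscript analysis/02_background.R && ...

library(hkatlas)

data_dir <- "results/synthetic_study/data"
tab_dir <- "results/synthetic_study/tables"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)

study_config <- function() sim_config(seed = 20260925 %% 2^20)

read_study_matrix <- function() {
  samples <- read_sample_sheet(file.path(data_dir, "samples.tsv"))
  read_expression_tsv(file.path(data_dir, "expression.tsv"), samples)
}

read_study_tsv <- function(name)
  utils::read.delim(file.path(tab_dir, name), check.names = FALSE)

write_study_tsv <- function(df, name) {
  path <- file.path(tab_dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
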