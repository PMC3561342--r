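# Generate the synthetic two-group study: 10,000 genes, 12 normal + 9 cancer
# samples, planted HK classes / expression modes / variation statuses, an
# intergenic negative set, and gene annotation with planted AT-richness in
# the cancer-associated class.

source("analysis/00_common.R")

cfg <- study_config()
sim <- simulate_expression(cfg)
ann <- simulate_annotation(cfg)
intergenic <- simulate_intergenic(cfg, 10000)

write_expression_tsv(sim$matrix, file.path(data_dir, "expression.tsv"))
write_sample_sheet(sim$matrix$samples, file.path(data_dir, "samples.tsv"))
utils::write.table(sim$truth, file.path(data_dir, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(region = seq_along(intergenic),
                              value = intergenic),
                   file.path(data_dir, "intergenic.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_annotation_bed12(ann, file.path(data_dir, "annotation.bed"))

message(sprintf("simulated %d genes x %d samples (seed %d)",
                nrow(sim$matrix$values), ncol(sim$matrix$values), cfg$seed))
message(sprintf("planted classes: %s",
                paste(names(table(sim$truth$class)),
                      table(sim$truth$class), collapse = ", ")))
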