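# Classify genes into the five HK types from expression breadth at the
# unified background threshold, and check recovery against the planted truth.

source("analysis/00_common.R")

x <- read_study_matrix()
bg <- read_study_tsv("background_unified.tsv")$value

catalog <- classify_five_types(define_hk(x, bg, "normal"),
                               define_hk(x, bg, "cancer"),
                               rownames(x$values))
write_study_tsv(data.frame(gene_id = names(catalog$class),
                           class = catalog$class), "hk_catalog.tsv")
write_study_tsv(catalog_accounting(catalog, nrow(x$values)),
                "hk_accounting.tsv")

truth <- utils::read.delim(file.path(data_dir, "truth.tsv"))
truth_class <- ifelse(truth$class == "tissue_specific", "non_HK", truth$class)
agree <- mean(catalog$class[truth$gene_id] == truth_class)
message(sprintf("HK sets: normal %d, cancer %d, shared %d, non-HK %d",
                catalog$counts[["normal_HK"]], catalog$counts[["cancer_HK"]],
                catalog$counts[["shared"]], catalog$counts[["non_HK"]]))
message(sprintf("agreement with planted classes: %.2f%%", 100 * agree))
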