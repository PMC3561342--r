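# Gene-structure bias per HK class: feature medians and rank-sum shifts of
# each class against the genome background.

source("analysis/00_common.R")

ann <- read_annotation_bed12(file.path(data_dir, "annotation.bed"))
catalog <- read_study_tsv("hk_catalog.tsv")
structures <- structure_table(ann)

cls <- setNames(catalog$class, catalog$gene_id)
normal_hk <- names(cls)[cls %in% c("shared", "normal_unique")]
cancer_hk <- names(cls)[cls %in% c("shared", "cancer_associated")]
cat5 <- classify_five_types(normal_hk, cancer_hk, names(cls))

bias <- class_bias(structures, cat5)
write_study_tsv(structures, "gene_structures.tsv")
write_study_tsv(bias, "structure_bias.tsv")

gc_ca <- bias[bias$class == "cancer_associated" & bias$feature == "gc", ]
message(sprintf(
  "cancer-associated GC median %.3f vs background %.3f (p = %.3g, direction %d)",
  gc_ca$class_median, gc_ca$background_median, gc_ca$p_value, gc_ca$direction))
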