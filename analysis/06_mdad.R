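# MDAD statistics (span and mid-level differences of log2 group extremes),
# maxR/minR extreme ratios, paired signed-rank tests per variation subtype,
# and the accumulation tables for shared and cancer-associated HK genes.

source("analysis/00_common.R")

x <- read_study_matrix()
catalog <- read_study_tsv("hk_catalog.tsv")
cvst <- read_study_tsv("cv_status.tsv")
st_n <- setNames(cvst$status_normal, cvst$gene_id)
st_c <- setNames(cvst$status_cancer, cvst$gene_id)

rec <- ratios(mdad(group_extremes(x)))
write_study_tsv(rec, "mdad_records.tsv")

shared <- catalog$gene_id[catalog$class == "shared"]
ca <- catalog$gene_id[catalog$class == "cancer_associated"]
sum_sh <- mdad_test_summary(rec[rec$gene_id %in% shared, ], st_n)
sum_ca <- mdad_test_summary(rec[rec$gene_id %in% ca, ], st_c)
write_study_tsv(sum_sh, "mdad_summary_shared.tsv")
write_study_tsv(sum_ca, "mdad_summary_cancer_associated.tsv")
write_study_tsv(accumulated_ratio_table(rec[rec$gene_id %in% shared, ], st_n),
                "accumulation_shared.tsv")
write_study_tsv(accumulated_ratio_table(rec[rec$gene_id %in% ca, ], st_c),
                "accumulation_cancer_associated.tsv")

ad <- sum_sh[sum_sh$type == "AD", ]
message(sprintf("shared HK genes AD test: Z = %.2f, p = %.3g (reject = %d)",
                ad$Z, ad$p_value, ad$reject))
acc <- accumulated_ratio_table(rec[rec$gene_id %in% shared, ])
message(sprintf("shared HK genes with minR <= 1: %.2f%%; maxR <= 1: %.2f%%",
                acc$minR_le_pct[1], acc$maxR_le_pct[1]))
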