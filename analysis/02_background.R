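# Estimate the expressed/not-expressed background threshold per sample by
# coordinating FPR (intergenic called expressed) against FNR (genes called
# silent), then unify across samples by the median.

source("analysis/00_common.R")

x <- read_study_matrix()
intergenic <- read_study_tsv("../data/intergenic.tsv")$value

thr <- background_thresholds(x, intergenic)
write_study_tsv(data.frame(sample_id = names(thr$per_sample),
                           group = x$samples$group,
                           threshold = thr$per_sample),
                "background_thresholds.tsv")
write_study_tsv(data.frame(quantity = "unified_background",
                           value = thr$unified), "background_unified.tsv")

message(sprintf("per-sample thresholds span %.3f-%.3f RPKM; unified median %.3f",
                min(thr$per_sample), max(thr$per_sample), thr$unified))
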