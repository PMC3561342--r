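# Partition each sample's expressed genes into LEG/MEG/HEG with the
# one-dimensional weighted k-medians and unify low/high thresholds as the
# medians over the normal group (the control standard).

source("analysis/00_common.R")

x <- read_study_matrix()
bg <- read_study_tsv("background_unified.tsv")$value

tri <- trilevel_matrix(x, bg)
write_study_tsv(tri$per_sample, "trilevel_thresholds.tsv")
write_study_tsv(data.frame(quantity = c("unified_low", "unified_high"),
                           value = unname(tri$unified)),
                "trilevel_unified.tsv")

message(sprintf("low thresholds span %.2f-%.2f, high %.2f-%.2f RPKM",
                min(tri$per_sample$low), max(tri$per_sample$low),
                min(tri$per_sample$high), max(tri$per_sample$high)))
message(sprintf("unified (normal-group medians): low %.2f, high %.2f RPKM",
                tri$unified[["low"]], tri$unified[["high"]]))
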