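# Rank expression 1/2/3 with the unified thresholds, compute the rank-based
# CV per gene and condition, derive constant/variable cutoffs from the
# normal-group quartiles, and tabulate status transitions of shared HK genes.

source("analysis/00_common.R")

x <- read_study_matrix()
bg <- read_study_tsv("background_unified.tsv")$value
uni <- read_study_tsv("trilevel_unified.tsv")$value
catalog <- read_study_tsv("hk_catalog.tsv")

ranks <- assign_ranks(x, uni[1], uni[2], bg)
cv_n <- cv_values(ranks, group = "normal", samples = x$samples)
cv_c <- cv_values(ranks, group = "cancer", samples = x$samples)
normal_hk <- catalog$gene_id[catalog$class %in% c("shared", "normal_unique")]
cuts <- cv_thresholds(cv_n[normal_hk])
st_n <- variation_status(cv_n, cuts[["q1"]], cuts[["q3"]])
st_c <- variation_status(cv_c, cuts[["q1"]], cuts[["q3"]])

write_study_tsv(data.frame(gene_id = names(cv_n), cv_normal = cv_n,
                           cv_cancer = cv_c, status_normal = st_n,
                           status_cancer = st_c), "cv_status.tsv")
shared <- catalog$gene_id[catalog$class == "shared"]
tm <- transition_matrix(st_n[shared], st_c[shared])
write_study_tsv(cbind(normal_status = rownames(tm),
                      as.data.frame.matrix(tm)), "status_transitions.tsv")

message(sprintf("control CV quartiles: q1 %.3f, q3 %.3f", cuts[1], cuts[2]))
message(sprintf("%d of %d shared HK genes change variation status in cancer",
                sum(tm) - sum(diag(tm)), sum(tm)))
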