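# Spearman-correlation hierarchical clustering of sample profiles and the
# two-group separation readout.

source("analysis/00_common.R")

x <- read_study_matrix()
tree <- hierarchical_cluster(spearman_matrix(x))
labels <- setNames(x$samples$group, x$samples$sample_id)
cut2 <- cut_k(tree, 2, labels)

write_tree_newick(tree, file.path(tab_dir, "sample_tree.nwk"))
write_study_tsv(data.frame(sample_id = names(cut2$partition),
                           cluster = cut2$partition,
                           group = labels[names(cut2$partition)]),
                "cluster_partition_k2.tsv")

message(sprintf("two-cluster purity against condition labels: %.3f",
                cut2$purity))
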