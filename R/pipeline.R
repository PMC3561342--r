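#' Run the full expression-pattern analysis
#'
#' End-to-end orchestration over an expression matrix with group labels and
#' an intergenic negative set: background thresholding, five-type HK
#' classification, tri-level thresholds, rank-CV variation statuses and
#' transitions, MDAD/ratio statistics with signed-rank tests, Spearman
#' profile clustering, and (when annotation is supplied) gene-structure
#' bias. Deterministic given its inputs; the only randomness in the whole
#' pipeline is the optional k-medians restarts.
#'
#' Variation statuses are computed per condition with the control (normal
#' group) CV quartiles as cutoffs for both conditions. Subtype tables over
#' the shared HK genes are emitted under both the normal-condition and the
#' cancer-condition status partition; cancer-associated subtype tables use
#' the cancer-condition statuses (those genes need not be expressed in every
#' normal sample).
#'
#' @param x An [expr_matrix()].
#' @param intergenic Intergenic negative-set values (see
#'   [simulate_intergenic()]).
#' @param annotation Optional annotation `data.frame`
#'   ([simulate_annotation()] layout) for structure bias.
#' @param total_loci Locus total for accounting percentages (defaults to the
#'   number of genes in `x`).
#' @param outdir Optional directory: report tables are written as TSVs plus
#'   a JSON run manifest.
#' @param background Optional override of the unified background threshold.
#' @param restarts,kmedians_seed Passed to [weighted_kmedians_1d()].
#' @param alpha Signed-rank rejection level.
#' @return List of all stage results (thresholds, catalog, accounting,
#'   trilevel tables, CV cutoffs and statuses, transition matrix, MDAD
#'   records and summaries, accumulation tables, clustering, structure
#'   bias).
#' @export
run_pipeline <- function(x, intergenic, annotation = NULL,
                         total_loci = nrow(x$values), outdir = NULL,
                         background = NULL, restarts = 0, kmedians_seed = 1L,
                         alpha = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  res <- list()

  bg <- background_thresholds(x, intergenic)
  if (!is.null(background)) bg$unified <- background
  res$background <- bg

  normal_hk <- define_hk(x, bg$unified, "normal")
  cancer_hk <- define_hk(x, bg$unified, "cancer")
  catalog <- classify_five_types(normal_hk, cancer_hk, rownames(x$values))
  res$catalog <- catalog
  res$accounting <- catalog_accounting(catalog, total_loci)

  tri <- trilevel_matrix(x, bg$unified, restarts = restarts,
                         seed = kmedians_seed)
  res$trilevel <- tri

  ranks <- assign_ranks(x, tri$unified[["low"]], tri$unified[["high"]],
                        bg$unified)
  res$ranks <- ranks
  cv_n <- cv_values(ranks, group = "normal", samples = x$samples)
  cv_c <- cv_values(ranks, group = "cancer", samples = x$samples)
  cuts <- cv_thresholds(cv_n[catalog$normal_HK])
  res$cv <- list(normal = cv_n, cancer = cv_c, q1 = cuts[["q1"]],
                 q3 = cuts[["q3"]])
  st_n <- variation_status(cv_n, cuts[["q1"]], cuts[["q3"]])
  st_c <- variation_status(cv_c, cuts[["q1"]], cuts[["q3"]])
  res$status <- list(normal = st_n, cancer = st_c)
  res$transitions <- transition_matrix(st_n[catalog$shared],
                                       st_c[catalog$shared])

  ext <- group_extremes(x)
  rec <- ratios(mdad(ext))
  res$mdad_records <- rec
  shared_rec <- rec[rec$gene_id %in% catalog$shared, , drop = FALSE]
  ca_rec <- rec[rec$gene_id %in% catalog$cancer_associated, , drop = FALSE]
  res$mdad_summary_shared <- mdad_test_summary(shared_rec, st_n, alpha)
  res$mdad_summary_cancer_associated <-
    mdad_test_summary(ca_rec, st_c, alpha)
  res$accumulation_shared_status_normal <-
    accumulated_ratio_table(shared_rec, st_n)
  res$accumulation_shared_status_cancer <-
    accumulated_ratio_table(shared_rec, st_c)
  res$accumulation_cancer_associated <-
    accumulated_ratio_table(ca_rec, st_c)

  tree <- hierarchical_cluster(spearman_matrix(x))
  labels <- setNames(x$samples$group, x$samples$sample_id)
  res$cluster <- list(tree = tree, cut2 = cut_k(tree, 2, labels))

  if (!is.null(annotation)) {
    structures <- structure_table(annotation)
    res$structure_bias <- class_bias(structures, catalog)
  }

  if (!is.null(outdir)) write_pipeline_reports(res, x, outdir)
  res
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write pipeline report tables to a directory
#'
#' @param res Result of [run_pipeline()].
#' @param x The analysed [expr_matrix()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_reports <- function(res, x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(data.frame(sample_id = names(res$background$per_sample),
                       threshold = res$background$per_sample),
            file.path(outdir, "background_thresholds.tsv"))
  write_tsv(data.frame(gene_id = names(res$catalog$class),
                       class = res$catalog$class),
            file.path(outdir, "hk_catalog.tsv"))
  write_tsv(res$accounting, file.path(outdir, "hk_accounting.tsv"))
  write_tsv(res$trilevel$per_sample, file.path(outdir, "trilevel_thresholds.tsv"))
  write_tsv(data.frame(gene_id = names(res$cv$normal),
                       cv_normal = res$cv$normal,
                       cv_cancer = res$cv$cancer,
                       status_normal = res$status$normal,
                       status_cancer = res$status$cancer),
            file.path(outdir, "cv_status.tsv"))
  tm <- as.data.frame.matrix(res$transitions)
  write_tsv(cbind(normal_status = rownames(tm), tm),
            file.path(outdir, "status_transitions.tsv"))
  write_tsv(res$mdad_records, file.path(outdir, "mdad_records.tsv"))
  write_tsv(res$mdad_summary_shared,
            file.path(outdir, "mdad_summary_shared.tsv"))
  write_tsv(res$mdad_summary_cancer_associated,
            file.path(outdir, "mdad_summary_cancer_associated.tsv"))
  write_tsv(res$accumulation_shared_status_normal,
            file.path(outdir, "accumulation_shared_status_normal.tsv"))
  write_tsv(res$accumulation_shared_status_cancer,
            file.path(outdir, "accumulation_shared_status_cancer.tsv"))
  write_tsv(res$accumulation_cancer_associated,
            file.path(outdir, "accumulation_cancer_associated.tsv"))
  write_tree_newick(res$cluster$tree, file.path(outdir, "sample_tree.nwk"))
  if (!is.null(res$structure_bias))
    write_tsv(res$structure_bias, file.path(outdir, "structure_bias.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hkatlas")),
    n_genes = nrow(x$values),
    n_normal = sum(x$samples$group == "normal"),
    n_cancer = sum(x$samples$group == "cancer"),
    unified_background = res$background$unified,
    unified_low = res$trilevel$unified[["low"]],
    unified_high = res$trilevel$unified[["high"]],
    cv_q1 = res$cv$q1, cv_q3 = res$cv$q3,
    cluster_purity_k2 = res$cluster$cut2$purity
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
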