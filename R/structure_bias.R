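#' Structural features of one gene
#'
#' Derives intron lengths from the exon gaps of the representative
#' transcript and summarises the features compared across HK classes: gene
#' size, CDS length, exon count, counts of minimal and large introns, and GC
#' content. Intron-length cutoffs are configurable; defaults follow common
#' usage in the gene-architecture literature (minimal <= 125 bp, large >=
#' 50 kb).
#'
#' @param exon_sizes,exon_starts Comma-separated block sizes and 0-based
#'   relative starts (BED12 convention) of the representative transcript.
#' @param cds_length_bp CDS length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param minimal_intron_max_bp,large_intron_min_bp Intron class cutoffs.
#' @return One-row `data.frame`: `gene_size_bp`, `cds_length_bp`, `n_exons`,
#'   `n_minimal_introns`, `n_large_introns`, `gc`.
#' @export
gene_structure <- function(exon_sizes, exon_starts, cds_length_bp, gc,
                           minimal_intron_max_bp = 125,
                           large_intron_min_bp = 50000) {
  sz <- as.integer(strsplit(exon_sizes, ",")[[1]])
  st <- as.integer(strsplit(exon_starts, ",")[[1]])
  if (length(sz) == 0 || length(sz) != length(st))
    stop_input("invalid exon blocks")
  ne <- length(sz)
  span <- st[ne] + sz[ne] - st[1]
  introns <- if (ne > 1) st[-1] - (st[-ne] + sz[-ne]) else integer(0)
  if (any(introns < 0)) stop_input("overlapping exon blocks")
  data.frame(
    gene_size_bp = span,
    cds_length_bp = cds_length_bp,
    n_exons = ne,
    n_minimal_introns = sum(introns <= minimal_intron_max_bp),
    n_large_introns = sum(introns >= large_intron_min_bp),
    gc = gc
  )
}

#' Structure table for a whole annotation
#'
#' @param annotation Annotation `data.frame` in the [simulate_annotation()]
#'   layout (or read back via [read_annotation_bed12()]).
#' @param ... Intron cutoffs passed to [gene_structure()].
#' @return `data.frame` with `gene_id` plus the [gene_structure()] columns.
#' @export
structure_table <- function(annotation, ...) {
  rows <- lapply(seq_len(nrow(annotation)), function(i)
    gene_structure(annotation$exon_sizes[i], annotation$exon_starts[i],
                   annotation$cds_length_bp[i], annotation$gc[i], ...))
  cbind(data.frame(gene_id = annotation$gene_id, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Gene-structure bias per HK class
#'
#' For every HK class and structural feature: the class median, the
#' genome-background (all genes) median, a two-sided rank-sum
#' (Mann-Whitney) p-value of the class against the background, and the
#' direction of shift (sign of the median difference).
#'
#' @param structures Output of [structure_table()].
#' @param catalog An `hk_catalog` from [classify_five_types()].
#' @param classes Which catalog sets to compare (defaults to the five HK
#'   types).
#' @return `data.frame`: `class`, `feature`, `n`, `class_median`,
#'   `background_median`, `p_value`, `direction` (-1/0/+1).
#' @export
class_bias <- function(structures, catalog,
                       classes = c("shared", "normal_unique",
                                   "cancer_associated", "normal_HK",
                                   "cancer_HK")) {
  stopifnot(inherits(catalog, "hk_catalog"))
  features <- c("gene_size_bp", "cds_length_bp", "n_exons",
                "n_minimal_introns", "n_large_introns", "gc")
  rows <- list()
  for (cl in classes) {
    ids <- catalog[[cl]]
    ids <- intersect(ids, structures$gene_id)
    if (length(ids) == 0) {
      warning(sprintf("class '%s' is empty; skipped", cl))
      next
    }
    sub <- structures[structures$gene_id %in% ids, , drop = FALSE]
    for (f in features) {
      p <- suppressWarnings(
        stats::wilcox.test(sub[[f]], structures[[f]])$p.value)
      cm <- stats::median(sub[[f]])
      bm <- stats::median(structures[[f]])
      rows[[paste(cl, f)]] <- data.frame(
        class = cl, feature = f, n = nrow(sub),
        class_median = cm, background_median = bm,
        p_value = p, direction = sign(cm - bm), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
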