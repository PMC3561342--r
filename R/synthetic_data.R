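#' Configuration for the synthetic two-group RNA-Seq study
#'
#' The generator emulates a bulk RNA-Seq design with one normal group and one
#' cancer group. Genes are planted into four classes — `shared` (expressed
#' above background in every sample), `normal_unique` (ubiquitous in the
#' normal group, off in at least one cancer sample), `cancer_associated`
#' (the mirror image) and `tissue_specific` (off in at least one sample of
#' each group). Expression levels come from a tri-modal log-normal mixture
#' (low / moderate / high modes with a heavy right tail); per-sample
#' variability is multiplicative log2-normal noise whose spread is set by a
#' planted variation status (constant / moderate / variable); a configurable
#' fraction of shared and cancer-associated genes is up-regulated in the
#' cancer group by a fixed log2 fold change. Intergenic (negative-set)
#' signal is a separate low log-normal density used for background
#' thresholding.
#'
#' @param n_genes Number of genes.
#' @param n_normal_samples,n_cancer_samples Group sizes (defaults 12 and 9,
#'   the reference study design).
#' @param class_fractions Named fractions over
#'   `shared`/`normal_unique`/`cancer_associated`/`tissue_specific`, summing
#'   to 1.
#' @param level_meanlog,level_sdlog,level_weights Tri-modal log-normal mixture
#'   for the low/moderate/high expression modes (RPKM scale). Defaults put the
#'   mode medians at 0.5, 4 and 40 RPKM.
#' @param dropout_rate Probability that a sample on the "off" side of a
#'   planted class is silent in that sample.
#' @param cancer_upregulation_log2fc Log2 fold change applied in the cancer
#'   group to the up-regulated fraction of shared and cancer-associated genes.
#' @param upregulated_fraction Fraction of shared + cancer-associated genes
#'   receiving the fold change.
#' @param variation_fractions Planted fractions of
#'   constant/moderate/variable genes (matching the quartile-based status
#'   definition used downstream).
#' @param variation_sd Per-status log2 noise standard deviations.
#' @param intergenic_meanlog,intergenic_sdlog Log-normal parameters for the
#'   intergenic negative set, concentrated well below the low expression mode.
#' @param at_rich_shift GC fraction subtracted from cancer-associated genes'
#'   mean GC content.
#' @param ca_size_log2_shift Log2 shift applied to cancer-associated gene
#'   sizes (negative values plant large-gene depletion).
#' @param min_on_rpkm Guarantee floor: every "on" cell exceeds this value, so
#'   planted classes survive background thresholding.
#' @param off_anchor_max_rpkm Ceiling for the one anchor "off" cell that
#'   certifies each planted off requirement.
#' @param off_max_rpkm Ceiling for the remaining off cells.
#' @param force_zero If `TRUE`, off cells are exactly 0 instead of intergenic
#'   draws (degenerate configuration for exact tests).
#' @param seed Integer seed; fixes all randomness. Annotation, expression and
#'   intergenic draws use `seed`, `seed + 1L` and `seed + 2L` respectively.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000,
                       n_normal_samples = 12, n_cancer_samples = 9,
                       class_fractions = c(shared = 0.5, normal_unique = 0.2,
                                           cancer_associated = 0.1,
                                           tissue_specific = 0.2),
                       level_meanlog = log(c(0.5, 4, 40)),
                       level_sdlog = c(0.4, 0.5, 0.5),
                       level_weights = c(0.25, 0.60, 0.15),
                       dropout_rate = 0.3,
                       cancer_upregulation_log2fc = 1,
                       upregulated_fraction = 0.5,
                       variation_fractions = c(constant = 0.25,
                                               moderate_variable = 0.50,
                                               variable = 0.25),
                       variation_sd = c(constant = 0.5,
                                        moderate_variable = 1.2,
                                        variable = 2.2),
                       intergenic_meanlog = log(0.1),
                       intergenic_sdlog = 0.6,
                       at_rich_shift = 0.10,
                       ca_size_log2_shift = 0,
                       min_on_rpkm = 0.35,
                       off_anchor_max_rpkm = 0.05,
                       off_max_rpkm = 0.20,
                       force_zero = FALSE,
                       seed = 1L) {
  cf <- class_fractions
  need <- c("shared", "normal_unique", "cancer_associated", "tissue_specific")
  if (!setequal(names(cf), need)) stop_input("class_fractions must name %s",
                                             paste(need, collapse = ", "))
  if (abs(sum(cf) - 1) > 1e-9) stop_input("class_fractions must sum to 1")
  if (n_genes < 4) stop_input("need n_genes >= 4 to host all four classes")
  if (any(c(level_sdlog, variation_sd, intergenic_sdlog) < 0))
    stop_input("standard deviations must be >= 0")
  if (cancer_upregulation_log2fc < 0)
    stop_input("cancer_upregulation_log2fc must be >= 0")
  if (abs(sum(level_weights) - 1) > 1e-9)
    stop_input("level_weights must sum to 1")
  if (abs(sum(variation_fractions) - 1) > 1e-9)
    stop_input("variation_fractions must sum to 1")
  if (seed < 0 || seed > 2^31 - 10) stop_input("seed out of range")
  structure(as.list(environment()), class = "sim_config")
}

# Deterministic class assignment: contiguous blocks in gene order, sized by
# largest-remainder apportionment of the fractions. Gene order carries no
# meaning, so no shuffle is needed, and annotation/expression stay consistent.
assign_classes <- function(n_genes, fractions) {
  need <- c("shared", "normal_unique", "cancer_associated", "tissue_specific")
  raw <- fractions[need] * n_genes
  k <- floor(raw)
  rem <- n_genes - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  if (any(fractions[need] > 0 & k == 0))
    stop_input("class fractions incompatible with n_genes = %d", n_genes)
  rep(need, times = k)
}

apportion <- function(n, fractions) {
  raw <- fractions * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  k
}

#' Simulate gene annotation with planted structural bias
#'
#' Draws per-gene exon/intron architecture (heavy-tailed gene sizes, a mix of
#' minimal, typical and large introns), CDS length and GC content. GC of
#' cancer-associated genes is lowered by `at_rich_shift`; their sizes can be
#' shifted by `ca_size_log2_shift`. Genes are laid head-to-tail along one
#' synthetic chromosome.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with one row per gene: coordinates, strand,
#'   `gene_size_bp`, `cds_length_bp`, `n_exons`, comma-separated
#'   `exon_sizes`/`exon_starts` (BED12 block convention, 0-based starts
#'   relative to the gene start), `gc` and the planted `class`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  cls <- assign_classes(n, config$class_fractions)

  n_exons <- 1L + stats::rpois(n, 7)
  size_shift <- ifelse(cls == "cancer_associated",
                       2^config$ca_size_log2_shift, 1)
  genes <- vector("list", n)
  cursor <- 10000L
  for (i in seq_len(n)) {
    ne <- n_exons[i]
    ex_len <- pmax(30L, round(stats::rlnorm(ne, log(150), 0.6)))
    if (ne > 1) {
      kind <- sample(c("minimal", "typical", "large"), ne - 1L, replace = TRUE,
                     prob = c(0.15, 0.80, 0.05))
      in_len <- integer(ne - 1L)
      in_len[kind == "minimal"] <- round(stats::runif(sum(kind == "minimal"), 30, 125))
      in_len[kind == "large"] <- round(stats::runif(sum(kind == "large"), 5e4, 2e5))
      nt <- sum(kind == "typical")
      in_len[kind == "typical"] <-
        pmin(49000L, pmax(126L, round(stats::rlnorm(nt, log(1500), 1) * size_shift[i])))
    } else in_len <- integer(0)
    starts <- cumsum(c(0L, ex_len[-ne] + in_len))
    span <- starts[ne] + ex_len[ne]
    cds <- max(90L, round(0.8 * sum(ex_len)))
    genes[[i]] <- list(start = cursor, ex_len = ex_len, ex_start = starts,
                       span = span, cds = min(cds, span))
    cursor <- cursor + span + 10000L
  }
  gc <- stats::rnorm(n, 0.46, 0.08)
  gc[cls == "cancer_associated"] <- gc[cls == "cancer_associated"] -
    config$at_rich_shift
  gc <- pmin(0.85, pmax(0.05, gc))

  data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = "chrS",
    start = vapply(genes, `[[`, numeric(1), "start"),
    end = vapply(genes, function(g) g$start + g$span, numeric(1)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_size_bp = vapply(genes, `[[`, numeric(1), "span"),
    cds_length_bp = vapply(genes, `[[`, numeric(1), "cds"),
    n_exons = n_exons,
    exon_sizes = vapply(genes, function(g) paste(g$ex_len, collapse = ","),
                        character(1)),
    exon_starts = vapply(genes, function(g) paste(g$ex_start, collapse = ","),
                         character(1)),
    gc = gc,
    class = cls,
    stringsAsFactors = FALSE
  )
}

#' Simulate the two-group expression matrix with planted truth
#'
#' Each gene draws a base level from the tri-modal mixture, a variation
#' status per group, and an on/off pattern dictated by its planted class.
#' "On" cells are `base * 2^(fold change in cancer, if up-regulated) *
#' 2^(noise)`; draws are kept above `min_on_rpkm` (base truncation plus
#' cell-level redraws, floored after 50 attempts) so planted classes survive
#' any plausible background threshold. "Off" cells are intergenic-density
#' draws capped at `off_max_rpkm`; one anchor off cell per planted off
#' requirement is capped at `off_anchor_max_rpkm`, pinning the class label.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (an [expr_matrix()]) and `truth` (`data.frame`
#'   of per-gene class, level mode, per-group variation status, log2 fold
#'   change).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  nn <- config$n_normal_samples
  nc <- config$n_cancer_samples
  cls <- assign_classes(n, config$class_fractions)

  mode_idx <- sample(1:3, n, replace = TRUE, prob = config$level_weights)
  base <- stats::rlnorm(n, config$level_meanlog[mode_idx],
                        config$level_sdlog[mode_idx])
  # keep bases clear of the on-floor so the planted mixture stays tri-modal
  lo <- base < config$min_on_rpkm * 1.25
  for (tries in 1:100) {
    if (!any(lo)) break
    base[lo] <- stats::rlnorm(sum(lo), config$level_meanlog[mode_idx[lo]],
                              config$level_sdlog[mode_idx[lo]])
    lo <- base < config$min_on_rpkm * 1.25
  }
  base[lo] <- config$min_on_rpkm * 1.25

  statuses <- names(config$variation_fractions)
  status_n <- sample(statuses, n, replace = TRUE, prob = config$variation_fractions)
  status_c <- sample(statuses, n, replace = TRUE, prob = config$variation_fractions)

  upreg_pool <- cls %in% c("shared", "cancer_associated")
  upreg <- upreg_pool & stats::runif(n) < config$upregulated_fraction
  log2fc <- ifelse(upreg, config$cancer_upregulation_log2fc, 0)

  # on/off pattern per planted class; anchors certify the off requirements
  on <- matrix(TRUE, n, nn + nc)
  is_cancer <- c(rep(FALSE, nn), rep(TRUE, nc))
  plant_off <- function(on_row, side_idx) {
    off <- stats::runif(length(side_idx)) < config$dropout_rate
    if (!any(off)) off[sample(length(side_idx), 1)] <- TRUE
    on_row[side_idx[off]] <- FALSE
    on_row
  }
  for (i in seq_len(n)) {
    if (cls[i] == "normal_unique") {
      on[i, ] <- plant_off(on[i, ], which(is_cancer))
    } else if (cls[i] == "cancer_associated") {
      on[i, ] <- plant_off(on[i, ], which(!is_cancer))
    } else if (cls[i] == "tissue_specific") {
      on[i, ] <- plant_off(on[i, ], which(!is_cancer))
      on[i, ] <- plant_off(on[i, ], which(is_cancer))
    }
  }

  sd_n <- config$variation_sd[status_n]
  sd_c <- config$variation_sd[status_c]
  vals <- matrix(0, n, nn + nc)
  for (j in seq_len(nn + nc)) {
    sdj <- if (is_cancer[j]) sd_c else sd_n
    v <- base * 2^(if (is_cancer[j]) log2fc else 0) * 2^stats::rnorm(n, 0, sdj)
    low <- v <= config$min_on_rpkm
    for (tries in 1:50) {
      if (!any(low)) break
      v[low] <- base[low] * 2^(if (is_cancer[j]) log2fc[low] else 0) *
        2^stats::rnorm(sum(low), 0, sdj[low])
      low <- v <= config$min_on_rpkm
    }
    v[low] <- config$min_on_rpkm * 1.05
    vals[, j] <- v
  }

  # off cells: intergenic-level draws (truncated), or exact zeros
  n_off <- sum(!on)
  if (n_off > 0) {
    if (config$force_zero) {
      vals[!on] <- 0
    } else {
      draw_trunc <- function(k, cap) {
        u <- stats::runif(k, 0, stats::plnorm(cap, config$intergenic_meanlog,
                                              config$intergenic_sdlog))
        stats::qlnorm(u, config$intergenic_meanlog, config$intergenic_sdlog)
      }
      vals[!on] <- draw_trunc(n_off, config$off_max_rpkm)
      # one anchor per gene per off-side group, pinned far below background
      for (i in which(cls != "shared")) {
        for (side in list(which(!is_cancer), which(is_cancer))) {
          off_side <- side[!on[i, side]]
          if (length(off_side) > 0)
            vals[i, off_side[1]] <- draw_trunc(1, config$off_anchor_max_rpkm)
        }
      }
    }
  }

  samples <- data.frame(
    sample_id = c(sprintf("normal_%02d", seq_len(nn)),
                  sprintf("cancer_%02d", seq_len(nc))),
    group = c(rep("normal", nn), rep("cancer", nc)),
    total_mapped_reads = rep(2e7, nn + nc)
  )
  rownames(vals) <- sprintf("g%05d", seq_len(n))
  truth <- data.frame(
    gene_id = rownames(vals),
    class = cls,
    level_mode = c("low", "moderate", "high")[mode_idx],
    status_normal = status_n,
    status_cancer = status_c,
    log2fc = log2fc,
    stringsAsFactors = FALSE
  )
  list(matrix = expr_matrix(vals, samples), truth = truth)
}

#' Simulate the intergenic negative set
#'
#' Draws `n_regions` intergenic expression densities from the configured
#' log-normal, concentrated well below the low expression mode; these form
#' the negative set for background thresholding.
#'
#' @param config A [sim_config()].
#' @param n_regions Number of intergenic regions.
#' @return Numeric vector of non-negative expression densities.
#' @export
simulate_intergenic <- function(config, n_regions) {
  stopifnot(inherits(config, "sim_config"))
  if (n_regions <= 0) stop_input("n_regions must be positive")
  set.seed(config$seed + 2L)
  stats::rlnorm(n_regions, config$intergenic_meanlog, config$intergenic_sdlog)
}

#' Write simulated annotation as BED12 (plus a structure side table)
#'
#' BED12 carries coordinates and exon blocks; GC content, CDS length and the
#' planted class go to `<path>.meta.tsv` since BED has no such columns.
#' Requires the `rtracklayer` stack.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param path Output BED file path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  blocks <- mapply(function(sz, st) {
    sz <- as.integer(strsplit(sz, ",")[[1]])
    st <- as.integer(strsplit(st, ",")[[1]])
    IRanges::IRanges(start = st + 1L, width = sz)
  }, annotation$exon_sizes, annotation$exon_starts, SIMPLIFY = FALSE)
  gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1L, annotation$end),
    strand = annotation$strand,
    name = annotation$gene_id,
    blocks = methods::as(blocks, "IRangesList")
  )
  rtracklayer::export(gr, path, format = "bed")
  meta <- annotation[, c("gene_id", "cds_length_bp", "gc", "class")]
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BED12 annotation written by [write_annotation_bed12()]
#' @param path BED file path.
#' @return Annotation `data.frame` in the [simulate_annotation()] layout.
#' @export
read_annotation_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  sizes <- vapply(blocks, function(b) paste(IRanges::width(b), collapse = ","),
                  character(1))
  starts <- vapply(blocks, function(b)
    paste(IRanges::start(b) - 1L, collapse = ","), character(1))
  out <- data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_size_bp = GenomicRanges::width(gr),
    n_exons = lengths(blocks),
    exon_sizes = sizes,
    exon_starts = starts,
    stringsAsFactors = FALSE
  )
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    out <- merge(out, meta, by = "gene_id", sort = FALSE)
  }
  out[order(out$gene_id), , drop = FALSE]
}
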