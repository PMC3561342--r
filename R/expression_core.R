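#' Expression matrix with sample metadata
#'
#' Light container for a genes-by-samples matrix of non-negative expression
#' values (RPKM) plus a sample sheet. The sample sheet must carry one row per
#' matrix column, in column order, with the sample's group label
#' (`"normal"` or `"cancer"`) and its library size.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids, unique),
#'   samples in columns.
#' @param samples `data.frame` with columns `sample_id`, `group`
#'   (`"normal"`/`"cancer"`) and `total_mapped_reads` (positive integers).
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `samples`.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2, dimnames = list(c("g1", "g2"), NULL))
#' sm <- data.frame(sample_id = c("s1", "s2"), group = c("normal", "cancer"),
#'                  total_mapped_reads = c(1e6, 2e6))
#' em <- expr_matrix(m, sm)
#' dim(em)
#' @export
expr_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("'values' must be a numeric matrix")
  if (is.null(rownames(values)))
    stop_input("'values' must have gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop_input("duplicate gene ids: %s",
               paste(unique(rownames(values)[duplicated(rownames(values))]),
                     collapse = ", "))
  if (any(values < 0)) stop_input("expression values must be non-negative")
  req <- c("sample_id", "group", "total_mapped_reads")
  if (!all(req %in% names(samples)))
    stop_input("sample sheet must have columns %s", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop_input("sample sheet rows (%d) != matrix columns (%d)",
               nrow(samples), ncol(values))
  if (anyDuplicated(samples$sample_id)) stop_input("duplicate sample ids")
  if (!all(samples$group %in% c("normal", "cancer")))
    stop_input("sample group must be 'normal' or 'cancer'")
  if (any(samples$total_mapped_reads <= 0))
    stop_input("total_mapped_reads must be positive")
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d normal, %d cancer)\n",
              nrow(x$values), ncol(x$values),
              sum(x$samples$group == "normal"),
              sum(x$samples$group == "cancer")))
  invisible(x)
}

#' Columns of an expression matrix belonging to one group
#' @param x An `expr_matrix`.
#' @param group `"normal"` or `"cancer"`.
#' @return Numeric sub-matrix with that group's samples.
#' @export
group_values <- function(x, group) {
  if (!group %in% c("normal", "cancer"))
    stop_input("unknown group label '%s'", group)
  x$values[, x$samples$group == group, drop = FALSE]
}

#' Reads per kilobase of CDS per million mapped reads
#'
#' RPKM normalises a raw exonic read count by coding-sequence length (kb) and
#' library size (millions of mapped reads), making values comparable across
#' genes and libraries.
#'
#' @param read_count Non-negative read count(s).
#' @param cds_length_bp Positive CDS length(s) in bp.
#' @param total_mapped_reads Positive library size(s).
#' @return RPKM value(s); vectorised over arguments.
#' @examples
#' compute_rpkm(1000, 2000, 1e7) # 50
#' @export
compute_rpkm <- function(read_count, cds_length_bp, total_mapped_reads) {
  if (any(read_count < 0)) stop_input("read_count must be non-negative")
  if (any(cds_length_bp <= 0)) stop_input("cds_length_bp must be positive")
  if (any(total_mapped_reads <= 0))
    stop_input("total_mapped_reads must be positive")
  read_count / (cds_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Sum isoform expression into gene expression
#'
#' A gene's expression is the sum of the expression of all isoforms assigned
#' to it; total expression mass is conserved.
#'
#' @param transcript_expression Named numeric vector, transcript id -> value.
#' @param gene_map Named character vector, transcript id -> gene id.
#' @return Named numeric vector, gene id -> summed expression.
#' @export
aggregate_isoforms <- function(transcript_expression, gene_map) {
  if (length(transcript_expression) == 0) return(setNames(numeric(0), character(0)))
  tx <- names(transcript_expression)
  missing <- setdiff(tx, names(gene_map))
  if (length(missing) > 0)
    stop_input("transcript(s) missing from gene map: %s",
               paste(missing, collapse = ", "))
  g <- gene_map[tx]
  out <- tapply(transcript_expression, g, sum)
  setNames(as.numeric(out), names(out))
}

#' Read / write a genes-by-samples expression TSV
#'
#' Layout: first column `gene_id`, remaining columns one per sample, header
#' row carries sample ids. Values are written at 12 significant digits so a
#' write/read round trip is lossless at that precision.
#'
#' @param path File path.
#' @param samples Sample sheet `data.frame` (see [expr_matrix()]); for
#'   `read_expression_tsv` it is matched to the file's sample columns by id.
#' @return `read_expression_tsv`: an `expr_matrix`.
#' @export
read_expression_tsv <- function(path, samples) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (names(df)[1] != "gene_id") stop_input("first column must be 'gene_id'")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    line <- which(duplicated(ids))[1] + 1L  # +1 for the header line
    stop_input("duplicate gene id '%s' at line %d", ids[duplicated(ids)][1], line)
  }
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad) > 0)
      stop_input("non-numeric cell in column '%s' at line %d",
                 names(body)[j], bad[1] + 1L)
    if (any(v < 0, na.rm = TRUE))
      stop_input("negative value in column '%s' at line %d", names(body)[j],
                 which(v < 0)[1] + 1L)
    body[[j]] <- v
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx))
    stop_input("sample(s) absent from sample sheet: %s",
               paste(colnames(m)[is.na(idx)], collapse = ", "))
  expr_matrix(m, samples[idx, , drop = FALSE])
}

#' @rdname read_expression_tsv
#' @param x An `expr_matrix` to write.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values),
                   signif(x$values, 12), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet TSV
#' @param path File path.
#' @return `read_sample_sheet`: `data.frame` with columns `sample_id`,
#'   `group`, `total_mapped_reads`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "total_mapped_reads")
  if (!all(req %in% names(df)))
    stop_input("sample sheet must have columns %s", paste(req, collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @param samples Sample sheet `data.frame` to write.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
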