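#' Construct a count matrix with gene lengths and sample metadata
#'
#' The raw substrate of the pipeline: a gene-by-sample matrix of non-negative
#' integer read counts (reads mapped per coding sequence), per-gene CDS
#' lengths in base pairs, and per-sample metadata describing genotype, tissue,
#' developmental stage and replicate.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Missing values are not permitted;
#'   absence must be encoded as 0 upstream.
#' @param gene_lengths named numeric vector of positive CDS lengths (bp), one
#'   entry per gene in `counts`.
#' @param metadata data.frame with one row per sample and columns `sample`,
#'   `genotype`, `tissue`, `stage`, `replicate`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_lengths` and `metadata`.
#' @export
count_matrix <- function(counts, gene_lengths, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values; encode absence as 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  nonint <- which(counts != floor(counts), arr.ind = TRUE)
  if (nrow(nonint) > 0)
    stop(sprintf("non-integer count %s at gene '%s', sample '%s'",
                 format(counts[nonint[1, , drop = FALSE]]),
                 rownames(counts)[nonint[1, 1]], colnames(counts)[nonint[1, 2]]))
  storage.mode(counts) <- "double"

  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_len) > 0)
    stop("gene length missing for: ", paste(missing_len, collapse = ", "))
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene lengths must be positive and finite")

  metadata <- as.data.frame(metadata)
  req <- c("sample", "genotype", "tissue", "stage", "replicate")
  miss_col <- setdiff(req, names(metadata))
  if (length(miss_col) > 0)
    stop("metadata missing column(s): ", paste(miss_col, collapse = ", "))
  no_meta <- setdiff(colnames(counts), metadata$sample)
  if (length(no_meta) > 0)
    stop("sample(s) in counts absent from metadata: ", paste(no_meta, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL

  structure(list(counts = counts, gene_lengths = gene_lengths, metadata = metadata),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("genotypes:", paste(unique(x$metadata$genotype), collapse = ", "), "\n")
  cat("stages:   ", paste(unique(x$metadata$stage), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from tab-separated files
#'
#' Reads the three-file on-disk representation: a counts table (first column
#' gene id, remaining columns one per sample), a gene-length table (columns
#' `gene_id`, `length_bp`) and a sample metadata table (columns `sample`,
#' `genotype`, `tissue`, `stage`, `replicate`). Row and column order is
#' preserved from the files. All files are tab-separated UTF-8 with a header
#' row and no quoting.
#'
#' @param counts_path,lengths_path,metadata_path file paths.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(counts_path, lengths_path, metadata_path) {
  ct <- utils::read.delim(counts_path, check.names = FALSE, quote = "")
  counts <- as.matrix(ct[, -1, drop = FALSE])
  rownames(counts) <- as.character(ct[[1]])
  lt <- utils::read.delim(lengths_path, quote = "")
  lengths <- stats::setNames(lt$length_bp, as.character(lt$gene_id))
  md <- utils::read.delim(metadata_path, quote = "",
                          colClasses = c(sample = "character"))
  count_matrix(counts, lengths, md)
}

#' Write a count matrix to tab-separated files
#'
#' Inverse of [read_counts()]: emits the identical TSV dialect so that a
#' write/read round trip reproduces the object.
#'
#' @param cm a [count_matrix()].
#' @param counts_path,lengths_path,metadata_path output file paths.
#' @return Invisibly, `cm`.
#' @export
write_counts <- function(cm, counts_path, lengths_path, metadata_path) {
  ct <- data.frame(gene_id = rownames(cm$counts), cm$counts, check.names = FALSE)
  utils::write.table(ct, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  lt <- data.frame(gene_id = names(cm$gene_lengths), length_bp = cm$gene_lengths)
  utils::write.table(lt, lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cm)
}

#' Reads per kilobase of CDS per million mapped reads
#'
#' Normalizes raw counts against the number of mapped reads (taken as the
#' per-sample column sum) and CDS length:
#' `rpkm[g, s] = counts[g, s] / (length_kb[g] * total_millions[s])`.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of RPKM values with the same dimnames as the counts.
#' @export
rpkm <- function(cm) {
  totals <- colSums(cm$counts)
  zero <- colnames(cm$counts)[totals == 0]
  if (length(zero) > 0)
    stop("sample(s) with zero total counts: ", paste(zero, collapse = ", "))
  sweep(cm$counts / (cm$gene_lengths / 1e3), 2, totals / 1e6, "/")
}

#' Average expression over replicate samples
#'
#' Collapses an expression matrix to one column per metadata group, each the
#' arithmetic mean of the member samples' RPKM values (replicates are averaged
#' on the RPKM scale, not re-derived from summed counts).
#'
#' @param em expression matrix (genes x samples), e.g. from [rpkm()].
#' @param metadata per-sample metadata data.frame covering `colnames(em)`.
#' @param group_by character vector of metadata column names defining the
#'   groups.
#' @return matrix with one column per group, named by the group keys joined
#'   with `"."`; columns appear in order of first occurrence in `metadata`.
#' @export
summarize_replicates <- function(em, metadata,
                                 group_by = c("genotype", "tissue", "stage")) {
  bad <- setdiff(group_by, names(metadata))
  if (length(bad) > 0)
    stop("group_by key(s) absent from metadata: ", paste(bad, collapse = ", "))
  metadata <- metadata[match(colnames(em), metadata$sample), , drop = FALSE]
  key <- do.call(paste, c(metadata[group_by], sep = "."))
  groups <- unique(key)
  out <- vapply(groups, function(g) {
    rowMeans(em[, key == g, drop = FALSE])
  }, numeric(nrow(em)))
  dimnames(out) <- list(rownames(em), groups)
  out
}
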