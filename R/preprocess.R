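#' Count matrix container
#'
#' A light list-based container (in the style of edgeR's \code{DGEList})
#' holding a genes x cells integer count matrix \code{x_ij}, per-gene
#' transcript lengths in bp, and per-cell scale-normalization factors
#' \code{t_j} (geometric mean 1 once computed).
#'
#' @param counts integer matrix, genes in rows, cells in columns.
#' @param gene_lengths positive numeric vector of transcript lengths (bp),
#'   one per gene; may be NULL when lengths play no role (e.g. synthetic
#'   data on the normalized scale).
#' @param gene_ids,cell_ids identifiers; default to dimnames or generated.
#' @param norm_factors per-cell factors; default 1 (uncomputed).
#'
#' @return object of class \code{"count_matrix"}.
#' @export
count_matrix <- function(counts, gene_lengths = NULL, gene_ids = NULL,
                         cell_ids = NULL, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)))
    stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be non-negative (first offending row: ",
         rownames(counts)[which(apply(counts < 0, 1, any))[1]], ")",
         call. = FALSE)
  if (any(counts != floor(counts)))
    stop("counts must be integers (first offending row: ",
         rownames(counts)[which(apply(counts != floor(counts), 1, any))[1]],
         ")", call. = FALSE)
  storage.mode(counts) <- "double"
  if (is.null(gene_ids))
    gene_ids <- rownames(counts) %||% sprintf("gene%03d", seq_len(nrow(counts)))
  if (is.null(cell_ids))
    cell_ids <- colnames(counts) %||% sprintf("cell%03d", seq_len(ncol(counts)))
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (!is.null(gene_lengths)) {
    if (length(gene_lengths) != nrow(counts))
      stop("one length per gene required: got ", length(gene_lengths),
           " lengths for ", nrow(counts), " genes", call. = FALSE)
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
      stop("gene lengths must be positive (gene ",
           gene_ids[which(!is.finite(gene_lengths) | gene_lengths <= 0)[1]],
           ")", call. = FALSE)
    gene_lengths <- stats::setNames(as.numeric(gene_lengths), gene_ids)
  }
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 norm_factors = stats::setNames(norm_factors, cell_ids)),
            class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  gene lengths:", if (is.null(x$gene_lengths)) "none" else "present", "\n")
  cat("  norm factors:", if (all(x$norm_factors == 1)) "uninitialized (1)"
      else sprintf("computed (range %.3g-%.3g)", min(x$norm_factors),
                   max(x$norm_factors)), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: header row of cell ids, first column of gene ids, integer
#' counts. MatrixMarket layout: coordinate integer \code{.mtx} file with
#' companion row- and column-name files (one id per line), located by
#' replacing the extension with \code{.rownames} / \code{.colnames} unless
#' given. Gene lengths come from a two-column TSV (gene_id, length_bp).
#'
#' @param path count file.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param lengths_path optional gene-length TSV; every gene in the matrix
#'   must appear in it.
#' @param rownames_path,colnames_path name files for mtx input.
#' @return a \code{\link{count_matrix}} with norm factors initialized to 1.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"), lengths_path = NULL,
                        rownames_path = NULL, colnames_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m))
      stop("non-numeric count entries in ", path, call. = FALSE)
    rownames(m) <- gene_ids
  } else {
    rn <- rownames_path %||% sub("\\.mtx$", ".rownames", path)
    cn <- colnames_path %||% sub("\\.mtx$", ".colnames", path)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
  }
  gene_lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- utils::read.delim(lengths_path, header = TRUE,
                            stringsAsFactors = FALSE)
    idx <- match(rownames(m), lt[[1]])
    if (any(is.na(idx)))
      stop("no length entry for gene ", rownames(m)[which(is.na(idx))[1]],
           call. = FALSE)
    gene_lengths <- lt[[2]][idx]
  }
  count_matrix(m, gene_lengths = gene_lengths)
}

#' Write a count matrix (and companions) to TSV
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param path output TSV for the counts.
#' @param lengths_path,factors_path optional outputs for the gene-length and
#'   norm-factor tables.
#' @return \code{cm}, invisibly.
#' @export
write_counts <- function(cm, path, lengths_path = NULL, factors_path = NULL) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path) && !is.null(cm$gene_lengths))
    utils::write.table(
      data.frame(gene_id = names(cm$gene_lengths), length_bp = cm$gene_lengths),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(factors_path))
    utils::write.table(
      data.frame(cell_id = names(cm$norm_factors), t_j = cm$norm_factors),
      factors_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cm)
}

#' Per-cell scale-normalization factors
#'
#' Computes the cell normalization factor \code{t_j} as library size times
#' the trimmed-mean-of-M-values (TMM) factor, rescaled so the factors have
#' geometric mean 1 across cells. TMM is computed by
#' \code{edgeR::calcNormFactors} with its canonical settings (log-ratio
#' trim 0.30, intensity trim 0.05, reference column the cell whose upper
#' quartile is closest to the mean upper quartile). Factors are always
#' computed on the full, unfiltered matrix.
#'
#' @param cm a \code{\link{count_matrix}} with >= 2 cells.
#' @return \code{cm} with \code{norm_factors} set.
#' @export
compute_norm_factors <- function(cm) {
  counts <- cm$counts
  if (ncol(counts) < 2)
    stop("normalization needs at least 2 cells", call. = FALSE)
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("cell(s) with all-zero counts: ",
         paste(colnames(counts)[libsize == 0], collapse = ", "),
         call. = FALSE)
  tmm <- edgeR::calcNormFactors(counts, method = "TMM",
                                logratioTrim = 0.30, sumTrim = 0.05)
  tj <- libsize * tmm
  tj <- tj / exp(mean(log(tj)))
  cm$norm_factors <- stats::setNames(tj, colnames(counts))
  cm
}

#' Normalized counts
#'
#' Entry (i, j) is \code{x_ij / t_j}: counts on a common per-cell scale. No
#' gene-length division is applied here — the expression filter below is
#' about read-count magnitude, and gene length enters the model as an
#' offset instead (see \code{\link{length_offsets}}).
#'
#' @param cm a \code{\link{count_matrix}} (factors default to 1 if not
#'   computed).
#' @return numeric genes x cells matrix.
#' @export
normalized_counts <- function(cm) {
  sweep(cm$counts, 2, cm$norm_factors, "/")
}

#' Filter lowly expressed genes
#'
#' Removes genes whose maximum normalized read count across cells is below
#' \code{cutoff} (default 50): such genes are dominated by technical noise
#' in single-cell protocols and are excluded before model fitting. A gene
#' is retained iff \code{max_j x_ij / t_j >= cutoff}; gene order is
#' preserved, and norm factors are left untouched (they are computed on the
#' full matrix).
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param cutoff non-negative threshold on the maximum normalized count.
#' @return filtered \code{\link{count_matrix}}.
#' @export
filter_genes <- function(cm, cutoff = 50) {
  keep <- apply(normalized_counts(cm), 1, max) >= cutoff
  cm$counts <- cm$counts[keep, , drop = FALSE]
  if (!is.null(cm$gene_lengths)) cm$gene_lengths <- cm$gene_lengths[keep]
  cm
}

#' Gene-length offsets for the hierarchical model
#'
#' The Poisson rate of the model is \code{t_i t_j s_i p_ij} where \code{t_i}
#' reflects transcript length. Raw bp would push \code{s_i} onto an
#' astronomically small scale, so \code{t_i} is length in bp divided by the
#' median length across the (retained) genes, keeping \code{s_i} on the
#' scale of normalized counts. Genes without lengths get \code{t_i = 1}.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @return numeric vector of per-gene offsets \code{t_i}.
#' @export
length_offsets <- function(cm) {
  if (is.null(cm$gene_lengths)) return(rep(1, nrow(cm$counts)))
  cm$gene_lengths / stats::median(cm$gene_lengths)
}
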