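#' Gene models and strand-aware coverage for GRO-seq metrics
#'
#' \code{read_gene_models} imports a BED6 file of gene coordinates
#' (0-based half-open; the TSS is the start on the plus strand and the last
#' base on the minus strand). \code{read_coverage} imports one bedGraph of
#' per-base read coverage per strand and returns a coverage track:
#' run-length encoded per-base counts per chromosome and strand, absent
#' positions being zero. Parsing goes through \code{rtracklayer}.
#'
#' @param path BED6 (genes) or bedGraph (coverage) file.
#' @return \code{read_gene_models}: data.frame with \code{gene_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("gene models must be stranded (BED6)", call. = FALSE)
  data.frame(gene_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # back to 0-based
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_gene_models
#' @param plus_path,minus_path bedGraph files for the two strands (either
#'   may be NULL for an empty strand).
#' @return \code{read_coverage}: object of class \code{"coverage_track"}.
#' @export
read_coverage <- function(plus_path = NULL, minus_path = NULL) {
  imp <- function(p) {
    if (is.null(p)) return(list())
    gr <- rtracklayer::import(p, format = "bedGraph")
    cov <- GenomicRanges::coverage(gr, weight = gr$score)
    as.list(cov)
  }
  structure(list(`+` = imp(plus_path), `-` = imp(minus_path)),
            class = "coverage_track")
}

#' Build a coverage track from per-base vectors
#'
#' Convenience constructor used in simulations and tests: a named list per
#' strand of numeric per-base coverage vectors (position 1 = chromosome
#' base 0).
#'
#' @param plus,minus named lists of per-base numeric vectors, one per
#'   chromosome.
#' @return object of class \code{"coverage_track"}.
#' @export
coverage_track <- function(plus = list(), minus = list()) {
  as_rle <- function(l) lapply(l, function(v) {
    if (any(v < 0)) stop("coverage must be non-negative", call. = FALSE)
    S4Vectors::Rle(v)
  })
  structure(list(`+` = as_rle(plus), `-` = as_rle(minus)),
            class = "coverage_track")
}

## Per-base coverage over [start, end) (0-based half-open) on one strand,
## zero-padded outside the recorded track.
track_window <- function(track, strand, chrom, start, end) {
  n <- end - start
  rle <- track[[strand]][[chrom]]
  out <- numeric(n)
  if (is.null(rle) || length(rle) == 0L || n <= 0L) return(out)
  lo <- max(start, 0L)
  hi <- min(end, length(rle))
  if (hi > lo)
    out[(lo - start + 1):(hi - start)] <-
      as.numeric(S4Vectors::window(rle, lo + 1, hi))
  out
}

tss_of <- function(gene) if (gene$strand == "+") gene$start else gene$end - 1L

#' Gene body activity from a GRO-seq coverage track
#'
#' Total strand-matched reads in the gene body — from 1 kb downstream of
#' the TSS (in the direction of transcription) to the gene end — divided by
#' the body length: reads per bp. Genes of 1 kb or less have no body
#' region and return NA.
#'
#' @param track a \code{\link{coverage_track}}.
#' @param gene one-row gene-model data.frame (\code{chrom}, \code{start},
#'   \code{end}, \code{strand}; 0-based half-open).
#' @return reads per bp, or NA for an undefined region.
#' @export
gene_body_activity <- function(track, gene) {
  len <- gene$end - gene$start
  if (len <= 1000) return(NA_real_)
  reg <- if (gene$strand == "+") c(gene$start + 1000L, gene$end)
         else c(gene$start, gene$end - 1000L)
  v <- track_window(track, gene$strand, gene$chrom, reg[1], reg[2])
  sum(v) / (reg[2] - reg[1])
}

#' Promoter activity: maximal 50-bp window around the TSS
#'
#' Maximum strand-matched read count over all 50-bp windows (1-bp step)
#' fully contained in the +/- 1 kb region around the TSS.
#'
#' @inheritParams gene_body_activity
#' @return the maximal window count.
#' @export
promoter_activity <- function(track, gene) {
  tss <- tss_of(gene)
  v <- track_window(track, gene$strand, gene$chrom, tss - 1000L, tss + 1000L)
  cs <- c(0, cumsum(v))
  max(cs[(50 + 1):length(cs)] - cs[1:(length(cs) - 50)])
}

#' Polymerase pause index
#'
#' Ratio of promoter activity per bp (the maximal 50-bp window count
#' divided by 50) to gene body activity (reads per bp). A paused gene
#' accumulates polymerase near the TSS relative to its body; uniform
#' coverage gives exactly 1. Undefined (NA) when the body activity is 0 or
#' the body region is empty.
#'
#' @inheritParams gene_body_activity
#' @return the pause index, or NA when undefined.
#' @export
pause_index <- function(track, gene) {
  body <- gene_body_activity(track, gene)
  if (is.na(body) || body == 0) return(NA_real_)
  (promoter_activity(track, gene) / 50) / body
}

#' All three PolII metrics for a table of genes
#'
#' @param track a \code{\link{coverage_track}}.
#' @param genes gene-model data.frame as from \code{\link{read_gene_models}}.
#' @return data.frame with \code{gene_id}, \code{body_activity},
#'   \code{promoter_activity}, \code{pause_index}.
#' @export
polii_metrics <- function(track, genes) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    data.frame(gene_id = g$gene_id,
               body_activity = gene_body_activity(track, g),
               promoter_activity = promoter_activity(track, g),
               pause_index = pause_index(track, g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
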