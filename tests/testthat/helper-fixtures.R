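# Small builders shared across test files. Everything is generated in code;
# no binary fixtures.

toy_counts <- function(seed = 1, genes = 6, cells = 4, lambda = 20) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    m <- matrix(rpois(genes * cells, lambda), genes, cells)
    count_matrix(m, gene_lengths = sample(500:5000, genes))
  })
}

# uniform-coverage track over one chromosome
uniform_track <- function(depth, chrom_len = 20000, strand = "+") {
  v <- rep(depth, chrom_len)
  if (strand == "+") coverage_track(plus = list(chr1 = v))
  else coverage_track(minus = list(chr1 = v))
}

gene1 <- function(start = 5000, end = 10000, strand = "+") {
  data.frame(gene_id = "g1", chrom = "chr1", start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

# brute-force PolII metrics by direct window enumeration over an explicit
# per-base vector (independent of the package's cumsum/Rle implementation)
brute_metrics <- function(v_by_strand, gene) {
  v <- v_by_strand[[gene$strand]]
  at <- function(from, to) {       # sum over 0-based [from, to)
    idx <- seq.int(from, to - 1)
    idx <- idx[idx >= 0 & idx < length(v)]
    if (length(idx) == 0) 0 else sum(v[idx + 1])
  }
  tss <- if (gene$strand == "+") gene$start else gene$end - 1
  body <- if (gene$strand == "+") c(gene$start + 1000, gene$end)
          else c(gene$start, gene$end - 1000)
  body_act <- if (gene$end - gene$start <= 1000) NA_real_ else
    at(body[1], body[2]) / (body[2] - body[1])
  prom <- max(vapply((tss - 1000):(tss + 1000 - 50),
                     function(a) at(a, a + 50), numeric(1)))
  pi <- if (is.na(body_act) || body_act == 0) NA_real_ else (prom / 50) / body_act
  list(body = body_act, prom = prom, pause = pi)
}
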