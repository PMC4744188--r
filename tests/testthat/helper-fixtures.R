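# Small in-code fixtures shared across test files.

# deterministic coverage track from explicit per-chromosome/strand vectors
make_track <- function(cov, total = 1e6) {
  suppressWarnings(coverage_track(cov, total))
}

# single-chromosome stranded track with given '+' and '-' vectors
track1 <- function(plus, minus = rep(0, length(plus)), total = 1e6) {
  coverage_track(list(chr1 = list("+" = plus, "-" = minus)), total)
}

# a handful of genes on one chromosome exercising both strands; layout:
#   A + [1000,3000) exons [1000,1500),[2000,3000)   TTS 3000
#   B + [9000,12000) single exon                    TSS 9000 (gap 6000 from A)
#   C - [20000,24000) exons [20000,21000),[23000,24000)  TSS 24000, TTS 20000
tiny_annotation <- function(chrom_size = 40000) {
  genome_annotation(list(
    gene_model("A", "chr1", "+", rbind(c(1000, 1500), c(2000, 3000))),
    gene_model("B", "chr1", "+", rbind(c(9000, 12000))),
    gene_model("C", "chr1", "-", rbind(c(20000, 21000), c(23000, 24000)))
  ), c(chr1 = chrom_size))
}

# random small gene set on one chromosome for property tests
random_annotation <- function(n, chrom_size = 200000) {
  pos <- 5000
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(500:3000, 1)
    n_ex <- sample(1:4, 1)
    cuts <- sort(sample(seq_len(len - 1), 2 * (n_ex - 1)))
    b <- c(0, cuts, len)
    ex <- cbind(pos + b[seq(1, length(b), 2)], pos + b[seq(2, length(b), 2)])
    genes[[i]] <- gene_model(sprintf("g%02d", i), "chr1",
                             sample(c("+", "-"), 1), ex)
    pos <- pos + len + sample(1000:9000, 1)
  }
  genome_annotation(genes, c(chr1 = max(pos + 6000, chrom_size)))
}

# window_vector built directly from RPKM values (grid bookkeeping only)
wv <- function(values, gene_id = "g", width = 100) {
  structure(list(gene_id = gene_id, window_bp = width, values = values,
                 n_windows = length(values), truncated = FALSE),
            class = "window_vector")
}
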