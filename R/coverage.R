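#' Coverage tracks
#'
#' A coverage track holds per-base read depth per chromosome, per strand when
#' the library is stranded, plus the sample's total mapped read count used
#' for RPKM normalization.
#'
#' @param cov nested list: `cov[[chrom]][[strand]]` numeric vector of per-base
#'   depth over the whole chromosome; strand names `"+"`/`"-"` for stranded
#'   data or a single `"*"` for unstranded.
#' @param total_mapped_reads positive scalar; the RPKM denominator.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(cov, total_mapped_reads) {
  stopifnot(is.list(cov), total_mapped_reads > 0)
  stranded <- all(vapply(cov, function(x) all(c("+", "-") %in% names(x)), TRUE))
  if (!stranded) {
    if (!all(vapply(cov, function(x) "*" %in% names(x), TRUE)))
      stop("cov must provide '+'/'-' per chromosome, or '*' for unstranded")
    warning("unstranded coverage supplied; gene-strand assignment is assumed",
            call. = FALSE)
  }
  structure(list(cov = cov, stranded = stranded,
                 total_mapped_reads = total_mapped_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), %s, %.3g total mapped reads\n",
              length(x$cov), if (x$stranded) "stranded" else "unstranded",
              x$total_mapped_reads))
  invisible(x)
}

# per-base depth vector for one chromosome on one gene strand
strand_vector <- function(track, chrom, strand) {
  ch <- track$cov[[chrom]]
  if (is.null(ch)) stop("chromosome ", chrom, " absent from coverage track")
  if (track$stranded) ch[[strand]] else ch[["*"]]
}

#' Raw counts in fixed-width windows over an oriented interval
#'
#' Windows are ordered TTS-proximal to distal: left-to-right on `+`,
#' right-to-left on `-`. A trailing partial window (interval length not a
#' multiple of `width_bp`) is dropped with a warning.
#'
#' @param track a [coverage_track].
#' @param interval list with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open), as returned by [downstream_interval].
#' @param width_bp window width in bp (default 100).
#' @param warn_partial warn when a trailing partial window is dropped
#'   (default TRUE; callers that window arbitrary-length regions by design
#'   pass FALSE).
#' @return numeric vector of per-window summed depth; empty for an empty
#'   interval.
#' @export
window_counts <- function(track, interval, width_bp = 100, warn_partial = TRUE) {
  len <- interval$end - interval$start
  if (len <= 0) return(numeric(0))
  n_win <- len %/% width_bp
  if (n_win == 0L) return(numeric(0))
  if (len %% width_bp != 0 && warn_partial)
    warning("interval length not a multiple of width; trailing partial window dropped",
            call. = FALSE)
  v <- strand_vector(track, interval$chrom, interval$strand)
  used <- n_win * width_bp
  if (interval$strand == "+") {
    seg <- v[(interval$start + 1L):(interval$start + used)]
  } else {
    seg <- rev(v[(interval$end - used + 1L):interval$end])
  }
  unname(colSums(matrix(seg, nrow = width_bp)))
}

#' RPKM normalization
#'
#' Reads per kilobase of region per million mapped reads:
#' `count / (region_len_bp/1000) / (total_mapped_reads/1e6)`.
#'
#' @param raw_count summed read depth (or read count) over the region.
#' @param region_len_bp region length, > 0.
#' @param total_mapped_reads sample total, > 0.
#' @return RPKM value(s); vectorized over `raw_count`/`region_len_bp`.
#' @export
rpkm <- function(raw_count, region_len_bp, total_mapped_reads) {
  stopifnot(all(region_len_bp > 0), total_mapped_reads > 0)
  raw_count / (region_len_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Per-window RPKM vector downstream of a gene's TTS
#'
#' @param track a [coverage_track].
#' @param gene a [gene_model].
#' @param span_bp downstream extent (default 4000).
#' @param width_bp window width (default 100).
#' @param chrom_size optional chromosome length for clipping.
#' @return object of class `window_vector`: list with `gene_id`, `window_bp`,
#'   `values` (RPKM, TTS-proximal first), `n_windows`, `truncated`.
#' @export
window_vector <- function(track, gene, span_bp = 4000, width_bp = 100,
                          chrom_size = NULL) {
  iv <- downstream_interval(gene, span_bp, chrom_size)
  counts <- window_counts(track, iv, width_bp)
  structure(list(gene_id = gene$gene_id, window_bp = width_bp,
                 values = rpkm(counts, width_bp, track$total_mapped_reads),
                 n_windows = length(counts), truncated = iv$truncated),
            class = "window_vector")
}

#' Per-window fold-change between matched test and control window vectors
#'
#' @param test,control `window_vector` objects on the same grid and gene.
#' @param pseudocount RPKM added to numerator and denominator (default 0.1)
#'   so zero-control windows stay defined.
#' @return numeric vector `(test + pc) / (control + pc)` per window.
#' @export
fold_change_vector <- function(test, control, pseudocount = 0.1) {
  if (test$gene_id != control$gene_id ||
      test$window_bp != control$window_bp ||
      test$n_windows != control$n_windows)
    stop("window vectors are on different grids (gene ", test$gene_id, ")")
  (test$values + pseudocount) / (control$values + pseudocount)
}

#' Gene-body expression in RPKM
#'
#' @param track a [coverage_track].
#' @param gene a [gene_model]; the whole `[start, end)` span is used.
#' @return RPKM over the gene body.
#' @export
gene_body_expression <- function(track, gene) {
  v <- strand_vector(track, gene$chrom, gene$strand)
  rpkm(sum(v[(gene$start + 1L):gene$end]), gene$end - gene$start,
       track$total_mapped_reads)
}

#' Read a bedGraph pair (or single unstranded file) into a coverage track
#'
#' @param plus_path bedGraph for the `+` strand (or the only file when
#'   `minus_path` is NULL, read as unstranded).
#' @param minus_path optional bedGraph for the `-` strand.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param total_mapped_reads sample total mapped reads (from the sample sheet).
#' @return a [coverage_track].
#' @export
read_bedgraph_track <- function(plus_path, minus_path = NULL, chrom_sizes,
                                total_mapped_reads) {
  read_one <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    lapply(stats::setNames(nm = names(chrom_sizes)), function(ch) {
      v <- numeric(chrom_sizes[[ch]])
      sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
      if (length(sub)) {
        cov <- GenomicRanges::coverage(
          GenomicRanges::GRanges(ch, IRanges::IRanges(GenomicRanges::start(sub),
                                                      GenomicRanges::end(sub)),
                                 seqlengths = stats::setNames(chrom_sizes[[ch]], ch)),
          weight = sub$score)[[ch]]
        v <- as.numeric(cov)
      }
      v
    })
  }
  plus <- read_one(plus_path)
  if (is.null(minus_path)) {
    cov <- lapply(plus, function(v) list("*" = v))
  } else {
    minus <- read_one(minus_path)
    cov <- lapply(stats::setNames(nm = names(chrom_sizes)), function(ch)
      list("+" = plus[[ch]], "-" = minus[[ch]]))
  }
  coverage_track(cov, total_mapped_reads)
}

#' Write one strand of a coverage track as bedGraph
#'
#' Zero-depth runs are omitted, the usual bedGraph convention.
#'
#' @param track a [coverage_track].
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, strand, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$cov)) {
    v <- if (track$stranded) track$cov[[ch]][[strand]] else track$cov[[ch]][["*"]]
    r <- rle(as.numeric(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    nz <- r$values != 0
    if (any(nz))
      writeLines(paste(ch, starts[nz], ends[nz],
                       format(r$values[nz], trim = TRUE, scientific = FALSE),
                       sep = "\t"), con)
  }
  invisible(path)
}
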