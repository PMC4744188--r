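#' Metagene profile of one gene
#'
#' Coverage around a gene summarized on a fixed grid so profiles from genes
#' of different lengths can be averaged with all TSSs and TTSs aligned: 40
#' 100-bp windows over the 4 Kb upstream of the TSS, the gene body scaled to
#' 60 equally sized bins (remainder bases assigned to the last bin), and 40
#' 100-bp windows over the 4 Kb downstream of the TTS. Values are RPKM per
#' bin. Minus-strand genes are flipped so the TSS is always on the left.
#' Flank bins falling outside the chromosome are NA.
#'
#' @param track a [coverage_track].
#' @param gene a [gene_model] with body length >= `body_bins` bp (shorter
#'   genes are rejected with a message naming the gene).
#' @param flank_bp flank extent (default 4000).
#' @param flank_window_bp flank window width (default 100).
#' @param body_bins number of gene-body bins (default 60).
#' @param chrom_size optional chromosome length for flank clipping.
#' @return object of class `metagene_profile`: list with `gene_id`,
#'   `upstream`, `body`, `downstream` (RPKM vectors), `units`.
#' @export
metagene_profile <- function(track, gene, flank_bp = 4000,
                             flank_window_bp = 100, body_bins = 60,
                             chrom_size = NULL) {
  body_len <- gene$end - gene$start
  if (body_len < body_bins)
    stop("gene ", gene$gene_id, ": body shorter than ", body_bins,
         " bp, metagene profile skipped")
  v <- strand_vector(track, gene$chrom, gene$strand)
  n_flank <- flank_bp %/% flank_window_bp
  total <- track$total_mapped_reads

  flank_vals <- function(from) { # windows over [from, from + flank_bp), left to right
    vapply(seq_len(n_flank) - 1L, function(k) {
      s <- from + k * flank_window_bp
      e <- s + flank_window_bp
      if (s < 0 || (!is.null(chrom_size) && e > chrom_size)) return(NA_real_)
      rpkm(sum(v[(s + 1L):e]), flank_window_bp, total)
    }, 0)
  }

  base_w <- body_len %/% body_bins
  widths <- rep(base_w, body_bins)
  widths[body_bins] <- body_len - base_w * (body_bins - 1L)
  starts <- gene$start + c(0, cumsum(widths[-body_bins]))
  body_vals <- vapply(seq_len(body_bins), function(j)
    rpkm(sum(v[(starts[j] + 1L):(starts[j] + widths[j])]), widths[j], total), 0)

  if (gene$strand == "+") {
    up <- flank_vals(gene$start - flank_bp)
    down <- flank_vals(gene$end)
  } else {
    up <- rev(flank_vals(gene$end))
    down <- rev(flank_vals(gene$start - flank_bp))
    body_vals <- rev(body_vals)
  }
  structure(list(gene_id = gene$gene_id, upstream = up, body = body_vals,
                 downstream = down, units = "rpkm"),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %s: %d/%d/%d bins (%s)\n", x$gene_id,
              length(x$upstream), length(x$body), length(x$downstream), x$units))
  invisible(x)
}

# 140-value row for matrices / averaging (NA-safe)
flatten_profile <- function(p) c(p$upstream, p$body, p$downstream)

#' Average metagene profile over many genes
#'
#' @param profiles list of `metagene_profile` objects on the same grid.
#' @return a `metagene_profile` with per-bin means (NA bins dropped per bin),
#'   gene_id `"<average>"`.
#' @export
average_metagene <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  m <- do.call(rbind, lapply(profiles, flatten_profile))
  nu <- length(profiles[[1]]$upstream)
  nb <- length(profiles[[1]]$body)
  nd <- length(profiles[[1]]$downstream)
  mu <- colMeans(m, na.rm = TRUE)
  structure(list(gene_id = "<average>", upstream = mu[seq_len(nu)],
                 body = mu[nu + seq_len(nb)], downstream = mu[nu + nb + seq_len(nd)],
                 units = profiles[[1]]$units),
            class = "metagene_profile")
}

#' Cohort heatmap matrices from paired metagene profiles
#'
#' Two aligned matrices, one row per gene over the 40+60+40 bin grid:
#' log2 RPKM of the control sample, and log2 test/control fold-change. Rows
#' are ordered by descending read-through length, the ordering used for
#' read-through heatmaps.
#'
#' @param control_profiles,test_profiles lists of `metagene_profile` objects,
#'   matched per gene.
#' @param readthrough_lengths numeric vector of per-gene read-through lengths
#'   (bp), same order as the profile lists.
#' @param pseudocount RPKM pseudocount for the log2 transforms (default 0.1).
#' @return list with matrices `control_log2` and `fc_log2` (rownames =
#'   gene_ids, rows sorted by descending `readthrough_lengths`), and
#'   `readthrough_length_bp` in row order.
#' @export
cohort_matrix <- function(control_profiles, test_profiles, readthrough_lengths,
                          pseudocount = 0.1) {
  stopifnot(length(control_profiles) == length(test_profiles),
            length(control_profiles) == length(readthrough_lengths))
  ids <- vapply(control_profiles, `[[`, "", "gene_id")
  ctrl <- do.call(rbind, lapply(control_profiles, flatten_profile))
  test <- do.call(rbind, lapply(test_profiles, flatten_profile))
  rownames(ctrl) <- rownames(test) <- ids
  ord <- order(readthrough_lengths, ids, decreasing = c(TRUE, FALSE),
               method = "radix")
  list(control_log2 = log2(ctrl + pseudocount)[ord, , drop = FALSE],
       fc_log2 = (log2(test + pseudocount) - log2(ctrl + pseudocount))[ord, , drop = FALSE],
       readthrough_length_bp = readthrough_lengths[ord])
}

#' Plot a metagene profile
#'
#' Base-graphics line plot with TSS/TTS marks; a quick visual check, not a
#' publication figure.
#'
#' @param x a `metagene_profile`.
#' @param ... passed to [graphics::plot].
#' @export
plot.metagene_profile <- function(x, ...) {
  y <- flatten_profile(x)
  nu <- length(x$upstream); nb <- length(x$body)
  graphics::plot(seq_along(y), y, type = "l", xlab = "bin",
                 ylab = paste0("coverage (", x$units, ")"),
                 main = x$gene_id, ...)
  graphics::abline(v = c(nu + 0.5, nu + nb + 0.5), lty = 2, col = "grey40")
  graphics::mtext(c("TSS", "TTS"), at = c(nu + 0.5, nu + nb + 0.5), side = 3,
                  cex = 0.8)
  invisible(x)
}
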