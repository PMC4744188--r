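#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; delegates to [stats::p.adjust] after validating
#' the input.
#'
#' @param pvalues numeric vector of p-values in [0, 1]; NAs are carried
#'   through unadjusted and do not count toward the family size.
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Invasion of the intergenic region and downstream gene by read-through
#'
#' Quantifies how far read-through from a called upstream gene runs into the
#' downstream gene of a tandem pair. The downstream gene is partitioned into
#' 100-bp windows from its 5' end; the invaded fraction is the contiguous run
#' of windows at or above the fold-change threshold *starting at the first
#' window* (continuity with the intergenic tail is required — isolated
#' internal elevation does not count), divided by the gene length. A run
#' covering every window counts as fraction 1.
#'
#' @param test_track,control_track matched [coverage_track]s.
#' @param pair one row of the [build_tandem_pairs] table.
#' @param annotation a [genome_annotation].
#' @param params a [caller_params] (window width, fold-change threshold,
#'   pseudocount).
#' @return one-row data.frame: `upstream_id`, `downstream_id`,
#'   `intergenic_fc` (fold-change over the whole intergenic interval; NA with
#'   `intergenic_undefined = TRUE` when the gap is 0), `invaded_fraction`,
#'   `downstream_body_fc`.
#' @export
invasion_fraction <- function(test_track, control_track, pair, annotation,
                              params = caller_params()) {
  down <- annotation$genes[[pair$downstream_id]]
  if (is.null(down)) stop("downstream gene ", pair$downstream_id, " not in annotation")
  pc <- params$pseudocount

  region_fc <- function(chrom, start, end, strand) {
    len <- end - start
    iv <- list(chrom = chrom, start = start, end = end, strand = strand)
    t <- rpkm(sum(window_counts(test_track, iv, len)), len,
              test_track$total_mapped_reads)
    c <- rpkm(sum(window_counts(control_track, iv, len)), len,
              control_track$total_mapped_reads)
    (t + pc) / (c + pc)
  }

  ig_len <- pair$intergenic_end - pair$intergenic_start
  ig_fc <- if (ig_len > 0)
    region_fc(pair$chrom, pair$intergenic_start, pair$intergenic_end, pair$strand)
  else NA_real_

  body_iv <- list(chrom = down$chrom, start = down$start, end = down$end,
                  strand = down$strand)
  t_counts <- window_counts(test_track, body_iv, params$window_bp,
                            warn_partial = FALSE)
  c_counts <- window_counts(control_track, body_iv, params$window_bp,
                            warn_partial = FALSE)
  gene_len <- down$end - down$start
  if (length(t_counts) == 0L) {
    frac <- 0
  } else {
    fc <- (rpkm(t_counts, params$window_bp, test_track$total_mapped_reads) + pc) /
          (rpkm(c_counts, params$window_bp, control_track$total_mapped_reads) + pc)
    pass <- fc >= params$fc_threshold
    if (!pass[1L]) {
      frac <- 0
    } else {
      stop_at <- which(!pass)
      run <- if (length(stop_at) == 0L) length(pass) else stop_at[1L] - 1L
      frac <- if (run == length(pass)) 1 else
        min(1, params$window_bp * run / gene_len)
    }
  }
  data.frame(upstream_id = pair$upstream_id, downstream_id = pair$downstream_id,
             intergenic_fc = ig_fc, intergenic_undefined = ig_len <= 0,
             invaded_fraction = frac,
             downstream_body_fc = region_fc(down$chrom, down$start, down$end,
                                            down$strand))
}

#' Read-through level of a gene in one sample pair
#'
#' The quantity correlated against downstream-gene expression in the cohort
#' screen: the log2 fold-change of read counts over the downstream-of-TTS
#' zone between test and control.
#'
#' @param test_track,control_track matched [coverage_track]s.
#' @param gene a [gene_model].
#' @param params a [caller_params].
#' @return log2 fold-change (RPKM with pseudocount).
#' @export
readthrough_level <- function(test_track, control_track, gene,
                              params = caller_params()) {
  cs <- NULL
  iv <- downstream_interval(gene, params$downstream_span_bp, cs)
  len <- iv$end - iv$start
  pc <- params$pseudocount
  t <- rpkm(sum(window_counts(test_track, iv, len)), len,
            test_track$total_mapped_reads)
  c <- rpkm(sum(window_counts(control_track, iv, len)), len,
            control_track$total_mapped_reads)
  log2((t + pc) / (c + pc))
}

#' Correlation screen: read-through vs downstream-gene expression
#'
#' For each tandem pair, correlates (across sample pairs) the upstream
#' gene's read-through level with the downstream gene's expression
#' fold-change, then adjusts across all tested pairs by Benjamini-Hochberg.
#'
#' @param rt_levels,expr_levels numeric matrices, tandem pairs in rows and
#'   sample pairs in columns: upstream read-through level and downstream
#'   log2 expression fold-change. Row names identify the pair.
#' @param min_samples minimum informative (non-NA in both) sample pairs for
#'   a pair to enter the screen (default 10).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return data.frame with `pair_id`, `n`, `r`, `p`, `q`, `significant`,
#'   `direction`, `tested` (FALSE rows — too few samples or a constant
#'   vector — are excluded from the BH family).
#' @export
correlation_screen <- function(rt_levels, expr_levels, min_samples = 10,
                               method = c("spearman", "pearson"),
                               alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(identical(dim(rt_levels), dim(expr_levels)))
  res <- lapply(seq_len(nrow(rt_levels)), function(i) {
    x <- rt_levels[i, ]
    y <- expr_levels[i, ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_samples || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(pair_id = rownames(rt_levels)[i], n = n, r = NA_real_,
                        p = NA_real_, tested = FALSE))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method,
                                           exact = FALSE))
    data.frame(pair_id = rownames(rt_levels)[i], n = n,
               r = unname(ct$estimate), p = ct$p.value, tested = TRUE)
  })
  res <- do.call(rbind, res)
  res$q <- NA_real_
  res$q[res$tested] <- bh_adjust(res$p[res$tested])
  res$significant <- !is.na(res$q) & res$q < alpha
  res$direction <- ifelse(is.na(res$r), NA_character_,
                          ifelse(res$r >= 0, "positive", "negative"))
  res[c("pair_id", "n", "r", "p", "q", "significant", "direction", "tested")]
}

#' Assemble correlation-screen inputs from a cohort of track pairs
#'
#' @param sample_pairs named list; each element a list with `test` and
#'   `control` [coverage_track]s.
#' @param pairs tandem-pair table from [build_tandem_pairs] (typically
#'   pre-filtered to pairs whose upstream gene is called somewhere in the
#'   cohort).
#' @param annotation a [genome_annotation].
#' @param params a [caller_params].
#' @return list of matrices `rt_levels` and `expr_levels` (pairs x samples).
#' @export
screen_inputs <- function(sample_pairs, pairs, annotation,
                          params = caller_params()) {
  pc <- params$pseudocount
  rt <- matrix(NA_real_, nrow(pairs), length(sample_pairs),
               dimnames = list(paste(pairs$upstream_id, pairs$downstream_id,
                                     sep = ":"),
                               names(sample_pairs)))
  ex <- rt
  for (j in seq_along(sample_pairs)) {
    sp <- sample_pairs[[j]]
    for (i in seq_len(nrow(pairs))) {
      up <- annotation$genes[[pairs$upstream_id[i]]]
      dn <- annotation$genes[[pairs$downstream_id[i]]]
      rt[i, j] <- readthrough_level(sp$test, sp$control, up, params)
      ex[i, j] <- log2((gene_body_expression(sp$test, dn) + pc) /
                       (gene_body_expression(sp$control, dn) + pc))
    }
  }
  list(rt_levels = rt, expr_levels = ex)
}
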