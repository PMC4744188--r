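#' Read a tab-delimited junction file
#'
#' Columns: chrom, donor_pos, acceptor_pos, strand, read_id (0-based
#' positions; the donor is the 3' boundary of the upstream exon, the
#' acceptor the 5' boundary of the downstream exon).
#'
#' @param path junction TSV (with header).
#' @return data.frame of junction records.
#' @export
read_junctions <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "donor_pos", "acceptor_pos", "strand", "read_id")
  if (!all(need %in% names(tab)))
    stop("junction file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  tab[need]
}

#' Call read-through RNA chimeras from split-read junctions
#'
#' A junction supports a chimera when its donor position matches (within
#' `tolerance_bp`) an exon 3' boundary of the upstream gene of a tandem pair
#' and its acceptor position matches an exon 5' boundary of the downstream
#' gene, on the pair's strand, with a span of at least `min_dist_bp`.
#' Records are deduplicated by read_id before support counting, grouped by
#' (pair, donor exon, acceptor exon), and emitted only with at least
#' `min_support` supporting reads. Only cis, same-strand, tandem-pair
#' chimeras are considered.
#'
#' @param junctions data.frame from [read_junctions] (or equivalent).
#' @param annotation a [genome_annotation].
#' @param pairs tandem-pair table from [build_tandem_pairs].
#' @param min_support minimum deduplicated supporting reads (default 2).
#' @param min_dist_bp minimum junction span (default 100).
#' @param tolerance_bp boundary-match tolerance for alignment jitter
#'   (default 3).
#' @param sample_id label carried into the calls.
#' @return list of class `chimera_calls`: `calls` (data.frame: upstream_id,
#'   downstream_id, donor_exon_rank_from_end, acceptor_exon_rank,
#'   donor_pos, acceptor_pos, n_supporting_reads, pattern, sample_id) and
#'   `n_unassigned` (junctions matching no annotated tandem boundary).
#' @export
call_chimeras <- function(junctions, annotation, pairs, min_support = 2,
                          min_dist_bp = 100, tolerance_bp = 3,
                          sample_id = "sample") {
  jx <- unique(junctions[c("chrom", "donor_pos", "acceptor_pos", "strand",
                           "read_id")])
  jx <- jx[abs(jx$acceptor_pos - jx$donor_pos) >= min_dist_bp, , drop = FALSE]
  assigned <- rep(FALSE, nrow(jx))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    up <- annotation$genes[[pairs$upstream_id[i]]]
    dn <- annotation$genes[[pairs$downstream_id[i]]]
    n_up <- nrow(up$exons); n_dn <- nrow(dn$exons)
    donors <- vapply(seq_len(n_up), function(r) exon_donor_pos(up, r), 0)
    acceptors <- vapply(seq_len(n_dn), function(r) exon_acceptor_pos(dn, r), 0)
    cand <- which(jx$chrom == pairs$chrom[i] & jx$strand == pairs$strand[i])
    if (!length(cand)) next
    for (k in cand) {
      dr <- which(abs(donors - jx$donor_pos[k]) <= tolerance_bp)
      ar <- which(abs(acceptors - jx$acceptor_pos[k]) <= tolerance_bp)
      if (length(dr) != 1L || length(ar) != 1L) next
      # transcription order: donor must precede acceptor along the strand
      if (pairs$strand[i] == "+" && jx$donor_pos[k] >= jx$acceptor_pos[k]) next
      if (pairs$strand[i] == "-" && jx$donor_pos[k] <= jx$acceptor_pos[k]) next
      assigned[k] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        upstream_id = pairs$upstream_id[i], downstream_id = pairs$downstream_id[i],
        donor_exon_rank_from_end = dr, acceptor_exon_rank = ar,
        donor_pos = donors[dr], acceptor_pos = acceptors[ar],
        read_id = jx$read_id[k])
    }
  }
  if (length(out)) {
    hits <- do.call(rbind, out)
    key <- interaction(hits$upstream_id, hits$downstream_id,
                       hits$donor_exon_rank_from_end, hits$acceptor_exon_rank,
                       drop = TRUE)
    calls <- do.call(rbind, lapply(split(hits, key), function(h) {
      h1 <- h[1L, c("upstream_id", "downstream_id", "donor_exon_rank_from_end",
                    "acceptor_exon_rank", "donor_pos", "acceptor_pos")]
      h1$n_supporting_reads <- length(unique(h$read_id))
      h1
    }))
    calls <- calls[calls$n_supporting_reads >= min_support, , drop = FALSE]
    calls$pattern <- classify_splice_pattern(calls$donor_exon_rank_from_end,
                                             calls$acceptor_exon_rank)
    calls$sample_id <- sample_id
    calls <- calls[order(calls$upstream_id, calls$acceptor_exon_rank), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(upstream_id = character(), downstream_id = character(),
                        donor_exon_rank_from_end = integer(),
                        acceptor_exon_rank = integer(), donor_pos = numeric(),
                        acceptor_pos = numeric(), n_supporting_reads = integer(),
                        pattern = character(), sample_id = character())
  }
  structure(list(calls = calls, n_unassigned = sum(!assigned)),
            class = "chimera_calls")
}

#' @export
print.chimera_calls <- function(x, ...) {
  cat(sprintf("<chimera_calls> %d call(s), %d unassigned junction(s)\n",
              nrow(x$calls), x$n_unassigned))
  invisible(x)
}

#' Splice-pattern label for chimera exon ranks
#'
#' Donor rank 1 is the last exon of the upstream gene (`E[last]`), rank 2 the
#' second-last (`E[last-1]`); acceptor rank 1 is the first exon of the
#' downstream gene (`E1`). The dominant read-through pattern joins the
#' second-last exon to the second exon: `E[last-1]->E2`.
#'
#' @param donor_rank_from_end,acceptor_rank integer vectors.
#' @return character vector of labels.
#' @export
classify_splice_pattern <- function(donor_rank_from_end, acceptor_rank) {
  donor <- ifelse(donor_rank_from_end == 1, "E[last]",
                  paste0("E[last-", donor_rank_from_end - 1, "]"))
  paste0(donor, "->E", acceptor_rank)
}

#' Tabulate splice patterns over a cohort
#'
#' @param calls data.frame of chimera calls (rows from one or many samples).
#' @return data.frame of `pattern`, `n_events`, sorted by count.
#' @export
tabulate_splice_patterns <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(pattern = character(), n_events = integer()))
  tb <- sort(table(calls$pattern), decreasing = TRUE)
  data.frame(pattern = names(tb), n_events = as.integer(tb),
             row.names = NULL)
}

#' Association between chimera counts and read-through burden
#'
#' Correlates, across samples, the number of chimeras called with the number
#' of read-through genes, and compares mean chimera counts between high and
#' low read-through strata when a stratification is supplied.
#'
#' @param n_readthrough,n_chimeras named numeric vectors per sample (names
#'   must match).
#' @param strata optional named character vector of `"high"`/`"low"` per
#'   sample.
#' @param method correlation type (default `"pearson"`).
#' @return list with `r`, `p`, `n`, `flagged` (TRUE when fewer than 3
#'   samples or a constant vector makes the correlation undefined), and when
#'   strata are given `mean_high`, `mean_low`.
#' @export
chimera_readthrough_association <- function(n_readthrough, n_chimeras,
                                            strata = NULL,
                                            method = "pearson") {
  common <- intersect(names(n_readthrough), names(n_chimeras))
  x <- n_readthrough[common]
  y <- n_chimeras[common]
  out <- list(n = length(common))
  if (length(common) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    out$r <- NA_real_; out$p <- NA_real_; out$flagged <- TRUE
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                           exact = FALSE))
    out$r <- unname(ct$estimate); out$p <- ct$p.value; out$flagged <- FALSE
  }
  if (!is.null(strata)) {
    out$mean_high <- mean(y[strata[common] == "high"])
    out$mean_low <- mean(y[strata[common] == "low"])
  }
  out
}

#' Write chimera calls and a Circos-style link file
#'
#' @param chimeras a `chimera_calls` object.
#' @param path output TSV.
#' @param links_path optional link file (chrom, donor_pos, chrom,
#'   acceptor_pos) for external plotting.
#' @param annotation required when `links_path` is given, to look up
#'   chromosomes.
#' @export
write_chimeras_tsv <- function(chimeras, path, links_path = NULL,
                               annotation = NULL) {
  utils::write.table(chimeras$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(links_path)) {
    stopifnot(!is.null(annotation))
    ch <- vapply(chimeras$calls$upstream_id,
                 function(id) annotation$genes[[id]]$chrom, "")
    utils::write.table(
      data.frame(chrom1 = ch, pos1 = chimeras$calls$donor_pos,
                 chrom2 = ch, pos2 = chimeras$calls$acceptor_pos),
      links_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
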