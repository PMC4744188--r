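#' Gene models and genome annotation
#'
#' All coordinates are 0-based, half-open internally. GTF I/O converts from
#' the 1-based inclusive dialect at the boundary; BED I/O is already 0-based.
#'
#' @name annotation
NULL

#' Construct a merged gene model
#'
#' A gene model is the union of all transcripts of a gene collapsed into a
#' single transcript model: one interval per gene with the exon union.
#'
#' @param gene_id character scalar.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of exon `start`, `end` (0-based half-open),
#'   need not be sorted or disjoint; overlapping exons are unioned.
#' @return An object of class `gene_model`: a list with fields `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `exons` (sorted disjoint matrix),
#'   `tss`, `tts`. The TSS is the 5' end (equal to `start` on `+`, `end` on
#'   `-`); the TTS is the 3' end.
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  stopifnot(length(gene_id) == 1L, length(chrom) == 1L)
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": strand must be '+' or '-'")
  exons <- as.matrix(exons)
  if (nrow(exons) < 1L) stop("gene ", gene_id, ": at least one exon required")
  if (any(exons[, 2] <= exons[, 1]))
    stop("gene ", gene_id, ": empty or inverted exon interval")
  exons <- interval_union(exons)
  dimnames(exons) <- list(NULL, c("start", "end"))
  start <- unname(exons[1L, 1L])
  end <- unname(exons[nrow(exons), 2L])
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end, exons = exons,
    tss = if (strand == "+") start else end,
    tts = if (strand == "+") end else start
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

# union of 0-based half-open intervals -> sorted disjoint matrix
interval_union <- function(intervals) {
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals[, 1] + 1L,
                                         end = intervals[, 2]))
  cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merge the transcripts of one gene into a single transcript model
#'
#' Collapses a set of transcript exon structures into the per-gene model used
#' throughout the pipeline: the exon set is the interval union over all
#' transcripts and the gene span is the min start / max end.
#'
#' @param gene_id gene identifier shared by all transcripts.
#' @param chrom,strand shared chromosome and strand; a transcript disagreeing
#'   on either is an error naming the gene.
#' @param transcripts list of two-column exon matrices (0-based half-open),
#'   one per transcript.
#' @return A [gene_model].
#' @export
merge_transcripts <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(is.list(transcripts), length(transcripts) > 0L)
  gene_model(gene_id, chrom, strand, do.call(rbind, lapply(transcripts, as.matrix)))
}

#' Build a genome annotation from gene models
#'
#' @param genes list of [gene_model] objects with unique `gene_id`s.
#' @param chrom_sizes named integer vector of chromosome lengths; if missing,
#'   sizes are taken as the maximum gene end per chromosome.
#' @return An object of class `genome_annotation`: list with `genes` (named
#'   list of gene models) and `chrom_sizes`.
#' @export
genome_annotation <- function(genes, chrom_sizes = NULL) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(vapply(genes, `[[`, 0, "end"),
                          vapply(genes, `[[`, "", "chrom"), max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  for (g in genes) {
    cs <- chrom_sizes[[g$chrom]]
    if (is.null(cs) || is.na(cs) || g$end > cs)
      stop("gene ", g$gene_id, " extends past chromosome ", g$chrom, " bounds")
  }
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d gene(s) on %d chromosome(s)\n",
              length(x$genes), length(x$chrom_sizes)))
  invisible(x)
}

# flat data.frame view (no exons) used by the interval logic
annotation_table <- function(annotation) {
  g <- annotation$genes
  data.frame(
    gene_id = vapply(g, `[[`, "", "gene_id"),
    chrom = vapply(g, `[[`, "", "chrom"),
    strand = vapply(g, `[[`, "", "strand"),
    start = vapply(g, `[[`, 0, "start"),
    end = vapply(g, `[[`, 0, "end"),
    tss = vapply(g, `[[`, 0, "tss"),
    tts = vapply(g, `[[`, 0, "tts"),
    row.names = NULL
  )
}

#' Strand-oriented interval downstream of a gene's TTS
#'
#' @param gene a [gene_model].
#' @param length_bp positive extent past the TTS.
#' @param chrom_size optional chromosome length used to clip the interval.
#' @return list with `chrom`, `start`, `end` (0-based half-open), `strand`
#'   (traversal is always TTS-proximal to distal: left-to-right for `+`,
#'   right-to-left for `-`) and `truncated` (TRUE when clipped at a
#'   chromosome bound).
#' @export
downstream_interval <- function(gene, length_bp, chrom_size = NULL) {
  stopifnot(length_bp > 0)
  if (gene$strand == "+") {
    start <- gene$tts
    end <- gene$tts + length_bp
    truncated <- FALSE
    if (!is.null(chrom_size) && end > chrom_size) {
      end <- chrom_size
      truncated <- TRUE
    }
  } else {
    end <- gene$tts
    start <- gene$tts - length_bp
    truncated <- FALSE
    if (start < 0) {
      start <- 0
      truncated <- TRUE
    }
  }
  list(chrom = gene$chrom, start = start, end = end,
       strand = gene$strand, truncated = truncated)
}

#' Genes eligible for read-through calling (clear-zone filter)
#'
#' A gene is retained only if no other annotated gene, on either strand,
#' overlaps the region within `clear_zone_bp` downstream of its TTS. Genes
#' whose body is overlapped by another gene are also removed (their
#' downstream zone would be ambiguous). Zones running past a chromosome end
#' are truncated, not discarded.
#'
#' @param annotation a [genome_annotation].
#' @param clear_zone_bp width of the downstream clear zone (default 5000).
#' @return character vector of eligible gene_ids.
#' @export
eligible_readthrough_genes <- function(annotation, clear_zone_bp = 5000) {
  stopifnot(clear_zone_bp > 0)
  tab <- annotation_table(annotation)
  n <- nrow(tab)
  if (n == 0L) return(character())
  keep <- logical(n)
  for (i in seq_len(n)) {
    zone <- downstream_interval(annotation$genes[[i]], clear_zone_bp,
                                annotation$chrom_sizes[[tab$chrom[i]]])
    others <- tab$chrom == tab$chrom[i] & seq_len(n) != i
    # overlap with the clear zone (either strand) or with the gene body
    hit <- others & (
      (tab$start < zone$end & tab$end > zone$start) |
      (tab$start < tab$end[i] & tab$end > tab$start[i])
    )
    keep[i] <- !any(hit)
  }
  tab$gene_id[keep]
}

#' Tandem gene pairs
#'
#' For each gene, the nearest same-strand gene on the same chromosome whose
#' TSS lies 3' of the gene's TTS forms a tandem pair: the configuration in
#' which read-through from the upstream gene can invade the downstream gene.
#' Overlapping genes never form a pair.
#'
#' @param annotation a [genome_annotation].
#' @return data.frame with columns `upstream_id`, `downstream_id`, `chrom`,
#'   `strand`, `intergenic_start`, `intergenic_end` (0-based half-open
#'   interval between upstream TTS and downstream TSS) and `gap_bp`.
#' @export
build_tandem_pairs <- function(annotation) {
  tab <- annotation_table(annotation)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    same <- tab$chrom == tab$chrom[i] & tab$strand == tab$strand[i] &
      seq_len(nrow(tab)) != i
    if (!any(same)) next
    cand <- tab[same, ]
    if (tab$strand[i] == "+") {
      cand <- cand[cand$tss >= tab$tts[i], ]
      if (nrow(cand) == 0L) next
      j <- which.min(cand$tss - tab$tts[i])
      gap <- cand$tss[j] - tab$tts[i]
      ig <- c(tab$tts[i], cand$tss[j])
    } else {
      cand <- cand[cand$tss <= tab$tts[i], ]
      if (nrow(cand) == 0L) next
      j <- which.min(tab$tts[i] - cand$tss)
      gap <- tab$tts[i] - cand$tss[j]
      ig <- c(cand$tss[j], tab$tts[i])
    }
    out[[length(out) + 1L]] <- data.frame(
      upstream_id = tab$gene_id[i], downstream_id = cand$gene_id[j],
      chrom = tab$chrom[i], strand = tab$strand[i],
      intergenic_start = ig[1], intergenic_end = ig[2], gap_bp = gap
    )
  }
  if (length(out) == 0L)
    return(data.frame(upstream_id = character(), downstream_id = character(),
                      chrom = character(), strand = character(),
                      intergenic_start = numeric(), intergenic_end = numeric(),
                      gap_bp = numeric()))
  do.call(rbind, out)
}

#' Read gene models from a GTF file
#'
#' Exon rows are grouped by the `gene_id` attribute and merged into one
#' transcript model per gene.
#'
#' @param path GTF file path.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return A [genome_annotation].
#' @export
read_annotation_gtf <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  ids <- as.character(gr$gene_id)
  genes <- lapply(split(seq_along(gr), ids), function(idx) {
    sub <- gr[idx]
    chrom <- unique(as.character(GenomicRanges::seqnames(sub)))
    strand <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(chrom) != 1L || length(strand) != 1L)
      stop("gene ", ids[idx[1]], ": transcripts disagree on chromosome or strand")
    gene_model(ids[idx[1]], chrom, strand,
               cbind(GenomicRanges::start(sub) - 1L, GenomicRanges::end(sub)))
  })
  genome_annotation(unname(genes), chrom_sizes)
}

#' Write merged gene models as GTF
#'
#' @param annotation a [genome_annotation].
#' @param path output file.
#' @export
write_annotation_gtf <- function(annotation, path) {
  rows <- lapply(annotation$genes, function(g) {
    ex <- g$exons
    GenomicRanges::GRanges(
      g$chrom,
      IRanges::IRanges(start = ex[, 1] + 1L, end = ex[, 2]),
      strand = g$strand, type = "exon",
      gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".m"),
      source = "rtscan"
    )
  })
  gr <- suppressWarnings(do.call(c, unname(rows)))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write merged gene models as BED12
#'
#' @param annotation a [genome_annotation].
#' @param path output file.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  lines <- vapply(annotation$genes, function(g) {
    ex <- g$exons
    paste(g$chrom, g$start, g$end, g$gene_id, 0, g$strand, g$start, g$end,
          "0,0,0", nrow(ex),
          paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
          paste0(paste(ex[, 1] - g$start, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a BED12 file
#'
#' @param path BED12 file path (one merged model per line; the name column is
#'   the gene_id).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return A [genome_annotation].
#' @export
read_annotation_bed12 <- function(path, chrom_sizes = NULL) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected BED12 (12 columns) in ", path)
  genes <- lapply(seq_len(nrow(tab)), function(i) {
    sizes <- as.numeric(strsplit(tab[i, 11], ",")[[1]])
    offs <- as.numeric(strsplit(tab[i, 12], ",")[[1]])
    st <- tab[i, 2] + offs
    gene_model(tab[i, 4], tab[i, 1], tab[i, 6], cbind(st, st + sizes))
  })
  genome_annotation(genes, chrom_sizes)
}

#' Write tandem pairs as TSV
#'
#' @param pairs data.frame from [build_tandem_pairs].
#' @param path output file.
#' @export
write_tandem_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
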