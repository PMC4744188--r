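#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' structure the analysis assumes: paired test/control strand-resolved
#' coverage with per-base Poisson noise, planted exponentially decaying
#' read-through tails past the TTS (gene-body expression unchanged, so a
#' planted call is attributable to termination failure alone), invasion of
#' downstream tandem genes, chimeric junction reads, and survival times
#' whose hazard depends on true read-through burden.
#'
#' @param n_chroms,chrom_len_bp number of chromosomes and their length;
#'   `chrom_len_bp = NULL` (default) auto-sizes each chromosome to fit its
#'   genes. An explicit length too small for the genes is an error.
#' @param n_genes total genes across chromosomes.
#' @param gene_len_meanlog,gene_len_sdlog,gene_len_min,gene_len_max log-normal
#'   gene-length model (median 10 kb) with clamping.
#' @param gap_meanlog,gap_sdlog,gap_min intergenic gap model (median 8 kb,
#'   min 1 kb).
#' @param short_gap_fraction fraction of gaps drawn below 5 kb so the
#'   clear-zone filter is exercised (default 0.2).
#' @param plus_strand_prob per-gene probability of the `+` strand; values
#'   near 1 give the same-strand gene chains tandem pairs need (default 0.8).
#' @param exon_range min/max exons per gene (default 2..10).
#' @param depth_meanlog,depth_sdlog log-normal gene-body mean read depth.
#' @param background_depth intergenic mean depth (default 0.5; low relative
#'   to gene bodies but deep enough that a 100-bp window carries signal).
#' @param readthrough_fraction fraction of plantable genes given a tail per
#'   test sample (default 0.3); `n_readthrough` overrides with an absolute
#'   count when not NULL.
#' @param min_planted_depth only genes at or above this control depth are
#'   planted (default 30), keeping planted effects well above noise.
#' @param rho initial tail depth as a fraction of gene depth (default 0.8).
#' @param decay_bp exponential tail characteristic length (default 2000).
#' @param tail_len_range planted tail extents, uniform (default 2-6 kb),
#'   truncated at the next annotated gene.
#' @param invasion_fraction_of_rt fraction of planted read-through genes with
#'   a tandem pair whose tail invades the downstream gene (default 0.3).
#' @param invaded_fraction_target fraction of the downstream gene covered by
#'   a planted invasion (default 0.2).
#' @param invasion_boost added depth inside the invaded region, as a multiple
#'   of the downstream gene's own depth (default 2: fold-change about 3).
#' @param lambda_chim Poisson mean of junction reads per invaded pair.
#' @param chim_modal_prob probability a planted chimera joins the second-last
#'   exon of the upstream gene to the second exon of the downstream gene
#'   (default 0.8).
#' @param n_noise_junctions unassigned singleton decoy junctions per sample.
#' @param surv_scale_days baseline exponential survival scale (mean days).
#' @param hazard_multiplier hazard multiplier for samples whose true burden
#'   exceeds `survival_cutoff` (default 3).
#' @param admin_censor_days administrative censoring time (default 2000).
#' @param survival_cutoff true-burden cutoff defining the high stratum.
#' @param burden_span per-sample planted burden, as a uniform range of
#'   fractions of the plantable gene count (default 0.05-0.95), so cohorts
#'   span the stratification cutoff.
#' @param mut_prob_high,mut_prob_low probability of the "mutant" label in the
#'   sample sheet for high/low true-burden samples (for 2x2 contrasts).
#' @param read_len_bp nominal read length; total mapped reads is defined as
#'   total depth-bases / read length (default 100).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_len_bp = NULL, n_genes = 200,
                       gene_len_meanlog = log(10000), gene_len_sdlog = 0.5,
                       gene_len_min = 1500, gene_len_max = 50000,
                       gap_meanlog = log(8000), gap_sdlog = 0.6, gap_min = 1000,
                       short_gap_fraction = 0.2, plus_strand_prob = 0.8,
                       exon_range = c(2, 10),
                       depth_meanlog = log(20), depth_sdlog = 0.7,
                       background_depth = 0.5,
                       readthrough_fraction = 0.3, n_readthrough = NULL,
                       min_planted_depth = 30, rho = 0.8, decay_bp = 2000,
                       tail_len_range = c(2000, 6000),
                       invasion_fraction_of_rt = 0.3,
                       invaded_fraction_target = 0.2, invasion_boost = 2,
                       lambda_chim = 3, chim_modal_prob = 0.8,
                       n_noise_junctions = 10,
                       surv_scale_days = 1000, hazard_multiplier = 3,
                       admin_censor_days = 2000, survival_cutoff = 200,
                       burden_span = c(0.05, 0.95),
                       mut_prob_high = 0.8, mut_prob_low = 0.2,
                       read_len_bp = 100) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$rho >= 0, cfg$decay_bp > 0,
            cfg$short_gap_fraction >= 0, cfg$short_gap_fraction <= 1,
            cfg$invaded_fraction_target >= 0, cfg$invaded_fraction_target <= 1,
            cfg$readthrough_fraction >= 0, cfg$readthrough_fraction <= 1,
            cfg$background_depth >= 0, cfg$read_len_bp > 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a genome annotation
#'
#' Genes are packed sequentially per chromosome: log-normal lengths, 2-10
#' exons, strand-biased chains, intergenic gaps with a configurable fraction
#' below 5 kb so the clear-zone filter has work to do.
#'
#' @param config a [sim_config].
#' @param seed integer seed; fixed seed gives identical output.
#' @return a [genome_annotation].
#' @export
simulate_annotation <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  genes <- list()
  chrom_sizes <- numeric(0)
  gid <- 0L
  for (ci in seq_len(config$n_chroms)) {
    chrom <- paste0("chr", ci)
    pos <- 6000  # leading margin for upstream flanks
    for (k in seq_len(n_per[ci])) {
      gid <- gid + 1L
      len <- round(min(config$gene_len_max,
                       max(config$gene_len_min,
                           stats::rlnorm(1, config$gene_len_meanlog,
                                         config$gene_len_sdlog))))
      n_ex <- sample(config$exon_range[1]:config$exon_range[2], 1)
      cuts <- sort(sample(seq_len(len - 1L), 2L * (n_ex - 1L)))
      bounds <- c(0, cuts, len)
      ex <- cbind(pos + bounds[seq(1, length(bounds), by = 2)],
                  pos + bounds[seq(2, length(bounds), by = 2)])
      strand <- if (stats::runif(1) < config$plus_strand_prob) "+" else "-"
      genes[[gid]] <- gene_model(sprintf("G%04d", gid), chrom, strand, ex)
      if (stats::runif(1) < config$short_gap_fraction) {
        gap <- round(stats::runif(1, config$gap_min, 4999))
      } else {
        # long branch truncated at 5 kb so short_gap_fraction is the realized
        # fraction of sub-5 kb gaps
        repeat {
          gap <- round(stats::rlnorm(1, config$gap_meanlog, config$gap_sdlog))
          if (gap >= 5000) break
        }
      }
      pos <- pos + len + gap
    }
    size <- pos + 6000
    if (!is.null(config$chrom_len_bp)) {
      if (size > config$chrom_len_bp)
        stop("infeasible packing: ", chrom, " needs ", size,
             " bp but chrom_len_bp is ", config$chrom_len_bp)
      size <- config$chrom_len_bp
    }
    chrom_sizes[chrom] <- size
  }
  genome_annotation(genes, chrom_sizes)
}

# per-chromosome/strand mean-depth vectors for a control sample
control_means <- function(annotation, depths, config) {
  means <- lapply(annotation$chrom_sizes, function(sz)
    list("+" = rep(config$background_depth, sz),
         "-" = rep(config$background_depth, sz)))
  for (id in names(annotation$genes)) {
    g <- annotation$genes[[id]]
    idx <- (g$start + 1L):g$end
    means[[g$chrom]][[g$strand]][idx] <-
      means[[g$chrom]][[g$strand]][idx] + depths[[id]]
  }
  means
}

# add a planted tail profile downstream of a gene's TTS (in place semantics
# via returned list)
add_downstream <- function(means, gene, profile) {
  n <- length(profile)
  if (n == 0L) return(means)
  v <- means[[gene$chrom]][[gene$strand]]
  if (gene$strand == "+") {
    idx <- (gene$tts + 1L):(gene$tts + n)
  } else {
    idx <- gene$tts:(gene$tts - n + 1L)
  }
  keep <- idx >= 1L & idx <= length(v)
  v[idx[keep]] <- v[idx[keep]] + profile[keep]
  means[[gene$chrom]][[gene$strand]] <- v
  means
}

poisson_track <- function(means, read_len_bp) {
  cov <- lapply(means, function(ch)
    lapply(ch, function(mu) stats::rpois(length(mu), mu)))
  total <- sum(vapply(cov, function(ch)
    sum(vapply(ch, function(v) sum(as.numeric(v)), 0)), 0))
  coverage_track(cov, max(1, round(total / read_len_bp)))
}

# distance from a gene's TTS to the next annotated gene on its chromosome
# (either strand), used to truncate planted tails
gap_past_tts <- function(tab, chrom_sizes, gene) {
  same <- tab$chrom == gene$chrom & tab$gene_id != gene$gene_id
  if (gene$strand == "+") {
    d <- tab$start[same] - gene$tts
    lim <- chrom_sizes[[gene$chrom]] - gene$tts
  } else {
    d <- gene$tts - tab$end[same]
    lim <- gene$tts
  }
  d <- d[d >= 0]
  if (length(d) == 0L) lim else min(min(d), lim)
}

#' Simulate one matched test/control sample pair
#'
#' Control coverage is Poisson around per-gene mean depths with near-zero
#' intergenic background. The test sample shares every gene-body mean (so
#' the overall-increase filter is never triggered by planting) and adds, for
#' planted genes, an exponentially decaying tail from the TTS; for planted
#' invasions, elevated coverage across the whole intergenic gap and over the
#' leading fraction of the downstream gene; and junction reads for planted
#' chimeras.
#'
#' @param annotation a [genome_annotation].
#' @param config a [sim_config].
#' @param seed integer seed.
#' @param sample_id label used in read ids and ground truth.
#' @param n_readthrough optional absolute number of planted genes, overriding
#'   `config$readthrough_fraction` (and `config$n_readthrough`).
#' @return list with `control`, `test` ([coverage_track]s), `junctions`
#'   (data.frame: chrom, donor_pos, acceptor_pos, strand, read_id), `truth`
#'   (list: `readthrough` data.frame of planted genes with tail lengths and
#'   depths; `invaded` data.frame with planted fractions; `chimeras`
#'   data.frame with exon ranks and read counts; `n_true_readthrough`;
#'   `depths`).
#' @export
simulate_sample_pair <- function(annotation, config = sim_config(), seed = 1,
                                 sample_id = "S1", n_readthrough = NULL) {
  set.seed(seed)
  genes <- annotation$genes
  ids <- names(genes)
  depths <- stats::setNames(
    stats::rlnorm(length(ids), config$depth_meanlog, config$depth_sdlog), ids)

  eligible <- eligible_readthrough_genes(annotation, 5000)
  active_cut <- stats::quantile(depths, 0.25, names = FALSE)
  plantable <- ids[ids %in% eligible & depths >= config$min_planted_depth &
                     depths > active_cut]
  n_rt <- n_readthrough %||% config$n_readthrough %||%
    round(config$readthrough_fraction * length(plantable))
  n_rt <- min(n_rt, length(plantable))
  planted <- if (n_rt > 0) sample(plantable, n_rt) else character(0)

  pairs <- build_tandem_pairs(annotation)
  # invadable: planted upstream gene of a tandem pair (downstream body >= 1 kb
  # so a planted fraction spans at least a few windows)
  pair_ok <- pairs$upstream_id %in% planted &
    vapply(pairs$downstream_id, function(d)
      genes[[d]]$end - genes[[d]]$start >= 1000, TRUE)
  n_inv <- round(config$invasion_fraction_of_rt * sum(pair_ok))
  inv_rows <- if (n_inv > 0) sample(which(pair_ok), n_inv) else integer(0)
  invaded_up <- pairs$upstream_id[inv_rows]

  means_ctrl <- control_means(annotation, depths, config)
  means_test <- means_ctrl
  tab <- annotation_table(annotation)

  rt_truth <- list()
  for (id in planted) {
    g <- genes[[id]]
    d <- depths[[id]]
    if (id %in% invaded_up) {
      row <- pairs[inv_rows[match(id, invaded_up)], ]
      dn <- genes[[row$downstream_id]]
      gap <- row$gap_bp
      # flat elevated intergenic tail reaching the downstream gene
      if (gap > 0)
        means_test <- add_downstream(means_test, g, rep(config$rho * d, gap))
      inv_len <- round(config$invaded_fraction_target * (dn$end - dn$start))
      prof_dn <- rep(config$invasion_boost * depths[[row$downstream_id]], inv_len)
      dn_as_tts <- list(chrom = dn$chrom, strand = dn$strand,
                        tts = dn$tss, gene_id = dn$gene_id)
      # reuse the downstream-adder with the downstream gene's TSS as origin
      means_test <- add_downstream(means_test, dn_as_tts, prof_dn)
      tail_len <- gap
    } else {
      tail_len <- round(stats::runif(1, config$tail_len_range[1],
                                     config$tail_len_range[2]))
      tail_len <- min(tail_len, gap_past_tts(tab, annotation$chrom_sizes, g))
      if (tail_len > 0) {
        x <- seq_len(tail_len) - 1L
        means_test <- add_downstream(means_test, g,
                                     config$rho * d * exp(-x / config$decay_bp))
      }
    }
    rt_truth[[id]] <- data.frame(gene_id = id, tail_len_bp = tail_len,
                                 depth = d)
  }

  # chimera junction reads for invaded pairs
  jx <- list()
  chim_truth <- list()
  for (k in seq_along(inv_rows)) {
    row <- pairs[inv_rows[k], ]
    n_reads <- stats::rpois(1, config$lambda_chim)
    if (n_reads == 0L) next
    up <- genes[[row$upstream_id]]
    dn <- genes[[row$downstream_id]]
    if (stats::runif(1) < config$chim_modal_prob) {
      dr <- 2L; ar <- 2L
    } else {
      alt <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L))
      pick <- alt[sample(nrow(alt), 1), ]
      dr <- pick[1]; ar <- pick[2]
    }
    dr <- min(dr, nrow(up$exons))
    ar <- min(ar, nrow(dn$exons))
    donor_pos <- exon_donor_pos(up, dr)
    acceptor_pos <- exon_acceptor_pos(dn, ar)
    jx[[length(jx) + 1L]] <- data.frame(
      chrom = row$chrom, donor_pos = donor_pos, acceptor_pos = acceptor_pos,
      strand = row$strand,
      read_id = sprintf("%s_chim%02d_r%d", sample_id, k, seq_len(n_reads)),
      row.names = NULL)
    chim_truth[[length(chim_truth) + 1L]] <- data.frame(
      upstream_id = row$upstream_id, downstream_id = row$downstream_id,
      donor_exon_rank_from_end = dr, acceptor_exon_rank = ar,
      n_reads = n_reads)
  }
  # unassigned singleton decoys
  if (config$n_noise_junctions > 0) {
    ch <- sample(names(annotation$chrom_sizes), config$n_noise_junctions,
                 replace = TRUE)
    dp <- vapply(ch, function(c)
      round(stats::runif(1, 1000, annotation$chrom_sizes[[c]] - 7000)), 0)
    jx[[length(jx) + 1L]] <- data.frame(
      chrom = ch, donor_pos = dp,
      acceptor_pos = dp + round(stats::runif(config$n_noise_junctions, 200, 5000)),
      strand = sample(c("+", "-"), config$n_noise_junctions, replace = TRUE),
      read_id = sprintf("%s_noise_r%d", sample_id,
                        seq_len(config$n_noise_junctions)))
  }
  junctions <- if (length(jx)) do.call(rbind, jx) else
    data.frame(chrom = character(), donor_pos = numeric(),
               acceptor_pos = numeric(), strand = character(),
               read_id = character())
  rownames(junctions) <- NULL

  truth <- list(
    readthrough = if (length(rt_truth)) do.call(rbind, c(rt_truth,
                                                         make.row.names = FALSE))
                  else data.frame(gene_id = character(), tail_len_bp = numeric(),
                                  depth = numeric()),
    invaded = if (length(inv_rows))
      data.frame(upstream_id = pairs$upstream_id[inv_rows],
                 downstream_id = pairs$downstream_id[inv_rows],
                 invaded_fraction = config$invaded_fraction_target)
    else data.frame(upstream_id = character(), downstream_id = character(),
                    invaded_fraction = numeric()),
    chimeras = if (length(chim_truth)) do.call(rbind, c(chim_truth,
                                                        make.row.names = FALSE))
               else data.frame(upstream_id = character(),
                               downstream_id = character(),
                               donor_exon_rank_from_end = integer(),
                               acceptor_exon_rank = integer(),
                               n_reads = integer()),
    n_true_readthrough = length(planted),
    depths = depths
  )
  list(control = poisson_track(means_ctrl, config$read_len_bp),
       test = poisson_track(means_test, config$read_len_bp),
       junctions = junctions, truth = truth)
}

# genomic coordinate of a donor exon's 3' boundary (transcription order);
# rank 1 = last exon
exon_donor_pos <- function(gene, rank_from_end) {
  n <- nrow(gene$exons)
  stopifnot(rank_from_end >= 1, rank_from_end <= n)
  if (gene$strand == "+") gene$exons[n - rank_from_end + 1L, 2L]
  else gene$exons[rank_from_end, 1L]
}

# genomic coordinate of an acceptor exon's 5' boundary; rank 1 = first exon
exon_acceptor_pos <- function(gene, rank) {
  n <- nrow(gene$exons)
  stopifnot(rank >= 1, rank <= n)
  if (gene$strand == "+") gene$exons[rank, 1L]
  else gene$exons[n - rank + 1L, 2L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of sample pairs with burden-linked survival
#'
#' Per-sample planted burden is drawn uniformly over a configurable fraction
#' of the plantable genes so the cohort spans the stratification cutoff;
#' survival times are exponential with the hazard multiplied by
#' `config$hazard_multiplier` for samples whose true burden exceeds
#' `config$survival_cutoff`, censored administratively.
#'
#' @param annotation a [genome_annotation].
#' @param config a [sim_config].
#' @param n_samples number of test/control pairs (>= 2).
#' @param seed integer master seed; each sample uses a derived substream
#'   (`seed + 7919 * i`).
#' @return list with `samples` (named list of [simulate_sample_pair] results),
#'   `survival` (data.frame: sample_id, time_days, event), `sample_sheet`
#'   (data.frame: sample_id, control_id, total reads, true burden, mutation
#'   label), `truth` (per-sample truth plus `true_stratum`).
#' @export
simulate_cohort <- function(annotation, config = sim_config(), n_samples = 10,
                            seed = 1) {
  stopifnot(n_samples >= 2)
  set.seed(seed)
  burden_frac <- stats::runif(n_samples, config$burden_span[1],
                              config$burden_span[2])
  samples <- list()
  sheet <- list()
  truth <- list()
  for (i in seq_len(n_samples)) {
    sid <- sprintf("T%02d", i)
    sub_seed <- seed + 7919L * i
    # plantable count is depth-dependent; pass the burden as a fraction by
    # temporarily scaling readthrough_fraction
    cfg_i <- config
    cfg_i$readthrough_fraction <- burden_frac[i]
    cfg_i$n_readthrough <- NULL
    sp <- simulate_sample_pair(annotation, cfg_i, seed = sub_seed,
                               sample_id = sid)
    samples[[sid]] <- sp
    truth[[sid]] <- sp$truth
    sheet[[i]] <- data.frame(
      sample_id = sid, control_id = paste0("N", substring(sid, 2)),
      test_total_reads = sp$test$total_mapped_reads,
      control_total_reads = sp$control$total_mapped_reads,
      true_burden = sp$truth$n_true_readthrough)
  }
  sheet <- do.call(rbind, sheet)
  high <- sheet$true_burden > config$survival_cutoff
  sheet$mutation_status <- ifelse(
    stats::runif(n_samples) < ifelse(high, config$mut_prob_high,
                                     config$mut_prob_low),
    "mutant", "wildtype")
  rate <- ifelse(high, config$hazard_multiplier, 1) / config$surv_scale_days
  t_raw <- stats::rexp(n_samples, rate)
  survival <- data.frame(
    sample_id = sheet$sample_id,
    time_days = pmin(t_raw, config$admin_censor_days),
    event = as.integer(t_raw <= config$admin_censor_days))
  list(samples = samples, survival = survival, sample_sheet = sheet,
       truth = list(per_sample = truth,
                    true_stratum = ifelse(high, "high", "low")))
}

#' Write a simulated cohort to disk
#'
#' Emits `genes.gtf`, `chrom_sizes.tsv`, per-sample strand-split bedGraphs
#' and junction TSVs, `samples.tsv`, `survival.tsv` and `truth.json`.
#'
#' @param annotation a [genome_annotation].
#' @param cohort result of [simulate_cohort].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(annotation, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation_gtf(annotation, file.path(out_dir, "genes.gtf"))
  utils::write.table(
    data.frame(chrom = names(annotation$chrom_sizes),
               size = as.numeric(annotation$chrom_sizes)),
    file.path(out_dir, "chrom_sizes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (sid in names(cohort$samples)) {
    sp <- cohort$samples[[sid]]
    cid <- cohort$sample_sheet$control_id[cohort$sample_sheet$sample_id == sid]
    write_bedgraph(sp$test, "+", file.path(out_dir, paste0(sid, ".plus.bedgraph")))
    write_bedgraph(sp$test, "-", file.path(out_dir, paste0(sid, ".minus.bedgraph")))
    write_bedgraph(sp$control, "+", file.path(out_dir, paste0(cid, ".plus.bedgraph")))
    write_bedgraph(sp$control, "-", file.path(out_dir, paste0(cid, ".minus.bedgraph")))
    utils::write.table(sp$junctions,
                       file.path(out_dir, paste0(sid, ".junctions.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$sample_sheet, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, file.path(out_dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$per_sample <- lapply(truth$per_sample, function(t)
    t[setdiff(names(t), "depths")])
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
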