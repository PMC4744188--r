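#' Run the per-sample stages for one test/control pair
#'
#' Reads a data directory laid out as the simulator writes it (`genes.gtf`,
#' `chrom_sizes.tsv`, `samples.tsv`, per-sample strand-split bedGraphs and
#' junction TSVs), runs the requested stages for one sample, and writes
#' per-sample TSVs plus a `.run.json` manifest (parameters, package version,
#' input checksums). Outputs are pure functions of the inputs and
#' parameters.
#'
#' @param data_dir input directory.
#' @param sample_id sample to process (must appear in `samples.tsv` with its
#'   control).
#' @param out_dir output directory (created if needed).
#' @param params a [caller_params].
#' @param stages subset of `c("call", "interfere", "chimera")`; interference
#'   and chimera calling require (and imply) the call stage.
#' @return invisibly, a list with `profile`, `invasion`, `chimeras`.
#' @export
run_pair <- function(data_dir, sample_id, out_dir, params = caller_params(),
                     stages = c("call", "interfere", "chimera")) {
  stages <- match.arg(stages, c("call", "interfere", "chimera"),
                      several.ok = TRUE)
  inp <- load_run_inputs(data_dir)
  row <- inp$sheet[inp$sheet$sample_id == sample_id, ]
  if (nrow(row) != 1L)
    stop("sample ", sample_id, " not found in ", file.path(data_dir, "samples.tsv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tracks <- load_pair_tracks(data_dir, row, inp$chrom_sizes)
  prof <- profile_sample(tracks$test, tracks$control, inp$annotation, params,
                         sample_id = sample_id, control_id = row$control_id)
  write_calls_tsv(prof, file.path(out_dir, paste0(sample_id, ".calls.tsv")))

  invasion <- NULL
  if ("interfere" %in% stages) {
    called <- prof$calls$gene_id[which(prof$calls$called)]
    use <- inp$pairs[inp$pairs$upstream_id %in% called, , drop = FALSE]
    invasion <- do.call(rbind, lapply(seq_len(nrow(use)), function(i)
      invasion_fraction(tracks$test, tracks$control, use[i, ],
                        inp$annotation, params)))
    if (is.null(invasion))
      invasion <- data.frame(upstream_id = character(),
                             downstream_id = character(),
                             intergenic_fc = numeric(),
                             intergenic_undefined = logical(),
                             invaded_fraction = numeric(),
                             downstream_body_fc = numeric())
    utils::write.table(invasion,
                       file.path(out_dir, paste0(sample_id, ".invasion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  chim <- NULL
  if ("chimera" %in% stages) {
    jx_path <- file.path(data_dir, paste0(sample_id, ".junctions.tsv"))
    if (file.exists(jx_path)) {
      chim <- call_chimeras(read_junctions(jx_path), inp$annotation,
                            inp$pairs, sample_id = sample_id)
      write_chimeras_tsv(chim,
                         file.path(out_dir, paste0(sample_id, ".chimeras.tsv")))
    }
  }

  manifest <- list(
    sample_id = sample_id, control_id = row$control_id, stages = stages,
    params = unclass(params), package_version = as.character(
      utils::packageVersion("rtscan")),
    input_md5 = as.list(tools::md5sum(list.files(data_dir, full.names = TRUE))))
  names(manifest$input_md5) <- basename(names(manifest$input_md5))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(sample_id, ".run.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profile = prof, invasion = invasion, chimeras = chim))
}

load_run_inputs <- function(data_dir) {
  cs_tab <- utils::read.table(file.path(data_dir, "chrom_sizes.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  chrom_sizes <- stats::setNames(cs_tab$size, cs_tab$chrom)
  annotation <- read_annotation_gtf(file.path(data_dir, "genes.gtf"),
                                    chrom_sizes)
  sheet <- utils::read.table(file.path(data_dir, "samples.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  list(annotation = annotation, chrom_sizes = chrom_sizes, sheet = sheet,
       pairs = build_tandem_pairs(annotation))
}

load_pair_tracks <- function(data_dir, row, chrom_sizes) {
  path <- function(id, s) file.path(data_dir, paste0(id, ".", s, ".bedgraph"))
  miss <- !file.exists(c(path(row$sample_id, "plus"), path(row$sample_id, "minus"),
                         path(row$control_id, "plus"), path(row$control_id, "minus")))
  if (any(miss)) stop("missing bedGraph file(s) for ", row$sample_id,
                      " / ", row$control_id, " in ", data_dir)
  list(test = read_bedgraph_track(path(row$sample_id, "plus"),
                                  path(row$sample_id, "minus"),
                                  chrom_sizes, row$test_total_reads),
       control = read_bedgraph_track(path(row$control_id, "plus"),
                                     path(row$control_id, "minus"),
                                     chrom_sizes, row$control_total_reads))
}

#' Run the full cohort analysis
#'
#' Per-sample read-through profiling with failure isolation, then the cohort
#' aggregates: the per-sample burden table, stratification by read-through
#' burden with a log-rank survival comparison (when `survival.tsv` is
#' present), the read-through vs downstream-expression correlation screen,
#' chimera calls with the splice-pattern histogram and the chimera/burden
#' association, and per-sample metagene matrices over called genes.
#'
#' @param data_dir input directory ([write_cohort] layout).
#' @param out_dir output directory.
#' @param params a [caller_params].
#' @param cutoff_genes stratification cutoff (default 200).
#' @param screen_min_samples minimum informative sample pairs per tandem pair
#'   in the correlation screen (default 10).
#' @param screen_min_called minimum samples in which the upstream gene is
#'   called for a tandem pair to enter the screen (default 1).
#' @param stages subset of `c("call", "interfere", "chimera", "cohort")`.
#' @param write_metagene write per-sample metagene matrices for called genes
#'   (default TRUE).
#' @return invisibly, a list with `burden`, `stratification`, `logrank`,
#'   `screen`, `patterns`, `association`, `failed_samples`.
#' @export
run_cohort <- function(data_dir, out_dir, params = caller_params(),
                       cutoff_genes = 200, screen_min_samples = 10,
                       screen_min_called = 1,
                       stages = c("call", "interfere", "chimera", "cohort"),
                       write_metagene = TRUE) {
  stages <- match.arg(stages, c("call", "interfere", "chimera", "cohort"),
                      several.ok = TRUE)
  inp <- load_run_inputs(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- inp$sheet

  profiles <- list()
  tracks <- list()
  chim_calls <- list()
  failed <- character(0)
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    res <- tryCatch({
      tr <- load_pair_tracks(data_dir, sheet[i, ], inp$chrom_sizes)
      prof <- profile_sample(tr$test, tr$control, inp$annotation, params,
                             sample_id = sid,
                             control_id = sheet$control_id[i])
      write_calls_tsv(prof, file.path(out_dir, paste0(sid, ".calls.tsv")))
      if ("interfere" %in% stages) {
        called <- prof$calls$gene_id[which(prof$calls$called)]
        use <- inp$pairs[inp$pairs$upstream_id %in% called, , drop = FALSE]
        inv <- do.call(rbind, lapply(seq_len(nrow(use)), function(k)
          invasion_fraction(tr$test, tr$control, use[k, ], inp$annotation,
                            params)))
        if (!is.null(inv))
          utils::write.table(inv,
                             file.path(out_dir, paste0(sid, ".invasion.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if ("chimera" %in% stages) {
        jx_path <- file.path(data_dir, paste0(sid, ".junctions.tsv"))
        if (file.exists(jx_path)) {
          ch <- call_chimeras(read_junctions(jx_path), inp$annotation,
                              inp$pairs, sample_id = sid)
          write_chimeras_tsv(ch, file.path(out_dir,
                                           paste0(sid, ".chimeras.tsv")))
          chim_calls[[sid]] <- ch$calls
        }
      }
      if (write_metagene) write_sample_metagene(tr, prof, inp, params, out_dir)
      list(prof = prof, tr = tr)
    }, error = function(e) {
      message("sample ", sid, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      failed <- c(failed, sid)
    } else {
      profiles[[sid]] <- res$prof
      tracks[[sid]] <- res$tr
    }
  }
  if (length(failed))
    message(length(failed), " sample(s) failed: ", paste(failed, collapse = ", "))

  burden <- stats::setNames(
    vapply(profiles, `[[`, 0, "n_readthrough_genes"), names(profiles))
  utils::write.table(
    data.frame(sample_id = names(burden), n_readthrough_genes = burden,
               row.names = NULL),
    file.path(out_dir, "burden.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  strat <- logrank <- screen <- patterns <- assoc <- NULL
  if ("cohort" %in% stages) {
    strat <- stratify_by_readthrough(burden, cutoff_genes)
    utils::write.table(strat, file.path(out_dir, "stratification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    surv_path <- file.path(data_dir, "survival.tsv")
    if (file.exists(surv_path)) {
      surv <- read_survival_tsv(surv_path)
      m <- merge(surv, strat, by = "sample_id")
      logrank <- logrank_test(m$time_days, m$event, m$stratum)
      utils::write.table(
        data.frame(chisq = logrank$chisq, p = logrank$p, n = logrank$n,
                   flagged = logrank$flagged),
        file.path(out_dir, "logrank.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }

    # correlation screen over pairs whose upstream gene is called somewhere
    called_n <- table(unlist(lapply(profiles, function(p)
      p$calls$gene_id[which(p$calls$called)])))
    keep <- inp$pairs$upstream_id %in%
      names(called_n)[called_n >= screen_min_called]
    if (any(keep) && length(tracks) >= 2) {
      si <- screen_inputs(tracks, inp$pairs[keep, , drop = FALSE],
                          inp$annotation, params)
      screen <- correlation_screen(si$rt_levels, si$expr_levels,
                                   min_samples = screen_min_samples)
      utils::write.table(screen, file.path(out_dir, "screen.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    if (length(chim_calls)) {
      all_calls <- do.call(rbind, chim_calls)
      patterns <- tabulate_splice_patterns(all_calls)
      utils::write.table(patterns, file.path(out_dir, "chimera_patterns.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      n_chim <- stats::setNames(
        vapply(names(profiles), function(s)
          if (is.null(chim_calls[[s]])) 0 else nrow(chim_calls[[s]]), 0),
        names(profiles))
      assoc <- chimera_readthrough_association(
        burden, n_chim, strata = stats::setNames(strat$stratum, strat$sample_id))
      utils::write.table(
        data.frame(r = assoc$r, p = assoc$p, n = assoc$n,
                   flagged = assoc$flagged,
                   mean_chimeras_high = assoc$mean_high %||% NA,
                   mean_chimeras_low = assoc$mean_low %||% NA),
        file.path(out_dir, "chimera_association.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    stages = stages, params = unclass(params), cutoff_genes = cutoff_genes,
    screen_min_samples = screen_min_samples,
    screen_min_called = screen_min_called,
    package_version = as.character(utils::packageVersion("rtscan")),
    failed_samples = failed,
    input_md5 = as.list(tools::md5sum(list.files(data_dir, full.names = TRUE))))
  names(manifest$input_md5) <- basename(names(manifest$input_md5))
  jsonlite::write_json(manifest, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(burden = burden, stratification = strat, logrank = logrank,
                 screen = screen, patterns = patterns, association = assoc,
                 failed_samples = failed))
}

write_sample_metagene <- function(tr, prof, inp, params, out_dir) {
  called <- prof$calls[which(prof$calls$called), ]
  ok <- vapply(called$gene_id, function(id) {
    g <- inp$annotation$genes[[id]]
    g$end - g$start >= 60
  }, TRUE)
  called <- called[ok, , drop = FALSE]
  if (nrow(called) == 0L) return(invisible(NULL))
  profs <- function(track) lapply(called$gene_id, function(id)
    metagene_profile(track, inp$annotation$genes[[id]],
                     chrom_size = inp$chrom_sizes[[
                       inp$annotation$genes[[id]]$chrom]]))
  cm <- cohort_matrix(profs(tr$control), profs(tr$test),
                      called$readthrough_length_bp, params$pseudocount)
  write_mat <- function(m, path) {
    utils::write.table(data.frame(gene_id = rownames(m), m,
                                  check.names = FALSE, row.names = NULL),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(cm$control_log2,
            file.path(out_dir, paste0(prof$sample_id, ".metagene_control.tsv")))
  write_mat(cm$fc_log2,
            file.path(out_dir, paste0(prof$sample_id, ".metagene_fc.tsv")))
  sidecar <- list(window_bp = 100, flank_bp = 4000, body_bins = 60,
                  pseudocount = params$pseudocount,
                  order = "descending read-through length")
  jsonlite::write_json(sidecar,
                       file.path(out_dir,
                                 paste0(prof$sample_id, ".metagene.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
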