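#' Caller parameters
#'
#' Houses every threshold of the read-through caller. Defaults follow the
#' standard rule: RPKM counted in 100-bp windows over the 4 Kb downstream of
#' the TTS; a gene is called when more than six windows show at least a
#' 1.5-fold increase over the matched control; genes are first restricted to
#' transcriptionally active ones (above the 25th percentile of control
#' gene-body RPKM), to genes with a 5 Kb clear zone downstream of the TTS,
#' and genes with an overall gene-body increase are excluded.
#'
#' @param downstream_span_bp downstream extent scanned (default 4000).
#' @param window_bp window width (default 100).
#' @param fc_threshold per-window fold-change threshold, inclusive
#'   (default 1.5).
#' @param min_windows_above minimum windows at or above threshold for a call;
#'   the rule "more than six" means 7 (default 7, compared with >=).
#' @param active_percentile percentile of control gene-body RPKM defining
#'   transcriptionally active genes (default 25; strictly-above).
#' @param clear_zone_bp downstream clear zone for eligibility (default 5000).
#' @param overall_increase_fc gene-body fold-change at or above which a gene
#'   is excluded as globally upregulated (default 1.5).
#' @param pseudocount RPKM pseudocount for all fold-changes (default 0.1).
#' @param length_rule how read-through length is measured: `"contiguous"`
#'   (default; run of passing windows starting at the first passing window
#'   nearest the TTS) or `"distal"` (distance to the distal-most passing
#'   window).
#' @return list of class `caller_params`.
#' @export
caller_params <- function(downstream_span_bp = 4000, window_bp = 100,
                          fc_threshold = 1.5, min_windows_above = 7,
                          active_percentile = 25, clear_zone_bp = 5000,
                          overall_increase_fc = 1.5, pseudocount = 0.1,
                          length_rule = c("contiguous", "distal")) {
  stopifnot(downstream_span_bp > 0, window_bp > 0, fc_threshold > 0,
            min_windows_above > 0, clear_zone_bp > 0, overall_increase_fc > 0,
            pseudocount >= 0,
            min_windows_above <= downstream_span_bp / window_bp)
  structure(list(downstream_span_bp = downstream_span_bp, window_bp = window_bp,
                 fc_threshold = fc_threshold,
                 min_windows_above = min_windows_above,
                 active_percentile = active_percentile,
                 clear_zone_bp = clear_zone_bp,
                 overall_increase_fc = overall_increase_fc,
                 pseudocount = pseudocount,
                 length_rule = match.arg(length_rule)),
            class = "caller_params")
}

#' Transcriptionally active genes
#'
#' Genes strictly above the given percentile of the control-sample gene-body
#' RPKM distribution; the percentile is computed over all supplied genes,
#' zeros included (R's default linear-interpolation quantile).
#'
#' @param expression named numeric vector, gene_id -> control gene-body RPKM.
#' @param percentile percentile in [0, 100) (default 25).
#' @return character vector of active gene_ids.
#' @export
active_gene_filter <- function(expression, percentile = 25) {
  stopifnot(length(expression) > 0)
  cut <- stats::quantile(expression, percentile / 100, names = FALSE)
  names(expression)[expression > cut]
}

#' Overall-increase exclusion
#'
#' A gene whose whole-body expression rises at least `overall_increase_fc`
#' fold over the control is excluded from read-through calling: its
#' downstream elevation could reflect global upregulation rather than a
#' termination defect.
#'
#' @param test_expr,control_expr gene-body RPKM in test and control.
#' @param params a [caller_params].
#' @return TRUE when the gene is excluded.
#' @export
overall_increase_filter <- function(test_expr, control_expr, params = caller_params()) {
  pc <- params$pseudocount
  (test_expr + pc) / (control_expr + pc) >= params$overall_increase_fc
}

#' Read-through length from a fold-change vector
#'
#' With the default `"contiguous"` rule: `window_bp` times the run length of
#' consecutive windows at or above the fold-change threshold, starting at the
#' first passing window nearest the TTS; 0 when no window passes. The
#' `"distal"` rule instead returns the distance to the far edge of the
#' distal-most passing window.
#'
#' @param fc per-window fold-change vector, TTS-proximal first.
#' @param params a [caller_params].
#' @return length in bp.
#' @export
readthrough_length <- function(fc, params = caller_params()) {
  pass <- fc >= params$fc_threshold
  if (!any(pass)) return(0)
  if (params$length_rule == "distal")
    return(params$window_bp * max(which(pass)))
  first <- which(pass)[1L]
  run <- which(!pass[first:length(pass)])
  n <- if (length(run) == 0L) length(pass) - first + 1L else run[1L] - 1L
  params$window_bp * n
}

#' Call read-through for one gene from matched window vectors
#'
#' The core detection rule: more than `min_windows_above - 1` (default: more
#' than six) 100-bp windows with RPKM increased at least `fc_threshold`-fold
#' over control.
#'
#' @param test_wv,control_wv matched `window_vector` objects.
#' @param params a [caller_params].
#' @return one-row data.frame with `gene_id`, `called`, `n_windows_above`,
#'   `readthrough_length_bp`, `mean_downstream_fc`, `excluded_reason` (NA).
#' @export
call_gene_readthrough <- function(test_wv, control_wv, params = caller_params()) {
  fc <- fold_change_vector(test_wv, control_wv, params$pseudocount)
  n_above <- sum(fc >= params$fc_threshold)
  data.frame(
    gene_id = test_wv$gene_id,
    called = n_above >= params$min_windows_above,
    n_windows_above = n_above,
    readthrough_length_bp = readthrough_length(fc, params),
    mean_downstream_fc = mean(fc),
    excluded_reason = NA_character_
  )
}

excluded_call <- function(gene_id, reason) {
  data.frame(gene_id = gene_id, called = FALSE, n_windows_above = NA_integer_,
             readthrough_length_bp = NA_real_, mean_downstream_fc = NA_real_,
             excluded_reason = reason)
}

#' Read-through profile of one test/control sample pair
#'
#' Applies the full filter cascade, then calls every surviving
#' gene: (1) clear-zone eligibility from the annotation alone; (2) activity
#' in the control sample; (3) overall-increase exclusion; (4) downstream zones
#' truncated by a chromosome end to fewer than `min_windows_above` windows
#' are excluded as undecidable; (5) windowed fold-change call. Per-gene
#' exclusion reasons are recorded.
#'
#' @param test_track,control_track matched [coverage_track]s.
#' @param annotation a [genome_annotation].
#' @param params a [caller_params].
#' @param sample_id,control_id sample labels carried into the result.
#' @return object of class `readthrough_profile`: list with `sample_id`,
#'   `control_id`, `calls` (data.frame, one row per annotated gene),
#'   `n_readthrough_genes`, `params`.
#' @export
profile_sample <- function(test_track, control_track, annotation,
                           params = caller_params(),
                           sample_id = "test", control_id = "control") {
  if (is.null(control_track)) stop("control track is required")
  genes <- annotation$genes
  expr_ctrl <- vapply(genes, function(g) gene_body_expression(control_track, g), 0)
  active <- active_gene_filter(expr_ctrl, params$active_percentile)
  eligible <- eligible_readthrough_genes(annotation, params$clear_zone_bp)

  calls <- lapply(names(genes), function(id) {
    g <- genes[[id]]
    if (!id %in% eligible)
      return(excluded_call(id, "neighbor_within_clear_zone"))
    if (!id %in% active)
      return(excluded_call(id, "inactive"))
    expr_test <- gene_body_expression(test_track, g)
    if (overall_increase_filter(expr_test, expr_ctrl[[id]], params))
      return(excluded_call(id, "overall_increase"))
    cs <- annotation$chrom_sizes[[g$chrom]]
    t_wv <- window_vector(test_track, g, params$downstream_span_bp,
                          params$window_bp, cs)
    if (t_wv$n_windows < params$min_windows_above)
      return(excluded_call(id, "truncated_zone"))
    c_wv <- window_vector(control_track, g, params$downstream_span_bp,
                          params$window_bp, cs)
    call_gene_readthrough(t_wv, c_wv, params)
  })
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  structure(list(sample_id = sample_id, control_id = control_id,
                 calls = calls, n_readthrough_genes = sum(calls$called),
                 params = params),
            class = "readthrough_profile")
}

#' @export
print.readthrough_profile <- function(x, ...) {
  excl <- table(x$calls$excluded_reason, useNA = "no")
  cat(sprintf("<readthrough_profile> %s vs %s: %d/%d genes with read-through\n",
              x$sample_id, x$control_id, x$n_readthrough_genes, nrow(x$calls)))
  if (length(excl))
    cat("  excluded:", paste(names(excl), excl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.readthrough_profile <- function(object, ...) {
  called <- object$calls[which(object$calls$called), ]
  out <- list(sample_id = object$sample_id,
              n_genes = nrow(object$calls),
              n_readthrough = object$n_readthrough_genes,
              mean_length_bp = mean(called$readthrough_length_bp),
              exclusions = table(object$calls$excluded_reason, useNA = "no"))
  class(out) <- "summary.readthrough_profile"
  out
}

#' @export
print.summary.readthrough_profile <- function(x, ...) {
  cat(sprintf("Sample %s: %d of %d genes called (mean read-through %.0f bp)\n",
              x$sample_id, x$n_readthrough, x$n_genes,
              if (x$n_readthrough) x$mean_length_bp else 0))
  if (length(x$exclusions))
    cat("  exclusions:", paste(names(x$exclusions), x$exclusions, sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Write per-gene read-through calls as TSV
#'
#' @param profile a `readthrough_profile`.
#' @param path output file.
#' @export
write_calls_tsv <- function(profile, path) {
  utils::write.table(profile$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
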