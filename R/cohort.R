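#' Stratify a cohort by read-through burden
#'
#' A sample is "high read-through" when it has more than `cutoff_genes`
#' genes with read-through, "low" otherwise (a sample at exactly the cutoff
#' is low).
#'
#' @param counts named numeric vector, sample_id -> number of read-through
#'   genes (e.g. `n_readthrough_genes` from [profile_sample]).
#' @param cutoff_genes stratification cutoff (default 200).
#' @return data.frame with `sample_id`, `n_readthrough_genes`, `stratum`.
#' @export
stratify_by_readthrough <- function(counts, cutoff_genes = 200) {
  data.frame(sample_id = names(counts) %||% character(0),
             n_readthrough_genes = as.numeric(counts),
             stratum = ifelse(counts > cutoff_genes, "high", "low"),
             row.names = NULL)
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param time non-negative follow-up times (days).
#' @param event 0/1 (or logical) event indicator; 0 = censored.
#' @return object of class `km_curve`: data.frame with `time` (distinct
#'   event/censoring times), `n_risk`, `n_event`, `surv` (the product-limit
#'   estimate S(t)).
#' @export
kaplan_meier <- function(time, event) {
  if (any(time < 0)) stop("negative survival times")
  stopifnot(length(time) == length(event), length(time) >= 1)
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of survival between two groups: observed vs
#' expected events at each distinct event time under the hypergeometric
#' model, chi-square with 1 df.
#'
#' @param time,event survival times and 0/1 event indicators.
#' @param group two-level grouping vector (e.g. `"high"`/`"low"`).
#' @return list with `chisq`, `p`, `n`, and `flagged` (TRUE when the test is
#'   undefined: no events, or fewer than two groups).
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (length(unique(group)) != 2 || sum(event) == 0)
    return(list(chisq = NA_real_, p = NA_real_, n = length(time),
                flagged = TRUE))
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = length(time), flagged = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `p` (two-sided), `flagged` (TRUE when a zero margin
#'   makes the table degenerate; p = 1 by convention).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, flagged = TRUE))
  list(p = stats::fisher.test(tab)$p.value, flagged = FALSE)
}

#' Student's t-test for metagene region comparisons
#'
#' Paired by default: tumor vs matched-normal region means over the same
#' gene set.
#'
#' @param test_values,control_values numeric vectors (equal length when
#'   paired).
#' @param paired paired test (default TRUE).
#' @return list with `t`, `p`, `n`, `flagged` (TRUE when the test is
#'   undefined, e.g. zero variance of the paired differences).
#' @export
region_ttest <- function(test_values, control_values, paired = TRUE) {
  n <- length(test_values)
  stopifnot(n >= 2, !paired || length(control_values) == n)
  res <- tryCatch(stats::t.test(test_values, control_values, paired = paired),
                  error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic))
    return(list(t = NA_real_, p = NA_real_, n = n, flagged = TRUE))
  list(t = unname(res$statistic), p = res$p.value, n = n, flagged = FALSE)
}

#' Read a survival table
#'
#' @param path TSV with columns sample_id, time_days, event.
#' @return data.frame.
#' @export
read_survival_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "event")
  if (!all(need %in% names(tab)))
    stop("survival file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  tab[need]
}
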