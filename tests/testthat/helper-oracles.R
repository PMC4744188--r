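# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most literal definition of each quantity and
# share no code with the package internals.

# interval union by per-base rasterization (0-based half-open input/output)
oracle_interval_union <- function(intervals) {
  hi <- max(intervals[, 2])
  hit <- logical(hi)
  for (i in seq_len(nrow(intervals)))
    hit[(intervals[i, 1] + 1):intervals[i, 2]] <- TRUE
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

# per-base window sums over an oriented interval
oracle_window_counts <- function(v, start, end, strand, width) {
  n_win <- (end - start) %/% width
  if (n_win == 0) return(numeric(0))
  bases <- if (strand == "+") (start + 1):end else rev((start + 1):end)
  vapply(seq_len(n_win), function(i)
    sum(v[bases[((i - 1) * width + 1):(i * width)]]), 0)
}

# literal per-base metagene: flank 100-bp window means and 60 body bins with
# the remainder in the last bin, in RPKM, minus strand mirrored
oracle_metagene <- function(v, start, end, strand, total,
                            flank_bp = 4000, w = 100, bins = 60) {
  to_rpkm <- function(s, len) s / (len / 1000) / (total / 1e6)
  win_means <- function(a) vapply(seq_len(flank_bp / w), function(k)
    to_rpkm(sum(v[(a + (k - 1) * w + 1):(a + k * w)]), w), 0)
  len <- end - start
  bw <- len %/% bins
  widths <- c(rep(bw, bins - 1), len - bw * (bins - 1))
  off <- cumsum(c(0, widths[-bins]))
  body <- vapply(seq_len(bins), function(j)
    to_rpkm(sum(v[(start + off[j] + 1):(start + off[j] + widths[j])]),
            widths[j]), 0)
  if (strand == "+") {
    list(up = win_means(start - flank_bp), body = body, down = win_means(end))
  } else {
    list(up = rev(win_means(end)), body = rev(body),
         down = rev(win_means(start - flank_bp)))
  }
}

# BH step-up, written independently of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# two-sided Fisher exact p by hypergeometric enumeration (same relative
# tolerance convention as the textbook definition implemented in R)
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kaplan-Meier product-limit by explicit risk-set enumeration
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_i <- sum(time >= tt[i])
    d_i <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# maximal run of TRUE starting at the first TRUE (scan, no vector tricks)
oracle_first_run <- function(pass) {
  i <- 1
  while (i <= length(pass) && !pass[i]) i <- i + 1
  if (i > length(pass)) return(0)
  n <- 0
  while (i + n <= length(pass) && pass[i + n]) n <- n + 1
  n
}

# exhaustive nearest same-strand downstream neighbour search
oracle_tandem <- function(tab) {
  out <- list()
  for (i in seq_len(nrow(tab))) {
    best <- NULL; best_gap <- Inf
    for (j in seq_len(nrow(tab))) {
      if (j == i || tab$chrom[j] != tab$chrom[i] ||
          tab$strand[j] != tab$strand[i]) next
      gap <- if (tab$strand[i] == "+") tab$tss[j] - tab$tts[i]
             else tab$tts[i] - tab$tss[j]
      if (gap >= 0 && gap < best_gap) { best <- j; best_gap <- gap }
    }
    if (!is.null(best))
      out[[length(out) + 1]] <- data.frame(upstream_id = tab$gene_id[i],
                                           downstream_id = tab$gene_id[best],
                                           gap_bp = best_gap)
  }
  if (length(out)) do.call(rbind, out) else NULL
}
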