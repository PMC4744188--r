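test_that("active gene filter uses the linear-interpolation percentile, strictly above", {
  x <- c(a = 0, b = 1, c = 2, d = 3)
  expect_equal(stats::quantile(x, 0.25, names = FALSE), 0.75)
  expect_setequal(active_gene_filter(x, 25), c("b", "c", "d"))
  # all equal -> none strictly above
  expect_length(active_gene_filter(c(a = 2, b = 2, c = 2), 25), 0)
  # percentile 0 -> everything above the minimum
  expect_setequal(active_gene_filter(x, 0), c("b", "c", "d"))
})

test_that("the calling rule is 'more than six windows at fc >= 1.5'", {
  ctrl <- wv(rep(1, 40))
  up7 <- rep(1, 40); up7[1:7] <- 2
  call7 <- call_gene_readthrough(wv(up7), ctrl, caller_params(pseudocount = 0))
  expect_true(call7$called)
  expect_equal(call7$n_windows_above, 7)

  up6 <- rep(1, 40); up6[1:6] <- 5
  call6 <- call_gene_readthrough(wv(up6), ctrl, caller_params(pseudocount = 0))
  expect_false(call6$called)
  expect_equal(call6$n_windows_above, 6)

  # fc exactly 1.5 is inclusive
  at15 <- rep(1, 40); at15[1:10] <- 1.5
  expect_true(call_gene_readthrough(wv(at15), ctrl,
                                    caller_params(pseudocount = 0))$called)

  # identical vectors -> no call
  id <- call_gene_readthrough(ctrl, ctrl, caller_params())
  expect_false(id$called)
  expect_equal(id$n_windows_above, 0)
})

test_that("read-through length is the contiguous run from the first passing window", {
  p <- caller_params(pseudocount = 0)
  fc <- rep(1, 40); fc[1:20] <- 2
  expect_equal(readthrough_length(fc, p), 2000)
  expect_equal(readthrough_length(rep(1, 40), p), 0)
  # run not starting at window 1
  fc2 <- rep(1, 40); fc2[5:10] <- 2; fc2[15:30] <- 2
  expect_equal(readthrough_length(fc2, p), 600)
  # distal rule option
  pd <- caller_params(length_rule = "distal")
  expect_equal(readthrough_length(fc2, pd), 3000)
})

test_that("read-through length equals the run-scan oracle on random vectors", {
  set.seed(301)
  p <- caller_params()
  for (rep in 1:200) {
    fc <- runif(40, 0.5, 3)
    expect_equal(readthrough_length(fc, p),
                 100 * oracle_first_run(fc >= p$fc_threshold))
  }
})

test_that("overall-increase filter excludes at and above the threshold", {
  p <- caller_params(pseudocount = 0)
  expect_true(overall_increase_filter(2, 1, p))    # fc 2.0
  expect_false(overall_increase_filter(1, 1, p))   # fc 1.0
  expect_true(overall_increase_filter(1.5, 1, p))  # boundary, >= convention
})

test_that("a control compared with itself yields zero calls", {
  cfg <- sim_config(n_genes = 40)
  ann <- simulate_annotation(cfg, seed = 5)
  sp <- simulate_sample_pair(ann, cfg, seed = 5)
  prof <- profile_sample(sp$control, sp$control, ann)
  expect_equal(prof$n_readthrough_genes, 0)
})

test_that("planted strong read-through genes are recovered exactly, and order does not matter", {
  cfg <- sim_config(n_genes = 60)
  ann <- simulate_annotation(cfg, seed = 6)
  sp <- simulate_sample_pair(ann, cfg, seed = 6)
  prof <- profile_sample(sp$test, sp$control, ann)
  called <- prof$calls$gene_id[prof$calls$called]
  expect_setequal(called, sp$truth$readthrough$gene_id)

  # shuffled gene order in the annotation leaves the call set unchanged
  set.seed(1)
  ann_shuf <- genome_annotation(sample(ann$genes), ann$chrom_sizes)
  prof2 <- profile_sample(sp$test, sp$control, ann_shuf)
  expect_setequal(prof2$calls$gene_id[prof2$calls$called], called)
})

test_that("exclusion reasons are recorded and calls imply no exclusion", {
  cfg <- sim_config(n_genes = 60)
  ann <- simulate_annotation(cfg, seed = 6)
  sp <- simulate_sample_pair(ann, cfg, seed = 6)
  prof <- profile_sample(sp$test, sp$control, ann)
  expect_true(all(is.na(prof$calls$excluded_reason[prof$calls$called])))
  expect_true(all(prof$calls$n_windows_above[prof$calls$called] >= 7))
  expect_in(stats::na.omit(prof$calls$excluded_reason),
            c("inactive", "neighbor_within_clear_zone", "overall_increase",
              "truncated_zone"))
  expect_equal(prof$n_readthrough_genes, sum(prof$calls$called))
})

test_that("raising thresholds never adds a called gene (monotonicity)", {
  cfg <- sim_config(n_genes = 50)
  ann <- simulate_annotation(cfg, seed = 7)
  sp <- simulate_sample_pair(ann, cfg, seed = 7)
  base <- profile_sample(sp$test, sp$control, ann, caller_params())
  stricter_fc <- profile_sample(sp$test, sp$control, ann,
                                caller_params(fc_threshold = 2))
  stricter_nw <- profile_sample(sp$test, sp$control, ann,
                                caller_params(min_windows_above = 15))
  called <- function(p) p$calls$gene_id[p$calls$called]
  expect_true(all(called(stricter_fc) %in% called(base)))
  expect_true(all(called(stricter_nw) %in% called(base)))
})

test_that("the caller is invariant to a common scaling of coverage and totals", {
  cfg <- sim_config(n_genes = 40)
  ann <- simulate_annotation(cfg, seed = 8)
  sp <- simulate_sample_pair(ann, cfg, seed = 8)
  scale_track <- function(tr, k) {
    coverage_track(lapply(tr$cov, function(ch) lapply(ch, function(v) v * k)),
                   tr$total_mapped_reads * k)
  }
  p1 <- profile_sample(sp$test, sp$control, ann)
  p2 <- profile_sample(scale_track(sp$test, 3), scale_track(sp$control, 3), ann)
  expect_equal(p1$calls$called, p2$calls$called)
  expect_equal(p1$calls$n_windows_above, p2$calls$n_windows_above)
})

test_that("genes with a truncated downstream zone are excluded as undecidable", {
  # '+' gene ending 300 bp before the chromosome end: only 3 windows fit
  ann <- genome_annotation(list(
    gene_model("edge", "chr1", "+", rbind(c(20000, 29700))),
    gene_model("low", "chr1", "+", rbind(c(1000, 3000)))
  ), c(chr1 = 30000))
  v <- numeric(30000); v[20001:29700] <- 5  # only 'edge' expressed
  tr <- track1(v, total = 1e5)
  prof <- suppressWarnings(profile_sample(tr, tr, ann))
  calls <- prof$calls
  expect_equal(calls$excluded_reason[calls$gene_id == "edge"], "truncated_zone")
  expect_equal(calls$excluded_reason[calls$gene_id == "low"], "inactive")
})

test_that("missing control is rejected", {
  ann <- tiny_annotation()
  tr <- track1(rep(1, 40000))
  expect_error(profile_sample(tr, NULL, ann), "control")
})
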