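test_that("simulated annotations are deterministic and well formed", {
  cfg <- sim_config(n_genes = 50)
  a1 <- simulate_annotation(cfg, seed = 12)
  a2 <- simulate_annotation(cfg, seed = 12)
  expect_identical(a1, a2)
  expect_length(a1$genes, 50)
  # genes non-overlapping per chromosome, exon counts within range
  tabs <- split(annotation_table <- data.frame(
    chrom = vapply(a1$genes, `[[`, "", "chrom"),
    start = vapply(a1$genes, `[[`, 0, "start"),
    end = vapply(a1$genes, `[[`, 0, "end")), annotation_table$chrom)
  for (tb in tabs) {
    tb <- tb[order(tb$start), ]
    expect_true(all(tb$start[-1] >= tb$end[-nrow(tb)]))
  }
  n_ex <- vapply(a1$genes, function(g) nrow(g$exons), 0)
  expect_true(all(n_ex >= 2 & n_ex <= 10))
  # GTF output is byte-identical across runs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotation_gtf(a1, f1)
  write_annotation_gtf(simulate_annotation(cfg, seed = 12), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an explicit chromosome length too small for the genes is rejected", {
  cfg <- sim_config(n_genes = 50, chrom_len_bp = 20000)
  expect_error(simulate_annotation(cfg, seed = 1), "infeasible")
})

test_that("requested short-gap fraction is approximately realized", {
  cfg <- sim_config(n_genes = 400, short_gap_fraction = 0.3)
  ann <- simulate_annotation(cfg, seed = 13)
  tab <- data.frame(
    chrom = vapply(ann$genes, `[[`, "", "chrom"),
    start = vapply(ann$genes, `[[`, 0, "start"),
    end = vapply(ann$genes, `[[`, 0, "end"))
  gaps <- unlist(lapply(split(tab, tab$chrom), function(tb) {
    tb <- tb[order(tb$start), ]
    tb$start[-1] - tb$end[-nrow(tb)]
  }))
  expect_equal(mean(gaps < 5000), 0.3, tolerance = 0.07)
})

test_that("planted tails follow the configured exponential decay", {
  cfg <- sim_config(n_genes = 40)
  ann <- simulate_annotation(cfg, seed = 14)
  sp <- simulate_sample_pair(ann, cfg, seed = 14)
  rt <- sp$truth$readthrough
  inv_up <- sp$truth$invaded$upstream_id
  plain <- rt[!(rt$gene_id %in% inv_up) & rt$tail_len_bp >= 3000, ]
  skip_if(nrow(plain) == 0, "no non-invading planted tail drawn at this seed")
  g <- ann$genes[[plain$gene_id[1]]]
  d <- plain$depth[1]
  iv <- downstream_interval(g, 3000)
  mean_obs <- window_counts(sp$test, iv, 100) / 100
  x <- (seq_len(30) - 0.5) * 100
  mean_exp <- cfg$background_depth + cfg$rho * d * exp(-x / cfg$decay_bp)
  # Poisson noise around the planted mean: relative error modest at depth>=30
  expect_equal(mean_obs, mean_exp, tolerance = 0.2)
  # analytic guarantee used by the caller: fc >= 1.5 in the first 10 windows
  ctrl_obs <- window_counts(sp$control, iv, 100) / 100
  expect_true(all((mean_obs[1:10] / pmax(ctrl_obs[1:10], 1e-6)) >= 1.5))
})

test_that("gene-body means are preserved for planted genes", {
  cfg <- sim_config(n_genes = 40)
  ann <- simulate_annotation(cfg, seed = 15)
  sp <- simulate_sample_pair(ann, cfg, seed = 15)
  for (id in sp$truth$readthrough$gene_id) {
    g <- ann$genes[[id]]
    fc <- gene_body_expression(sp$test, g) / gene_body_expression(sp$control, g)
    expect_equal(fc, 1, tolerance = 0.15)
  }
})

test_that("planted chimeras appear in the junction file with exact support", {
  cfg <- sim_config(n_genes = 60, readthrough_fraction = 0.8,
                    invasion_fraction_of_rt = 1, lambda_chim = 3)
  ann <- simulate_annotation(cfg, seed = 16)
  sp <- simulate_sample_pair(ann, cfg, seed = 16, sample_id = "SX")
  ch <- sp$truth$chimeras
  skip_if(nrow(ch) == 0, "no chimera drawn at this seed")
  for (k in seq_len(nrow(ch))) {
    up <- ann$genes[[ch$upstream_id[k]]]
    dn <- ann$genes[[ch$downstream_id[k]]]
    dpos <- rtscan:::exon_donor_pos(up, ch$donor_exon_rank_from_end[k])
    apos <- rtscan:::exon_acceptor_pos(dn, ch$acceptor_exon_rank[k])
    n_lines <- sum(sp$junctions$donor_pos == dpos &
                     sp$junctions$acceptor_pos == apos)
    expect_equal(n_lines, ch$n_reads[k])
  }
})

test_that("declared total mapped reads matches emitted coverage", {
  cfg <- sim_config(n_genes = 30)
  ann <- simulate_annotation(cfg, seed = 17)
  sp <- simulate_sample_pair(ann, cfg, seed = 17)
  depth_bases <- sum(vapply(sp$control$cov, function(ch)
    sum(vapply(ch, function(v) sum(as.numeric(v)), 0)), 0))
  expect_equal(sp$control$total_mapped_reads,
               round(depth_bases / cfg$read_len_bp))
})

test_that("a zero read-through fraction yields a quiet caller", {
  cfg <- sim_config(n_genes = 80, readthrough_fraction = 0)
  ann <- simulate_annotation(cfg, seed = 18)
  sp <- simulate_sample_pair(ann, cfg, seed = 18)
  prof <- profile_sample(sp$test, sp$control, ann)
  expect_equal(sp$truth$n_true_readthrough, 0)
  expect_lt(prof$n_readthrough_genes / length(ann$genes), 0.01)
})

test_that("cohort simulation is deterministic and burden-linked", {
  cfg <- sim_config(n_genes = 40, survival_cutoff = 5)
  ann <- simulate_annotation(cfg, seed = 19)
  c1 <- simulate_cohort(ann, cfg, n_samples = 3, seed = 19)
  c2 <- simulate_cohort(ann, cfg, n_samples = 3, seed = 19)
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$sample_sheet, c2$sample_sheet)
  expect_equal(c1$sample_sheet$true_burden,
               vapply(c1$truth$per_sample, `[[`, 0, "n_true_readthrough"),
               ignore_attr = TRUE)
  expect_equal(c1$truth$true_stratum,
               ifelse(c1$sample_sheet$true_burden > 5, "high", "low"),
               ignore_attr = TRUE)
})

test_that("caller-estimated burden tracks planted burden across a cohort", {
  cfg <- sim_config(n_genes = 100, survival_cutoff = 10)
  ann <- simulate_annotation(cfg, seed = 20)
  coh <- simulate_cohort(ann, cfg, n_samples = 5, seed = 20)
  est <- vapply(names(coh$samples), function(sid) {
    sp <- coh$samples[[sid]]
    profile_sample(sp$test, sp$control, ann)$n_readthrough_genes
  }, 0)
  truth <- coh$sample_sheet$true_burden
  expect_gte(cor(est, truth), 0.95)
})
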