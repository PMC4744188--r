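test_that("merge_transcripts unions exons and spans transcripts", {
  # idempotent on identical single-exon transcripts
  g <- merge_transcripts("g", "chr1", "+",
                         list(rbind(c(10, 110)), rbind(c(10, 110))))
  expect_equal(unname(g$exons), unname(cbind(10, 110)))

  # overlapping exons collapse
  g <- merge_transcripts("g", "chr1", "+", list(rbind(c(0, 100), c(50, 200))))
  expect_equal(unname(g$exons), unname(cbind(0, 200)))
  expect_equal(g$start, 0)
  expect_equal(g$end, 200)
})

test_that("merge_transcripts equals the per-base union oracle on random input", {
  set.seed(11)
  for (rep in 1:120) {
    txs <- lapply(1:3, function(i) {
      st <- sort(sample(1:500, 5))
      cbind(st, st + sample(5:80, 5, replace = TRUE))
    })
    g <- merge_transcripts("g", "chr1", "+", txs)
    expect_equal(unname(g$exons),
                 unname(oracle_interval_union(do.call(rbind, txs))))
  }
})

test_that("gene model invariants: tss/tts follow strand, exons disjoint", {
  gp <- gene_model("p", "chr1", "+", rbind(c(100, 200), c(300, 400)))
  expect_equal(gp$tss, 100)
  expect_equal(gp$tts, 400)
  gm <- gene_model("m", "chr1", "-", rbind(c(100, 200), c(300, 400)))
  expect_equal(gm$tss, 400)
  expect_equal(gm$tts, 100)
  expect_error(gene_model("bad", "chr1", "*", rbind(c(0, 10))), "strand")
  expect_error(gene_model("bad", "chr1", "+", rbind(c(10, 10))), "exon")
})

test_that("downstream_interval is strand-oriented and clips at bounds", {
  gp <- gene_model("p", "chr1", "+", rbind(c(100, 500)))
  iv <- downstream_interval(gp, 4000)
  expect_equal(c(iv$start, iv$end), c(500, 4500))
  expect_false(iv$truncated)

  gm <- gene_model("m", "chr1", "-", rbind(c(6000, 10000)))
  iv <- downstream_interval(gm, 4000)
  expect_equal(c(iv$start, iv$end), c(2000, 6000))

  gm2 <- gene_model("m2", "chr1", "-", rbind(c(1000, 2000)))
  iv <- downstream_interval(gm2, 4000)
  expect_equal(c(iv$start, iv$end), c(0, 1000))
  expect_true(iv$truncated)

  gp2 <- gene_model("p2", "chr1", "+", rbind(c(100, 500)))
  iv <- downstream_interval(gp2, 4000, chrom_size = 3000)
  expect_equal(iv$end, 3000)
  expect_true(iv$truncated)
})

test_that("clear-zone filter excludes neighbors within 5 Kb, either strand", {
  # neighbor starting 4900 bp downstream of TTS -> excluded
  ann <- genome_annotation(list(
    gene_model("up", "chr1", "+", rbind(c(1000, 5000))),
    gene_model("near", "chr1", "-", rbind(c(9900, 12000)))
  ), c(chr1 = 50000))
  expect_false("up" %in% eligible_readthrough_genes(ann))

  # neighbor starting 5100 bp downstream -> retained
  ann <- genome_annotation(list(
    gene_model("up", "chr1", "+", rbind(c(1000, 5000))),
    gene_model("far", "chr1", "-", rbind(c(10100, 12000)))
  ), c(chr1 = 50000))
  expect_true("up" %in% eligible_readthrough_genes(ann))

  # isolated gene retained even with a truncated zone
  ann1 <- genome_annotation(list(gene_model("solo", "chr1", "+",
                                            rbind(c(100, 900)))),
                            c(chr1 = 2000))
  expect_equal(eligible_readthrough_genes(ann1), "solo")
})

test_that("overlapping genes are ineligible and never form tandem pairs", {
  ann <- genome_annotation(list(
    gene_model("outer", "chr1", "+", rbind(c(1000, 20000))),
    gene_model("inner", "chr1", "+", rbind(c(5000, 8000)))
  ), c(chr1 = 50000))
  expect_length(eligible_readthrough_genes(ann), 0)
  expect_equal(nrow(build_tandem_pairs(ann)), 0)
})

test_that("clear-zone filter is monotone in the zone width", {
  set.seed(21)
  for (rep in 1:20) {
    ann <- random_annotation(12)
    wide <- eligible_readthrough_genes(ann, 5000)
    narrow <- eligible_readthrough_genes(ann, 2000)
    expect_true(all(wide %in% narrow))
  }
})

test_that("tandem pairs: construction, strand policy, oracle equivalence", {
  ann <- genome_annotation(list(
    gene_model("A", "chr1", "+", rbind(c(0, 1000))),
    gene_model("B", "chr1", "+", rbind(c(3000, 5000)))
  ), c(chr1 = 10000))
  pr <- build_tandem_pairs(ann)
  expect_equal(pr$upstream_id, c("A"))
  expect_equal(pr$downstream_id, c("B"))
  expect_equal(pr$gap_bp, 2000)

  # opposite strands only -> no pair
  ann2 <- genome_annotation(list(
    gene_model("A", "chr1", "+", rbind(c(0, 1000))),
    gene_model("B", "chr1", "-", rbind(c(3000, 5000)))
  ), c(chr1 = 10000))
  expect_equal(nrow(build_tandem_pairs(ann2)), 0)

  # 20 random genes vs exhaustive all-pairs search
  set.seed(31)
  for (rep in 1:10) {
    ann3 <- random_annotation(20)
    got <- build_tandem_pairs(ann3)
    tab <- data.frame(
      gene_id = names(ann3$genes),
      chrom = vapply(ann3$genes, `[[`, "", "chrom"),
      strand = vapply(ann3$genes, `[[`, "", "strand"),
      tss = vapply(ann3$genes, `[[`, 0, "tss"),
      tts = vapply(ann3$genes, `[[`, 0, "tts"), row.names = NULL)
    want <- oracle_tandem(tab)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      o1 <- got[order(got$upstream_id), c("upstream_id", "downstream_id", "gap_bp")]
      o2 <- want[order(want$upstream_id), ]
      rownames(o1) <- rownames(o2) <- NULL
      expect_equal(o1, o2)
    }
  }
})

test_that("tandem intergenic interval is disjoint from both gene bodies", {
  set.seed(41)
  for (rep in 1:10) {
    ann <- random_annotation(15)
    pr <- build_tandem_pairs(ann)
    for (i in seq_len(nrow(pr))) {
      up <- ann$genes[[pr$upstream_id[i]]]
      dn <- ann$genes[[pr$downstream_id[i]]]
      for (g in list(up, dn)) {
        overlap <- min(pr$intergenic_end[i], g$end) -
          max(pr$intergenic_start[i], g$start)
        expect_lte(overlap, 0)
      }
    }
  }
})

test_that("GTF and BED12 round-trips preserve gene models", {
  ann <- tiny_annotation()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(ann, gtf)
  back <- read_annotation_gtf(gtf, ann$chrom_sizes)
  for (id in names(ann$genes)) {
    expect_equal(unname(back$genes[[id]]$exons), unname(ann$genes[[id]]$exons))
    expect_equal(back$genes[[id]]$strand, ann$genes[[id]]$strand)
    expect_equal(back$genes[[id]]$tts, ann$genes[[id]]$tts)
  }
  bed <- withr::local_tempfile(fileext = ".bed")
  write_annotation_bed12(ann, bed)
  back2 <- read_annotation_bed12(bed, ann$chrom_sizes)
  for (id in names(ann$genes))
    expect_equal(unname(back2$genes[[id]]$exons), unname(ann$genes[[id]]$exons))
})

test_that("duplicate gene ids and out-of-bounds genes are rejected", {
  g <- gene_model("dup", "chr1", "+", rbind(c(0, 100)))
  expect_error(genome_annotation(list(g, g)), "duplicate")
  far <- gene_model("far", "chr1", "+", rbind(c(500, 900)))
  expect_error(genome_annotation(list(far), c(chr1 = 800)), "bounds")
})
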