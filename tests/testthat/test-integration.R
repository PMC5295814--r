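cons_df <- function(pos, direction = "left", chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
             stage = "wk8", direction = direction, mean_abs_diff = 40,
             n_samples_support = 2L, stringsAsFactors = FALSE)
}

gene_df <- function(gene_id, start, end, strand = "+", chrom = "chr1") {
  data.frame(gene_id = gene_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, stringsAsFactors = FALSE)
}

test_that("CpG-to-gene assignment uses a strand-aware upstream window", {
  g_plus <- gene_df("gp", 1000, 2000, "+")
  g_minus <- gene_df("gm", 1000, 2000, "-")

  # 0-based 999 (1-based 1000) sits in the +-strand upstream window
  expect_equal(assign_cpgs_to_genes(cons_df(999 + 1), g_plus)$gene_id, "gp")
  # half-open end: 0-based 2000 is outside a +-strand gene, no downstream window
  expect_equal(nrow(assign_cpgs_to_genes(cons_df(2000 + 1), g_plus)), 0)
  # upstream of a --strand gene is to the right of its end
  expect_equal(assign_cpgs_to_genes(cons_df(2100 + 1), g_minus)$gene_id, "gm")
  expect_equal(nrow(assign_cpgs_to_genes(cons_df(999 + 1), g_minus)), 0)
  # ignore_strand reproduces the naive left-of-start window on both strands
  cfg <- threshold_config(ignore_strand = TRUE)
  expect_equal(assign_cpgs_to_genes(cons_df(999 + 1), g_minus, cfg)$gene_id,
               "gm")
  expect_equal(nrow(assign_cpgs_to_genes(cons_df(2100 + 1), g_minus, cfg)), 0)
  # chromosomes must match
  expect_equal(nrow(assign_cpgs_to_genes(cons_df(1500, chrom = "chr2"),
                                         g_plus)), 0)
  # a CpG may land in several overlapping gene windows
  both <- rbind(g_plus, gene_df("gp2", 1400, 3000, "+"))
  expect_setequal(assign_cpgs_to_genes(cons_df(1500 + 1), both)$gene_id,
                  c("gp", "gp2"))
})

test_that("assignment agrees with a naive interval scan on random layouts", {
  set.seed(43)
  n_genes <- 150
  start <- sort(sample(0:200000, n_genes))
  genes <- gene_df(sprintf("g%03d", seq_len(n_genes)), start,
                   start + sample(500:5000, n_genes, TRUE),
                   sample(c("+", "-"), n_genes, TRUE))
  cons <- cons_df(sort(sample(1:210000, 2000)),
                  sample(c("left", "right"), 2000, TRUE))
  for (ignore in c(FALSE, TRUE)) {
    cfg <- threshold_config(ignore_strand = ignore)
    got <- assign_cpgs_to_genes(cons, genes, cfg)
    got <- got[order(got$gene_id, got$pos), ]
    want <- oracle_assign(cons, genes, 1500, ignore)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$pos, want$pos)
  }
})

test_that("laterality quotient follows (right-left)/(right+left)*100", {
  expect_equal(methylation_lq(2, 2), 0)
  expect_equal(methylation_lq(1, 3), 50)
  expect_equal(methylation_lq(5, 0), -100)
  expect_true(is.na(methylation_lq(0, 0)))
  expect_error(methylation_lq(-1, 2), class = "value_error")
  # bounded and antisymmetric over random counts
  set.seed(47)
  nl <- rpois(200, 4); nr <- rpois(200, 4)
  lq <- methylation_lq(nl, nr)
  ok <- !is.na(lq)
  expect_true(all(lq[ok] >= -100 & lq[ok] <= 100))
  expect_equal(methylation_lq(nr, nl)[ok], -lq[ok])
})

test_that("per-gene profiles count assigned consensus CpGs by direction", {
  genes <- gene_df(c("gA", "gB"), c(1000, 10000), c(2000, 12000))
  cons <- rbind(cons_df(c(1100, 1200, 1300), "left"),
                cons_df(1500, "right"),
                cons_df(10500, "right"))
  prof <- gene_methylation_profile(cons, genes)
  expect_equal(prof$n_cpg_hyper_left, c(3L, 0L))
  expect_equal(prof$n_cpg_hyper_right, c(1L, 1L))
  expect_equal(prof$lq, c(-50, 100))
})

test_that("gene classification matches the exhaustive rule table", {
  # spot checks forced by the opposite-direction rule
  expect_equal(classify_gene("right", -60, FALSE), "methylation_only")
  expect_equal(classify_gene("right", -60, TRUE), "both")
  expect_equal(classify_gene("right", 60, FALSE), "unexplained")
  expect_equal(classify_gene("left", 60, FALSE), "methylation_only")
  expect_equal(classify_gene("right", NA, TRUE), "mirna_only")
  # exact threshold is not "strongly asymmetric" (strict inequality)
  expect_equal(classify_gene("right", -25, FALSE), "unexplained")
  expect_equal(classify_gene("left", 25, FALSE), "unexplained")

  # full direction x LQ-sign x target grid against the rule-table oracle
  for (dir in c("left", "right")) {
    for (lq in c(NA, -100, -60, -25, 0, 25, 60, 100)) {
      for (tg in c(TRUE, FALSE)) {
        expect_equal(classify_gene(dir, lq, tg), oracle_classify(dir, lq, tg),
                     label = sprintf("dir=%s lq=%s target=%s", dir, lq, tg))
      }
    }
  }
})

test_that("partition summaries report half-up integer percentages", {
  s <- partition_summary(c(methylation_only = 451, both = 18, mirna_only = 47),
                         1690)
  expect_equal(unname(s$counts["unexplained"]), 1690L - 451L - 18L - 47L)
  expect_equal(unname(s$pct), c(27, 1, 3, 69))

  s10 <- partition_summary(c(mirna_only = 6, methylation_only = 2, both = 0),
                           24)
  expect_equal(unname(s10$pct), c(8, 0, 25, 67))

  s0 <- partition_summary(c(methylation_only = 0, both = 0, mirna_only = 0),
                          50)
  expect_equal(unname(s0$pct), c(0, 0, 0, 100))

  expect_error(partition_summary(c(methylation_only = 1), 0),
               class = "empty_summary_error")
  df <- data.frame(category = c("both", "unexplained"))
  expect_error(partition_summary(df, 5), class = "value_error")
  expect_equal(unname(partition_summary(df, 2)$counts), c(0L, 1L, 0L, 1L))
})
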