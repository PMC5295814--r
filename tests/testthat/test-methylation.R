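cpg_rows <- function(pos, ml, cl, mr, cr, sample = "s1", stage = "wk8",
                     chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
             sample_id = sample, stage = stage,
             side = rep(c("left", "right"), each = length(pos)),
             coverage = as.integer(c(cl, cr)),
             methylated = as.integer(c(ml, mr)), stringsAsFactors = FALSE)
}

test_that("fisher_cpg matches enumeration oracle values and conventions", {
  expect_equal(fisher_cpg(5, 5, 5, 5), 1)
  # frozen from the margin-enumeration oracle (margins 10/10/10/10)
  expect_equal(fisher_cpg(9, 1, 1, 9), 0.00109333391067137, tolerance = 1e-12)
  expect_lt(fisher_cpg(9, 1, 1, 9), 0.01)
  # the most extreme table attains the minimum two-sided p for its margins
  expect_equal(fisher_cpg(0, 10, 10, 0), 1.0825088224469e-05,
               tolerance = 1e-9)
  ps <- vapply(0:10, function(a) fisher_cpg(a, 10 - a, 10 - a, a), numeric(1))
  expect_equal(min(ps), fisher_cpg(0, 10, 10, 0))

  expect_error(fisher_cpg(0, 0, 5, 5), class = "test_error")
  expect_error(fisher_cpg(-1, 5, 5, 5), class = "value_error")
})

test_that("fisher_cpg agrees with stats::fisher.test and is two-sided", {
  set.seed(17)
  for (i in 1:200) {
    cl <- sample(1:30, 1); cr <- sample(1:30, 1)
    a <- sample(0:cl, 1); c_ <- sample(0:cr, 1)
    mine <- fisher_cpg(a, cl - a, c_, cr - c_)
    ref <- stats::fisher.test(matrix(c(a, cl - a, c_, cr - c_), 2,
                                     byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
    # invariance under left/right swap
    expect_equal(fisher_cpg(c_, cr - c_, a, cl - a), mine, tolerance = 1e-12)
  }
})

test_that("adjust_fdr is Benjamini-Hochberg and order-preserving", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_error(adjust_fdr(c(0.5, 1.2)), class = "value_error")

  set.seed(23)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(50)
  expect_equal(adjust_fdr(p[perm]), q[perm])
})

test_that("joint rule: significant iff q below fdr_q AND |diff| above 25", {
  # family: one strong CpG among nulls so BH keeps q small
  strong <- cpg_rows(100, ml = 2, cl = 10, mr = 8, cr = 10)
  nulls <- cpg_rows(seq(200, 1000, by = 100), ml = rep(5, 9), cl = rep(10, 9),
                    mr = rep(5, 9), cr = rep(10, 9))
  calls <- call_diff_methylation(rbind(strong, nulls), "wk8", "s1")
  hit <- calls[calls$pos == 100, ]
  expect_equal(hit$diff, 60)
  expect_equal(hit$p_raw, fisher_cpg(2, 8, 8, 2), tolerance = 1e-12)
  expect_equal(hit$q, adjust_fdr(calls$p_raw[order(calls$pos)])[1])
  expect_equal(hit$significant, hit$q < 0.01)
  # identical counts on both sides: p = 1, never significant
  expect_true(all(calls$p_raw[calls$pos != 100] == 1))
  expect_true(all(!calls$significant[calls$pos != 100]))

  # a 10-point difference never passes the magnitude gate, whatever the q
  mild <- cpg_rows(50, ml = 500, cl = 1000, mr = 600, cr = 1000)
  call <- call_diff_methylation(rbind(mild, nulls), "wk8", "s1")
  row <- call[call$pos == 50, ]
  expect_equal(row$diff, 10)
  expect_false(row$significant)
})

test_that("one-sided CpGs are excluded and tallied; min_coverage filters", {
  tab <- rbind(cpg_rows(100, 2, 10, 8, 10),
               data.frame(chrom = "chr1", pos = 900L, strand = "+",
                          sample_id = "s1", stage = "wk8", side = "left",
                          coverage = 10L, methylated = 5L,
                          stringsAsFactors = FALSE))
  calls <- call_diff_methylation(tab, "wk8", "s1")
  expect_equal(nrow(calls), 1)
  expect_equal(attr(calls, "n_excluded"), 1)

  low <- cpg_rows(c(100, 200), c(2, 1), c(10, 3), c(8, 3), c(10, 3))
  calls <- call_diff_methylation(low, "wk8", "s1",
                                 threshold_config(min_coverage = 5))
  expect_equal(calls$pos, 100L)
})

test_that("tightening either joint threshold never increases the call count", {
  set.seed(37)
  n <- 60
  cl <- sample(10:40, n, TRUE); cr <- sample(10:40, n, TRUE)
  tab <- cpg_rows(seq_len(n) * 10, rbinom(n, cl, runif(n)), cl,
                  rbinom(n, cr, runif(n)), cr)
  n_sig <- function(q, d) {
    sum(call_diff_methylation(tab, "wk8", "s1",
                              threshold_config(fdr_q = q,
                                               meth_diff_min = d))$significant)
  }
  for (d in c(0, 10, 25, 40)) {
    counts <- vapply(c(0.2, 0.05, 0.01, 0.001), n_sig, numeric(1), d = d)
    expect_true(all(diff(counts) <= 0))
  }
  for (q in c(0.2, 0.01)) {
    counts <- vapply(c(0, 10, 25, 40, 60), function(d) n_sig(q, d), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("consensus keeps CpGs significant in the same direction in all samples", {
  mk <- function(pos, diff, sig, dir, sample) {
    data.frame(chrom = "chr1", pos = as.integer(pos), strand = "+",
               sample_id = sample, p_raw = 1e-6, q = 1e-5,
               pct_left = 50 - diff / 2, pct_right = 50 + diff / 2,
               diff = diff, significant = sig, direction = dir,
               stringsAsFactors = FALSE)
  }
  s1 <- rbind(mk(100, +30, TRUE, "right", "s1"),
              mk(200, +40, TRUE, "right", "s1"),
              mk(300, -50, TRUE, "left", "s1"))
  s2 <- rbind(mk(100, +40, TRUE, "right", "s2"),
              mk(200, -40, TRUE, "left", "s2"))
  cons <- consensus_across_samples(list(s1, s2), "wk8")
  # pos 100: same direction in both samples, mean(|30|, |40|) = 35
  # pos 200: direction conflict; pos 300: absent from s2
  expect_equal(cons$pos, 100L)
  expect_equal(cons$direction, "right")
  expect_equal(cons$mean_abs_diff, 35)
  expect_equal(cons$n_samples_support, 2L)

  # single-sample stages pass their significant set through
  single <- consensus_across_samples(list(s1), "wk12")
  expect_equal(single$pos, c(100L, 200L, 300L))

  # consensus count is bounded by every per-sample significant count
  expect_lte(nrow(cons), min(sum(s1$significant), sum(s2$significant)))
})
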