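mirna_rows <- function(id, left, right, len = 22L, lib = 5e6L,
                       sample = "s1", stage = "wk8") {
  data.frame(mirna_id = rep(id, 2), sample_id = sample, stage = stage,
             side = c("left", "right"),
             read_count = as.integer(c(left, right)),
             transcript_length = len, library_size = as.integer(lib),
             stringsAsFactors = FALSE)
}

test_that("low-count filter removes miRNAs only when both sides are low", {
  tab <- rbind(mirna_rows("both_low", 3, 5),
               mirna_rows("one_high", 3, 50),
               mirna_rows("boundary", 10, 10))
  kept <- unique(filter_low_count(tab, "wk8")$mirna_id)
  expect_setequal(kept, c("one_high", "boundary"))

  strict <- threshold_config(low_count_either_side = TRUE)
  kept2 <- unique(filter_low_count(tab, "wk8", strict)$mirna_id)
  expect_setequal(kept2, "boundary")

  # raising the floor never keeps more miRNAs
  n_kept <- vapply(c(1, 5, 10, 20, 60), function(m) {
    length(unique(filter_low_count(
      tab, "wk8", threshold_config(mirna_min_reads = m))$mirna_id))
  }, numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("rpkm implements 1e9 * reads / (library * length)", {
  expect_equal(rpkm(0, 22, 5e6), 0)
  expect_equal(rpkm(100, 1000, 5e6), 20)
  # linear in reads, inverse-linear in library and length
  set.seed(41)
  for (i in 1:20) {
    rc <- rpois(1, 500); len <- sample(20:2000, 1); lib <- sample(1e5:1e7, 1)
    base <- rpkm(rc, len, lib)
    expect_equal(rpkm(3 * rc, len, lib), 3 * base)
    expect_equal(rpkm(rc, 2 * len, lib), base / 2)
    expect_equal(rpkm(rc, len, 4 * lib), base / 4)
    expect_equal(rpkm(2 * rc, len, 2 * lib), base)
  }
  expect_error(rpkm(10, 0, 5e6), class = "value_error")
  expect_error(rpkm(10, 22, 0), class = "value_error")
})

test_that("miRNA calls use a minimum (>=) fold-change rule on RPKM means", {
  # equal RPKM on both sides: no call
  flat <- mirna_rows("flat", 200, 200)
  expect_equal(call_mirna_asymmetry(flat, "wk8")$direction, "none")

  # exactly at the threshold: called under the minimum rule, not under the
  # strict variant (counts 100 vs 800 give log2fc = 3 exactly)
  cfg3 <- threshold_config(lfc_threshold = 3)
  at <- mirna_rows("at", 100, 800)
  expect_equal(call_mirna_asymmetry(at, "wk8", cfg3)$direction, "right")
  cfg3s <- threshold_config(lfc_threshold = 3, mirna_lfc_strict = TRUE)
  expect_equal(call_mirna_asymmetry(at, "wk8", cfg3s)$direction, "none")

  # a zero side that survived the filter is floored at 0.5 reads and flagged
  zero <- mirna_rows("zero", 0, 50)
  kept <- filter_low_count(zero, "wk8")
  expect_equal(unique(kept$mirna_id), "zero")
  call <- call_mirna_asymmetry(kept, "wk8")
  expect_true(call$floored)
  expect_true(is.finite(call$log2fc))
  expect_equal(call$direction, "right")
  expect_equal(call$log2fc, log2(50 / 0.5))  # same library and length
})

test_that("calls agree with a brute-force oracle on random count tables", {
  set.seed(59)
  n <- 100
  tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    mirna_rows(sprintf("mir%03d", i), rnbinom(1, mu = 60, size = 3),
               rnbinom(1, mu = 60, size = 3),
               len = sample(20:24, 1))
  }))
  kept <- filter_low_count(tab, "wk8")
  calls <- call_mirna_asymmetry(kept, "wk8")
  calls <- calls[!calls$floored, ]
  oracle <- oracle_mirna_calls(tab, "wk8")
  calls <- calls[order(calls$mirna_id), ]
  expect_equal(calls$mirna_id, oracle$mirna_id)
  expect_equal(calls$log2fc, oracle$log2fc)
  expect_identical(calls$direction, oracle$direction)
})

test_that("target collection takes a strict-probability union over asymmetric miRNAs", {
  calls <- data.frame(mirna_id = c("mirA", "mirB", "mirC"), stage = "wk8",
                      rpkm_left = 1, rpkm_right = 1,
                      log2fc = c(2, -2, 0),
                      direction = c("right", "left", "none"),
                      floored = FALSE, stringsAsFactors = FALSE)
  tm <- data.frame(mirna_id = c("mirA", "mirA", "mirB", "mirC"),
                   gene_id = c("g1", "g2", "g1", "g9"),
                   probability = c(0.9, 0.8, 0.95, 0.99),
                   stringsAsFactors = FALSE)
  # g2 at exactly 0.8 is excluded (strict >); g1 counted once; g9's miRNA
  # is not asymmetric
  expect_equal(targets_of_asymmetric(calls, tm), "g1")

  none <- calls[calls$direction == "none", ]
  expect_length(targets_of_asymmetric(none, tm), 0)

  # repression-consistent mode: a right-asymmetric miRNA can only explain
  # a left-expressed target
  cfg <- threshold_config(mirna_direction_consistent = TRUE)
  dirs <- c(g1 = "right", g2 = "left")
  expect_length(targets_of_asymmetric(calls[1, ], tm, cfg,
                                      gene_directions = dirs), 0)
  dirs2 <- c(g1 = "left")
  expect_equal(targets_of_asymmetric(calls[1, ], tm, cfg,
                                     gene_directions = dirs2), "g1")
})
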