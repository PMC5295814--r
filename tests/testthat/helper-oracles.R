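# Independent oracles used to cross-check the implementation. These are
# deliberately naive: plain enumeration and loops, no shared code with R/.

# Two-sided Fisher p by exhaustive enumeration over all 2x2 tables with the
# observed margins; table probabilities from log-binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  K <- a + c; M <- b + d; n <- a + b
  lo <- max(0, n - M); hi <- min(n, K)
  xs <- lo:hi
  lp <- lchoose(K, xs) + lchoose(M, n - xs) - lchoose(K + M, n)
  p <- exp(lp)
  pobs <- p[xs == a]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# Naive O(n*m) CpG-to-gene window assignment (0-based half-open windows,
# CpG pos is 1-based).
oracle_assign <- function(consensus, genes, w, ignore_strand = FALSE) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    left_window <- ignore_strand || g$strand == "+"
    ws <- if (left_window) g$start - w else g$start
    we <- if (left_window) g$end else g$end + w
    for (j in seq_len(nrow(consensus))) {
      p0 <- consensus$pos[j] - 1L
      if (consensus$chrom[j] == g$chrom && p0 >= ws && p0 < we) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g$gene_id, pos = consensus$pos[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), pos = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$pos), , drop = FALSE]
}

# Brute-force expression asymmetry calls straight from raw rows.
oracle_expr_calls <- function(table, stage, lfc_threshold = 1.5, fpkm_min = 1) {
  sub <- table[table$stage == stage, ]
  out <- list()
  for (f in sort(unique(sub$feature_id))) {
    rows <- sub[sub$feature_id == f, ]
    ml <- mean(rows$fpkm[rows$side == "left"])
    mr <- mean(rows$fpkm[rows$side == "right"])
    if (ml < fpkm_min || mr < fpkm_min) next
    lfc <- log2(mr / ml)
    dir <- "none"
    if (lfc > lfc_threshold) dir <- "right"
    if (lfc < -lfc_threshold) dir <- "left"
    out[[length(out) + 1L]] <- data.frame(
      feature_id = f, mean_left = ml, mean_right = mr, log2fc = lfc,
      direction = dir, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Brute-force miRNA calls from raw counts (filter, RPKM, fold change).
oracle_mirna_calls <- function(table, stage, min_reads = 10,
                               lfc_threshold = 1.5) {
  sub <- table[table$stage == stage, ]
  out <- list()
  for (m in sort(unique(sub$mirna_id))) {
    rows <- sub[sub$mirna_id == m, ]
    cl <- mean(rows$read_count[rows$side == "left"])
    cr <- mean(rows$read_count[rows$side == "right"])
    if (cl < min_reads && cr < min_reads) next
    rp <- 1e9 * rows$read_count / (rows$library_size * rows$transcript_length)
    rl <- mean(rp[rows$side == "left"])
    rr <- mean(rp[rows$side == "right"])
    if (rl == 0 || rr == 0) next  # oracle skips floored cases
    lfc <- log2(rr / rl)
    dir <- "none"
    if (lfc >= lfc_threshold) dir <- "right"
    if (lfc <= -lfc_threshold) dir <- "left"
    out[[length(out) + 1L]] <- data.frame(
      mirna_id = m, rpkm_left = rl, rpkm_right = rr, log2fc = lfc,
      direction = dir, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Rule-table classification of one asymmetric gene.
oracle_classify <- function(direction, lq, is_target, lq_threshold = 25) {
  meth <- !is.na(lq) && ((direction == "right" && lq < -lq_threshold) ||
                           (direction == "left" && lq > lq_threshold))
  if (meth && is_target) "both"
  else if (meth) "methylation_only"
  else if (is_target) "mirna_only"
  else "unexplained"
}

# 95% binomial (Wald) interval around a planted proportion.
binom_ci95 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
}

# Small paired expression fixture builder.
make_expr <- function(feature_id, sample_id, stage, side, fpkm) {
  data.frame(feature_id = feature_id, sample_id = sample_id, stage = stage,
             side = side, fpkm = fpkm, stringsAsFactors = FALSE)
}

# One gene measured on both sides of each sample; means chosen directly.
expr_from_means <- function(gene, left, right, stage = "wk8") {
  make_expr(rep(gene, 2 * length(left)),
            rep(sprintf("s%d", seq_along(left)), 2),
            stage,
            rep(c("left", "right"), each = length(left)),
            c(left, right))
}

# Swap the side labels of every table in a bundle.
swap_sides <- function(bundle) {
  flip <- function(df) {
    df$side <- ifelse(df$side == "left", "right", "left")
    df
  }
  bundle$expression <- flip(bundle$expression)
  bundle$mirna <- flip(bundle$mirna)
  bundle$cpg <- flip(bundle$cpg)
  bundle
}
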