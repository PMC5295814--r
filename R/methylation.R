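# Per-CpG left-vs-right differential methylation.
#
# Each CpG covered on both sides within one sample is tested with a
# two-sided Fisher exact test on the 2x2 table
#   [[methylated_left, unmethylated_left],
#    [methylated_right, unmethylated_right]],
# p-values are FDR-adjusted within that sample's test family, and a CpG is
# called differentially methylated when q < fdr_q AND the absolute percent
# methylation difference exceeds meth_diff_min. A stage-level consensus
# keeps CpGs called in the same direction in every sample of the stage.

#' Two-sided Fisher exact p-value for 2x2 methylation tables
#'
#' Point-probability convention: conditioning on the margins, the p-value is
#' the sum of hypergeometric probabilities of all tables whose probability
#' does not exceed that of the observed table (a relative tolerance of
#' 1e-7 guards floating-point ties, the usual convention). Vectorised over
#' tables; implemented directly on the hypergeometric density so that
#' hundreds of thousands of CpG tables can be tested in one call.
#'
#' @param meth_left,unmeth_left methylated / unmethylated read counts, left.
#' @param meth_right,unmeth_right same for the right side.
#' @return numeric vector of two-sided p-values.
#' @export
#' @examples
#' fisher_cpg(5, 5, 5, 5)  # 1: perfectly symmetric table
fisher_cpg <- function(meth_left, unmeth_left, meth_right, unmeth_right) {
  a <- as.integer(meth_left); b <- as.integer(unmeth_left)
  cc <- as.integer(meth_right); d <- as.integer(unmeth_right)
  n <- length(a)
  if (length(b) != n || length(cc) != n || length(d) != n)
    sa_stop("value_error", "count vectors must have equal length")
  if (any(a < 0 | b < 0 | cc < 0 | d < 0))
    sa_stop("value_error", "counts must be non-negative")
  if (any(a + b == 0L | cc + d == 0L))
    sa_stop("test_error", "a side has zero coverage; filter such rows upstream")
  K <- a + cc          # total methylated (white balls)
  M <- b + d           # total unmethylated (black balls)
  nn <- a + b          # left coverage (draws)
  p <- numeric(n)
  groups <- split(seq_len(n), paste(K, M, nn))
  relerr <- 1 + 1e-7
  for (grp in groups) {
    i1 <- grp[1]
    lo <- max(0L, nn[i1] - M[i1]); hi <- min(nn[i1], K[i1])
    dens <- stats::dhyper(lo:hi, K[i1], M[i1], nn[i1])
    obs <- a[grp] - lo + 1L
    for (u in unique(obs)) {
      pv <- min(1, sum(dens[dens <= dens[u] * relerr]))
      p[grp[obs == u]] <- pv
    }
  }
  p
}

#' FDR adjustment of p-values
#'
#' Benjamini-Hochberg step-up by default (order-preserving, never decreases
#' a p-value, q in \[0,1\]).
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @param method adjustment procedure; only `"BH"` is provided.
#' @return q-values in input order.
#' @export
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
adjust_fdr <- function(p_values, method = c("BH")) {
  method <- match.arg(method)
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    sa_stop("value_error", "p-values must lie in [0,1]")
  stats::p.adjust(p_values, method = method)
}

#' Call differential methylation for one sample at one stage
#'
#' Pairs left and right coverage per CpG `(chrom, pos, strand)` within the
#' sample; CpGs covered on one side only (or below `cfg$min_coverage` on a
#' side) are excluded and tallied in the `n_excluded` attribute. q-values
#' are computed within this sample's family of both-side-covered CpGs.
#'
#' @param cpg_table validated CpG data.frame.
#' @param stage stage label.
#' @param sample_id sample to test.
#' @param cfg a [threshold_config()].
#' @return data.frame with `chrom, pos, strand, sample_id, p_raw, q,
#'   pct_left, pct_right, diff, significant, direction`
#'   (diff = pct_right - pct_left, percentage points), sorted by position;
#'   attribute `n_excluded` counts CpGs dropped for one-sided coverage.
#' @export
call_diff_methylation <- function(cpg_table, stage, sample_id, cfg = NULL) {
  cfg <- as_threshold_config(cfg)
  stage <- normalize_stage(stage)
  sub <- cpg_table[cpg_table$stage == stage &
                     cpg_table$sample_id == sample_id &
                     cpg_table$coverage >= cfg$min_coverage, , drop = FALSE]
  key <- paste(sub$chrom, sub$pos, sub$strand, sep = "\r")
  lft <- sub[sub$side == "left", , drop = FALSE]
  rgt <- sub[sub$side == "right", , drop = FALSE]
  kl <- key[sub$side == "left"]; kr <- key[sub$side == "right"]
  common <- intersect(kl, kr)
  n_excluded <- length(unique(c(kl, kr))) - length(common)
  il <- match(common, kl); ir <- match(common, kr)
  out <- data.frame(chrom = lft$chrom[il], pos = lft$pos[il],
                    strand = lft$strand[il], sample_id = sample_id,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0) {
    ml <- lft$methylated[il]; cl <- lft$coverage[il]
    mr <- rgt$methylated[ir]; cr <- rgt$coverage[ir]
    out$p_raw <- fisher_cpg(ml, cl - ml, mr, cr - mr)
    out$q <- adjust_fdr(out$p_raw)
    out$pct_left <- 100 * ml / cl
    out$pct_right <- 100 * mr / cr
    out$diff <- out$pct_right - out$pct_left
    out$significant <- out$q < cfg$fdr_q & abs(out$diff) > cfg$meth_diff_min
    out$direction <- ifelse(out$significant & out$diff > 0, "right",
                            ifelse(out$significant & out$diff < 0, "left",
                                   "none"))
    out <- out[sa_order(out$chrom, out$pos, out$strand), , drop = FALSE]
  } else {
    out$p_raw <- numeric(0); out$q <- numeric(0)
    out$pct_left <- numeric(0); out$pct_right <- numeric(0)
    out$diff <- numeric(0); out$significant <- logical(0)
    out$direction <- character(0)
  }
  attr(out, "n_excluded") <- n_excluded
  rownames(out) <- NULL
  out
}

#' Stage-level consensus of differentially methylated CpGs
#'
#' A CpG enters the consensus iff it is significant with the same direction
#' in *every* sample of the stage; single-sample stages pass their
#' significant set through unchanged. `mean_abs_diff` averages the absolute
#' percent difference across the supporting samples.
#'
#' @param per_sample_calls list of data.frames from
#'   [call_diff_methylation()], one per sample of the stage (a single
#'   combined data.frame is also accepted).
#' @param stage stage label (recorded in the output).
#' @return data.frame `chrom, pos, strand, stage, direction, mean_abs_diff,
#'   n_samples_support`, sorted by position.
#' @export
consensus_across_samples <- function(per_sample_calls, stage) {
  stage <- normalize_stage(stage)
  if (is.data.frame(per_sample_calls)) per_sample_calls <- list(per_sample_calls)
  all <- do.call(rbind, per_sample_calls)
  n_samples <- length(unique(all$sample_id))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stage = character(0),
                      direction = character(0), mean_abs_diff = numeric(0),
                      n_samples_support = integer(0), stringsAsFactors = FALSE)
  sig <- all[all$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  key <- paste(sig$chrom, sig$pos, sig$strand, sep = "\r")
  spl <- split(seq_len(nrow(sig)), key)
  keep <- vapply(spl, function(i) {
    length(unique(sig$sample_id[i])) == n_samples &&
      length(unique(sig$direction[i])) == 1L
  }, logical(1))
  spl <- spl[keep]
  if (length(spl) == 0) return(empty)
  first <- vapply(spl, `[`, integer(1), 1L)
  out <- data.frame(chrom = sig$chrom[first], pos = sig$pos[first],
                    strand = sig$strand[first], stage = stage,
                    direction = sig$direction[first],
                    mean_abs_diff = vapply(spl, function(i)
                      mean(abs(sig$diff[i])), numeric(1)),
                    n_samples_support = n_samples,
                    stringsAsFactors = FALSE)
  out <- out[sa_order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
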