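# Integration of the three layers: promoter-aware CpG-to-gene assignment,
# per-gene methylation laterality quotient, and the four-way partition of
# asymmetrically expressed genes.

#' Assign consensus CpG sites to genes
#'
#' A CpG is assigned to every gene whose body plus upstream promoter window
#' contains it: `[start - w, end)` for a `+`-strand gene, `[start, end + w)`
#' for a `-`-strand gene (0-based half-open, `w = cfg$upstream_window`).
#' "Upstream" is transcription-relative; `cfg$ignore_strand = TRUE`
#' reproduces the naive left-of-start reading for both strands. A CpG may
#' be assigned to multiple overlapping genes; the CpG's own strand plays no
#' role in the assignment.
#'
#' @param consensus data.frame from [consensus_across_samples()] (1-based
#'   `pos`).
#' @param genes validated gene models (0-based half-open).
#' @param cfg a [threshold_config()].
#' @return data.frame with one row per (gene, CpG) assignment: `gene_id,
#'   chrom, pos, strand, direction, mean_abs_diff`.
#' @export
assign_cpgs_to_genes <- function(consensus, genes, cfg = NULL) {
  cfg <- as_threshold_config(cfg)
  w <- cfg$upstream_window
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      direction = character(0), mean_abs_diff = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(consensus) == 0 || nrow(genes) == 0) return(empty)
  upstream_of_start <- cfg$ignore_strand | genes$strand == "+"
  win_start0 <- ifelse(upstream_of_start, genes$start - w, genes$start)
  win_end0 <- ifelse(upstream_of_start, genes$end, genes$end + w)
  # 0-based half-open window -> 1-based closed IRanges; clamp at position 1
  gene_rng <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(win_start0 + 1L, 1L),
                              end = win_end0))
  cpg_rng <- GenomicRanges::GRanges(
    seqnames = consensus$chrom,
    ranges = IRanges::IRanges(start = consensus$pos, width = 1L))
  # disjoint seqlevels (CpGs on a chromosome without genes) are a valid
  # empty result, not worth a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(cpg_rng, gene_rng, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  out <- data.frame(gene_id = genes$gene_id[si],
                    chrom = consensus$chrom[qi],
                    pos = consensus$pos[qi],
                    strand = consensus$strand[qi],
                    direction = consensus$direction[qi],
                    mean_abs_diff = consensus$mean_abs_diff[qi],
                    stringsAsFactors = FALSE)
  out <- out[sa_order(out$gene_id, out$chrom, out$pos, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Methylation laterality quotient
#'
#' `LQ = 100 * (n_right - n_left) / (n_right + n_left)` over a gene's
#' hyper-methylated consensus CpG counts per side; `NA` (undefined) when
#' both counts are zero. Ranges over \[-100, 100\]: -100 all CpGs
#' hyper-methylated on the left, +100 all on the right.
#'
#' @param n_left,n_right non-negative CpG counts (vectorised).
#' @return numeric LQ vector with `NA` where undefined.
#' @export
#' @examples
#' methylation_lq(1, 3)  # 50
methylation_lq <- function(n_left, n_right) {
  if (any(n_left < 0 | n_right < 0))
    sa_stop("value_error", "CpG counts must be non-negative")
  tot <- n_left + n_right
  ifelse(tot == 0, NA_real_, 100 * (n_right - n_left) / tot)
}

#' Per-gene methylation profile
#'
#' Counts, for each gene, the consensus CpGs assigned to it
#' (body + upstream window) that are hyper-methylated on the left and on
#' the right, and computes the laterality quotient.
#'
#' @param consensus data.frame from [consensus_across_samples()].
#' @param genes validated gene models.
#' @param cfg a [threshold_config()].
#' @return data.frame `gene_id, n_cpg_hyper_left, n_cpg_hyper_right, lq`
#'   with one row per gene in `genes` (lq `NA` when the gene has no
#'   consensus CpG).
#' @export
gene_methylation_profile <- function(consensus, genes, cfg = NULL) {
  asg <- assign_cpgs_to_genes(consensus, genes, cfg)
  nl <- nr <- integer(nrow(genes))
  if (nrow(asg) > 0) {
    tl <- table(factor(asg$gene_id[asg$direction == "left"],
                       levels = genes$gene_id))
    tr <- table(factor(asg$gene_id[asg$direction == "right"],
                       levels = genes$gene_id))
    nl <- as.integer(tl); nr <- as.integer(tr)
  }
  data.frame(gene_id = genes$gene_id,
             n_cpg_hyper_left = nl, n_cpg_hyper_right = nr,
             lq = methylation_lq(nl, nr),
             stringsAsFactors = FALSE)
}

#' Classify one asymmetrically expressed gene
#'
#' Methylation explains a gene's expression asymmetry when its CpG
#' laterality is *strong and towards the opposite side*: a rightward
#' expressed gene requires `LQ < -cfg$lq_threshold` (hyper-methylation on
#' the left), a leftward gene `LQ > cfg$lq_threshold` (strict
#' inequalities; undefined LQ never explains). miRNA explains it when the
#' gene is in the asymmetric-miRNA target set. Vectorised.
#'
#' @param direction expression direction, `"left"` or `"right"`.
#' @param lq laterality quotient (may be `NA`).
#' @param is_target logical, membership in the asymmetric-miRNA target set.
#' @param cfg a [threshold_config()].
#' @return character vector over `{"methylation_only", "mirna_only",
#'   "both", "unexplained"}`.
#' @export
classify_gene <- function(direction, lq, is_target, cfg = NULL) {
  cfg <- as_threshold_config(cfg)
  if (any(!direction %in% c("left", "right")))
    sa_stop("value_error", "direction must be 'left' or 'right'")
  t <- cfg$lq_threshold
  meth_flag <- !is.na(lq) &
    ((direction == "right" & lq < -t) | (direction == "left" & lq > t))
  mirna_flag <- as.logical(is_target)
  ifelse(meth_flag & mirna_flag, "both",
         ifelse(meth_flag, "methylation_only",
                ifelse(mirna_flag, "mirna_only", "unexplained")))
}

partition_levels <- c("methylation_only", "both", "mirna_only", "unexplained")

#' Summarise the partition of asymmetrically expressed genes
#'
#' Reports counts and integer percentages (rounded half-up) per category,
#' with the full asymmetric gene set as denominator. Accepts either the
#' per-gene partition data.frame or explicit counts for the explained
#' categories (unexplained is then the remainder).
#'
#' @param partitions data.frame with a `category` column, or a named
#'   numeric vector with entries among `methylation_only, both, mirna_only`
#'   (and optionally `unexplained`).
#' @param n_asym_total total number of asymmetrically expressed genes.
#' @return list with `n_asym_total`, `counts` (named, all four categories)
#'   and `pct` (named integer percentages).
#' @export
#' @examples
#' partition_summary(c(methylation_only = 451, both = 18, mirna_only = 47),
#'                   1690)$pct
#' # methylation_only 27, both 1, mirna_only 3, unexplained 69
partition_summary <- function(partitions, n_asym_total) {
  if (length(n_asym_total) != 1 || !isTRUE(n_asym_total > 0))
    sa_stop("empty_summary_error", "n_asym_total must be a positive number")
  if (is.data.frame(partitions)) {
    counts <- table(factor(partitions$category, levels = partition_levels))
    counts <- stats::setNames(as.integer(counts), partition_levels)
    if (sum(counts) != nrow(partitions))
      sa_stop("value_error", "unknown category values in partitions")
  } else {
    counts <- stats::setNames(integer(4), partition_levels)
    bad <- setdiff(names(partitions), partition_levels)
    if (length(bad) > 0)
      sa_stop("value_error", "unknown category '%s'", bad[1])
    counts[names(partitions)] <- as.integer(partitions)
    if (!"unexplained" %in% names(partitions))
      counts["unexplained"] <-
        as.integer(n_asym_total) - sum(counts[partition_levels != "unexplained"])
  }
  if (sum(counts) != n_asym_total)
    sa_stop("value_error", "category counts (%d) do not sum to n_asym_total (%d)",
            sum(counts), n_asym_total)
  if (any(counts < 0))
    sa_stop("value_error", "negative category count")
  pct <- round_half_up(100 * counts / n_asym_total, 0)
  list(n_asym_total = as.integer(n_asym_total),
       counts = counts,
       pct = stats::setNames(as.numeric(pct), partition_levels))
}
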