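# Per-miRNA left/right asymmetry from raw small-RNA read counts.
#
# Counts are filtered (low-count miRNAs yield unrealistically high fold
# changes), normalised to RPKM, then called with the same
# fold-change-of-means arithmetic as the mRNA layer, except that the miRNA
# rule is a minimum (>=) rather than a strict inequality.

#' Remove low-count miRNAs at one stage
#'
#' A miRNA is removed iff its mean read count across the stage's samples is
#' below `cfg$mirna_min_reads` on *both* sides; a miRNA at or above the
#' floor on at least one side is kept. Set `cfg$low_count_either_side =
#' TRUE` for the stricter reading (removed when either side is below).
#'
#' @param table validated miRNA count data.frame.
#' @param stage stage label.
#' @param cfg a [threshold_config()].
#' @return the stage's rows for kept miRNAs.
#' @export
filter_low_count <- function(table, stage, cfg = NULL) {
  cfg <- as_threshold_config(cfg)
  stage <- normalize_stage(stage)
  sub <- table[table$stage == stage, , drop = FALSE]
  if (nrow(sub) == 0) return(sub)
  sm <- side_means(sub, stage, value_col = "read_count", id_col = "mirna_id")
  ml <- ifelse(is.na(sm$mean_left), 0, sm$mean_left)
  mr <- ifelse(is.na(sm$mean_right), 0, sm$mean_right)
  low_l <- ml < cfg$mirna_min_reads
  low_r <- mr < cfg$mirna_min_reads
  drop <- if (cfg$low_count_either_side) low_l | low_r else low_l & low_r
  keep_ids <- sm$id[!drop]
  sub[sub$mirna_id %in% keep_ids, , drop = FALSE]
}

#' Reads per kilobase per million (RPKM)
#'
#' `10^9 * read_count / (library_size * transcript_length)`: read counts
#' corrected for sequencing depth and transcript length. Vectorised.
#'
#' @param read_count non-negative reads mapped to the transcript.
#' @param transcript_length transcript length in nucleotides (> 0).
#' @param library_size total reads in the library (> 0).
#' @return RPKM value(s).
#' @export
#' @examples
#' rpkm(100, 1000, 5e6)  # 20
rpkm <- function(read_count, transcript_length, library_size) {
  if (any(transcript_length <= 0))
    sa_stop("value_error", "transcript_length must be > 0")
  if (any(library_size <= 0))
    sa_stop("value_error", "library_size must be > 0")
  if (any(read_count < 0))
    sa_stop("value_error", "read_count must be >= 0")
  1e9 * as.numeric(read_count) /
    (as.numeric(library_size) * as.numeric(transcript_length))
}

#' Call per-miRNA asymmetry at one stage
#'
#' Expects an already low-count-filtered table (see [filter_low_count()]).
#' Each row's RPKM is computed, side means are taken across the stage's
#' samples, and `log2fc = log2(rpkm_right / rpkm_left)`. Direction is
#' assigned at `|log2fc| >= cfg$lfc_threshold` (minimum rule; strict with
#' `cfg$mirna_lfc_strict`).
#'
#' A side whose mean RPKM is zero (possible when the other side carried the
#' miRNA past the filter) is replaced by a floor equivalent to 0.5 reads in
#' that side's library, so the fold change stays finite and deterministic;
#' such calls are flagged in the `floored` column.
#'
#' @param table filtered, validated miRNA count data.frame.
#' @param stage stage label.
#' @param cfg a [threshold_config()].
#' @return data.frame with `mirna_id, stage, rpkm_left, rpkm_right, log2fc,
#'   direction, floored`, sorted by decreasing `|log2fc|`.
#' @export
call_mirna_asymmetry <- function(table, stage, cfg = NULL) {
  cfg <- as_threshold_config(cfg)
  stage <- normalize_stage(stage)
  sub <- table[table$stage == stage, , drop = FALSE]
  empty <- data.frame(mirna_id = character(0), stage = character(0),
                      rpkm_left = numeric(0), rpkm_right = numeric(0),
                      log2fc = numeric(0), direction = character(0),
                      floored = logical(0), stringsAsFactors = FALSE)
  if (nrow(sub) == 0) return(empty)
  sub$rpkm <- rpkm(sub$read_count, sub$transcript_length, sub$library_size)
  # floor: 0.5 reads at the row's library size / length
  sub$rpkm_floor <- rpkm(0.5, sub$transcript_length, sub$library_size)
  agg <- function(col) {
    a <- stats::aggregate(sub[[col]],
                          by = list(id = sub$mirna_id, side = sub$side),
                          FUN = mean)
    a
  }
  m <- agg("rpkm"); fl <- agg("rpkm_floor")
  get_side <- function(a, s, ids) {
    v <- a$x[a$side == s][match(ids, a$id[a$side == s])]
    v
  }
  ids <- sort(unique(sub$mirna_id), method = "radix")
  rl <- get_side(m, "left", ids); rr <- get_side(m, "right", ids)
  fll <- get_side(fl, "left", ids); flr <- get_side(fl, "right", ids)
  # absent side (no rows) treated as zero, floored with the other side's floor
  rl[is.na(rl)] <- 0; rr[is.na(rr)] <- 0
  fll[is.na(fll)] <- flr[is.na(fll)]; flr[is.na(flr)] <- fll[is.na(flr)]
  floored <- (rl == 0) | (rr == 0)
  rl_eff <- ifelse(rl == 0, fll, rl)
  rr_eff <- ifelse(rr == 0, flr, rr)
  lfc <- log2(rr_eff / rl_eff)
  thr <- cfg$lfc_threshold
  hit <- if (cfg$mirna_lfc_strict) abs(lfc) > thr else abs(lfc) >= thr
  direction <- ifelse(hit & lfc > 0, "right", ifelse(hit & lfc < 0, "left", "none"))
  out <- data.frame(mirna_id = ids, stage = stage,
                    rpkm_left = rl, rpkm_right = rr, log2fc = lfc,
                    direction = direction, floored = floored,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$log2fc), out$mirna_id, method = "radix"), , drop = FALSE]
}

#' Target genes of asymmetrically expressed miRNAs
#'
#' The union of genes whose interaction probability exceeds
#' `cfg$target_prob_min` (strict `>`) under any miRNA called asymmetric
#' (direction != none). With `cfg$mirna_direction_consistent = TRUE` a
#' direction map must be supplied via `gene_directions` and only
#' repression-consistent pairs count (miRNA up on the side where the target
#' gene is down).
#'
#' @param mirna_calls data.frame from [call_mirna_asymmetry()].
#' @param target_map validated target data.frame
#'   (`mirna_id, gene_id, probability`).
#' @param cfg a [threshold_config()].
#' @param gene_directions optional named character vector gene_id ->
#'   direction (`left`/`right`), required for the direction-consistent mode.
#' @return sorted character vector of target gene ids.
#' @export
targets_of_asymmetric <- function(mirna_calls, target_map, cfg = NULL,
                                  gene_directions = NULL) {
  cfg <- as_threshold_config(cfg)
  asym <- mirna_calls[mirna_calls$direction != "none", , drop = FALSE]
  if (nrow(asym) == 0) return(character(0))
  hits <- target_map[target_map$probability > cfg$target_prob_min &
                       target_map$mirna_id %in% asym$mirna_id, , drop = FALSE]
  if (cfg$mirna_direction_consistent) {
    if (is.null(gene_directions))
      sa_stop("value_error",
              "gene_directions required when mirna_direction_consistent = TRUE")
    mdir <- asym$direction[match(hits$mirna_id, asym$mirna_id)]
    gdir <- unname(gene_directions[hits$gene_id])
    # repression: miRNA high on one side suppresses its target there,
    # so the gene should be high on the opposite side
    keep <- !is.na(gdir) &
      ((mdir == "left" & gdir == "right") | (mdir == "right" & gdir == "left"))
    hits <- hits[keep, , drop = FALSE]
  }
  sort(unique(hits$gene_id), method = "radix")
}
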