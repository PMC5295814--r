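# Per-gene left/right expression asymmetry at one developmental stage.
#
# With n = 2 fetuses per stage (1 at the last stage) no per-gene variance
# test is sensible; asymmetry is therefore called by fold change of the
# per-side means, after an abundance filter that removes lowly expressed
# genes whose ratios would be unstable.

# per-feature per-side mean FPKM at one stage
side_means <- function(df, stage, value_col = "fpkm", id_col = "feature_id") {
  sub <- df[df$stage == stage, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  agg <- stats::aggregate(sub[[value_col]],
                          by = list(id = sub[[id_col]], side = sub$side),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "id", timevar = "side", direction = "wide")
  ml <- wide[["x.left"]]; mr <- wide[["x.right"]]
  if (is.null(ml)) ml <- rep(NA_real_, nrow(wide))
  if (is.null(mr)) mr <- rep(NA_real_, nrow(wide))
  out <- data.frame(id = wide$id, mean_left = ml, mean_right = mr,
                    stringsAsFactors = FALSE)
  out[sa_order(out$id), , drop = FALSE]
}

#' Abundance filter
#'
#' A gene is abundant at a stage when its mean FPKM across that stage's
#' samples is at least `cfg$fpkm_min` on *both* sides. Ratios of
#' near-zero FPKM values are large even when the absolute difference is
#' biologically negligible, so only abundant genes are tested.
#'
#' @param table validated expression data.frame.
#' @param stage stage label (canonical or gestational synonym).
#' @param cfg a [threshold_config()] (default thresholds when `NULL`).
#' @return character vector of abundant feature ids (sorted).
#' @export
abundance_filter <- function(table, stage, cfg = NULL) {
  cfg <- as_threshold_config(cfg)
  stage <- normalize_stage(stage)
  sm <- side_means(table, stage)
  if (is.null(sm)) {
    warning(sprintf("no rows at stage %s; abundance filter returns empty set",
                    stage))
    return(character(0))
  }
  sm$id[!is.na(sm$mean_left) & !is.na(sm$mean_right) &
          sm$mean_left >= cfg$fpkm_min & sm$mean_right >= cfg$fpkm_min]
}

#' Log2 fold change of side means
#'
#' `log2(mean_right / mean_left)`, means taken across the stage's samples.
#' Positive values indicate rightward asymmetry. With a single sample the
#' means reduce to the per-sample values.
#'
#' @param table validated expression data.frame.
#' @param feature_id feature to evaluate.
#' @param stage stage label.
#' @return log2 fold change (scalar).
#' @export
fold_change_of_means <- function(table, feature_id, stage) {
  stage <- normalize_stage(stage)
  sub <- table[table$stage == stage & table$feature_id == feature_id, ,
               drop = FALSE]
  if (nrow(sub) == 0)
    sa_stop("value_error", "feature '%s' absent at stage %s", feature_id, stage)
  ml <- mean(sub$fpkm[sub$side == "left"])
  mr <- mean(sub$fpkm[sub$side == "right"])
  if (!isTRUE(ml > 0) || !isTRUE(mr > 0))
    sa_stop("ratio_error",
            "undefined ratio for feature '%s': a side mean is zero", feature_id)
  log2(mr / ml)
}

#' Call per-gene expression asymmetry at one stage
#'
#' Returns one row per abundant feature, sorted by decreasing `|log2fc|`.
#' Direction is `right` iff `log2fc > cfg$lfc_threshold` (strict), `left`
#' iff `log2fc < -cfg$lfc_threshold`, else `none`.
#'
#' @param table validated expression data.frame.
#' @param stage stage label.
#' @param cfg a [threshold_config()].
#' @return data.frame with columns `feature_id, stage, mean_left,
#'   mean_right, log2fc, direction, abundant`.
#' @export
#' @examples
#' tab <- data.frame(
#'   feature_id = rep("g1", 4),
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   stage = "wk8",
#'   side = rep(c("left", "right"), 2),
#'   fpkm = c(1, 4, 3, 4))
#' call_expression_asymmetry(tab, "wk8")  # log2fc = log2(4/2) = 1
call_expression_asymmetry <- function(table, stage, cfg = NULL) {
  cfg <- as_threshold_config(cfg)
  stage <- normalize_stage(stage)
  sm <- side_means(table, stage)
  if (is.null(sm)) {
    warning(sprintf("no rows at stage %s", stage))
    return(data.frame(feature_id = character(0), stage = character(0),
                      mean_left = numeric(0), mean_right = numeric(0),
                      log2fc = numeric(0), direction = character(0),
                      abundant = logical(0), stringsAsFactors = FALSE))
  }
  abundant <- !is.na(sm$mean_left) & !is.na(sm$mean_right) &
    sm$mean_left >= cfg$fpkm_min & sm$mean_right >= cfg$fpkm_min
  sm <- sm[abundant, , drop = FALSE]
  lfc <- ifelse(sm$mean_left == 0 & sm$mean_right == 0, NA_real_,
                log2(sm$mean_right / sm$mean_left))
  direction <- rep("none", nrow(sm))
  direction[!is.na(lfc) & lfc > cfg$lfc_threshold] <- "right"
  direction[!is.na(lfc) & lfc < -cfg$lfc_threshold] <- "left"
  out <- data.frame(feature_id = sm$id, stage = stage,
                    mean_left = sm$mean_left, mean_right = sm$mean_right,
                    log2fc = lfc, direction = direction, abundant = TRUE,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$log2fc), out$feature_id, method = "radix"), , drop = FALSE]
}

#' Summarise asymmetry calls against the transcriptome size
#'
#' The reported percentage uses the full transcriptome as denominator and is
#' rounded half-up to two decimals (so 1690 of 51408 reports 3.29).
#'
#' @param calls either the data.frame returned by
#'   [call_expression_asymmetry()] (or [call_mirna_asymmetry()]), or a
#'   single count of asymmetric features.
#' @param total_transcripts number of transcripts investigated (> 0).
#' @return list with `n_asym`, `n_left`, `n_right` (NA when `calls` is a
#'   bare count) and `pct`.
#' @export
#' @examples
#' summarize_expression(1690, 51408)$pct  # 3.29
summarize_expression <- function(calls, total_transcripts) {
  if (length(total_transcripts) != 1 || !isTRUE(total_transcripts > 0))
    sa_stop("value_error", "total_transcripts must be a single positive number")
  if (is.data.frame(calls)) {
    n_left <- sum(calls$direction == "left")
    n_right <- sum(calls$direction == "right")
    n_asym <- n_left + n_right
  } else if (is.numeric(calls) && length(calls) == 1) {
    n_asym <- as.integer(calls); n_left <- NA_integer_; n_right <- NA_integer_
  } else {
    sa_stop("value_error", "calls must be a call data.frame or a single count")
  }
  if (n_asym > total_transcripts)
    sa_stop("value_error", "n_asym exceeds total_transcripts")
  list(n_asym = n_asym, n_left = n_left, n_right = n_right,
       pct = round_half_up(100 * n_asym / total_transcripts, 2))
}
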