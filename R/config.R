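#' Analysis thresholds
#'
#' Bundles every numeric constant used by the asymmetry-calling rules into a
#' single list so a whole analysis is reproducible from one object.
#'
#' The defaults implement the study design this package targets:
#' \describe{
#'   \item{lfc_threshold}{log2 fold-change threshold (log2 units). mRNA
#'     calls use a strict `>`; miRNA calls use a minimum rule `>=`.}
#'   \item{fpkm_min}{abundance floor: a gene must have mean FPKM at least
#'     this value on *both* sides to be tested.}
#'   \item{mirna_min_reads}{a miRNA is dropped when its read count is below
#'     this on *both* sides.}
#'   \item{target_prob_min}{miRNA-target interaction probability; strict `>`.}
#'   \item{fdr_q}{FDR-adjusted p-value threshold for differential CpG
#'     methylation; strict `<`.}
#'   \item{meth_diff_min}{minimum absolute left/right percent-methylation
#'     difference (percentage points); strict `>`.}
#'   \item{lq_threshold}{methylation laterality-quotient magnitude beyond
#'     which a gene's methylation is "strongly asymmetric"; strict
#'     `LQ > t` / `LQ < -t`.}
#'   \item{upstream_window}{promoter window in nucleotides upstream of the
#'     transcription start site included when assigning CpG sites to genes.}
#'   \item{mirna_lfc_strict}{if TRUE the miRNA rule also uses strict `>`
#'     instead of `>=`.}
#'   \item{low_count_either_side}{if TRUE a miRNA is removed when *either*
#'     side is below `mirna_min_reads` (alternative reading of the filter).}
#'   \item{min_coverage}{minimum per-side read coverage for a CpG to enter
#'     the differential test.}
#'   \item{ignore_strand}{if TRUE the promoter window is always to the left
#'     of `start`, regardless of gene strand.}
#'   \item{mirna_direction_consistent}{if TRUE, "explained by miRNA"
#'     additionally requires the targeting miRNA to be asymmetric towards
#'     the side where the gene is *lower* expressed (repression-consistent);
#'     off by default.}
#' }
#'
#' @param lfc_threshold positive real, default 1.5 (log2 units).
#' @param fpkm_min non-negative real, default 1.
#' @param mirna_min_reads positive integer, default 10.
#' @param target_prob_min real in \[0,1\], default 0.8.
#' @param fdr_q real in (0,1\], default 0.01.
#' @param meth_diff_min percentage points, default 25.
#' @param lq_threshold real in (0,100), default 25.
#' @param upstream_window non-negative integer (nt), default 1500.
#' @param mirna_lfc_strict logical, default FALSE.
#' @param low_count_either_side logical, default FALSE.
#' @param min_coverage positive integer, default 1.
#' @param ignore_strand logical, default FALSE.
#' @param mirna_direction_consistent logical, default FALSE.
#' @return a list of class `"threshold_config"`.
#' @export
#' @examples
#' cfg <- threshold_config()
#' cfg$lfc_threshold
threshold_config <- function(lfc_threshold = 1.5,
                             fpkm_min = 1,
                             mirna_min_reads = 10L,
                             target_prob_min = 0.8,
                             fdr_q = 0.01,
                             meth_diff_min = 25,
                             lq_threshold = 25,
                             upstream_window = 1500L,
                             mirna_lfc_strict = FALSE,
                             low_count_either_side = FALSE,
                             min_coverage = 1L,
                             ignore_strand = FALSE,
                             mirna_direction_consistent = FALSE) {
  if (!is.finite(lfc_threshold) || lfc_threshold <= 0)
    sa_stop("config_error", "lfc_threshold must be a finite positive number")
  if (!is.finite(fpkm_min) || fpkm_min < 0)
    sa_stop("config_error", "fpkm_min must be non-negative")
  if (mirna_min_reads < 1)
    sa_stop("config_error", "mirna_min_reads must be >= 1")
  if (target_prob_min < 0 || target_prob_min > 1)
    sa_stop("config_error", "target_prob_min must be in [0,1]")
  if (fdr_q <= 0 || fdr_q > 1)
    sa_stop("config_error", "fdr_q must be in (0,1]")
  if (meth_diff_min < 0 || meth_diff_min > 100)
    sa_stop("config_error", "meth_diff_min must be in [0,100]")
  if (lq_threshold < 0 || lq_threshold > 100)
    sa_stop("config_error", "lq_threshold must be in [0,100]")
  if (upstream_window < 0)
    sa_stop("config_error", "upstream_window must be >= 0")
  structure(list(
    lfc_threshold = lfc_threshold,
    fpkm_min = fpkm_min,
    mirna_min_reads = as.integer(mirna_min_reads),
    target_prob_min = target_prob_min,
    fdr_q = fdr_q,
    meth_diff_min = meth_diff_min,
    lq_threshold = lq_threshold,
    upstream_window = as.integer(upstream_window),
    mirna_lfc_strict = isTRUE(mirna_lfc_strict),
    low_count_either_side = isTRUE(low_count_either_side),
    min_coverage = as.integer(min_coverage),
    ignore_strand = isTRUE(ignore_strand),
    mirna_direction_consistent = isTRUE(mirna_direction_consistent)
  ), class = "threshold_config")
}

as_threshold_config <- function(cfg) {
  if (is.null(cfg)) return(threshold_config())
  if (inherits(cfg, "threshold_config")) return(cfg)
  if (is.list(cfg)) return(do.call(threshold_config, cfg))
  sa_stop("config_error", "cfg must be NULL, a list, or a threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Threshold configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
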