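# End-to-end orchestration: expression calls, miRNA calls, consensus CpGs,
# CpG-to-gene assignment, and the explained/unexplained partition, per
# developmental stage.

#' Run the full left/right asymmetry pipeline
#'
#' For every requested stage: (1) call per-gene expression asymmetry;
#' (2) low-count-filter the miRNA counts, call miRNA asymmetry and collect
#' the asymmetric miRNAs' high-probability target genes; (3) test per-CpG
#' differential methylation in each of the stage's samples and form the
#' cross-sample consensus; (4) assign consensus CpGs to genes, compute the
#' per-gene laterality quotient, and partition the asymmetrically expressed
#' genes into methylation-explained / miRNA-explained / both / unexplained.
#'
#' @param bundle named list with elements `expression`, `mirna`, `cpg`,
#'   `genes`, `targets` (validated tables, as produced by the `read_*`
#'   functions or by [generate_dataset()]).
#' @param cfg a [threshold_config()].
#' @param stages stages to analyse; default: all stages present in the
#'   expression table.
#' @return object of class `spinasym_report`: a list with one element per
#'   stage (`expression`, `mirna`, `methylation`, `profile`, `partitions`,
#'   `summary`) plus the `cfg` used.
#' @export
run_pipeline <- function(bundle, cfg = NULL, stages = NULL) {
  cfg <- as_threshold_config(cfg)
  for (el in c("expression", "mirna", "cpg", "genes", "targets"))
    if (is.null(bundle[[el]]))
      sa_stop("value_error", "bundle is missing element '%s'", el)
  expr <- validate_expression_table(bundle$expression)
  mirna <- validate_mirna_table(bundle$mirna)
  cpg <- validate_cpg_table(bundle$cpg)
  genes <- validate_gene_models(bundle$genes)
  targets <- validate_target_map(bundle$targets)
  if (is.null(stages)) {
    stages <- intersect(stages_known, unique(expr$stage))
  } else {
    stages <- normalize_stage(stages)
  }

  report <- list(cfg = cfg, stages = list())
  for (st in stages) {
    if (!st %in% expr$stage)
      sa_stop("stage_error", "stage %s: no expression rows", st)
    res <- tryCatch({
      expr_calls <- call_expression_asymmetry(expr, st, cfg)
      n_total <- length(unique(expr$feature_id[expr$stage == st]))

      kept <- filter_low_count(mirna, st, cfg)
      mirna_calls <- call_mirna_asymmetry(kept, st, cfg)
      gene_dirs <- stats::setNames(expr_calls$direction, expr_calls$feature_id)
      target_genes <- targets_of_asymmetric(mirna_calls, targets, cfg,
                                            gene_directions = gene_dirs)

      samples <- sort(unique(cpg$sample_id[cpg$stage == st]), method = "radix")
      per_sample <- lapply(samples, function(s)
        call_diff_methylation(cpg, st, s, cfg))
      consensus <- if (length(per_sample) > 0) {
        consensus_across_samples(per_sample, st)
      } else {
        consensus_across_samples(
          list(call_diff_methylation(cpg[0, , drop = FALSE], st, "none", cfg)),
          st)
      }

      profile <- gene_methylation_profile(consensus, genes, cfg)
      asym <- expr_calls[expr_calls$direction != "none", , drop = FALSE]
      lq <- profile$lq[match(asym$feature_id, profile$gene_id)]
      partitions <- data.frame(
        gene_id = asym$feature_id, stage = rep(st, nrow(asym)),
        expr_direction = asym$direction,
        chrom = genes$chrom[match(asym$feature_id, genes$gene_id)],
        log2fc = asym$log2fc, lq = lq,
        is_target = asym$feature_id %in% target_genes,
        stringsAsFactors = FALSE)
      partitions$category <- if (nrow(partitions) > 0) {
        classify_gene(partitions$expr_direction, partitions$lq,
                      partitions$is_target, cfg)
      } else character(0)

      expr_sum <- summarize_expression(expr_calls, max(n_total, 1L))
      mirna_n <- length(unique(mirna_calls$mirna_id))
      mirna_sum <- if (mirna_n > 0) {
        summarize_expression(mirna_calls, mirna_n)
      } else {
        list(n_asym = 0L, n_left = 0L, n_right = 0L, pct = NA_real_)
      }
      part_sum <- if (nrow(partitions) > 0) {
        partition_summary(partitions, nrow(partitions))
      } else NULL
      summary <- list(
        stage = st,
        expression = c(expr_sum, list(n_tested = nrow(expr_calls),
                                      n_total = n_total)),
        mirna = c(mirna_sum, list(n_expressed = mirna_n,
                                  n_target_genes = length(target_genes))),
        methylation = list(
          n_samples = length(samples),
          n_consensus = nrow(consensus),
          n_consensus_left = sum(consensus$direction == "left"),
          n_consensus_right = sum(consensus$direction == "right")),
        partition = part_sum)

      list(expression = expr_calls, mirna = mirna_calls,
           target_genes = target_genes, per_sample_methylation = per_sample,
           consensus = consensus, profile = profile, partitions = partitions,
           summary = summary)
    }, spinasym_error = function(e) {
      sa_stop(class(e)[1], "stage %s: %s", st, conditionMessage(e))
    })
    report$stages[[st]] <- res
  }
  class(report) <- "spinasym_report"
  report
}

#' @export
print.spinasym_report <- function(x, ...) {
  cat("Left/right asymmetry report\n")
  for (st in names(x$stages)) {
    s <- x$stages[[st]]$summary
    cat(sprintf("\nStage %s:\n", st))
    cat(sprintf("  expression: %d asymmetric of %d (%s%%; left %d, right %d)\n",
                s$expression$n_asym, s$expression$n_total,
                format(s$expression$pct), s$expression$n_left,
                s$expression$n_right))
    cat(sprintf("  miRNA: %d asymmetric of %d kept; %d target genes\n",
                s$mirna$n_asym, s$mirna$n_expressed, s$mirna$n_target_genes))
    cat(sprintf("  methylation: %d consensus CpGs (left %d, right %d)\n",
                s$methylation$n_consensus, s$methylation$n_consensus_left,
                s$methylation$n_consensus_right))
    if (!is.null(s$partition)) {
      p <- s$partition
      cat(sprintf(
        "  partition: methylation %d%% | both %d%% | miRNA %d%% | unexplained %d%%\n",
        p$pct["methylation_only"], p$pct["both"], p$pct["mirna_only"],
        p$pct["unexplained"]))
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits, per stage, `expr_calls_<stage>.tsv`, `mirna_calls_<stage>.tsv`,
#' `consensus_<stage>.tsv` (BED-convertible: 1-based `pos` plus the
#' 0-based `pos0` column) and `partitions_<stage>.tsv`, plus a single
#' `summary.json` covering all stages. Deterministic for a given report.
#'
#' @param report object from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(report$stages)) {
    r <- report$stages[[st]]
    write_canonical(r$expression, file.path(dir, sprintf("expr_calls_%s.tsv", st)))
    write_canonical(r$mirna, file.path(dir, sprintf("mirna_calls_%s.tsv", st)))
    cons <- r$consensus
    cons$pos0 <- cons$pos - 1L
    write_canonical(cons, file.path(dir, sprintf("consensus_%s.tsv", st)))
    write_canonical(r$partitions, file.path(dir, sprintf("partitions_%s.tsv", st)))
  }
  summaries <- lapply(report$stages, function(r) r$summary)
  jsonlite::write_json(summaries, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
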