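# Readers and writers for the tabular interchange formats.
#
# All quantitative tables are TSV with mandatory headers; gene models are
# BED6 (0-based half-open, native) or GTF (1-based closed, converted at the
# boundary). Internal coordinates are 0-based half-open everywhere. CpG
# positions are the 1-based position of the cytosine on the annotated
# strand; +/- strand CpGs are never collapsed into dinucleotide units.

expr_cols   <- c("feature_id", "sample_id", "stage", "side", "fpkm")
mirna_cols  <- c("mirna_id", "sample_id", "stage", "side",
                 "read_count", "transcript_length", "library_size")
cpg_cols    <- c("chrom", "pos", "strand", "sample_id", "stage", "side",
                 "coverage", "methylated")
gene_cols   <- c("gene_id", "chrom", "start", "end", "strand")
target_cols <- c("mirna_id", "gene_id", "probability")

sides_known <- c("left", "right")

read_tsv_strict <- function(path, what) {
  if (!file.exists(path))
    sa_stop("io_error", "%s: file not found: %s", what, path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

check_side <- function(df, what) {
  bad <- which(!df$side %in% sides_known)
  if (length(bad) > 0)
    sa_stop("value_error", "%s: invalid side '%s' at row %d",
            what, df$side[bad[1]], bad[1])
}

check_unique <- function(df, keys, what) {
  key <- do.call(paste, c(df[keys], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    sa_stop("uniqueness_error",
            "%s: duplicate (%s) at row %d", what,
            paste(keys, collapse = ","), dup[1])
}

#' Validate a gene expression table
#'
#' Checks the schema (`feature_id, sample_id, stage, side, fpkm`), value
#' ranges (FPKM >= 0), key uniqueness, stage labels (gestational-age
#' synonyms are normalised to `wk8/wk10/wk12`) and that every
#' (feature, sample) pair has both a left and a right measurement.
#'
#' @param df data.frame to validate.
#' @return the validated data.frame, stages normalised, invisibly usable.
#' @export
validate_expression_table <- function(df) {
  check_columns(df, expr_cols, "expression table")
  df <- df[expr_cols]
  check_side(df, "expression table")
  df$stage <- normalize_stage(df$stage)
  bad <- which(!is.finite(df$fpkm) | df$fpkm < 0)
  if (length(bad) > 0)
    sa_stop("value_error", "expression table: negative or non-finite fpkm at row %d",
            bad[1])
  check_unique(df, c("feature_id", "sample_id", "side"), "expression table")
  # both sides present for every (feature, sample)
  key <- paste(df$feature_id, df$sample_id, sep = "\r")
  n_sides <- tapply(df$side, key, function(s) length(unique(s)))
  if (any(n_sides != 2L)) {
    k <- names(n_sides)[which(n_sides != 2L)[1]]
    sa_stop("pairing_error",
            "expression table: feature/sample '%s' lacks one side",
            gsub("\r", "/", k))
  }
  df
}

#' Read a gene expression table from TSV
#'
#' @param path TSV file with header `feature_id, sample_id, stage, side, fpkm`.
#' @return validated expression data.frame.
#' @seealso [validate_expression_table()]
#' @export
read_expression <- function(path) {
  validate_expression_table(read_tsv_strict(path, "expression table"))
}

#' Validate a miRNA count table
#'
#' Schema `mirna_id, sample_id, stage, side, read_count, transcript_length,
#' library_size`; enforces `0 <= read_count <= library_size` and
#' `transcript_length > 0`.
#'
#' @param df data.frame to validate.
#' @return validated data.frame.
#' @export
validate_mirna_table <- function(df) {
  check_columns(df, mirna_cols, "miRNA table")
  df <- df[mirna_cols]
  check_side(df, "miRNA table")
  df$stage <- normalize_stage(df$stage)
  for (col in c("read_count", "transcript_length", "library_size"))
    df[[col]] <- as.integer(df[[col]])
  bad <- which(df$read_count < 0 | df$read_count > df$library_size)
  if (length(bad) > 0)
    sa_stop("value_error",
            "miRNA table: read_count outside [0, library_size] at row %d", bad[1])
  bad <- which(df$transcript_length <= 0)
  if (length(bad) > 0)
    sa_stop("value_error", "miRNA table: non-positive transcript_length at row %d",
            bad[1])
  bad <- which(df$library_size <= 0)
  if (length(bad) > 0)
    sa_stop("value_error", "miRNA table: non-positive library_size at row %d", bad[1])
  check_unique(df, c("mirna_id", "sample_id", "side"), "miRNA table")
  df
}

#' Read a miRNA count table from TSV
#'
#' @param path TSV file with header `mirna_id, sample_id, stage, side,
#'   read_count, transcript_length, library_size`.
#' @return validated data.frame.
#' @export
read_mirna_counts <- function(path) {
  validate_mirna_table(read_tsv_strict(path, "miRNA table"))
}

#' Validate a per-CpG methylation call table
#'
#' Schema `chrom, pos, strand, sample_id, stage, side, coverage, methylated`;
#' `pos` is the 1-based position of the CpG cytosine on the annotated strand.
#' Enforces `0 <= methylated <= coverage`, `coverage >= 1` and uniqueness of
#' `(chrom, pos, strand, sample_id, side)`.
#'
#' @param df data.frame to validate.
#' @return validated data.frame.
#' @export
validate_cpg_table <- function(df) {
  check_columns(df, cpg_cols, "CpG table")
  df <- df[cpg_cols]
  check_side(df, "CpG table")
  df$stage <- normalize_stage(df$stage)
  df$pos <- as.integer(df$pos)
  df$coverage <- as.integer(df$coverage)
  df$methylated <- as.integer(df$methylated)
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0)
    sa_stop("value_error", "CpG table: invalid strand at row %d", bad[1])
  bad <- which(df$coverage < 1)
  if (length(bad) > 0)
    sa_stop("value_error", "CpG table: coverage < 1 at row %d", bad[1])
  bad <- which(df$methylated < 0 | df$methylated > df$coverage)
  if (length(bad) > 0)
    sa_stop("value_error",
            "CpG table: methylated outside [0, coverage] at row %d", bad[1])
  check_unique(df, c("chrom", "pos", "strand", "sample_id", "side"), "CpG table")
  df
}

#' Read a per-CpG methylation table from TSV
#'
#' @param path TSV file with header `chrom, pos, strand, sample_id, stage,
#'   side, coverage, methylated`.
#' @return validated data.frame.
#' @export
read_cpg_calls <- function(path) {
  validate_cpg_table(read_tsv_strict(path, "CpG table"))
}

#' Validate a gene model set
#'
#' Coordinates must already be 0-based half-open (`start < end`); `gene_id`
#' unique; strand `+`/`-`.
#'
#' @param df data.frame with columns `gene_id, chrom, start, end, strand`.
#' @return validated data.frame.
#' @export
validate_gene_models <- function(df) {
  check_columns(df, gene_cols, "gene models")
  df <- df[gene_cols]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0)
    sa_stop("value_error", "gene models: invalid strand at row %d", bad[1])
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad) > 0)
    sa_stop("coordinate_error",
            "gene models: start >= end (or start < 0) at row %d", bad[1])
  dup <- which(duplicated(df$gene_id))
  if (length(dup) > 0)
    sa_stop("uniqueness_error", "gene models: duplicate gene_id at row %d", dup[1])
  df
}

#' Read gene models from BED6 or GTF
#'
#' The dialect must be declared explicitly; coordinates are normalised to a
#' single internal convention, 0-based half-open. BED is native; a GTF
#' interval `[s, e]` (1-based closed) becomes `[s-1, e)` so its stored
#' length is `e - s + 1`.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"gtf"`.
#' @param gtf_feature GTF feature type to keep (default `"gene"`; use `NULL`
#'   to keep all rows).
#' @return validated gene model data.frame (`gene_id, chrom, start, end,
#'   strand`), 0-based half-open.
#' @export
read_gene_models <- function(path, dialect = c("bed", "gtf"),
                             gtf_feature = "gene") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    sa_stop("io_error", "gene models: file not found: %s", path)
  if (dialect == "bed") {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 6)
      sa_stop("schema_error", "gene models: BED6 requires 6 columns")
    df <- data.frame(gene_id = as.character(raw[[4]]),
                     chrom = as.character(raw[[1]]),
                     start = as.integer(raw[[2]]),
                     end = as.integer(raw[[3]]),
                     strand = as.character(raw[[6]]),
                     stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(raw) < 9)
      sa_stop("schema_error", "gene models: GTF requires 9 columns")
    if (!is.null(gtf_feature)) raw <- raw[raw[[3]] == gtf_feature, , drop = FALSE]
    ids <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", raw[[9]])
    df <- data.frame(gene_id = ids,
                     chrom = as.character(raw[[1]]),
                     start = as.integer(raw[[4]]) - 1L,  # 1-based closed -> 0-based half-open
                     end = as.integer(raw[[5]]),
                     strand = as.character(raw[[7]]),
                     stringsAsFactors = FALSE)
  }
  validate_gene_models(df)
}

#' Validate a miRNA-target interaction table
#'
#' Schema `mirna_id, gene_id, probability`; probability in \[0,1\];
#' `(mirna_id, gene_id)` unique.
#'
#' @param df data.frame to validate.
#' @return validated data.frame.
#' @export
validate_target_map <- function(df) {
  check_columns(df, target_cols, "target map")
  df <- df[target_cols]
  bad <- which(!is.finite(df$probability) |
                 df$probability < 0 | df$probability > 1)
  if (length(bad) > 0)
    sa_stop("value_error", "target map: probability outside [0,1] at row %d",
            bad[1])
  check_unique(df, c("mirna_id", "gene_id"), "target map")
  df
}

#' Read a miRNA-target interaction table from TSV
#'
#' @param path TSV file with header `mirna_id, gene_id, probability`.
#' @return validated data.frame.
#' @export
read_target_map <- function(path) {
  validate_target_map(read_tsv_strict(path, "target map"))
}

# ---- canonical writers ------------------------------------------------------

# One fixed column order and row sort per table type, so outputs are
# deterministic and read -> write -> read is an identity.

canonical_sort <- function(df, keys) {
  df[do.call(sa_order, df[keys]), , drop = FALSE]
}

write_canonical <- function(df, path, header = TRUE) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = header, eol = "\n")
  invisible(path)
}

#' Write tables in canonical TSV/BED form
#'
#' Writers emit the schema columns in canonical order with rows sorted on
#' the table's natural key, so that writing the result of a read reproduces
#' a canonical file byte-identically. `write_gene_models()` emits BED6
#' (score column `.`), matching the 0-based half-open internal convention.
#'
#' @param df a validated table of the corresponding type.
#' @param path output file path.
#' @return the path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_expression <- function(df, path) {
  df <- validate_expression_table(df)
  write_canonical(canonical_sort(df, c("stage", "feature_id", "sample_id", "side")),
                  path)
}

#' @rdname writers
#' @export
write_mirna_counts <- function(df, path) {
  df <- validate_mirna_table(df)
  write_canonical(canonical_sort(df, c("stage", "mirna_id", "sample_id", "side")),
                  path)
}

#' @rdname writers
#' @export
write_cpg_calls <- function(df, path) {
  df <- validate_cpg_table(df)
  write_canonical(
    canonical_sort(df, c("stage", "chrom", "pos", "strand", "sample_id", "side")),
    path)
}

#' @rdname writers
#' @export
write_gene_models <- function(df, path) {
  df <- validate_gene_models(df)
  df <- canonical_sort(df, c("chrom", "start", "gene_id"))
  bed <- data.frame(df$chrom, df$start, df$end, df$gene_id, ".", df$strand)
  write_canonical(bed, path, header = FALSE)
}

#' @rdname writers
#' @export
write_target_map <- function(df, path) {
  df <- validate_target_map(df)
  write_canonical(canonical_sort(df, c("mirna_id", "gene_id")), path)
}
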