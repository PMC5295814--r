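# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so that
#' e.g. 2.785 prints as 2.79 rather than R's default round-half-even 2.78.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13
#' round_half_up(2.5, 0)    # 3
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Stop with a class so callers/tests can distinguish error kinds.
sa_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "spinasym_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Locale-independent ordering (radix) for deterministic output tables.
sa_order <- function(...) order(..., method = "radix")

stages_known <- c("wk8", "wk10", "wk12")

#' Normalise developmental-stage labels
#'
#' Canonical stage labels are weeks post conception: `"wk8"`, `"wk10"`,
#' `"wk12"`. Gestational-age synonyms (post conception + 2 weeks) are
#' accepted on input and normalised: `"10"` -> `"wk8"`, `"12"` -> `"wk10"`,
#' `"14"` -> `"wk12"` (with or without a `"wk"` prefix is not accepted for
#' the gestational variants to avoid ambiguity).
#'
#' @param stage character vector of stage labels.
#' @return character vector of canonical labels.
#' @export
normalize_stage <- function(stage) {
  stage <- as.character(stage)
  ga_map <- c("10" = "wk8", "12" = "wk10", "14" = "wk12")
  out <- ifelse(stage %in% stages_known, stage,
                unname(ga_map[stage]))
  bad <- is.na(out)
  if (any(bad)) {
    sa_stop("stage_error", "unknown stage label(s): %s",
            paste(unique(stage[bad]), collapse = ", "))
  }
  out
}

# Check that a data.frame has exactly the required columns (order-free).
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    sa_stop("schema_error", "%s: missing column(s): %s",
            what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
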