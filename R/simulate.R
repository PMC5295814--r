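# Synthetic paired left/right multi-omic datasets with planted ground truth.
#
# The generator emulates the study design the pipeline targets: two
# replicate fetuses at the first two developmental stages and one at the
# last; a transcriptome in which a small fraction of genes is planted with
# a strong side bias; promoter/body CpG methylation planted in the
# direction *opposite* to expression for a configurable subset of the
# asymmetric genes; and miRNA-target coupling for another subset. Every
# planted feature is recorded in a ground-truth object so downstream calls
# can be scored.

run_with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults mirror the study design and effect scales the pipeline targets
#' (samples per stage 2/2/1; ~3.3% of genes asymmetric; exclusive
#' methylation- / miRNA- / both-coupling class shares echoing the 451, 47
#' and 18 of 1690 asymmetric genes of the motivating dataset; a planted
#' |log2 fold change| of 3; a 0.4 planted methylation-proportion gap;
#' 5-million-read miRNA libraries). Noise magnitudes are chosen for
#' testability, not measured from tissue.
#'
#' @param n_genes number of genes.
#' @param n_mirnas number of miRNAs.
#' @param n_samples_per_stage integer vector (recycled/named over
#'   `wk8, wk10, wk12`); default `c(2, 2, 1)`.
#' @param frac_asym_expr fraction of genes planted asymmetric.
#' @param right_bias share of planted asymmetric genes that are rightward.
#' @param planted_lfc true |log2 fold change| of asymmetric genes.
#' @param expr_noise_sd sd of multiplicative lognormal FPKM noise
#'   (natural-log scale).
#' @param frac_meth_coupled share of asymmetric genes in the exclusive
#'   methylation-explained class.
#' @param frac_mirna_coupled share in the exclusive miRNA-explained class.
#' @param both_overlap share in the "both" class (explicit overlap
#'   parameter; the three class shares must sum to at most 1).
#' @param cpgs_per_gene CpG sites simulated per gene (body plus one
#'   promoter site 500 nt upstream of the TSS).
#' @param cpg_coverage_mean mean Poisson read coverage per CpG and side
#'   (floored at 1).
#' @param meth_delta planted left-right methylation-proportion difference
#'   for coupled genes, in (0,1]; sign always opposite to the gene's
#'   expression direction.
#' @param library_size nominal miRNA library size (reads; jittered ±10%
#'   per sample/side).
#' @param frac_asym_mirna fraction of miRNAs planted asymmetric.
#' @param mirna_right_bias share of asymmetric miRNAs that are rightward.
#' @param planted_mirna_lfc true |log2 fold change| of asymmetric miRNAs.
#' @param mirna_dispersion negative-binomial size parameter for miRNA
#'   counts (larger = less overdispersed).
#' @param gene_length,intergenic_gap toy gene model geometry (nt). The gap
#'   exceeds the default 1500-nt promoter window so windows never collide.
#' @param n_chroms number of toy chromosomes genes are spread over.
#' @param seed RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_mirnas = 300L,
                             n_samples_per_stage = c(2L, 2L, 1L),
                             frac_asym_expr = 0.0329,
                             right_bias = 0.5,
                             planted_lfc = 3,
                             expr_noise_sd = 0.2,
                             frac_meth_coupled = 451 / 1690,
                             frac_mirna_coupled = 47 / 1690,
                             both_overlap = 18 / 1690,
                             cpgs_per_gene = 10L,
                             cpg_coverage_mean = 60,
                             meth_delta = 0.4,
                             library_size = 5e6,
                             frac_asym_mirna = 5 / 301,
                             mirna_right_bias = 1,
                             planted_mirna_lfc = 3,
                             mirna_dispersion = 50,
                             gene_length = 2000L,
                             intergenic_gap = 4000L,
                             n_chroms = 1L,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              n_samples_per_stage = n_samples_per_stage,
              frac_asym_expr = frac_asym_expr, right_bias = right_bias,
              planted_lfc = planted_lfc, expr_noise_sd = expr_noise_sd,
              frac_meth_coupled = frac_meth_coupled,
              frac_mirna_coupled = frac_mirna_coupled,
              both_overlap = both_overlap,
              cpgs_per_gene = as.integer(cpgs_per_gene),
              cpg_coverage_mean = cpg_coverage_mean, meth_delta = meth_delta,
              library_size = library_size,
              frac_asym_mirna = frac_asym_mirna,
              mirna_right_bias = mirna_right_bias,
              planted_mirna_lfc = planted_mirna_lfc,
              mirna_dispersion = mirna_dispersion,
              gene_length = as.integer(gene_length),
              intergenic_gap = as.integer(intergenic_gap),
              n_chroms = as.integer(n_chroms), seed = as.integer(seed))
  fracs <- c("frac_asym_expr", "right_bias", "frac_meth_coupled",
             "frac_mirna_coupled", "both_overlap", "frac_asym_mirna",
             "mirna_right_bias")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      sa_stop("config_error", "%s must lie in [0,1] (got %s)", f, format(v))
  }
  if (cfg$frac_meth_coupled + cfg$frac_mirna_coupled + cfg$both_overlap > 1)
    sa_stop("config_error",
            "coupling class fractions (incl. both_overlap) exceed 1")
  if (cfg$n_genes < 1 || cfg$n_mirnas < 1)
    sa_stop("config_error", "n_genes and n_mirnas must be positive")
  if (any(cfg$n_samples_per_stage < 1))
    sa_stop("config_error", "n_samples_per_stage must be positive")
  if (cfg$meth_delta <= 0 || cfg$meth_delta > 1)
    sa_stop("config_error", "meth_delta must lie in (0,1]")
  if (cfg$expr_noise_sd < 0)
    sa_stop("config_error", "expr_noise_sd must be non-negative")
  if (cfg$planted_lfc <= 0 || cfg$planted_mirna_lfc <= 0)
    sa_stop("config_error", "planted fold changes must be positive")
  if (cfg$intergenic_gap <= 2L * 1500L - cfg$gene_length)
    cfg$intergenic_gap <- as.integer(2L * 1500L)  # keep windows collision-free
  n <- rep_len(as.integer(cfg$n_samples_per_stage), 3L)
  cfg$n_samples_per_stage <- stats::setNames(n, stages_known)
  structure(cfg, class = "synthetic_config")
}

pick_first <- function(x, n) if (n > 0) x[seq_len(n)] else x[0]

#' Generate a synthetic paired left/right multi-omic dataset
#'
#' Deterministic given `config$seed` (the caller's RNG state is restored on
#' exit). Baseline FPKM is lognormal around a positive median with
#' multiplicative lognormal noise; planted asymmetric genes have side-mean
#' ratio `2^planted_lfc` (baselines floored at 4 FPKM so the low side
#' survives the abundance filter); miRNA counts are negative binomial,
#' thinned on one side for planted asymmetric miRNAs; CpG coverage is
#' Poisson floored at 1 with binomial methylated counts; coupled genes'
#' CpGs get side proportions differing by `meth_delta` opposite to the
#' expression direction; miRNA-coupled genes receive a > 0.8 interaction
#' probability under a planted asymmetric miRNA. Gene models tile toy
#' chromosomes with intergenic gaps wide enough that promoter windows never
#' reach a neighbouring gene's CpGs.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `expression`, `mirna`, `cpg`, `genes`,
#'   `targets` (validated tables) and `truth` (list of `genes`, `mirnas`,
#'   `cpgs` ground-truth data.frames plus the `config`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  run_with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  ng <- cfg$n_genes; nm <- cfg$n_mirnas
  gene_ids <- sprintf("g%05d", seq_len(ng))
  mirna_ids <- sprintf("mir%04d", seq_len(nm))
  stages <- stages_known
  nspst <- cfg$n_samples_per_stage
  sample_ids <- lapply(stages, function(st)
    sprintf("s_%s_%d", st, seq_len(nspst[st])))
  names(sample_ids) <- stages

  # --- gene models: tiled toy chromosomes, alternating strand -------------
  per_chrom <- ceiling(ng / cfg$n_chroms)
  chrom_of <- rep(sprintf("chr%d", seq_len(cfg$n_chroms)),
                  each = per_chrom)[seq_len(ng)]
  idx_in_chrom <- stats::ave(seq_len(ng), chrom_of, FUN = seq_along)
  pitch <- cfg$gene_length + cfg$intergenic_gap
  start <- (idx_in_chrom - 1L) * pitch + cfg$intergenic_gap
  genes <- data.frame(gene_id = gene_ids, chrom = chrom_of,
                      start = start, end = start + cfg$gene_length,
                      strand = rep_len(c("+", "-"), ng),
                      stringsAsFactors = FALSE)

  # --- planted truth: directions and coupling classes ---------------------
  n_asym <- as.integer(round_half_up(cfg$frac_asym_expr * ng))
  asym_idx <- sample(ng, n_asym)
  n_right <- as.integer(round_half_up(cfg$right_bias * n_asym))
  direction <- rep("none", ng)
  direction[pick_first(asym_idx, n_right)] <- "right"
  direction[asym_idx[direction[asym_idx] == "none"]] <- "left"
  n_both <- as.integer(round_half_up(cfg$both_overlap * n_asym))
  n_meth <- as.integer(round_half_up(cfg$frac_meth_coupled * n_asym))
  n_mir <- as.integer(round_half_up(cfg$frac_mirna_coupled * n_asym))
  if (n_both + n_meth + n_mir > n_asym)
    n_mir <- n_asym - n_both - n_meth
  coupling <- rep("none", ng)
  coupling[pick_first(asym_idx, n_both)] <- "both"
  coupling[asym_idx[seq_len(n_meth) + n_both]] <- if (n_meth > 0) "methylation" else character(0)
  coupling[asym_idx[seq_len(n_mir) + n_both + n_meth]] <- if (n_mir > 0) "mirna" else character(0)
  truth_genes <- data.frame(gene_id = gene_ids, direction = direction,
                            coupling = coupling, stringsAsFactors = FALSE)

  # --- expression table ---------------------------------------------------
  base <- stats::rlnorm(ng, meanlog = log(8), sdlog = 1)
  base[direction != "none"] <- pmax(base[direction != "none"], 4)
  gain <- 2^cfg$planted_lfc
  rows <- list()
  for (st in stages) {
    for (s in sample_ids[[st]]) {
      for (sd_ in c("left", "right")) {
        mu <- base
        mu[direction == "right" & sd_ == "right"] <-
          mu[direction == "right" & sd_ == "right"] * gain
        mu[direction == "left" & sd_ == "left"] <-
          mu[direction == "left" & sd_ == "left"] * gain
        noise <- stats::rlnorm(ng, meanlog = 0, sdlog = cfg$expr_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = gene_ids, sample_id = s, stage = st, side = sd_,
          fpkm = mu * noise, stringsAsFactors = FALSE)
      }
    }
  }
  expression <- do.call(rbind, rows)

  # --- miRNA counts (one library per stage, mirroring the design that
  # --- small-RNA material suffices in a single sample per stage) ----------
  n_asym_mirna <- max(0L, as.integer(round_half_up(cfg$frac_asym_mirna * nm)))
  m_dir <- rep("none", nm)
  if (n_asym_mirna > 0) {
    m_idx <- sample(nm, n_asym_mirna)
    n_mr <- as.integer(round_half_up(cfg$mirna_right_bias * n_asym_mirna))
    m_dir[pick_first(m_idx, n_mr)] <- "right"
    m_dir[m_idx[m_dir[m_idx] == "none"]] <- "left"
  }
  truth_mirnas <- data.frame(mirna_id = mirna_ids, direction = m_dir,
                             stringsAsFactors = FALSE)
  tlen <- as.integer(round(stats::runif(nm, 20, 24)))
  mbase <- stats::rlnorm(nm, meanlog = log(200), sdlog = 1)
  mbase[m_dir != "none"] <- pmax(mbase[m_dir != "none"], 50)
  mgain <- 2^cfg$planted_mirna_lfc
  rows <- list()
  for (st in stages) {
    s <- sample_ids[[st]][1]
    for (sd_ in c("left", "right")) {
      lib <- as.integer(round(cfg$library_size * stats::runif(1, 0.9, 1.1)))
      mu <- mbase
      mu[m_dir == "right" & sd_ == "right"] <-
        mu[m_dir == "right" & sd_ == "right"] * mgain
      mu[m_dir == "left" & sd_ == "left"] <-
        mu[m_dir == "left" & sd_ == "left"] * mgain
      counts <- stats::rnbinom(nm, mu = mu, size = cfg$mirna_dispersion)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mirna_ids, sample_id = s, stage = st, side = sd_,
        read_count = counts, transcript_length = tlen, library_size = lib,
        stringsAsFactors = FALSE)
    }
  }
  mirna <- do.call(rbind, rows)

  # --- target map ---------------------------------------------------------
  coupled_gene_idx <- which(coupling %in% c("mirna", "both"))
  asym_mirna_ids <- mirna_ids[m_dir != "none"]
  tgt <- list()
  if (length(coupled_gene_idx) > 0 && length(asym_mirna_ids) > 0) {
    reg <- rep_len(asym_mirna_ids, length(coupled_gene_idx))
    tgt[[1]] <- data.frame(mirna_id = reg,
                           gene_id = gene_ids[coupled_gene_idx],
                           probability = stats::runif(length(coupled_gene_idx),
                                                      0.85, 0.99),
                           stringsAsFactors = FALSE)
  }
  # background links: low probability everywhere; high-probability decoys
  # only from non-asymmetric miRNAs to non-asymmetric genes
  n_bg <- 5L * nm
  bg <- data.frame(mirna_id = mirna_ids[sample(nm, n_bg, replace = TRUE)],
                   gene_id = gene_ids[sample(ng, n_bg, replace = TRUE)],
                   probability = stats::runif(n_bg, 0, 0.8),
                   stringsAsFactors = FALSE)
  tgt[[length(tgt) + 1L]] <- bg
  quiet_m <- mirna_ids[m_dir == "none"]
  quiet_g <- gene_ids[direction == "none"]
  if (length(quiet_m) > 0 && length(quiet_g) > 0) {
    n_dec <- min(50L, length(quiet_g))
    tgt[[length(tgt) + 1L]] <- data.frame(
      mirna_id = quiet_m[sample(length(quiet_m), n_dec, replace = TRUE)],
      gene_id = quiet_g[sample(length(quiet_g), n_dec)],
      probability = stats::runif(n_dec, 0.81, 0.99),
      stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, tgt)
  targets <- targets[!duplicated(paste(targets$mirna_id, targets$gene_id)), ,
                     drop = FALSE]

  # --- CpG methylation ----------------------------------------------------
  k <- cfg$cpgs_per_gene
  body_k <- max(k - 1L, 1L)
  offs <- as.integer(round(cfg$gene_length * (seq_len(body_k) - 0.5) / body_k))
  pos0 <- rep(genes$start, each = body_k) + rep(offs, times = ng)
  gene_of_cpg <- rep(seq_len(ng), each = body_k)
  if (k > 1L) {  # one promoter CpG 500 nt upstream of the TSS
    prom0 <- ifelse(genes$strand == "+", genes$start - 500L,
                    genes$end + 499L)
    pos0 <- c(pos0, prom0)
    gene_of_cpg <- c(gene_of_cpg, seq_len(ng))
  }
  ord <- order(gene_of_cpg, pos0, method = "radix")
  pos0 <- pos0[ord]; gene_of_cpg <- gene_of_cpg[ord]
  ncpg <- length(pos0)
  cpg_chrom <- genes$chrom[gene_of_cpg]
  coupled <- coupling[gene_of_cpg] %in% c("methylation", "both")
  gdir <- direction[gene_of_cpg]
  p0 <- stats::runif(ncpg, 0.2, 0.8)
  p0[coupled] <- 0.5
  half <- cfg$meth_delta / 2
  # opposite-direction planting: rightward expression -> hyper-methylated left
  p_left <- ifelse(coupled & gdir == "right", 0.5 + half,
                   ifelse(coupled & gdir == "left", 0.5 - half, p0))
  p_right <- ifelse(coupled & gdir == "right", 0.5 - half,
                    ifelse(coupled & gdir == "left", 0.5 + half, p0))
  p_left <- pmin(pmax(p_left, 0.01), 0.99)
  p_right <- pmin(pmax(p_right, 0.01), 0.99)
  truth_cpgs <- data.frame(chrom = cpg_chrom, pos = pos0 + 1L, strand = "+",
                           gene_id = gene_ids[gene_of_cpg],
                           p_left = p_left, p_right = p_right,
                           stringsAsFactors = FALSE)
  rows <- list()
  for (st in stages) {
    for (s in sample_ids[[st]]) {
      for (sd_ in c("left", "right")) {
        cov <- pmax(1L, stats::rpois(ncpg, cfg$cpg_coverage_mean))
        p <- if (sd_ == "left") p_left else p_right
        meth <- stats::rbinom(ncpg, cov, p)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cpg_chrom, pos = pos0 + 1L, strand = "+",
          sample_id = s, stage = st, side = sd_,
          coverage = cov, methylated = meth, stringsAsFactors = FALSE)
      }
    }
  }
  cpg <- do.call(rbind, rows)

  list(expression = validate_expression_table(expression),
       mirna = validate_mirna_table(mirna),
       cpg = validate_cpg_table(cpg),
       genes = validate_gene_models(genes),
       targets = validate_target_map(targets),
       truth = list(genes = truth_genes, mirnas = truth_mirnas,
                    cpgs = truth_cpgs, config = cfg))
}

#' Generate a "week-8-like" dataset
#'
#' Preset applying the strong rightward bias observed at the earliest
#' developmental stage: `right_bias = 1651/1690` (the observed
#' rightward/asymmetric gene ratio) is set on the configuration before
#' generation; all other settings come from `config`.
#'
#' @param config a [synthetic_config()]; its `right_bias` is overridden.
#' @return same bundle as [generate_dataset()].
#' @export
generate_week8_like <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  config$right_bias <- 1651 / 1690
  generate_dataset(config)
}

#' Write a synthetic bundle to a directory
#'
#' Emits `expression.tsv`, `mirna.tsv`, `cpg.tsv`, `genes.bed`,
#' `targets.tsv` in canonical form plus `ground_truth.tsv` (per-gene
#' direction and coupling class).
#'
#' @param bundle list from [generate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  write_mirna_counts(bundle$mirna, file.path(dir, "mirna.tsv"))
  write_cpg_calls(bundle$cpg, file.path(dir, "cpg.tsv"))
  write_gene_models(bundle$genes, file.path(dir, "genes.bed"))
  write_target_map(bundle$targets, file.path(dir, "targets.tsv"))
  if (!is.null(bundle$truth))
    write_canonical(bundle$truth$genes, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
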