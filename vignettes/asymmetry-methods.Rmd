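---
title: "Calling left-right multi-omic asymmetries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling left-right multi-omic asymmetries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinasym)
```

# The problem and the modelling stance

Molecular lateralisation — systematic left/right differences in gene
expression and its epigenetic regulators — can be probed by sequencing the
left and right halves of the same specimen. The design this package
targets is severely sample-limited: a handful of fetal specimens per
developmental stage (two at the first two stages, one at the last), each
contributing one left and one right measurement per molecular layer. With
n = 2 paired replicates, per-feature variance estimation is hopeless and
classical differential-expression machinery (negative-binomial GLMs,
moderated t-statistics) has nothing to moderate against. The package
therefore implements the pragmatic rule set used in this setting:
thresholded fold changes of side means for expression layers, exact
count-based tests within samples for methylation, and deterministic
set/threshold logic for the integration step. Every call is a rule
evaluation, not a posterior: the output should be read as "passes the
stated filter", and all filters live in one `threshold_config()` object so
an analysis is fully specified by its inputs plus that object.

A consequence worth stating plainly: with two replicates, the expression
layer cannot distinguish biological asymmetry from a single discordant
specimen. The methylation layer compensates by testing within each sample
and then requiring cross-sample *consensus* (same direction, every
sample); the expression layer has no analogous guard and inherits the full
false-positive behaviour of a fold-change threshold at the chosen noise
level.

# The rules, layer by layer

## Expression

For a stage $s$ with samples $k = 1..n_s$, each gene has side means
$\bar{x}_L = \frac{1}{n_s}\sum_k x_{Lk}$, $\bar{x}_R$ likewise, in FPKM.
Two rules apply:

* **Abundance**: keep the gene iff $\bar{x}_L \ge$ `fpkm_min` *and*
  $\bar{x}_R \ge$ `fpkm_min` (default 1 FPKM). Ratios of near-zero FPKM
  are dominated by measurement noise; requiring both sides also guarantees
  a positive denominator for the fold change.
* **Asymmetry**: $\log_2(\bar{x}_R/\bar{x}_L) > 1.5$ calls rightward,
  $< -1.5$ leftward, strict inequalities. The orientation (positive =
  rightward) is a package-wide sign convention shared by the miRNA
  log-fold-change, the methylation difference (right − left) and the
  laterality quotient.

Means are taken first, then the ratio — not per-sample ratios averaged.
The mean-of-sides form degrades gracefully to the single-sample case and
matches the abundance rule's arithmetic. The abundance rule is applied to
the *means* rather than per sample; a per-sample variant would interact
with the ratio-of-means in unobvious ways and is not offered.

## miRNA

Raw read counts are kept only when a miRNA has ≥ `mirna_min_reads`
(default 10) mean reads on at least one side: a miRNA low on *both* sides
yields a meaninglessly unstable ratio, whereas a miRNA high on exactly one
side is precisely the interesting case and must not be discarded. (The
stricter remove-if-either-side-low reading is available as
`low_count_either_side`.) Counts are then normalised to
RPKM $= 10^9 r / (N \ell)$ with $r$ reads on the transcript, $N$ the
library size and $\ell$ the transcript length, and the expression
procedure is repeated on RPKM side means with one deliberate difference:
the miRNA rule is a *minimum* ($|\log_2\mathrm{FC}| \ge 1.5$), the mRNA
rule strict. Both are configurable; the package logs no warning when they
coincide, only the convention differs by default.

Because the filter keeps one-side-high miRNAs, a side mean of exactly zero
can reach the ratio. Rather than emit an infinite fold change, the zero
side is floored at the RPKM equivalent of 0.5 reads in that side's library
and the call is flagged `floored`. The floor caps exactly the
"unrealistically high fold changes" the read-count filter exists to
prevent, and does so deterministically.

Target genes of asymmetric miRNAs are collected as a set union at
interaction probability strictly > `target_prob_min` (default 0.8). By
default no direction consistency is imposed between a miRNA and its
target — target membership alone counts as a candidate explanation. A
repression-consistent mode (`mirna_direction_consistent`), requiring the
miRNA to be up on the side where its target is down, is provided but off:
it is the biologically stricter reading, but it halves the explanation in
a way the default reporting convention does not assume.

## Methylation

Within one sample, each CpG covered on both sides is tested with a
two-sided Fisher exact test on
$[[m_L, u_L], [m_R, u_R]]$ (methylated/unmethylated reads). The two-sided
p-value uses the point-probability convention: conditioning on the
margins, sum the hypergeometric probabilities of all tables no more
probable than the observed one. Probability ties are compared with a
relative tolerance of $10^{-7}$, the convention used across standard
implementations; the test suite checks the implementation against an
independent log-binomial enumeration oracle to $10^{-12}$ on every table
with total ≤ 40, and against `stats::fisher.test` on random tables. The
in-package implementation exists because a per-CpG analysis tests $10^4$ –
$10^6$ tables: it vectorises by grouping tables with identical margins,
which a scalar `fisher.test` loop cannot.

P-values are FDR-adjusted with Benjamini–Hochberg *within one sample's
family* of both-side-covered CpGs. A $\pi_0$-adaptive estimator (such as
SLIM) would be less conservative; BH was chosen because it is fully
reproducible from first principles with no spline-fit degrees of freedom,
and the adjustment method is an explicit interface slot should an adaptive
variant be added. The joint call is `q < fdr_q` (default 0.01) **and**
|percent difference| > `meth_diff_min` (default 25 points); the magnitude
gate keeps deeply covered but biologically trivial differences out.

Consensus across a stage's samples requires significance with the same
direction in *every* sample; single-sample stages pass through. CpGs
covered on one side only are excluded and tallied (`n_excluded`
attribute), never imputed. Strand is carried, and +/− CpGs are never
collapsed into dinucleotide units: collapsing would silently change CpG
counts, and the per-strand representation loses nothing.

## Integration

Consensus CpGs are assigned to every gene whose body plus upstream window
contains them. Coordinates are 0-based half-open internally (BED native;
GTF converted at the boundary), and the window is strand-aware:
$[start - w, end)$ for +, $[start, end + w)$ for −, $w$ = 1500 nt.
"Upstream" of a gene is conventionally transcription-relative, so this is
the default; `ignore_strand` reproduces the naive left-of-start reading.
A CpG inside two overlapping gene windows counts for both genes — each
gene's profile is computed independently, and there is no principled way
to pick a single owner.

Per gene, the laterality quotient over hyper-methylated CpG counts is
$LQ = 100\,(n_R - n_L)/(n_R + n_L)$, undefined (NA) at $0/0$. LQ counts
*sites*, not methylation magnitude: a gene with one CpG at a 60-point
difference and a gene with five CpGs at 30 points are deliberately scored
by their site counts, with `mean_abs_diff` carried for reporting only.

The partition rule for an asymmetrically expressed gene:

| expression | condition | category |
|---|---|---|
| right | $LQ < -25$ | methylation-explained |
| left  | $LQ > +25$ | methylation-explained |
| any   | in asymmetric-miRNA target set | miRNA-explained |
| — | both conditions | both |
| — | neither | unexplained |

Strict inequalities throughout; $|LQ| = 25$ exactly explains nothing, and
an undefined LQ never sets the methylation flag. Only *opposite*-direction
methylation explains expression (the canonical repressive reading of
promoter/body hyper-methylation); same-direction methylation, however
strong, leaves a gene unexplained. "Explained variance" in the reported
percentages is a fraction of genes, not a variance decomposition, and the
report labels it accordingly.

# Reporting and rounding

Percentages are rounded half away from zero (`round_half_up()`): two
decimals for transcript-level rates (1690 of 51408 → 3.29), nearest
integer for partition shares (451 of 1690 → 27). R's default
round-half-even would report 2.78 where the field's conventions print
2.79; rounding is confined to the reporting layer, never applied to
intermediate values.

# The synthetic-data generator

`generate_dataset()` emulates the paired design end to end; its defaults
*are* the study conditions the package targets, and they are not tuning
knobs:

* design: 2/2/1 samples across stages `wk8/wk10/wk12` (gestational-age
  labels 10/12/14 are accepted as input aliases); one miRNA library per
  stage, mirroring designs where small-RNA material suffices in a single
  specimen.
* expression: baseline FPKM lognormal around ~8 with unit log-sd;
  multiplicative lognormal noise, `expr_noise_sd` 0.2 (log scale).
  3.29% of genes asymmetric (`frac_asym_expr`), planted |log2FC| = 3;
  baselines of planted genes floored at 4 FPKM so the *low* side clears
  the abundance filter — recall tests would otherwise measure the
  abundance rule, not the fold-change rule. The week-8-like preset sets
  the rightward share of planted genes to 1651/1690.
* coupling: exclusive class shares — `frac_meth_coupled` (default
  451/1690), `frac_mirna_coupled` (47/1690) and an explicit `both_overlap`
  (18/1690) — sized to echo the observed partition; the "both" class is a
  parameter, not an independence assumption.
* methylation: `cpgs_per_gene` sites (default 10), body-spread plus one
  promoter site 500 nt upstream of the TSS (strand-aware); Poisson
  coverage around `cpg_coverage_mean` (default 60, floored at 1);
  binomial methylated counts. Coupled genes get side proportions 0.5 ±
  `meth_delta`/2 (default Δ = 0.4) with the *left* side higher for
  rightward-expressed genes. Coverage 60 with Δ = 0.4 puts a typical
  per-CpG Fisher p near $10^{-5}$, so a planted CpG survives BH within a
  20 000-site family with high probability — a deliberate
  detectability choice, stated here because real bisulfite coverage is
  often far lower.
* miRNA: negative-binomial counts (size 50), planted |log2FC| = 3,
  asymmetric fraction 5/301; gene models tile a toy chromosome with
  4000-nt gaps so 1500-nt windows never reach a neighbour's CpGs.

What the generator does **not** emulate: stage-dependent effect sizes
(planted direction is constant across stages), read-level artefacts
(mappability, bisulfite conversion error), correlated noise between
layers, realistic FPKM/coverage distributions, or chromosome structure.
Passing recovery tests therefore demonstrates that the rules recover
*planted* structure under idealised noise — they say nothing about
sensitivity on real tissue, where coverage, effect sizes and confounding
are all less favourable.

```{r}
bundle <- generate_week8_like(synthetic_config(n_genes = 500,
                                               cpgs_per_gene = 5, seed = 7))
run_pipeline(bundle, stages = "wk8")
```

# Degenerate inputs and edge policies

* Empty stage in the expression table: hard error from the pipeline
  (stage-tagged); the per-layer functions warn and return empty.
* Both side means zero with `fpkm_min = 0`: log2FC is NA, direction
  `none`; `fold_change_of_means()` called directly on a zero mean raises
  a ratio error.
* CpG with zero coverage on a side: excluded upstream; `fisher_cpg()`
  itself refuses zero row sums.
* `adjust_fdr()` validates $p \in [0,1]$ and preserves order under input
  permutation.
* All output tables are radix-sorted on natural keys, so writes are
  locale-independent and re-running a pipeline on identical inputs is
  byte-identical.

# Problem sizes used in the tests

The bundled suites run at deliberately modest scale: 2000 genes × 10 CpGs
for the end-to-end recovery and side-swap checks, 120–500 genes for
pipeline unit tests, exhaustive Fisher validation over all 134 030 tables
with total ≤ 40, and 200 randomised small configurations for the
conservation properties. These sizes give stable binomial intervals for
the planted fractions (±1.3 points on the 10% asymmetric fraction at
n = 2000) while keeping the full suite under a minute; the generator
itself scales linearly and has been run at the ~50 000-transcript scale
of a full transcriptome.

# Known limitations

* The expression layer has no replicate-consistency guard (see above);
  treat single-stage expression calls as screening output.
* BH is used where an adaptive FDR estimator would be less conservative;
  significant-CpG counts are therefore, if anything, understated.
* The miRNA explanation imposes no direction consistency by default, so
  the miRNA-explained share is an upper bound under the default
  convention.
* LQ is a count statistic; a gene with one consensus CpG has LQ = ±100
  and can be "strongly asymmetric" on a single site. A minimum-CpG
  requirement is easy to impose downstream on the profile table but is
  not part of the default rule set.
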