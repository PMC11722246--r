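---
title: "Methods: ancestry-aware colocalisation of NDD GWAS and immune eQTL signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-aware colocalisation of NDD GWAS and immune eQTL signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndcoloc)
```

## Scope and model

`ndcoloc` asks whether the association signal for a neurodegenerative
disease at a genetic locus and the association signal for a gene's
expression in a peripheral immune cell type share one causal variant, and
it asks this separately per ancestry, cell type and viral activation
state. The package implements four statistical components — expression
specificity, summary-statistic harmonisation, Bayes-factor colocalisation
and effect-direction analysis — plus a simulator that generates inputs
with known ground truth, so every calibration claim in the test suite is
checked against data whose answer is known by construction.

### Expression specificity

Raw TPM per gene is normalised by the gene's maximal TPM across all
(cell type, activation state) columns ("proportion of expression"). The
specificity index is

$$\tau = \frac{\sum_{i=1}^{N} (1 - x_i)}{N - 1},$$

with $x_i$ the components normalised by the maximal component and $N$ the
number of categories. $\tau$ is scale-invariant and monotone under
concentration of mass onto the maximal category; both properties are
enforced as tests. Cell-type $\tau$ is computed after collapsing the state
axis: each cell type is represented by its maximal cell state, mirroring
heat-map summaries in which the maximal state is shown per cell type. The
alternative — flattening all 66 columns into one axis — is available via
`flatten = TRUE` and gives systematically higher values because the
additional near-zero columns inflate the sum; the collapsed form is the
default because the two axes answer different questions (which *cell
type*, then which *state within it*). Within the maximal cell type a
second $\tau$ across the three states measures activation-state
specificity, with unstimulated-maximal genes reported as `"-"`.

Ties in the maximal column are broken deterministically — cell types
alphabetically, states in the order unstimulated < influenza < SARS-CoV-2
— and flagged, so repeated runs cannot disagree. A gene is called
*expressed* when its maximal TPM reaches 1 (inclusive); no community
standard exists for this cutoff, so it is a configurable default and no
downstream result treats the expressed count as an estimate of anything.

Group comparisons of $\tau$ (e.g. myeloid-maximal versus NK-maximal
genes) use Welch's unequal-variance two-sample t-test. A pooled-variance
test would be defensible too; Welch is chosen because the groups are
small, of unequal size, and there is no reason to assume equal variances.
Degenerate constant groups short-circuit to $t = 0, p = 1$ (equal means)
rather than erroring.

### Harmonisation

Two summary-statistics tables are intersected on rsID and aligned to the
first table's effect allele: identical allele pairs pass through, swapped
pairs negate the effect and complement the frequency, strand-complement
pairs are complemented first. Palindromic variants (A/T, C/G) are
ambiguous between the swap and strand readings; below the minor-allele
frequency cutoff (default 0.42) the direct reading is taken, above it the
variant is dropped because frequency can no longer resolve strand either.
The module restricts itself to biallelic single-nucleotide variants;
indels and multiallelic records are dropped on input with logged counts.
Two properties pin the implementation down: harmonising an already-aligned
table is the identity (involution), and re-expressing a table with every
allele pair swapped (betas negated, frequencies complemented) yields an
identical harmonised result. Both are tested over the full 16-configuration
allele-pair enumeration and 1000 randomised records.

Genome-build remapping takes a user-supplied two-build coordinate table
and rsID assignment a (chrom, pos, alleles) lookup, with allele order
ignored and conflicts resolved to the lexicographically smallest
identifier; chain-file parsing and dbSNP access are deliberately out of
scope, as stock steps best done by dedicated tools.

### Colocalisation engine

Per variant, the log approximate Bayes factor is
$\tfrac12[\log(1-r) + r z^2]$ with $z = \hat\beta/s$ and
$r = W^2/(W^2+s^2)$. The effect-prior SD $W$ follows the conventional
defaults: 0.15 for case-control traits (log-odds scale) and $0.2\,
\mathrm{sd}_Y$ for quantitative traits, with $\mathrm{sd}_Y$ estimated
from the variance identity
$\mathrm{var}(\hat\beta_j) \approx \mathrm{sd}_Y^2 / (2 n_j f_j (1-f_j))$
via a zero-intercept regression; estimation failure falls back to
$W = 0.2$ with a warning, and every result records the $W$ values used.
Bayes factors are computed from beta/SE rather than from p-values, which
avoids rounding loss in published files.

The five-hypothesis posterior (no association; trait 1 only; trait 2
only; distinct variants; shared variant) uses per-SNP priors $p_1 = p_2 =
10^{-4}$ and $p_{12} = 10^{-5}$ and unnormalised weights $1$, $p_1 S_1$,
$p_2 S_2$, $p_1 p_2 (S_1 S_2 - S_{12})$, $p_{12} S_{12}$. Numerically,
every sum is a log-sum-exp, so a single variant with lABF of several
hundred cannot overflow; the distinct-variant term uses
$\log(1 - e^{d})$ with $d = \log S_{12} - \log S_1 - \log S_2$, and is set
to exactly $-\infty$ when $Q = 1$ (no distinct pair exists) or when $d
\ge 0$, which for $Q > 1$ can only occur when one variant so dominates
both traits that H3's mass is genuinely negligible. The package ships
`brute_force_posterior()`, an independent quadratic-time enumeration of
all $(Q+1)^2$ causal-configuration pairs; the suite requires agreement
with the fast path to $10^{-10}$ across 200 random instances.

Decision rule, threshold 0.75 throughout: *underpowered* when
$\mathrm{PPH3} + \mathrm{PPH4} < 0.75$ (the studies cannot be compared at
this locus), else *colocalised* when $\mathrm{PPH4} > 0.75$, *distinct*
when $\mathrm{PPH3} > 0.75$, and *indeterminate* otherwise — the last
call covers the region the three-way language does not (powered, but no
single hypothesis dominant) and is logged rather than silently folded
into another category. The PPH4/PPH3 ratio is always reported
($\infty$ when PPH3 is 0), since near-threshold loci are often triaged by
that ratio.

Locus windows are drawn around genome-wide-significant GWAS variants
($p < 5\times10^{-8}$, configurable; windows $\pm$1 Mb, half-open,
1-based GRCh38 coordinates, overlapping windows merged). Each window is
tested against each eQTL table with at least `min_snps = 50` overlapping
variants; thinner pairings are skipped with a recorded reason rather than
tested underpowered. No multiple-testing adjustment is applied across
genes and cell types — the scan reports the number of tests so users can
adjust downstream.

### Effect direction

At a locus, concordance is measured by the Pearson correlation of the two
traits' $-\log_{10}$ p-values and of their harmonised betas, with an OLS
line and 95% CI for the beta–beta relation. The direction call (higher
expression with higher risk, or the reverse) is made from the sign of the
beta correlation only when its two-sided p-value clears $\alpha = 0.05$;
zero-variance inputs give an explicit indeterminate call. The pipeline
runs direction analysis only at loci classified colocalised — a
correlation between two signals that do not share a variant has no causal
reading — though this gating is configurable. All harmonised SNPs in the
window are used, unfiltered.

## The synthetic-data generator

The simulator stands in for data the package cannot ship: multi-ancestry
immune eQTL summary statistics and ancestry-specific GWAS are access
controlled. It generates marginal z-scores for two traits directly on the
standardized summary-statistic scale: $z \sim \mathrm{MVN}(R\lambda, R)$,
where $R$ is an AR(1) LD correlation matrix ($R_{ij} = \rho^{|i-j|}$) and
$\lambda$ is zero except at the causal variant, where it equals
$\sqrt{n v/(1-v)}$ for variance explained $v$ — so SE $= 1/\sqrt{n}$
exactly and $\hat\beta = z\,\mathrm{SE}$. Effect-allele frequencies are
uniform on $[0.05, 0.95]$ and shared between the traits; a flag re-draws
them independently to emulate cross-ancestry pairings. AR(1) LD is the
minimal structure that makes shared and distinct causal variants
non-trivially confusable; no individual-level genotypes, haplotype
structure, or imputation error are modelled, so recovery rates measured
here say nothing about miscalibration arising from those features in real
data. The Cholesky factor of $R$ is computed once per LD structure and
reused across replicates.

Expression matrices draw each gene's TPM vector from a symmetric
Dirichlet scaled to a total of `base_tpm`: the concentration parameter
maps monotonically (and inversely) onto realised $\tau$, giving a tunable
ground truth — concentration 0.01 yields near-one-hot genes, $10^4$
near-uniform ones. The default 22 cell types × 3 states (unstimulated,
influenza, SARS-CoV-2) mirror the study design the package targets. The
phenotype-QTL simulator fills a (gene × blood-count metric × ancestry)
table by independent Bernoulli draws. Every generator is a pure function
of its arguments and seed, and restores the caller's RNG state.

Calibration settings used by the suite and the acceptance script — 200
replicates per scenario at 500 SNPs, $\rho = 0.9$, $n = 10^4$, $v = 0.01$,
default priors — were chosen once as a realistic desk-scale working
point: $z \approx 10$ at the causal variant is a typical strong GWAS hit,
and $\rho = 0.9$ gives adjacent variants correlated enough that H3 versus
H4 is a real discrimination problem when causal variants are 250 SNPs
apart but not when adjacent. The recovery thresholds (80% for hypothesis
calls, 90% for direction calls) are claims about this working point, not
about harder regimes (smaller $v$, adjacent causal variants, mismatched
LD), where single-causal-variant colocalisation is known to degrade.

## Degenerate inputs and numerical edges

* One-SNP loci: PPH3 is exactly zero (no distinct pair exists), by
  construction rather than by underflow.
* $p_{12} = 0$ annihilates H4 exactly.
* All-zero expression rows: proportions all zero, `expressed = FALSE`,
  $\tau$ undefined (`NA`) rather than 0 or 1.
* Exactly collinear beta–beta relations: the correlation p-value
  underflows to 0 and the CI collapses to the slope; the fit warning is
  suppressed as expected behaviour.
* Posterior vectors are renormalised to sum to 1 within $10^{-12}$ and
  are invariant to SNP permutation.
* Record validation drops (and counts) rows with non-positive SE,
  identical or non-ACGT alleles, out-of-range p; p/beta/SE disagreement
  beyond 10% relative tolerance is flagged, not fatal, because published
  p-values are rounded.

## Pipeline and reproducibility

`run_full_pipeline()` runs specificity → windows → coloc scan → direction
→ overlap → report from one YAML config; all thresholds live in the
config with package defaults. Every stage's randomness derives from the
single config seed, so two runs of one config are byte-identical in their
TSV outputs (tested); the run-metadata JSON carries the config hash, seed
and package version. The packaged gene catalog has the documented 39-gene
composition (18 AD, 15 PD including RAB32, 6 FTD); symbols published only
in supplementary material are shipped as flagged placeholder rows for the
user to complete rather than guessed.

## Known limitations

* Single-causal-variant colocalisation only: no SuSiE-style multi-signal
  decomposition, conditional analysis or LD-matrix methods.
* The differential-expression results the full analysis consumes are
  ingested as a table, never recomputed.
* The simulator's AR(1) LD and shared-frequency assumptions understate
  the harmonisation and LD-mismatch failure modes of real cross-ancestry
  analyses.
* Real-data headline quantities depend on restricted-access datasets and
  are not reproduced here; the package's claims are the property and
  calibration results its tests and acceptance script compute.
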