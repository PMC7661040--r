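---
title: "Models and methods behind methclock"
author: "methclock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`methclock` builds DNA-methylation age (DNAmAge) clocks for rodent
cohorts profiled by reduced representation bisulfite sequencing (RRBS),
transfers them between genome assemblies, decomposes their signal into
consensus co-methylation modules, and relates the resulting age estimates
to phenotype, cell composition, and caloric restriction (CR). This
vignette records the models, the tunable parameters and the reasoning
behind every numerically consequential choice; the README shows a worked
example.

# From call tables to a beta matrix

RRBS methylation callers emit one row per cytosine per sample: position,
methylated fraction (the *beta* value, in $[0,1]$) and read coverage.
`readCalls()` ingests the CGmap and bismark-coverage dialects; only
CpG-context rows are used, and forward/reverse-strand CpG calls are kept
as distinct sites because symmetric-strand merging is a lossy step that
not all upstream callers perform consistently.

`assembleMatrix()` unions the sites across samples. An entry is missing
unless its coverage is **strictly greater than** `minCoverage` (default
10): a "greater than 10x" rule and a "lower than 10x set to null" rule
only agree if the boundary 10x itself is masked, so the strict reading is
used; the constant is exposed. `filterSites()` then keeps sites observed
in at least `ceiling(minFraction * n)` samples (default 0.8) — "at least
80%" is a lower bound, hence the ceiling.

# kNN sliding-window imputation

A missing beta at (site $i$, sample $j$) is the mean of the values, in
sample $j$, of the $k = 5$ nearest neighbouring CpGs among candidates on
the same chromosome within a genomic window of `windowBp` = 3 Mb. Two
conventions are unstated in this scheme's usual description and were
fixed as follows:

* the window is **centered** on the target ($\pm$ 1.5 Mb), the symmetric
  and less arbitrary of the two readings; one-sided trailing windows
  would make the imputation depend on chromosome orientation;
* the Euclidean distance between two sites' beta profiles is computed
  over the samples where **both are observed** and divided by
  $\sqrt{\text{shared count}}$, which makes distances comparable across
  unequal overlaps; candidates sharing fewer than `minSharedSamples` = 3
  samples are excluded. Computing distances after a provisional
  mean-fill was rejected because it lets imputed values influence later
  distances.

Ties are broken by genomic distance, then by position. All imputations
are computed from the original observations and written afterwards, so
the result is independent of the order in which entries are processed
(and of sample order). With no eligible candidate, the site's own mean
is used and counted. Imputed values are convex combinations of observed
betas and therefore stay in $[0,1]$.

# The PC clock and its month rescaling

PCA is fitted on the **training samples only**: sites are centered by
their training means, with no per-site variance scaling — betas already
share the $[0,1]$ scale, and rescaling would up-weight near-constant
sites. The decomposition is an economy-size SVD of the
$n_\text{train} \times p$ centered matrix ($n \ll p$), so no $p \times p$
covariance is ever formed.

The clock is the affine map
$$\widehat{\text{age}} = \beta_0 + \sum_{c} \beta_c \, s_c,$$
where $s_c$ are the (sign-oriented) component scores and
$(\beta_0, \beta_c)$ come from ordinary least squares of training age on
the scores. PC signs are arbitrary, so each component is oriented to
correlate non-negatively with training age. With centered scores the
intercept equals the mean training age. The frozen means, loadings,
slope and intercept are applied verbatim to test data — predictions are
never re-centered on new samples.

`selectComponentsCV()` compares the cumulative sets $\{1\}, \{1,2\},
\dots$ by 10-fold cross-validated MSE and returns the smallest set within
one standard error of the minimum. On the default synthetic cohort the
planted sigmoidal trajectories put genuine age signal on components
beyond the first, so the rule may retain more than one component there;
on cohorts whose age signal is one-dimensional it returns 1.

The sparse alternative, `fitEnetClock()`, is an elastic net
($\alpha = 0.5$; the mixing is configurable because no canonical value
exists for this design) with the penalty chosen by 10-fold
cross-validation under the minimum-MSE rule on a 100-point logarithmic
grid; predictors are standardized internally and weights are returned on
the beta scale. The relationship between DNAmAge and age is visibly
sigmoidal in rodent data; the clock nevertheless uses a linear rescale
(the established practice this package follows), and residual
diagnostics are left to the user.

Clock performance is summarized by the biweight midcorrelation
(`bicor()`): Tukey biweights $w = (1-u^2)^2$ for $|u| < 1$ with
$u_i = (x_i - \mathrm{med}\,x) / (9\,\mathrm{mad}\,x)$, where
$\mathrm{mad}$ is the unscaled median absolute deviation. A zero MAD
(more than half the values identical) makes the estimator undefined, and
the function falls back to Pearson with a message rather than failing.

# Cross-assembly transfer

`readChain()` parses UCSC chain files; all 1-based/0-based conversion is
centralized in one pair of helpers because the off-by-one at the
boundary of a chain block is the classic failure mode of hand-rolled
liftover code. `liftoverSites()` maps single bases (CpGs, not
intervals): the highest-scoring chain containing the position wins, ties
go to file order, and minus-strand targets use
$t_0 = \text{plusEnd} - \text{offset} - 1$. Unmapped is a value, not an
error. Sites whose strand flips are kept — the mapped position is the
target CpG's cytosine on the other strand, and discarding them would
bias the conserved set against inverted regions.

`transferClock()` refits the PCA clock on the source-species training
split restricted to the chain-paired sites and carries the pairing, so
`predictAge()` can consume target-assembly matrices directly. When two
sources collide on one target the higher-scoring chain keeps the pair.

# Consensus co-methylation modules

The network is *signed*: $a_{ij} = ((1 + r_{ij})/2)^\beta$ with
$\beta = 1$, so anticorrelated CpGs get near-zero adjacency instead of
being conflated with correlated ones. Pearson correlation is used for
the network (configurable to bicor); the robust estimator is reserved
for the clock evaluations. The topological overlap is the canonical
$$\omega_{ij} = \frac{\ell_{ij} + a_{ij}}
                     {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
\ell_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj},$$
computed by one matrix product. Per-dataset TOMs are calibrated by
scaling each so its 0.95 off-diagonal quantile matches the first
(reference) dataset, then combined by element-wise minimum — a consensus
is a similarity supported in *every* dataset. Calibrating to a fixed
reference makes the operation asymmetric in the input order; the first
matrix is the reference by convention.

Modules come from average-linkage clustering of $1 - \omega$ followed by
a dynamic, branch-wise cut (no PAM-like reassignment stage). Every
subtree below 99% of the maximum merge height is a candidate branch and
qualifies when

1. it has at least `minModuleSize` = 25 tips;
2. its mean internal merge height (core scatter) stays below
   $h_{\text{ref}} + m_s (h_{\text{cut}} - h_{\text{ref}})$, with
   $h_{\text{ref}}$ the 5th percentile of merge heights;
3. the jump from its top merge to the height at which it attaches to the
   rest of the tree is at least $m_g (h_{\text{cut}} - h_{\text{ref}})$.

`deepSplit` $\in 0..4$ maps to $m_s \in (0.64, 0.73, 0.82, 0.91, 0.95)$
and $m_g = (1 - m_s) \cdot 3/4$ — the default 1 gives $(0.73, 0.2025)$.
Minimal qualifying subtrees (no qualifying sub-branch) become modules,
which splits each branch as deeply as the criteria allow; with a
power-1 signed TOM over thousands of mostly unstructured CpGs the
overlap matrix is nearly flat, and this attachment-gap formulation is
what still isolates tight blocks inside larger correlated
superstructures. Everything else is grey. Colour labels are assigned by
decreasing module size from a fixed palette; the colours are labels
only.

Membership is then pruned by **consensus kME**: a member's minimum,
across datasets, of its correlation with its own module's eigengene (the
first PC of the centered module submatrix, oriented so members' mean kME
is non-negative). Members below `minKME` = 0.4 go grey, and modules
falling below the size floor dissolve. Consensus (minimum) rather than
single-dataset kME is used because a consensus module should be
supported in each dataset. Module-specific clocks reuse the PC-clock
machinery on the module's CpGs.

# Association models

Phenotype (open-field + rotarod) and FACS feature tables are reduced by
training-anchored PCA: features are z-scored with training means and
standard deviations, loadings come from the training samples, PC1 is
oriented toward a positive training-age correlation (so "higher score =
older-typical"), and returned scores have unit standard deviation in the
analytic sample, making regression coefficients "months of DNAmAge per
s.d.".

All models are ordinary least squares with classical standard errors and
two-sided t-tests — a deliberate match to default linear-model output,
with no robust correction. The nested family regresses DNAmAge on age,
then adds phenotype PC1, then FACS PC1 (optionally the first 10 FACS
PCs); `attenuationPercent()` reports
$100(\beta_\text{before}-\beta_\text{after})/\beta_\text{before}$.
CR models add a diet indicator (main effect, in months) or an age-by-CR
product; the interaction is invariant to centering age. The
CR-duration analysis fits DNAmAge on age in the controls only, applies
that equation to CR animals, and Pearson-correlates their residuals with
time on diet — Pearson because a named estimator was not dictated and
the residuals are approximately Gaussian by construction; the choice is
configurable in spirit (the residuals are returned). Group comparisons
use the tie-corrected Kruskal–Wallis test.

# Genomic annotation and enrichment

Gene models come from GFF3 (1-based), region sets from BED (0-based
half-open, converted centrally on read, merged and sorted). CpG
categories follow the precedence promoter (TSS $\pm$ 1 kb) > exon >
intron > TTS (transcription end $\pm$ 1 kb) > intergenic, so every site
gets exactly one label; 1 kb is a conventional flank and is exposed as a
parameter. TSS distances are strand-aware (positive = downstream of the
gene's TSS) and binned at decade edges. CpG density counts catalogue
CpGs in a 100 bp window centered on the site, including the site itself.

Region-set enrichment crosses module membership against region overlap
in a 2×2 table whose background is module-versus-**rest** (not
module-versus-all, which would double-count the module in both margins),
with a two-sided Fisher exact p, fold = ratio of in-region proportions,
and Benjamini–Hochberg adjustment across the supplied sets. The package
ships no external region databases; enrichment runs against
user-supplied BED files, and the generator plants synthetic
H3K9me3-like/H3K27me3-like sets.

# The synthetic cohort generator

`simulateCohort()` is first-class, tested code that defines the study
conditions the acceptance checks run under. Per CpG and sample,
$$\beta = \mathrm{clamp}_{[0,1]}\big(b_0 + f_{\text{age}}(\tilde a)
 + \lambda L_m + c^\top (p - \bar p) + \varepsilon\big),$$
where $\tilde a$ is the *effective age* (chronological age shifted by
`crShiftMonths` + `crDurationRate` × months on diet for CR animals),
$f_{\text{age}}$ is linear or logistic in age (the logistic terms give
the clock-versus-age curve its sigmoidal shape), $L_m$ is the module
latent, $p$ are simulated cell-type proportions drifting with age, and
$\varepsilon$ is Gaussian with `noiseSd` = 0.05. Observation adds
binomial sampling at negative-binomial coverage (mean 30, size 6);
records are absent at zero coverage or with probability `missingExtra`,
and the assembly step masks everything at $\le$ 10x, for an analytic
masking probability recorded in the truth manifest.

Deliberate design points, fixed once:

* **Cohort design.** 134 rats cycling through ages 1–27 months (about
  five per monthly group, the test split taking ages 2, 6, ..., 26) and
  177 mice of which 20 are CR, restricted from 3.2 months of age with
  6.5–23 months on diet. 20,000 CpGs is the desk scale standing in for a
  multi-million-site matrix; every stage is dimension-agnostic.
* **Diffuse age signal vs modules.** The 1,000 linear + 500 sigmoidal
  age-trend CpGs carry extra per-site trajectory noise
  (`trajectoryNoiseSd` = 0.11): they correlate with age individually
  (r ≈ 0.5–0.7) but not tightly with one another, as heterogeneous
  aging trajectories do. Only the four planted blocks (sizes
  64/47/44/38, within-correlation 0.95) are tightly co-methylated, so
  module detection has a well-posed planted partition while the clock
  still aggregates thousands of weak age signals. Without this
  separation the diffuse age CpGs themselves cohere into large modules
  and swallow the age-weighted blocks — a property of power-1 signed
  TOMs worth knowing about on real data too.
* **Module anatomy.** Blocks mirror the published pattern: a dense-CpG
  block tagged with a synthetic H3K9me3-like region set, an age-neutral
  block, a sparse positively-ageing block, and a bimodal-density strongly
  ageing block tagged H3K27me3-like; two blocks also load on the
  individual (age-independent) part of the frailty factor, creating the
  age-adjusted DNAm–phenotype association the regression models probe.
* **Conservation and the chain.** 20% of rat CpGs are conserved; all
  module and a fixed share of age-trend CpGs are planted inside the
  conserved set (and protected from chain gaps), the rest of the
  conserved set is null. One chain per chromosome maps them to the
  second assembly with interior gaps (conserved CpGs inside gaps stay
  unmapped) and one minus-strand chain exercising the strand-flip
  arithmetic. Age slopes in the second species are attenuated by
  `crossSpeciesSlope` = 0.5 — reproducing the compressed, high-intercept
  DNAmAge-versus-age relation seen when a clock crosses species.
* **Phenotypes.** Ten locomotor features load on a frailty latent
  (age-driven part + individual part); 39 FACS features derive from the
  cell proportions. FACS PC1 is therefore more strongly age-correlated
  than phenotype PC1, matching the reported ordering.
* **FASTA.** Cohort genomes are coordinate-sparse (tens of Mb with
  clustered CpGs), so the bundle's FASTA is a small synthetic excerpt
  contig pair for exercising sequence-based CpG cataloguing, not the
  cohort genome; cohort CpG-density computations use the site catalogue
  itself. The file is named `genome_excerpt_synthetic.fa` accordingly.

What the generator does **not** emulate: read-level bisulfite chemistry,
strand-specific coverage structure, batch effects, genetic variation,
tissue heterogeneity beyond the five-cell-type mixture, or realistic
genome sequence. Passing tests therefore demonstrate the pipeline's
statistical machinery under a faithful covariance structure, not
robustness to every artefact of real RRBS data.

Everything is driven by one seed through a local RNG scope: the same
configuration and seed give a byte-identical bundle, and all written
files re-parse through the package's own readers.

# Problem sizes and runtime

The shipped checks run the default cohort (20,000 CpGs × 134 + 177
samples) end to end in about a minute per stage on one core: the
coverage pipeline and PC clock in ~1 min, the 3,800-site two-dataset
consensus network in ~1.5 min, and the cross-species transfer in ~1.5
min. The caloric-restriction calibration uses a 600-CpG panel with
age-neutral modules and a clean linear age axis so the clock tracks
effective age nearly 1:1 and the planted −1.2-month shift is identified
by its point estimate rather than by a wide interval.

# Known limitations

* Module detection with power-1 signed TOMs is only well-posed for
  tight blocks; diffusely correlated structure lands in grey by design.
* The elastic-net clock's support is unstable across nearby penalties,
  as sparse selectors are; the PC clock is the stable default.
* The tree cut implements the hybrid branch criteria without the
  PAM-like reassignment stage, so borderline CpGs adjacent to a module
  stay grey rather than being rescued.
* Blockwise decomposition for networks beyond ~50k CpGs, soft-threshold
  power selection, and module preservation statistics are out of scope.
* Reported training/test counts are the package's own; published cohort
  descriptions sometimes disagree internally on such counts, and
  `splitByAge()` simply reports what it produced.
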