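---
title: "Models and methods behind phagoScreen"
author: "phagoScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phagoScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoScreen)
```

# Scope

phagoScreen implements the computational arm of a FACS-sorted, pooled
CRISPR/Cas9 loss-of-function screen for genes controlling phagosome
acidification, together with the flow-cytometry gating model and the
ratiometric BCECF pH quantification used to characterize hits. Cells
carrying a knockout library are fed dual-labeled particles whose
pH-insensitive channel (YG) reports uptake and whose pH-sensitive channel
(pHrodo) reports acidification; acidification-positive (PhagoLate) and
phagocytosis-negative (PhagoNeg) cells are sorted, their sgRNA cassettes
sequenced, and genes whose sgRNAs deplete from the PhagoLate population
are candidate regulators. Because the original sequencing data are not
publicly deposited, the package ships a generative simulator of the whole
screen so that every downstream stage is testable against known ground
truth.

# The sgRNA library

The default design (`defaultScreenLibrary()`) follows the screen being
emulated: 391 solute-carrier (SLC) genes with six sgRNAs each, 20
essential genes with six sgRNAs each serving as dropout controls, and 120
non-targeting sgRNAs — 2,586 records in total, 20-nt spacers. The true
spacer sequences of the in-house library are not public, so spacers are
generated uniquely at random from a seed; all sequence-level behavior in
the package depends only on the composition and on exact spacer identity,
not on the particular sequences. Non-targeting sgRNAs carry the sentinel
gene `"NonTargeting"`: they take part in counting, normalization and
ranking (they inform the null) but form no gene during aggregation.

# The generative screen model

`simulateScreen()` draws, per replicate:

1. a log-normal plasmid-library skew (sd 0.3 on the log scale, a typical
   pooled-library skew; shared across replicates because the skew is a
   property of the plasmid pool);
2. infection at MOI 0.25 — the protocol's 0.2–0.3 window, chosen there to
   favor single integrations, which is why the model assumes exactly one
   sgRNA per transduced cell — at 1,000 transduced cells per sgRNA,
   assigned to sgRNAs multinomially;
3. knockout with probability 0.8 per integrated sgRNA; edited cells of
   essential genes survive to the sort with relative fitness 0.2;
4. a per-cell phenotype: a cell sorts PhagoLate with probability
   0.4 × `effectMap[gene]` when edited (baseline 0.4 otherwise), and
   PhagoNeg with the complementary probability; 3×10⁶ cells per
   population are then drawn multinomially from the post-sort
   proportions. The multinomial draw models the post-selection expansion
   of the real protocol (seven days of puromycin selection and PMA
   differentiation precede sorting), which is why the sorted depth may
   exceed the simulated transduced pool; `allowExpansion = FALSE`
   disables this and makes oversampling an error;
5. read counts per sgRNA from a negative binomial with mean proportional
   to the sorted-cell share (500 reads per sgRNA on average) and
   dispersion 0.05, representing PCR and sequencing overdispersion.

Sequencing depth per sample and library skew are not reported for the
original screen; the defaults above are declared modeling choices, not
inferences. The simulator reproduces the features that matter for the
analysis — hierarchical sampling noise, essential-gene dropout,
phenotype-dependent sorting, overdispersed reads — but not PCR jackpot
artifacts, index hopping, chimeric reads, or guide-specific editing
efficiencies; a pass on simulated data therefore demonstrates the
statistical machinery, not robustness to every artifact of real
sequencing.

`emitFastq()` materializes a count matrix as FASTQ: each read is
`upstream flank + spacer + downstream flank` with independent per-base
substitution errors (indels are out of scope) and constant placeholder
qualities. The default cassette flanks mirror the lentiCRISPRv2 context
(U6 promoter end, tracrRNA scaffold start). Under exact matching, a read
remains assignable only if the upstream flank, the spacer, and the four
checked downstream bases are all error-free, so the expected assignable
fraction at error rate $e$ is $(1-e)^{L_{up}+20+4}$ — the spacer-only
closed form $(1-e)^{20}$ is an upper bound.

# Counting

`extractSpacer()` finds the first exact occurrence of the upstream flank
anywhere in the read (the search is position-free), takes the following
20 bases, and requires at least the first four bases of the downstream
flank to follow; anything else returns `NA` rather than an error. Reads
are matched against the library by exact spacer identity — the counting
step mirrors an index-matching pipeline with no mismatch tolerance; a
single-substitution rescue exists behind `rescueMismatch = TRUE`
(default off), and reverse-complement search behind
`reverseComplement = TRUE` (default off, since the amplification design
fixes cassette orientation).

# Per-sgRNA differential abundance

The screen's published analysis used DESeq2 followed by gene-set
enrichment. phagoScreen re-implements a negative-binomial Wald test of
the same family, deliberately simplified to a desk-scale, fully testable
form: closed-form two-group means instead of an IRLS GLM, a
method-of-moments dispersion with trend shrinkage instead of the
empirical-Bayes prior, no LFC shrinkage, no independent filtering, no
outlier handling. Numerical parity with DESeq2 is explicitly not a goal;
the inferential structure is the same.

**Normalization.** Median-of-ratios size factors: the reference for each
sgRNA is its geometric mean across samples (rows with any zero
excluded), and a sample's factor is the median ratio to that reference.
`pseudoReference = TRUE` switches to a positive-counts geometric mean
for zero-heavy libraries, with zero counts excluded from the median.

**Dispersion.** For sgRNA $i$ with normalized mean $\mu_i$ and pooled
within-group variance $v_i$ (pooled over the two populations,
$d = \sum_g (n_g - 1)$ degrees of freedom), the raw estimate is
$\alpha_i = \max(0, (v_i - \mu_i)/\mu_i^2)$. A trend
$\alpha(\mu) = a_1/\mu + a_0$ is fitted over sgRNAs with positive raw
estimates by a gamma-family GLM with identity link, iterating with
15-fold outlier trimming; the gamma fit targets the conditional *mean*
of the right-skewed raw estimates, where a Huber M-estimator would track
a median-like center and bias the trend low. The final dispersion mixes
raw and trend in log space with weight 0.5. Two details matter for
calibration at three replicates per group:

* the mix applies the $\chi^2$ log-bias correction
  $\psi(d/2) - \log(d/2)$ to $\log \alpha_i$ (the same digamma
  correction limma applies when averaging log-variances); without it the
  geometric mean is systematically low at small $d$ and the test becomes
  anticonservative (type-I error ≈ 0.086 instead of ≈ 0.06);
* raw estimates of exactly zero carry no log-space information and take
  the trend value directly.

Final values are floored at $10^{-8}$.

**Wald test.** Group means of normalized counts (a pseudo-count of 0.5
substitutes only for a zero group mean, keeping non-zero cases
unbiased), $\mathrm{LFC} = \log_2(\mu_{\text{Late}}/\mu_{\text{Neg}})$,
and from the NB information
$\mathrm{SE} = \sqrt{\sum_g (1/\mu_g + \alpha)/n_g}\,/\ln 2$;
$z = \mathrm{LFC}/\mathrm{SE}$ is referred to the standard normal,
two-sided, and Benjamini–Hochberg adjusted. sgRNAs with all-zero counts
are flagged and excluded from adjustment and ranking. On null screens at
the default generator settings the empirical type-I error at
$p < 0.05$ is ≈ 0.06 (the acceptance suite checks the band
[0.03, 0.07]).

# Gene aggregation

sgRNAs are ranked by the signed metric
$r_i = \mathrm{sign}(\mathrm{LFC}_i)\,(-\log_{10}(p_{adj,i} + 10^{-300}))$,
descending, with deterministic tie-breaking (|LFC| descending, then id).
A ranking by adjusted p-value alone would lose direction, yet the
screen's readout is depletion from PhagoLate; the signed metric keeps
both, and `metric = "padj_only"` provides the unsigned variant.

Each gene is scored by the weighted Kolmogorov–Smirnov running sum: hits
increment by $|r_i|^q / \sum_{members} |r|^q$ (uniform when all member
metrics are zero), misses decrement by $1/(N - m)$, and the enrichment
score is the extremum. The weight exponent defaults to $q = 1$ (classic
weighted GSEA) and is configurable since the original setting is
unstated.

**Permutation null.** Null scores are enrichment scores of uniformly
drawn same-size sgRNA sets; `aggregateGenes()` shares one pool of 10,000
draws per set size (all genes of a size have exchangeable nulls) and the
p-value is sign-matched. Two properties of this null deserve note:

* it is *competitive*: draws containing the tested gene's own sgRNAs are
  excluded. With the naive null a genuine hit contaminates its own
  reference — at 6 hit sgRNAs among 2,586 about 1.4% of random draws
  contain one, and precisely those draws produce the most extreme null
  scores, robbing the hit of its top rank in roughly one seed in seven.
  The null hypothesis being tested is that a gene's sgRNAs behave like
  the rest of the library, so the reference is properly drawn from the
  complement;
* the output table is ordered by `p_adj`, then $|es|$ descending:
  with a competitive null both a true hit and an occasional spurious
  one-sgRNA gene can exhaust their permutation resolution (no null draw
  beats them), and among such floor-tied genes the effect size, not the
  sampling noise of the sign split, is the meaningful order.

The volcano table reports, per gene, the mean LFC over its sgRNAs (x
axis), $-\log_{10} p_{adj}$ of the BH-adjusted permutation p (y axis),
and the number of sgRNAs individually significant at BH 0.05 (dot
size).

# Flow-cytometry gating

Events are two positive intensities (YG, pHrodo). Gates are quadrants:
YG at or below its cut is PhagoNeg; YG above with pHrodo at or below its
cut is PhagoEarly; both above is PhagoLate. The unaddressed
YG⁻/pHrodo⁺ quadrant is assigned PhagoNeg — without the uptake marker an
event cannot be phagocytosis-positive — and its size is reported as a
diagnostic. Cuts are per-channel 0.995 quantiles of a negative-control
population, a reproducible surrogate for the manual gates of the
original experiments; intensities are compared on the raw scale
(log-transformation is a display concern). The accompanying assay
statistics are Welch's t test with Welch–Satterthwaite degrees of
freedom and 95% confidence intervals, the Wilcoxon–Mann–Whitney test
(exact by enumeration up to a combined n of 12 without ties, otherwise
normal approximation with tie correction), and the gentamicin-protection
survival percentage `100 · CFU(t)/CFU(0)`.

# BCECF pH quantification

The in-situ calibration (nigericin/valinomycin-clamped potassium
buffers, pH 4–10) is fit with the four-parameter sigmoid

$$R(\mathrm{pH}) = R_{min} + \frac{R_{max} - R_{min}}
 {1 + 10^{\,h\,(\mathrm{pK_a} - \mathrm{pH})}},$$

monotone increasing for $h > 0$ — a logistic dose-response family, the
kind of fit the original software list implies. Fitting is nonlinear
least squares (Levenberg–Marquardt) with multi-start initialization
($R_{min}/R_{max}$ from the data extremes, pK$_a$ from the half-max
crossing, $h \in \{0.5, 1, 2\}$), keeping the best fit by residual sum
of squares; at least five distinct pH points spanning three units are
required, and data whose Spearman correlation with pH is below 0.5 are
refused as non-sigmoidal. Ratios invert to pH in closed form; ratios at
or beyond the asymptotes clamp to the calibrated pH range and are
flagged. Image reduction is deliberately minimal — maximum projection
over z, background subtraction (default estimate: median of the
lowest-decile pixels, since the original estimator is unspecified)
clamped at zero, and per-ROI channel means with the 490/440 ratio for
cytoplasm ROIs. ROI masks are inputs; segmentation is out of scope.
Phagosomal acidification is reported as pHrodo intensity, not absolute
pH, mirroring the asymmetry of the original readout.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the generator at its
full default design (2,586 sgRNAs × 6 samples, 1,000× coverage, 3×10⁶
sorted cells, 500 reads/sgRNA — a simulated screen takes well under a
second) and use 2,000–10,000 permutations per null, 5 seeds for
calibration checks and 20 seeds for recovery checks; the FASTQ round
trip runs at the full ≈7.8 million reads. Seeds derive deterministically
from a single user seed via a fixed affine map kept within 32-bit range.
Known limitations: the Wald reference is the standard normal rather than
a t distribution (slightly liberal at three replicates — visible in the
type-I error sitting near 0.06 rather than 0.05); the permutation
p-value resolution is bounded by the draw count; and the simulator's
single-integration assumption ignores the small multi-integration
fraction a real MOI 0.2–0.3 infection produces.
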