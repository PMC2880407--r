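---
title: "Methods: a proteome-wide intrinsic disorder census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a proteome-wide intrinsic disorder census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DisorderCensus)
```

## Scope and model

`DisorderCensus` measures the abundance of intrinsic disorder in whole
proteomes. The pipeline has five stages — per-residue scoring, residue
binarization and segment statistics, whole-protein binary classification,
composition profiling, and ecological/phylogenetic reporting — plus a
synthetic proteome generator that provides ground truth for validating
all of them. This vignette records the models, the tunable parameters and
their defaults, the numerical conventions, and the limits of what the
synthetic validation can show.

## Per-residue scoring

The bundled predictor is deliberately simple and fully transparent: a
disorder propensity scale (TOP-IDP by default, shipped as constants)
smoothed along the chain.

For a sequence $s_1 \dots s_n$ the score at position $i$ is

$$ d_i \;=\; \frac{\bar v_i - v_{\min}}{v_{\max} - v_{\min}},
\qquad \bar v_i = \operatorname{mean}\{\,v(s_j) :
|j - i| \le (w-1)/2,\; 1 \le j \le n\,\}, $$

with $v$ the propensity scale, $v_{\min}, v_{\max}$ its extreme values
and $w$ the smoothing window. Three choices matter:

- **Window $w = 21$ residues (odd, default).** Trained per-residue
  predictors produce smooth profiles with structure on the scale of tens
  of residues; a mid-size window reproduces that smoothness. Small
  windows make the score noisy at the single-residue level; very large
  windows blur short ordered/disordered alternation. Tests that need
  exact per-position values use $w = 1$.
- **Edge handling: truncation.** Windows shrink near the termini instead
  of padding with virtual residues; a sequence shorter than the window
  scores uniformly at its whole-sequence mean.
- **Ambiguity codes** (X, B, Z, U, O) receive the scale's mean value
  before smoothing, so they neither push toward order nor disorder. They
  are kept in sequences but excluded from all composition and
  charge/hydropathy denominators, keeping frequency vectors on the
  20-residue simplex.

Min–max rescaling guarantees scores in $[0,1]$ with the extreme-propensity
homopolymers pinned at exactly 0 and 1. Externally computed scores (from
trained disorder predictors) can be imported instead via `loadScores()`,
which cross-checks ids, positions and residues against the FASTA input.

A residue is *disordered* iff its score is $\ge$ the decision threshold.
The conventional threshold is 0.5. Because the strict-inequality
convention on either side of the threshold leaves equality unassigned,
one side must own it; the tie goes to disordered so that thresholds act
as infima of the disordered range. `calibrateThreshold()` fits the
threshold to labeled residues by maximizing balanced accuracy on a 0.01
grid; ties are resolved at the midpoint of the optimal interval
$(t_{\text{low}}, t_{\text{high}}]$ (with $t_{\text{low}}$ the grid point
just below the smallest optimum), snapped to the grid — deterministic,
and equal to 0.50 for perfectly separated score distributions.

## Disorder content measures

Three proteome-level measures are computed:

- **IDAA**: disordered residues / all residues, *pooled over residues*
  rather than averaged over proteins. Pooling makes the measure
  independent of how residues happen to be partitioned into proteins and
  weights long proteins proportionally; the protein-averaged variant is
  exposed as an option (`perProtein = TRUE`) since the two differ when
  disorder correlates with length.
- **IDP>30aa**: fraction of proteins with at least one maximal disordered
  run of length *strictly greater than* 30 residues (i.e. $\ge 31$). The
  strictness follows the ">30 consecutive residues" convention for long
  IDRs.
- **WIDP**: fraction of proteins with CDF distance $< 0$. The CDF
  classifier is used (rather than CH or a consensus) because it is the
  more accurate whole-protein classifier in this lineage; the CH or joint
  call can be substituted by the user from the same outputs.

Maximal disordered segments are reported in 1-based inclusive
coordinates internally and exported as standard 0-based half-open BED.
Domain-level statistics (`domainDisorderStats()`) report percent
disordered to one decimal and count regions of any length.

## Whole-protein classifiers

**CDF.** The curve value at cutpoint $t$ is the fraction of residues with
score $\le t$, on a default grid of 20 equal cutpoints $k/20$. A
structured protein saturates immediately; a fully disordered one stays
near zero until the top bin (which always equals 1). The boundary is
calibrated from fully ordered vs fully disordered reference sets as the
midpoint of the class-mean curves; bins where the class means differ by
more than 0.02 (the separation tolerance) are *active*, and the signed
distance of a protein is the mean curve-minus-boundary difference over
active bins, positive on the ordered side. Grid and active-bin rules are
calibration artifacts and fully configurable — published CDF analyses do
not disclose their grids or boundary values, so the package fixes
reasonable ones and exposes both.

**CH plot.** $\langle H \rangle$ is the mean Kyte–Doolittle hydropathy
rescaled per residue to $[0,1]$ via $(KD + 4.5)/9$; $\langle R \rangle$
is the absolute mean net charge $|n_K + n_R - n_D - n_E| / n$. Histidine
is treated as neutral at pH 7 and terminal charges are ignored — standard
simplifications. The default boundary line
$\langle R \rangle = 2.785\,\langle H \rangle - 1.151$ is the published
linear separator for extended disordered vs compact proteins; the signed
vertical distance is positive above the line (disordered). An optional
window-smoothed $\langle H \rangle$ is provided for fidelity to
implementations that smooth before averaging; the two differ only at
sequence edges.

**Quadrants.** With CDF distance on one axis and CH distance on the
other: (−, −) molten-globule-like (disordered by CDF, compact by CH),
(−, +) extended disordered, (+, −) ordered, (+, +) disordered by CH but
ordered by CDF. Zero distances classify by the $\ge$ rule (to ordered on
the CDF axis, to disordered on the CH axis), making the partition total
and deterministic.

## Composition analysis

Compositions are counts over the 20 standard residues pooled across a
sequence set. The fractional difference profile against a reference is
$(C_X - C_{\text{ref}})/C_{\text{ref}}$ per residue, plotted in order of
increasing disorder propensity; residues with zero reference frequency
are flagged undefined rather than silently zeroed. The bundled default
reference approximates the composition of fully disordered protein sets;
because published fully-disordered dataset compositions are not
redistributable here, the shipped constants are an approximation
assembled from published composition surveys, and all package tests use
synthetic references instead of asserting the bundled values.

Dataset similarity uses the symmetrized divergence
$\tfrac12[\mathrm{KL}(p\Vert q) + \mathrm{KL}(q\Vert p)]$ with natural
logarithms (symmetry is required for use as a distance matrix). KL is
undefined on zeros, so when either composition contains a zero count a
pseudocount of 0.5 is added to *every* count of *both* vectors before
normalizing. The symmetric treatment makes the result insensitive to the
pseudocount: for compositions built from $\ge 10^4$ residues, halving the
pseudocount moves divergences by well under $10^{-3}$. Similarity bands
partition the scale as $[0, 0.01)$ similar, $[0.01, 0.05]$ gray,
$(0.05, 0.1]$ unlikely similar, $(0.1, \infty)$ non-similar; the prose
convention overlaps at the endpoints, so the closed/open choices above
fix a deterministic partition. Self-divergence is reported as 0 on the
matrix diagonal.

## Habitat correlation and tree annotation

`disorderVsEnvironment()` reports both Pearson and Spearman coefficients
(which one a given survey used is rarely stated, and the two can diverge
under outliers), a least-squares fit, and outliers defined as species
with absolute externally studentized residual $> 2$. The numeric rule
replaces visual outlier flagging with a reproducible criterion. Salinity
classes are rank-coded low $<$ normal $<$ high; missing habitat values
are dropped pairwise, never imputed.

Tree leaves are colored by disorder percentage with left-open bins:
$>30$ red, $>21$ orange, $>17$ yellow, $>14$ light blue, $\le 14$ dark
blue — exactly 21 is yellow and exactly 30 is orange, following the
strict-">" reading, with the bottom bin closed. Annotation never alters
topology; trees are parsed and written with `ape`.

## The synthetic proteome generator

The generator is the package's source of ground truth. Its defaults *are*
the study conditions, chosen once:

- **Disorder architecture.** A two-state hidden chain with geometric
  block lengths: disordered blocks with mean 40 residues, ordered block
  mean derived from the target stationary disordered fraction
  $\pi_d = m_d / (m_d + m_o)$. Geometric sojourns are the simplest model
  with controllable mean run lengths, and a 40-residue mean disordered
  block makes >30-residue IDRs occur at realistic rates. Initial state is
  drawn from the stationary distribution, so the expected disordered
  fraction equals $\pi_d$ at every length.
- **Emissions.** Residues are drawn from state-specific compositions
  built by doubling the weight of the order-promoting set
  (I, L, V, W, F, Y, C, N) or the disorder-promoting set
  (E, K, R, G, Q, S, P, A) over a uniform background and renormalizing.
  The promoting sets are established; their exact frequencies are not, so
  a uniform-reweighting construction keeps the bias interpretable.
- **Lengths.** Log-normal with median 210 residues, shape 0.64, floor
  20. These values were calibrated once against three descriptive
  targets for real proteomes — modal 50-residue bin between 100 and 200,
  under 2% of proteins shorter than 50 residues, roughly a tenth longer
  than 500 — and then frozen; the package asserts the first two by test.
- **Archetypes.** The default panel spans the observed extremes of
  archaeal disorder content: thermophile-like ($\pi_d = 0.14$, optimal
  growth 85–100 °C), mesophile-like ($\pi_d = 0.20$, 25–37 °C), and
  halophile-like ($\pi_d = 0.34$, high salinity), mirroring the
  ~14% vs ~34% disordered-residue contrast between the least and most
  disordered archaeal lineages. Species within an archetype get a small
  uniform jitter (±0.02) on $\pi_d$ and habitat values sampled from the
  archetype's range. All randomness descends from one master seed through
  per-species derived seeds, so panels are byte-reproducible.

**What the generator does not emulate.** Real proteomes have
length-dependent and functionally clustered disorder, non-geometric
segment lengths, sequence autocorrelation beyond the two-state
composition switch, GC- and phylogeny-driven composition covariance, and
predictor-specific score noise. Passing the synthetic recovery tests
therefore shows that the pipeline's statistics are computed correctly and
are sensitive to real composition-level disorder signals — not that the
bundled propensity predictor matches trained predictors on real
sequences. Proteome-level absolute values from the bundled predictor are
systematically offset from trained-predictor values (its per-residue
balanced accuracy on well-separated synthetic states is ~0.8, not ~1);
rankings and contrasts between archetypes are the meaningful output.

## Problem sizes and determinism

The validation suite runs the default panel at 9 species × 500 proteins
(~1.2 M residues), boundary calibration at 200 + 200 training and
100 + 100 held-out proteins, and the environment gradient at 14 species ×
300 proteins — sizes at which per-species disordered fractions
concentrate within ±0.02 of their targets (the per-species standard
error is ≈ 0.009 with the default block lengths) while the whole suite
stays fast. Statistical fixtures use fixed seeds throughout; the
stationarity check of the hidden chain uses a short-block archetype
(mean disordered block 5) so that a ±0.01 band at $10^5$ residues is a
~3σ test of the stationary distribution rather than of seed luck.

## Known limitations

- The bundled predictor is composition-driven; it cannot see
  position-specific structural signals (binding motifs, secondary
  structure propensity in context) and under-resolves disorder in
  proteins whose ordered and disordered regions have similar
  compositions.
- CDF boundary coordinates depend on the calibration sets; boundaries
  from different references are not interchangeable, which is why the
  boundary object carries its grid, active bins and training accuracy.
- The CH boundary constants are the published ones for natively unfolded
  vs compact proteins; at extreme compositions (e.g. halophilic acidic
  proteomes) the linear separator is known to be conservative.
- KL similarity bands were established for proteome-scale compositions;
  for small sequence sets the divergence estimate is upward-biased and
  the bands should not be over-interpreted.
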