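---
title: "Methods: solubility profiling and cytoplasm biophysics during germination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solubility profiling and cytoplasm biophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solubilome)
```

## The measurement model

Dormant yeast ascospores carry an unusually dense, viscous and acidic
cytoplasm, and many proteins sit in insoluble assemblies that dissolve as the
spore germinates. This package quantifies that transition from two sides:
a sedimentation-proteomics side (which proteins are insoluble, and how that
changes over the germination time course) and a biophysics side (how viscous
and how acidic the cytoplasm is, and how stress resistance decays).

### The pellet-partition index

Cell extracts are fractionated by ultracentrifugation and both fractions are
quantified by LC-MS/MS. For each protein the pellet-partition index is

$$P = \frac{A_{\mathrm{pellet}}}{A_{\mathrm{supernatant}} + A_{\mathrm{pellet}}}$$

with iBAQ-style abundances $A$. $P = 0$ means the protein was found only in
the supernatant (soluble), $P = 1$ only in the pellet (insoluble). The
statistic is scale-invariant (abundance units cancel) and complementary
(`P(s, p) + P(p, s) = 1`); both properties are enforced by tests. The index
is undefined when both fractions are zero, which is why detection filtering
precedes it.

### Detection filters

A protein enters the analysis only if

1. sequence coverage ≥ 10% (`min_coverage`),
2. at least 2 peptides (`min_peptides`),
3. total abundance (supernatant + pellet) > 0 in **every** replicate at
   **every** time point.

Coverage and peptide count are protein-level quantities in MaxQuant-style
tables, so they are evaluated on per-protein maxima across rows, i.e. across
the experiment rather than per time point. That reading of the "at least two
peptides" rule is the package default and is configurable. Each excluded
protein is reported with one reason, assigned in the priority order
`low_coverage` > `few_peptides` > `incomplete_series`, so the filter report
always partitions the input.

Per-replicate indices are averaged into the mean trajectory matrix used by
everything downstream; replicate agreement is summarized as pairwise Pearson
correlations over all shared protein × time cells (pairwise deletion for
missing cells).

## Trajectory clustering and class labels

Mean trajectories are clustered by agglomerative hierarchical clustering with
**complete linkage** on **Euclidean** distance. The linkage and the
distance-criterion cut are fixed by the method being reproduced; the metric
is not stated there, so Euclidean — the default of the library that method
used — is adopted. The tree is cut at the smallest distance threshold that
yields exactly `n_clusters` (default 5) flat clusters. When tied merge
heights make such a threshold impossible (duplicated trajectories are the
degenerate case), the cut fails loudly unless `force_split = TRUE`, which
falls back to the deterministic merge-order tie-break of `stats::hclust`.
Clustering runs on mean trajectories (not per-replicate ones) and the
vegetative column is included in the clustered vector; both choices follow
the upstream analysis where the mean index is the stated unit of analysis.

Cluster median profiles are mapped onto the five canonical classes by shape
rules on the median trajectory $m$ with range $r = \max m - \min m$:

* **static** ($r <$ `static_range`, default 0.25): `mostly_pellet` if
  $\bar m \ge 0.5$, else `mostly_supernatant`;
* **transient solubilization**: the minimum sits at an interior time point
  and both endpoints exceed it by `interior_margin` (default 0.2);
* otherwise **gradual desolubilization** if the net rise is at least
  `monotone_margin` (default 0.15), **gradual solubilization** for the
  mirror-image fall;
* anything else is an explicit ambiguity error (as is any label claimed by
  two clusters).

The thresholds were chosen once to separate the published archetype shapes
with margin, and they do: each archetype plus per-point Gaussian noise up to
sd 0.03 keeps its label in every tested draw. At sd 0.05 a single 5-point
profile crosses the static-range boundary by chance in roughly 2 of 1000
draws, so the often-quoted robustness to sd 0.1 does **not** hold for raw
profiles; it is irrelevant in practice because the rules are applied to
cluster medians, whose noise shrinks with cluster size
($\approx \mathrm{sd}/\sqrt{n}$).

The *changing set* is the union of the three dynamic classes, kept in input
order. It feeds the interaction-pair scan (each normalized undirected edge
with both endpoints in the set, counted once) and the per-class enrichment.

## Enrichment

Each (term, cluster) pair gets a one-sided (over-representation) exact
hypergeometric test: $P(X \ge k)$ with $X \sim \mathrm{Hyp}(N, K, n)$, where
$N$ is the size of the detected-protein background, $K$ the term's members
inside that background, $n$ the cluster size and $k$ the overlap. The
background is the filtered set, not the genome — terms are restricted to it
before counting. Two additions are standard practice rather than part of the
reproduced method and are therefore emitted alongside raw p-values, never in
place of them: Benjamini–Hochberg q-values per cluster, and a term-size
floor (`min_term_size = 2`) that drops degenerate single-protein
"enrichments".

The test suite checks the tail mass against direct enumeration of the pmf
for every configuration with $N \le 20$, and calibrates the procedure with a
permutation null: cluster labels drawn uniformly at random from the
background. Discreteness makes the attainable level depend on $(N, K, n)$;
the null configuration ($N = 150$, $K = 20$, $n = 40$) was chosen, before
running any permutation, so the exact attainable level (0.0468) sits close
to the nominal 0.05.

## Particle tracking and microrheology

Fluorescent tracer particles (self-assembling μNS-GFP) report cytoplasmic
viscosity through their mean squared displacement. Defaults follow the
imaging setup being emulated: 10/75 μm per pixel, 2 frames per second, and a
minimal integrated-mass threshold of 200 to reject spurious signals.

* **Detection**: local maxima within a `diameter` window, refined to a
  sub-pixel centroid by intensity weighting after subtracting the local
  background (median of the window's perimeter ring). Candidates closer than
  `separation` (default: the diameter) are merged, keeping the more massive.
* **Linking**: frame-to-frame assignment minimizing total squared
  displacement, with no link longer than `max_disp` and an unlinked
  detection costing `max_disp`². With at most 7 competing detections/tracks
  the assignment is exhaustive (exact); beyond that, greedy in ascending
  distance. Tests check the exhaustive regime against an independent
  brute-force matcher. Gaps up to `memory` frames can be bridged.
* **MSD**: per particle, the mean over all overlapping ordered pairs at each
  lag; the ensemble curve is the pair-count-weighted mean over particles.
  The estimator is translation- and rotation-invariant and an ensemble of
  copies of one track reproduces that track's curve (both tested).
* **Diffusion**: weighted least squares of $\mathrm{MSD} = 4 D \tau$ through
  the origin over lags 0.5–5 s (configurable). No localization-noise offset
  is subtracted, matching the reproduced analysis. A centered weighted $R^2$
  below 0.9 flags non-diffusive curves (a ballistic $\tau^2$ curve is
  flagged; clean Brownian ensembles are not).

One numerical consequence deserves emphasis. Localization noise of
$\sigma$ per coordinate adds a constant $4\sigma^2$ to the measured MSD. At
the benchmark settings ($\sigma = 0.02$ μm) this floor (0.0016 μm²) is
comparable to the spore-like diffusive signal at 1 s
($4 D \tau = 0.002$ μm² for $D = 5\times10^{-4}$ μm²/s), so the measured
vegetative/spore contrast compresses from the planted 2.0 decades to about
1.75. The acceptance benchmark computes and reports the measured value; no
offset correction is applied to chase the planted number.

## pH calibration and inversion

The ratiometric biosensor's 405/488 excitation ratio rises sigmoidally with
pH. Background-subtracted calibration medians are fitted by least squares to
a four-parameter logistic

$$\mathrm{ratio}(\mathrm{pH}) = \ell + \frac{u - \ell}{1 + e^{-s(\mathrm{pH} - m)}}$$

(increasing in pH for this sensor class), and per-cell sample ratios are
inverted analytically. Ratios outside the open interval $(\ell, u)$ are
clamped just inside the asymptotes and flagged; all-out-of-range input is an
error, as are flat (< 2% relative range) and non-monotone (Spearman ρ < 0.5)
calibration data. The blank is a per-sample-type parameter, because
calibration and measurement must share the subtraction convention.

On a 9-point pH 5.0–9.0 grid the curve's asymptotes are extrapolated, so the
midpoint parameter is only weakly identified under multiplicative noise —
individual fits can trade midpoint against slope and asymptotes while
reproducing the data closely. The package therefore treats the *inversion*
as the contract: noise-free round trips are exact to well below 0.02 pH, and
with 2% calibration noise plus 5% per-cell noise the planted pH series
(5.9, 6.2, 7.3, 7.4) is recovered within 0.1 pH. Parameter recovery is only
guaranteed (to 1e-6) on noise-free data.

## Growth, heterogeneity, trehalose

The **heat-resistance score** is the ratio of the areas under the treated
and untreated growth curves, both integrated up to the time the untreated
culture reaches its stationary plateau. The reproduced method delegated the
area to a fitting package without stating its rule; here the area is an
assumption-free trapezoid of OD above the initial baseline (clipped at zero
so read noise cannot create negative area), which matches the analytic
logistic integral within 1% at 0.1 h sampling — a documented deviation.
Plateau detection: the first time the 3-point moving average stays within 2%
of its maximum for 3 consecutive readings; if that never happens the full
window is used with a warning. The score is 1 when treatment does nothing,
0 when it sterilizes the culture, and decreases monotonically with
treatment-induced lag.

The **heterogeneity score** of a cell is the coefficient of variation
(sample sd / mean) of pixel intensities inside its mask — high for
concentrated foci, low for diffuse signal, invariant to exposure scaling.
**Trehalose content** is the glucose concentration after trehalase digestion
minus the concentration without digestion, floored at zero with a warning
when assay noise makes the difference negative.

## The synthetic world

Every pipeline input can be generated with planted truth; generators are
pure functions of configuration + seed (the caller's RNG state is restored),
and truth tables travel with each dataset.

* **Solubility**: five archetype trajectories over the default grid
  (0h, 1h, 3h, 6h, vegetative) — flat 0.85, flat 0.15, a transient dip
  (0.80, 0.20, 0.70, 0.80, 0.80), and two monotone ramps between 0.20 and
  0.80. Per-replicate per-time truth is archetype + additive Gaussian noise
  (default sd 0.05) clipped to [0.01, 0.99]; additive-clipped was chosen
  over logit-normal for transparency, and the recovery thresholds were
  established under it. Totals are log-normal per protein
  (meanlog = log(1e6), sdlog = 1.5, emulating iBAQ magnitudes) with mild
  per-measurement jitter; coverage and peptide counts pass the filters
  except for configurable spiked failures, one per filter reason. The
  default class counts (425/359/15/17/79) plant the published composition:
  895 analyzable proteins, 111 of them changing.
* **Brownian tracks**: per-axis increments $\mathcal N(0, 2D\Delta t)$, so
  the true ensemble MSD is $4D\tau$; optional per-coordinate localization
  noise.
* **pH**: calibration medians from the 4PL with multiplicative noise;
  per-cell ratios at planted true pH with a stated cv.
* **Growth**: logistic curves; treatment scales the initial population by
  (1 − kill fraction) and shifts the curve by a lag.
* **Cell images**: disk mask, diffuse signal plus Gaussian foci, optional
  Poisson-like noise, with the integrated signal reported so foci/diffuse
  pairs can be intensity-matched.

What the generator does **not** emulate: intensity-dependent MS noise,
missingness-not-at-random, correlated replicates, real GO term structure, or
optical artifacts beyond Gaussian spots. A green recovery test therefore
establishes that the estimators invert the stated generative model — not
that they are robust to everything real data does.

## Limitations

* The clustering layer is exact hierarchical clustering; for very large
  matrices ($\gg 10^4$ proteins) the $O(n^2)$ distance matrix dominates.
* Track linking is locally optimal per frame (exact only up to 7 competitors
  per frame); global multi-frame optimization is out of scope.
* The benchmark layer runs on the synthetic preset when the deposited
  per-protein solubility table (an online supplement) is not available
  locally; composition checks on the preset validate the pipeline, not the
  deposited data.
* Rheological moduli, cell segmentation, and raw MS/flow-cytometry file
  parsing are out of scope; tables are the input boundary.
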