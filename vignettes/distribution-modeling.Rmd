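---
title: "From presence-only records to validated distribution models"
author: "admodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From presence-only records to validated distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admodel)
```

## The modeling problem

Museum occurrence records tell us where a species *has been found*, not
where it is absent, and they were collected over decades while land cover
changed underneath them. `admodel` implements a pipeline built around that
asymmetry:

* a **potential distribution model (PDM)** is fitted from presence records
  and abiotic raster layers only (climate-like and topographic variables
  that change slowly), then binarized at a data-driven threshold;
* the PDM is reduced to an **actual distribution model (ADM)** by removing
  cells whose present-day land cover is unsuitable for the species;
* the ADM — the claim about where the species should be encounterable
  *today* — is validated against an independent field survey.

All grids share one georeferencing convention: square cells of one size,
row 1 at the top, cell `(r, c)` covering a half-open square so every point
belongs to exactly one cell (points exactly on the right/bottom edge of the
grid are clipped inward). Indices are 1-based, the natural convention for R
matrices; invalid cells are carried as a mask in memory and as a declared
nodata value on disk. Rasters are exchanged as ESRI ASCII grids — a plain
text, GIS-standard format whose header carries the same georeferencing
payload a GeoTIFF would, and which round-trips bit-identically at 17
significant digits.

## ENFA: marginality, specialization, tolerance

The Ecological Niche Factor Analysis engine compares the species'
environmental space against the global space of the study region. Layers
are standardized to global mean 0, sd 1 (population denominator, so
standardization is idempotent). The presence sample is the set of
*distinct* presence cells: duplicate records within one cell add no
environmental information and would otherwise overweight heavily collected
localities.

With `m` the presence mean vector, the global marginality is
`M = ||m||/1.96`; the 1.96 constant is kept literal so that `M = 1`
corresponds to a ~2-sd displacement from the regional mean. The marginality
axis is `u1 = m/||m||`; if `||m|| = 0` (a species indistinguishable from
the background) the first principal axis of the presence sample is
substituted, with a message.

Specialization axes should maximize the variance ratio global/presence in
the subspace orthogonal to `u1`. Generalized eigenvectors of that problem
are orthogonal with respect to the presence covariance, not the identity, so
"ratio-maximizing directions" and "orthonormal factors" cannot both hold
exactly. We solve the symmetric whitened eigenproblem
`Sp^(-1/2) Sg Sp^(-1/2)` inside an orthonormal basis of the
orthocomplement: the eigen*values* are exactly the generalized variance
ratios, and the returned axes are exactly orthonormal (a validity-checked
invariant of the fitted object). The tolerance index is
`T = 1/sqrt(mean λ)` over all V factors; when the presence covariance
equals the global covariance every ratio is 1 and `T = 1` exactly. Printed
tolerance values from other ENFA software may sit on a different scale, so
`T` is treated as a relative, not absolute, measure.

Numerical conventions:

* near-singular presence covariances (expected with collinear layers) get a
  ridge of `1e-6` on the diagonal, with a warning;
* retained factors are the smallest prefix (marginality axis always
  included; specialization axes ordered by decreasing eigenvalue) whose
  summed absolute eigenvalues reach 80% of the total — a deterministic
  alternative to broken-stick selection;
* suitability scoring uses a median-count rule: per retained factor, the
  share of presence cells whose score deviates from the presence median at
  least as much (two-sided, absolute deviation) as the focal cell's; cell
  score = eigenvalue-weighted mean of those shares, times 100. The rule is
  fixed here and verified against a brute-force counting oracle;
  deviations are rounded at `1e-9` standardized-score units before
  comparison so that tie handling is stable under serialization round trips
  and reordered floating-point arithmetic.

## Auxiliary engines and the external adapter

Multi-engine workflows (cross-engine pseudoabsences, engine comparison)
need more than one suitability surface. Two deterministic, assumption-light
engines stand in for heavier algorithms:

* **percentile envelope** — per layer, `2·min(F, 1−F)` with `F` the
  mid-distribution empirical CDF of the presence sample (the percentile
  convention under which the sample median sits exactly at 0.5, so a cell
  at the presence median of every layer scores 100); the cell score is the
  worst layer's score;
* **Mahalanobis distance** — squared distance to the presence centroid
  under the presence covariance, rank-normalized over valid cells (ties
  share the lowest rank). Rank normalization avoids the chi-square
  distributional assumption; scores are then uniform on the landscape,
  which is immaterial for thresholding by scan.

Suitability surfaces produced by external software enter through an
adapter that enforces grid alignment and the scale contract: continuous
surfaces are clipped to [0, 100]; ordinal surfaces must be integers 1–10
(the narrow-scale convention of some rule-based engines) and are
thresholded on their own 1–10 candidate grid.

## Thresholding and evaluation

Presence-only data cannot fill a confusion matrix, so pseudoabsences are
drawn uniformly, without replacement, from cells predicted *absent* by a
different engine than the one under evaluation (sampling them from the same
engine's absence area would make the test circular; the cross-engine rule
is enforced with a warning hook). Because the other engine has not been
thresholded yet at that point, its preliminary absence area is taken as
scores below 20 — the wide end of the candidate interval scan — and the
cutoff is exposed as a configuration parameter. One pseudoabsence per test
presence keeps the design balanced.

Occurrences are split 75/25 (train/evaluation) by a seeded shuffle of
records. Candidate thresholds are a finite ascending list — default
3, 20, 40, 60, 70, 80, 90 on the 0–100 scale, 1..10 for ordinal models —
mirroring an interval scan from wide to narrow prediction ranges rather
than a continuous optimizer. At each candidate the confusion matrix yields
kappa, sensitivity and specificity; the AUC is the trapezoid area over the
swept ROC points plus the endpoints (0,0) and (1,1), which equals the
Mann–Whitney estimate exactly when the candidate set contains every
distinct point score.

Two selection rules are provided: maximum kappa, and the ROC point closest
(Euclidean) to the perfect corner (0, 1) — the latter is the operational
reading of "maximize sensitivity, minimize 1−specificity"; Youden's J is
available as an alternative. Ties go to the *lowest* threshold in both
rules (the more inclusive model). Selected threshold sets are compared
with a Wilcoxon signed-rank test implemented in-package: zero differences
dropped, midranks for ties, `W = min(W+, W−)`, exact two-sided p by full
enumeration of sign assignments up to n = 20 (correct under ties, which the
closed-form null distribution is not), and a tie-corrected,
continuity-corrected normal approximation above.

## Habitat masking and validation

The ADM reduction requires the land-cover raster to nest exactly under the
model grid (integer subcell ratio; the bundled generator uses 4, the analog
of 250 m cover under 1 km cells). A presence cell survives if the fraction
of its subcells carrying a suitable class reaches `suitableFraction`. The
original overlay rule behind such reductions is rarely stated; majority
(0.5) is the neutral default and the parameter is exposed. ADM presence is
asserted to be a subset of PDM presence on every call.

Validation runs twice, as in point-count field studies:

* **site evaluation** — distinct cells containing at least one field point;
  success = share of those cells the ADM predicts present. Duplicate points
  in a cell collapse, so the statistic is per occupied cell, not per record;
* **buffer evaluation** — the union of disks (default radius: one cell)
  around field points, membership by *cell-centre* inclusion (the
  deterministic reading of pixel-count extraction); success = share of
  buffer cells predicted present.

Batch summaries report the mean and *population* (n-denominator) standard
deviation of the success columns over species with at least one field
presence cell. The museum-vs-field proportionality check is a plain Pearson
correlation of per-species counts with the t-transform p-value.

Stacked richness is the cellwise sum of ADM presences, cross-tabulated
against ecoregion polygons by cell-centre containment (even-odd rule over
rings, so holes are honoured; boundary cells go to the first containing
region in file order). Default richness classes follow the low/medium/high
convention 1–4, 5–8, 9–n, truncated for small stacks.

## What the synthetic module emulates — and what it does not

Every stage is exercised end-to-end on generated data:

* **layers** are random mixtures of 3 latent Gaussian-smoothed fields plus
  30% independent smoothed noise, standardized exactly. The latent
  structure reproduces the strong collinearity of real bioclimatic
  variables, which both ENFA's use of data redundancy and the realism of
  planted niches depend on. The smoothing sd (`autocorrRange`, default 6
  cells) sets the spatial autocorrelation range; 0 gives white noise.
* **virtual species** have Gaussian niches in standardized environmental
  space. The centre norm is exactly `1.96 × marginalityTarget`, so the ENFA
  marginality estimator targets the planted value; the centre *direction*
  points toward the environment of a seeded random landscape cell (screened
  over up to 50 candidates for niche support), because an isotropic random
  direction at that norm almost surely points into environmentally
  unrealised space — real species optima lie on the realised manifold.
  Widths are solved per layer by root finding so the suitability-weighted
  sd matches `toleranceTarget` (default 0.5). Niches with fewer than 50
  cells above suitability 0.5 are rejected as degenerate.
* **museum sampling** draws cells with probability ∝ truth^γ (γ = 2:
  detection concentrates in good habitat), with optional seeded hotspot
  bias for collection clustering; points are uniform within the cell.
  In the scenario driver, per-species record counts are Poisson draws
  scaled by landscape prevalence — widespread species are collected more,
  which is what makes the museum-vs-field proportionality check meaningful.
* **field surveys** place sites by stratified random sampling in cells
  whose *dominant* land-cover class (modal subcell class, ties to the
  lowest code) suits the species, then fill a square site extent (default
  2 cells) with up to 30 points at ≥ 0.2 map-unit spacing — the analog of
  ~30 point counts 200 m apart under 1-km cells — and record at most one
  occurrence per point with probability `detectionProb × truth`.

Default scenario sizes: 100 × 100 cells, 6 layers, 3 species with planted
marginalities 1.0/1.2/1.5 and tolerance 0.5, ~100 museum records per
species, 46 survey sites, 4 land-cover classes at a 4× finer grid. These
sizes keep a full 20-seed study under a minute while leaving every fitted
quantity well away from small-sample degeneracy; the bundled
`scenario_small.yaml` records a 60 × 60 three-species instance with its
seed for quick demonstrations.

What passing synthetic tests does **not** show: the generator has no
observation-effort covariates, no temporal land-cover change (the ADM's
main real-world failure mode), no coastline/resolution mismatches, no
spatially structured detection failure, and Gaussian niches with a single
optimum. Success rates on real data should be expected to be lower and
more heterogeneous than the synthetic medians.

## Degenerate inputs and edge conventions

* All-zero difference vectors in the Wilcoxon test return a flagged
  degenerate result with p = 1 rather than an error.
* Zero-variance count vectors make the proportionality correlation
  undefined; the result is flagged, with a warning.
* Points on invalid cells are dropped from evaluation with a logged count;
  points outside the grid are dropped by the declared clip step.
* Kappa or the ROC criterion undefined at *every* candidate threshold is a
  selection error; undefined values at some candidates are skipped.
* Empty richness classes cross-tabulate as flagged all-zero rows.

## Limitations

The ENFA suitability scoring rule is one defensible reading of the
"median-count" family used by ENFA software whose exact algorithm is
unpublished; absolute scores are therefore not comparable across
implementations, though orderings and thresholded models are robust. The
tolerance index shares this caveat. The pseudoabsence procedure inherits
the geography of the donor engine's absence area; with only two internal
engines the donor is fixed by exclusion. Buffer membership by cell-centre
inclusion undercounts cells clipped by the disk boundary relative to
any-overlap extraction; with the default radius equal to the cell size the
difference is one ring of cells at most.
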