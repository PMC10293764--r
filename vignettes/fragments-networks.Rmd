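---
title: "Annotating Orbitrap MS2 spectra with fragments networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating Orbitrap MS2 spectra with fragments networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragnets)
```

## The measurement model

An Orbitrap records, per MS2 scan, a profile spectrum: many (m/z, intensity)
points tracing the shape of each peak. `fragnets` treats every point as one
observation of the underlying ion's m/z and assumes the points of a peak are
normally distributed around it. Under that model a peak is not a number but
a sample, and it carries its own uncertainty:

* **centroid** — the intensity-weighted mean of the cluster's m/z values
  (an unweighted mean is available via `run_params(weighted_centroid =
  FALSE)` for sensitivity checks);
* **confidence interval** — the two-sided t-interval for the mean,
  `qt(1 - (1 - level)/2, n - 1) * sd(mz) / sqrt(n)`, reported as a
  half-width in ppm of the centroid. The level defaults to 0.95, the
  conventional reading of a "confidence interval";
* **Shapiro–Wilk p-value** — a per-peak check of the normality assumption.
  A rejection (p < 0.05) flags the peak in the results but does not drop
  it: a skewed point cloud still has a usable centroid, and dropping peaks
  on a 5% test would discard one peak in twenty under the null.

Clusters are formed by scanning the sorted points and splitting wherever
the gap between neighbours exceeds `gap_ppm` (default 10 ppm) of the local
m/z. A relative gap is the natural rule for an analyzer whose resolution
scales with m/z; an absolute-Da gap would over-split high masses or
under-split low ones. Clusters need `min_cluster_points = 3` points (the
smallest sample the Shapiro–Wilk test accepts) unless they dominate the
intensity (`intensity_floor_pct`), in which case they are kept with an
undefined CI and matched at the default tolerance instead.

The noise threshold (`noise_threshold`, counts) is applied before
clustering. It mostly buys speed: the clustering and the per-peak
statistics are robust to moderate noise, but every surviving point enters
the statistics, so a threshold separating electronic noise from signal is
worth setting when known.

## Chemical consistency and fragments networks

Fragmentation of a singly charged ion is modelled as a decomposition into a
smaller ion and a neutral molecule. Writing formulas as integer vectors
over the twelve isotope dimensions (H, C, ¹³C, N, O, F, Na, P, S, ³⁴S, Cl,
K), two annotations are *consistent* when their difference is non-negative
in every dimension and non-zero overall — the neutral loss. Heavy isotopes
are independent dimensions on purpose: a fragment containing ¹³C cannot
arise from a parent without one, so isotopologue candidates are pruned by
the same subtraction that prunes everything else.

A *fragments network* fixes one candidate formula per peak (nodes) and
draws an edge for every consistent pair; the direction (which ion is the
parent) is recorded but ignored for scoring. The *grade* — the edge count —
is the selection criterion: among all combinations of per-peak candidates,
the assignment with the most internally consistent chemistry wins. Ties are
broken by the smallest total |mass error| and then lexicographically by the
formula strings, making the selection deterministic.

Exact selection enumerates all combinations and is refused above
`network_cap` (default 10⁶) because the combination count is the product of
the per-peak candidate counts. Above the cap a greedy mode seeds each peak
with its minimum-error candidate and hill-climbs single-peak swaps,
restarted from every single-candidate perturbation of the seed; it is a
local optimum, and the exact mode serves as its oracle in the tests at
small scale. In practice tight per-peak tolerances keep candidate sets
small enough that exact mode handles published-size spectra in well under a
second.

## Candidate enumeration

`enumerate_formulas()` returns every formula within the user-supplied
maximum atomic subscripts whose ion m/z (exact mass minus/plus one electron
mass for cations/anions) falls within the peak's window. The search is a
depth-first scan over dimensions ordered by decreasing isotope mass,
pruning a branch as soon as the reachable mass range cannot intersect the
window; it is exact, and the tests verify it against a brute-force grid
filter. Negative ionization only flips the sign of the charge carrier.

Product-peak candidates must additionally be proper sub-formulas of at
least one precursor candidate, and peaks heavier than the precursor window
are excluded up front: they cannot be products of the selected precursor.
The precursor peak is a mandatory network node. When no measured peak falls
inside the precursor window — possible in profile mode when the precursor
fragments completely — a virtual node at the target m/z anchors the
network but is not reported as a spectrum row.

## Matching tolerances

* **Profile mode** (`annotate_profile()`): each peak is matched within its
  own confidence interval, floored at `ci_floor_ppm` (default 0.5 ppm) so
  that a degenerate cluster cannot produce a zero-width window.
* **Centroided mode** (`annotate_centroided()`): the per-peak information
  is gone, so one *fixed absolute window* is used for the entire spectrum:
  `default_tol_ppm` (default 10) parts per million **of the target
  precursor m/z**. For a 254 Da precursor that is ±0.0025 Da at every peak.
  We chose an absolute window over per-peak ppm deliberately: public
  centroided records are snapshots of an instrument whose absolute
  calibration error over one scan is roughly constant in Da, and a per-peak
  ppm rule starves low-mass fragments of tolerance while being needlessly
  generous near the precursor. The choice is visible in the worked
  examples: low-mass fragments whose formulas sit 5–15 ppm from their
  printed m/z are still correctly annotated, while the same absolute window
  stays selective at high m/z.

## Rejecting isolated annotations

Every product candidate is a sub-formula of the precursor by construction,
so an edge to the precursor node carries no evidence — it is guaranteed.
The informative edges are those *among product ions*. With
`reject_isolated = TRUE` (the default), a product-ion annotation that is
consistent with no other product-ion annotation is rejected and the peak
reported unannotated, provided the network contains at least two annotated
product ions; when there is only a single product ion (so no product–product
edge is possible), consistency with the precursor is accepted as the only
available evidence. This is what removes, e.g., an isotopologue-artifact
peak whose only arithmetic match is a formula unrelated to the rest of the
fragmentation chemistry. Setting `reject_isolated = FALSE` keeps such
annotations, flagged by their `status`.

## The synthetic-data generator

`simulate_spectrum()` realizes exactly the measurement model the method
assumes: for each true fragment ion, `points_per_peak` m/z values drawn
from Normal(ion m/z × (1 + bias), ion m/z × σ_ppm × 10⁻⁶), plus uniform
noise points tagged in the output. Intensities follow a Gaussian profile
around the centre by default (the approximate shape of an Orbitrap profile
peak); a flat profile is available as the worst case for intensity
weighting. Defaults — σ = 3 ppm, 8 points per peak — mirror the scale of
the per-peak statistics seen in real Orbitrap MS2 scans (confidence
intervals of a few ppm from 7–8 points per peak).

What the generator does *not* emulate: peak-shape asymmetry, coalescence of
near-isobaric ions, intensity-dependent m/z bias, chimeric precursors, and
chromatographic structure across scans. Passing the synthetic end-to-end
tests therefore demonstrates correctness of the statistics and the
combinatorics under the model's own assumptions, not robustness to every
real-data pathology.

Two calibration facts from the test suite are worth knowing. With the flat
intensity profile the centroid is the plain mean and the t-interval is
exact, so CI coverage sits at the nominal 95%. With the Gaussian profile
the intensity weighting down-weights outlying points, the centroid is
*more* precise than the unweighted interval assumes, and coverage runs
conservative (≈97–99%) — which also pushes end-to-end formula recovery at
σ = 3 ppm, 8 points/peak above 95%.

## Numerical and design choices

* Monoisotopic masses are CODATA/AME values; electron mass 5.4858×10⁻⁴ Da.
  Published reference tables differ at the 8th decimal, so predicted m/z
  values agree with other software to about 10⁻⁷ Da — below any realistic
  measurement uncertainty, but visible in the last printed digit of a
  7-decimal table.
* Mass errors are reported as magnitudes, rounded to one decimal only at
  report time; internal comparisons use full precision.
* Formula strings render in a fixed element order (C, ¹³C, S, ³⁴S, O, N, H,
  then the rest alphabetically) so equal formulas always compare equal.
* Scan selection for a target precursor uses a 0.5 Da window, a typical
  quadrupole isolation half-width; ties go to the highest total intensity.
* The results writer emits csv/tsv with a fixed column schema (formula,
  mass error, predicted m/z, measured m/z, CI, relative intensity, point
  count); identical inputs yield byte-identical files.

The test suite runs the worked examples at their published sizes (3–18
peaks), the oracle comparisons at 100 random enumeration instances and 15
selection instances of ≤ 10⁴ combinations, and the synthetic end-to-end
check at 20 seeds × 14 fragments plus 200 peaks for CI coverage — sizes
chosen to exercise every code path while keeping a full run around a
minute.

## Limitations

* Only singly charged ions and ±H adducts; no multimers, no Na/K adduct
  enumeration (sodium and potassium are available as formula dimensions,
  not as adduct hypotheses).
* No valence or ring-double-bond filtering of candidate formulas: the
  network grade is the only chemical plausibility criterion.
* No isotope-pattern scoring from MS1 intensities; the precursor is ranked
  by the same network that ranks the fragments.
* Exact selection is exponential in the worst case; the greedy fallback is
  a heuristic without optimality guarantees.
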