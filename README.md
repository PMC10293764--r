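# fragnets

De novo annotation of Orbitrap DDA MS2 spectra by **fragments networks**.

## The problem

High-resolution tandem mass spectrometry assigns each fragment peak a
molecular formula ("annotation"), which is the first rung on the ladder from
an accurate mass to an identified compound. Two pieces of information are
usually thrown away in that step:

1. **The per-peak uncertainty.** Orbitrap profile data traces each peak as a
   distribution of (m/z, intensity) points. Centroiding collapses it to a
   single number, so every downstream tool has to assume one global mass
   tolerance. `fragnets` keeps the distribution: the centroid is the
   intensity-weighted mean of the points, and the matching tolerance of each
   peak is the two-sided *t*-confidence interval of its mean m/z,

   CI = t(α/2, n−1) · s/√n,

   expressed in ppm of the centroid (normality of the point distribution is
   checked per peak with a Shapiro–Wilk test).

2. **The chemistry linking the fragments.** Fragmentation of a singly
   charged ion is a decomposition into a smaller ion plus a neutral molecule,
   so two correct annotations must balance atoms: parent − child must be a
   non-negative, non-empty formula in every isotope dimension (*chemical
   consistency*). Given one candidate formula per peak (nodes), every
   consistent pair is an edge; the resulting graph is a **fragments
   network** and its number of edges is its **grade** (at most n(n−1)/2 for
   n nodes). A spectrum with k₁, …, kₙ candidates per peak generates
   ∏ kᵢ networks — five peaks with five candidates each already give 3125 —
   and the network of maximum grade is selected as the annotation of the
   whole spectrum, ties broken by the smallest total mass error.

Candidate formulas per peak are enumerated exhaustively within user-supplied
maximum atomic subscripts over H, C, N, O, F, Na, P, S, Cl, K plus the heavy
isotopes ¹³C and ³⁴S, constrained to sub-formulas of a precursor candidate.
The method needs no spectral library or external database.

## Worked example

Annotate the published sulfamethoxazole MS2 peak list (centroided, so a
fixed 10 ppm window is used) against the protonated molecule at m/z
254.0603:

```r
library(fragnets)

pl     <- read_peaklist(system.file("extdata", "sulfamethoxazole_ms2.csv",
                                    package = "fragnets"))
bounds <- read_bounds(system.file("extdata", "sulfamethoxazole_bounds.csv",
                                  package = "fragnets"))
ann <- annotate_centroided(pl, 254.0603, bounds)
glance(ann)
#>   target_mz precursor_formula n_peaks n_annotated grade max_edges n_networks
#> 1      254. C10SO3N3H12+           16          14    66       112        288
write_results(ann, "sulfamethoxazole_annotated.csv")
```

The results table (`tidy(ann)` or the csv) assigns a formula to 14 of the 16
peaks:

```text
Molecular formula,Mass error (ppm),Predicted m/z (Da),Measured m/z (Da),...
C5H5+,5.8,65.0385766,65.0382000,...
C6NH6+,1.4,92.0494756,92.0496000,...
C6SO2NH6+,3.4,156.0113760,156.0119000,...
–,,,157.0146000,...
–,,,158.0078000,...
C10ON3H10+,1.9,188.0818384,188.0822000,...
C10SO3N3H12+,3.6,254.0593889,254.0603000,...
```

The precursor is identified as C₁₀SO₃N₃H₁₂⁺ (protonated sulfamethoxazole);
the 288 possible assignment combinations were enumerated exactly and the
grade-66 network won. The two `–` rows had candidates (C₉O₂NH₃⁺, C₉SNH₄⁺)
but were rejected because they are chemically consistent with no other
product ion — the network itself flags them as implausible. `mass error` is
|predicted − measured| / predicted × 10⁶.

For profile-mode data use `read_mzml()` + `select_ms2()` +
`annotate_profile()`, which estimates a confidence interval for every peak
and matches each peak within its own interval. `simulate_spectrum()`
generates profile spectra with known ground truth, and
`autoplot()` renders annotated spectra and networks. A command-line wrapper
with verbs `annotate`, `annotate-centroided`, `simulate` and `exact-mass`
is installed at `system.file("cli", "fragnets.R", package = "fragnets")`.

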