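---
title: "Quantifying dendrite order in nerve bundles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dendrite order in nerve bundles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The *C. elegans* amphid is a sensory organ whose twelve neurons extend
dendrites in a single tight bundle to the nose tip. With three of those
dendrites (AWA, AFD, ASE) labeled in separate fluorescence channels, one can
ask whether the dendrites occupy stereotyped positions relative to each other
— whether the bundle is *ordered* — and whether that order survives in
adhesion-molecule mutants whose bundles remain fasciculated. `bundleorder`
implements the full quantification chain: extracting a 3D trace per dendrite
from an image stack, reducing the trace triplet to per-position cross-section
triangles, classifying bundles as fasciculated or defasciculated, and testing
order at the population level. Because no microscopy data ship with the
package, a synthetic phantom generator with full ground-truth annotation
stands in for the imaging layer; every stage is validated against phantoms or
independent oracles.

## From image stacks to traces

Each channel is a `voxel_stack`: a 3D non-negative intensity grid with
anisotropic physical spacing (x, y, z in µm). `brightest_path()` runs
Dijkstra's algorithm between two user-supplied endpoint voxels on the voxel
graph, with edge cost

    ((1/(I(u)+eps) + 1/(I(v)+eps)) / 2) * ||p(u) - p(v)||

the mean *inverse intensity* of the two endpoint voxels times the physical
step length. Bright voxels are cheap, so the minimum-cost path follows the
dendrite. Design choices the image metric leaves open:

* **Connectivity.** 26-connectivity, so oblique dendrites do not force
  staircase detours.
* **Zero intensities.** `eps = 1` intensity unit guards the reciprocal;
  there is no division-by-zero failure mode. Exact path invariance under
  intensity rescaling holds when `eps` is scaled along; with fixed `eps` it
  is near-exact.
* **Physical step length.** Multiplying by the Euclidean step in µm makes
  anisotropic z-spacing behave correctly: a z-step through dim voxels is
  genuinely more expensive than an x-step of the same voxel count.
* **Determinism.** Priority-queue ties are broken by lexicographic voxel
  index; identical inputs give identical traces.

Endpoints come from a manifest (or, for phantoms, from ground truth) rather
than interactive clicking. Traced ends usually overshoot the true dendrite
ends; `trim_trace(trace, n_head, n_tail)` removes a counted number of points,
the programmatic equivalent of deleting rows from the distance spreadsheet.

On rendered phantoms at signal-to-background 10 the traced paths stay within
one voxel diagonal of the true centerline (asserted in the test suite).

## Cross-sections, the middle dendrite, and binning

`crop_to_common_extent()` aligns the three traces end-wise: at each end, the
three tip coordinates are averaged, the trace whose tip at that end lies
nearest the average tip of the *opposite* end is the one that reaches least
far, and the other two traces are re-anchored at their points nearest its
tip. `centroid_line()` then resamples each trace to a common number of
equal-arc-length samples (the finest of the three resolutions) and averages
them. Sampling in arc length re-interprets the original pixel-by-pixel walk
for traces that live in physical µm coordinates.

For each centroid sample, `cross_sections()` takes the Euclidean-nearest
vertex on each trace; the three points form a triangle with pairwise
distances d1, d2, d3. The longest distance is the **bundle width**; the
dendrite opposite the longest side is **in the middle** of the other two.
Both quantities depend only on inter-dendrite distances, so they are
invariant under rigid motion and twisting of the bundle (asserted to 1e-9 µm
under random rigid transforms). An exact tie between the two largest
distances (within 1e-9 µm) is flagged ambiguous and resolved by fixed
alphabetical identity priority; flagged counts are reported on the profile.

`bin_profile()` normalizes bundle length: the section series is cut into 100
contiguous bins with boundaries at `round(k*N/100)` and each pairwise
distance is averaged within bins. With 200 sections each bin holds exactly
two adjacent positions. A conservation property (the size-weighted mean of
bin means equals the global mean) guards the uneven cases. The bin's middle
label is recomputed from the *binned mean distances*, not voted over
per-section calls, since everything downstream works from the binned distance
table. Bin 1 is the distal (nose-tip) end. An anatomical head length can be
recorded as metadata, but binning itself is the cross-animal length
normalization, so it is not used in any computation.

## Fasciculation classification

Per-bin width mean and sample SD over an age-matched reference cohort
(`reference_stats()`; sample SD was chosen over the population variant) give
z-scores for any bundle. `classify_defasciculation()` marks a bundle
defasciculated when its width exceeds the reference mean by more than 3.5 SD
(one-sided, strict) for at least 10 consecutive bins. For normally
distributed widths a 3.5 SD two-sided excursion is roughly a 1-in-2000 event
(`z_exceedance_odds(3.5)` = 2149), so a sustained 10-bin run is far beyond
noise. Zero-SD reference bins (possible with degenerate synthetic references)
use z = 0 when the width does not exceed the mean and z = Inf otherwise. The
"positions" of the run rule are the 100 normalized bins. Classification is
monotone in width, and `exclude_defasciculated()` partitions the cohort;
excluded bundles still appear (pink) on width plots but not in order
statistics.

## Order statistics

`tabulate_population()` counts, per bin, how many retained animals have each
dendrite in the middle. Two complementary tests:

* **Chi-squared vs. random** (`chi_squared_vs_random()`): observed counts
  against the uniform expectation n/3 with 2 df. It refuses cohorts with
  n/3 < 5, where the large-count approximation fails — exactly the regime
  the permutation test exists for.
* **Fisher 3×2 permutation ranks** (`permutation_rank()`): the nominal
  p-value is Fisher's exact test on the 2×3 table of the two cohorts' counts,
  computed by full enumeration of margin-consistent tables (feasible for the
  cohort sizes here; there is no asymptotic fallback). For 500 iterations the
  pooled animals are shuffled and re-split into equal halves (⌈N/2⌉ and
  ⌊N/2⌋ when N is odd) and the Fisher p recomputed, yielding 501 p-values
  per bin. The rank of the nominal p among them is the statistic; ranks
  ≤ 25/501 correspond to p < 0.05 and ≤ 5/501 to p < 0.01, via the
  largest-integer-below-α rule.

Two decisions the rank definition leaves open:

* **Ties.** A resampled p equal to the nominal p counts *toward the rank*
  (rank = 1 + #{resampled ≤ nominal}). This is the conservative direction —
  identical cohorts, where every resampled p ties the nominal p of 1, get
  the maximal rank — and it keeps the significance tail exactly calibrated:
  under a true null the p<0.05 tier fires at the nominal 25/501 rate. Because
  the statistic is discrete, ranks are *not* exactly uniform over {1..501}
  under the null: the tie mass sits at the non-significant end, which is
  harmless for inference but visible to a goodness-of-fit test.
* **The random comparison cohort.** The "random" population is an explicit
  seeded multinomial cohort of the same size, not the expected-count vector,
  because the permutation machinery needs individual animals to shuffle.
  One master seed produces deterministic per-bin sub-seeds, so bins are
  independent yet the whole analysis is reproducible. Per-bin tests are not
  multiplicity-corrected across bins; ranks are reported per position as
  color bars.

`detect_switch_point()` finds the first bin whose (majority) middle label
differs from the bin-1 label and persists for more than one bin; single-bin
blips are ignored. Switch-point samples are compared with a two-sample
Kolmogorov–Smirnov test (asymptotic p), appropriate for their non-normal
distribution.

## The phantom generator

`bundle_spec()` + `generate_bundle_traces()` build three tubes on a gently
curving centerline (low-frequency sinusoids, ~30 µm long by default) with a
slowly rotating triangular cross-section frame — rotation is deliberate, so
middle-dendrite calls are exercised under twisting. Defaults emulate the
larval-stage bundle: tube radius 0.25 µm (≈0.5 µm diameter dendrites) and
flanker spacing 1.0 µm, so clean phantom widths sit near 1 µm, between the
~0.9 µm of early larvae and ~1.5 µm of adults. The planned middle dendrite
is placed between the two flankers with a perpendicular offset of 0.3× the
local spacing: the triangle is non-degenerate and the planned label is
geometrically opposite the longest side at every position. Bundle width
varies smoothly per animal (spline through 8 Gaussian knots, SD 0.1 µm);
planted defasciculation segments displace one dendrite radially with
half-cosine shoulders over 10% of the segment. Order models: `fixed`,
`switch` (one identity change at a chosen bin), `random`; `noise_rate`
replaces each position's planned identity with a uniform draw. At an identity
change the dendrites swap slots between adjacent positions — a hard
crossover, the one place the polylines are not smooth.

`render_stack()` rasterizes each tube into its own channel (binary mask at
the tube radius), blurs with a separable Gaussian point-spread approximation,
and adds Poisson-distributed signal plus Gaussian read noise (SD 2) at a
signal amplitude of 200 with background `amplitude/snr`; `snr = Inf` is the
exact noise-free limit. This is deliberately simpler than real optics — no
wavelength-dependent PSF, no camera calibration — but is sufficient to stress
the tracer. `generate_population()` bypasses geometry entirely and draws
categorical middle labels per animal and bin, which is what the statistical
machinery consumes.

What phantoms do *not* capture: out-of-bundle fluorescence (gut
autofluorescence, cell bodies), unequal channel brightness, chromatic offsets
between channels, and real biological width profiles that widen toward the
nose. Passing phantom tests therefore validates the algorithms, not the
imaging conditions of any particular microscope.

## Numerical choices and problem sizes

* Fisher 3×2 enumeration groups tables by probability (log-probability
  rounded to 10 decimals) so the "sum of tables no more probable" rule is
  stable under floating-point noise; permutation resampling reuses one
  enumeration per bin since all resampled tables share margins.
* The defasciculation z rule is strict (`>` 3.5), matching "more than".
* Within the test suite, cohort-scale checks use 18–21 animals and 100 bins
  (typical cohort sizes for this assay), 100-replicate recovery suites for
  switch points and defasciculation, 1000 replicates for null-rank
  calibration, and 120–200 axial positions per phantom; the 526-bundle
  bookkeeping cohort uses the fast non-imaging path.
* With smooth Gaussian width variation, a clean phantom has roughly a 1%
  chance of a sustained 3.5 SD excursion against a 20-animal reference, so
  occasional false-positive defasciculation calls on clean phantoms are
  expected behavior of the rule, not a defect.

## Known limitations

* One dendrite per channel; disambiguating multiple neurites in a channel is
  out of scope, as is automatic endpoint detection and deconvolution.
* Exactly three dendrites; the full twelve-dendrite bundle problem is not
  attempted.
* The Fisher enumeration is exact but quadratic in cohort size; it is meant
  for cohorts up to a few dozen animals, not hundreds.
* Cross-sections use nearest trace *vertices*; at hard identity crossovers
  of phantoms this mixes adjacent positions and can shave a few percent off
  the local width estimate.
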