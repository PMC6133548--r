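# bundleorder

Quantifying the ordered arrangement of labeled dendrites within a nerve
bundle.

In the *C. elegans* amphid, twelve sensory dendrites run to the nose tip as
one tightly fasciculated bundle (~1 µm wide). With three dendrites (AWA,
AFD, ASE) imaged in separate fluorescence channels, `bundleorder` measures
whether those dendrites occupy stereotyped positions relative to each other,
and whether that order changes in mutants whose bundles remain intact. It is
aimed at labs doing multi-channel neurite imaging who want a reproducible,
scriptable version of this quantification — and at anyone who needs its
statistical core: a permutation-rank test for position-wise categorical
distributions.

## Method

1. **Tracing.** Per channel, Dijkstra's algorithm finds the brightest path
   between two endpoint voxels on the 26-connected voxel graph; an edge
   costs the mean inverse intensity of its endpoints times the physical step
   length, `((1/(I(u)+ε) + 1/(I(v)+ε))/2)·‖p(u)−p(v)‖`, so bright dendrite
   voxels are cheap and the shortest path is a 3D trace of the dendrite.
2. **Cross-sections.** The three traces are cropped to a common extent and
   averaged into a centroid line; at each centroid sample the nearest point
   on each trace forms a triangle with pairwise distances *d₁, d₂, d₃*. The
   longest distance is the **bundle width**; the dendrite opposite the
   longest side is **in the middle**. Both are invariant to bundle rotation
   and twisting. Distances are binned into 100 equal segments to normalize
   bundle length across animals.
3. **Fasciculation filter.** A bundle whose width exceeds the age-matched
   reference mean by more than 3.5 SD for at least 10 consecutive bins is
   defasciculated and excluded from order analysis (for normal data a 3.5 SD
   excursion is a ~1-in-2000 event, so a sustained run is far beyond noise).
4. **Order statistics.** Per bin, the counts of animals with each dendrite
   in the middle are tested against a random arrangement (χ² with expected
   counts n/3) or against another cohort: Fisher's exact 3×2 test gives a
   nominal p; 500 merge–shuffle–split iterations give 500 resampled p's; the
   rank of the nominal p among all 501 is the statistic. Ranks ≤ 25/501
   correspond to p < 0.05, ≤ 5/501 to p < 0.01. Switch points (first
   persistent change of the majority middle identity) are compared across
   cohorts with a two-sample KS test.

A synthetic phantom generator (tube geometry with a planted middle-dendrite
program, rendered multi-channel TIFF stacks with PSF blur and Poisson noise,
or direct categorical populations) provides ground truth for every stage.

## Worked example

```r
library(bundleorder)

ordered <- generate_population("switch", n_animals = 18, n_bins = 100,
                               seed = 7, switch_bin = 45, noise_rate = 0.05)
random  <- generate_population("random", n_animals = 18, n_bins = 100, seed = 8)

ordered$counts[45, ]
#> AWA AFD ASE
#>   0   0  18

cs <- chi_squared_vs_random(ordered$counts[45, ])
#> chi-squared = 36.0 (expected 6 per category), p = 1.5e-08

pr <- permutation_rank(ordered$counts[45, ], random$counts[45, ], seed = 9)
#> nominal Fisher p = 7.42e-06, rank 1/501 -> p<0.01

detect_switch_point(majority_middle(ordered))
#> majority middle switches AFD -> ASE at bin 45
```

At bin 45 all 18 ordered animals have ASE in the middle: the χ² statistic of
36 rejects a uniform arrangement, and the permutation test ranks the nominal
Fisher p first among 501, i.e. the ordered cohort differs from a random one
by far more than resampling error (p < 0.01). The majority middle identity
switches from AFD to ASE exactly at the planted bin.

The `analysis/` scripts run the same machinery as a full study over phantom
cohorts — `01_simulate.R` through `05_pipeline.R`: simulation, tracing of a
rendered stack, defasciculation filtering, order statistics and a single-pass
`run_pipeline()` reproduction — writing tables, figures and a JSON summary
under `results/`.

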