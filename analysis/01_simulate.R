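#!/usr/bin/env Rscript
# Simulate the study cohorts.
#
# Two phantom cohorts stand in for the microscopy data: a "wildtype" cohort
# of 18 L4-stage bundles with an ordered middle-dendrite pattern that
# switches identity partway along the bundle, and a "mutant" cohort of 21
# bundles with randomized order, five of which carry a planted
# defasciculation segment. One wild-type phantom is additionally rendered as
# a three-channel image stack for the tracing demonstration in 02_trace.R.

library(bundleorder)

out <- "results/analysis"
dir.create(file.path(out, "stacks"), recursive = TRUE, showWarnings = FALSE)
seed <- 20260926

message("Simulating 18 wild-type-like phantoms (switch at bin 45)...")
wt <- generate_profiles(18, seed = seed, stage = "L4",
                        order_model = "switch", switch_bin = 45,
                        noise_rate = 0.05)

message("Simulating 21 mutant-like phantoms (random order, 5 defasciculated)...")
defasc <- setNames(
  lapply(1:5, function(i) list(c(20 + 8 * i, 40 + 8 * i, 2.0))),
  as.character(c(2, 7, 11, 16, 20)))
mut <- generate_profiles(21, seed = seed + 1, stage = "L4",
                         order_model = "random", defasc_animals = defasc)

saveRDS(list(wildtype = wt, mutant = mut),
        file.path(out, "profiles.rds"))  # scratch for the later stages

message("Rendering one wild-type phantom as a 3-channel stack (snr = 10)...")
spec <- bundle_spec(n_positions = 120, curve_length_um = 15,
                    curve_amp_um = 0.8, order_model = "switch",
                    switch_bin = 45, snr = 10, seed = seed + 2)
truth <- generate_bundle_traces(spec)
stacks <- render_stack(truth)
for (d in DENDRITES)
  write_stack(stacks[[d]], file.path(out, "stacks", paste0(d, ".tif")))
write_truth_json(truth, file.path(out, "stacks", "ground_truth.json"))
saveRDS(list(truth = truth, spec = spec),
        file.path(out, "stacks", "truth.rds"))

message("Cohorts written under ", out)
message("  wild-type animals: ", length(wt), "; mutant animals: ", length(mut))
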