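#!/usr/bin/env Rscript
# Population-level dendrite-order statistics.
#
# Tabulates which dendrite sits in the middle at each normalized position,
# tests the wild-type pattern against a random arrangement (chi-squared and
# Fisher 3x2 permutation ranks) and the mutant cohort against wild type,
# and locates per-animal switch points, comparing their distributions with
# a two-sample KS test.

library(bundleorder)

out <- "results/analysis"
parts <- readRDS(file.path(out, "partitions.rds"))
seed <- 20260926

pops <- lapply(names(parts), function(lab)
  tabulate_population(parts[[lab]]$retained, cohort = lab))
names(pops) <- names(parts)

for (lab in names(pops)) {
  pop <- pops[[lab]]
  write.csv(data.frame(bin = seq_len(pop$n_bins), pop$counts),
            file.path(out, paste0("population_", lab, ".csv")),
            row.names = FALSE)
  ggplot2::ggsave(file.path(out, paste0("population_", lab, ".png")),
                  plot_population(pop), width = 6, height = 4.5, dpi = 120)
  ggplot2::ggsave(file.path(out, paste0("summary_", lab, ".png")),
                  plot_summary_fractions(pop), width = 6, height = 4, dpi = 120)
}

message("Chi-squared vs. random, wild type (expected count n/3 per category):")
chi <- do.call(rbind, lapply(seq_len(pops$wildtype$n_bins), function(b) {
  cs <- chi_squared_vs_random(pops$wildtype$counts[b, ])
  data.frame(bin = b, statistic = cs$statistic, p = cs$p)
}))
write.csv(chi, file.path(out, "chisq_wildtype.csv"), row.names = FALSE)
message(sprintf("  %d/100 bins with p < 0.05", sum(chi$p < 0.05)))

for (lab in names(pops)) {
  n <- pops[[lab]]$n_animals
  rand <- generate_population("random", n, pops[[lab]]$n_bins,
                              seed = seed + 50 + match(lab, names(pops)))
  cmp <- compare_populations(pops[[lab]], rand, iterations = 500,
                             seed = seed + 60 + match(lab, names(pops)))
  write.csv(cmp[, c("bin", "nominal_p", "rank", "tier")],
            file.path(out, paste0("ranks_", lab, "_vs_random.csv")),
            row.names = FALSE)
  ggplot2::ggsave(file.path(out, paste0("ranks_", lab, "_vs_random.png")),
                  plot_rank_bars(cmp, "blue"), width = 7, height = 1.6,
                  dpi = 120)
  message(sprintf("%s vs. random: %d/100 bins significant (rank <= 25/501)",
                  lab, sum(cmp$rank <= 25)))
}

cmp_wt <- compare_populations(pops$mutant, pops$wildtype, iterations = 500,
                              seed = seed + 70)
write.csv(cmp_wt[, c("bin", "nominal_p", "rank", "tier")],
          file.path(out, "ranks_mutant_vs_wildtype.csv"), row.names = FALSE)
ggplot2::ggsave(file.path(out, "ranks_mutant_vs_wildtype.png"),
                plot_rank_bars(cmp_wt, "red"), width = 7, height = 1.6,
                dpi = 120)
message(sprintf("mutant vs. wild type: %d/100 bins significant",
                sum(cmp_wt$rank <= 25)))

message("Switch points (first persistent change of the middle identity):")
sw <- lapply(names(pops), function(lab) {
  s <- vapply(parts[[lab]]$retained, function(p)
    detect_switch_point(p$middle)$bin, 1L)
  write.csv(data.frame(animal = vapply(parts[[lab]]$retained, `[[`, "",
                                       "animal_id"),
                       switch_bin = s),
            file.path(out, paste0("switch_", lab, ".csv")), row.names = FALSE)
  s
})
names(sw) <- names(pops)
for (lab in names(sw))
  message(sprintf("  %s: %d/%d animals with a switch, median bin %s", lab,
                  sum(!is.na(sw[[lab]])), length(sw[[lab]]),
                  format(median(sw[[lab]], na.rm = TRUE))))
if (all(vapply(sw, function(s) sum(!is.na(s)) > 0, TRUE))) {
  ks <- compare_switch_points(sw$wildtype[!is.na(sw$wildtype)],
                              sw$mutant[!is.na(sw$mutant)])
  message(sprintf("  KS wild type vs. mutant: D = %.3f, p = %.3g",
                  ks$statistic, ks$p))
}
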