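#' Assemble a pipeline run configuration
#'
#' @param cohorts List of cohort definitions, each a list with `label`,
#'   `n_animals`, `order_model` and optionally `switch_bin`, `noise_rate`,
#'   `stage`, `defasc_animals` (see [generate_profiles()]) and further
#'   [bundle_spec()] arguments under `spec`.
#' @param output_dir Directory for all CSV/JSON/figure outputs.
#' @param seed Master seed; every stage derives sub-seeds from it.
#' @param iterations Permutation iterations per bin.
#' @param z_threshold,run_length Defasciculation rule parameters.
#' @param n_bins Number of length-normalized bins.
#' @param reference Label of the cohort used as the age-matched reference
#'   (default: first cohort).
#' @param figures Whether to write PNG figures.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohorts, output_dir, seed = 1L, iterations = 500L,
                       z_threshold = 3.5, run_length = 10L, n_bins = 100L,
                       reference = NULL, figures = TRUE) {
  stopifnot(length(cohorts) >= 1L)
  labels <- vapply(cohorts, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("cohort labels must be unique")
  if (is.null(reference)) reference <- labels[1]
  if (!reference %in% labels)
    stop("reference cohort '", reference, "' is not among: ",
         paste(labels, collapse = ", "))
  structure(list(cohorts = cohorts, output_dir = output_dir,
                 seed = as.integer(seed), iterations = as.integer(iterations),
                 z_threshold = z_threshold, run_length = as.integer(run_length),
                 n_bins = as.integer(n_bins), reference = reference,
                 figures = isTRUE(figures)),
            class = "run_config")
}

#' Load a pipeline configuration from JSON
#' @param path JSON file with the fields of [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  do.call(run_config, cfg)
}

stage_try <- function(stage, id, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed for ", id, ": ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Executes simulate -> quantify -> classify -> stats -> report: generates
#' each cohort's phantoms, writes per-animal pairwise-distance CSVs, builds
#' the reference width profile, classifies and excludes defasciculated
#' bundles, tabulates middle-dendrite populations, runs per-bin chi-squared
#' (when expected counts permit) and permutation comparisons against a
#' simulated random cohort and against the reference cohort, detects switch
#' points, and writes a machine-readable JSON summary plus figures. Every
#' number shown in a figure also lands in a CSV/JSON twin, and all randomness
#' flows from the config seed (recorded in the log).
#'
#' @param config A [run_config()] (or path to its JSON form).
#' @return The summary list, invisibly; written to
#'   `<output_dir>/summary.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  for (d in file.path(out, c(".", "distances", "figures")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("bundleorder pipeline; seed=%d iterations=%d",
                         config$seed, config$iterations),
                 sprintf("z_threshold=%g run_length=%d n_bins=%d",
                         config$z_threshold, config$run_length,
                         config$n_bins),
                 sprintf("started %s", format(Sys.time())))

  # simulate + quantify
  cohort_profiles <- list()
  for (ci in seq_along(config$cohorts)) {
    co <- config$cohorts[[ci]]
    spec_args <- c(list(n_bins = config$n_bins),
                   co$spec,
                   co[intersect(names(co),
                                c("order_model", "switch_bin", "noise_rate"))])
    profiles <- stage_try("simulate", paste0("cohort ", co$label),
      do.call(generate_profiles,
              c(list(n_animals = co$n_animals,
                     seed = derive_seed(config$seed, ci * 1000L),
                     stage = if (is.null(co$stage)) "L4" else co$stage,
                     defasc_animals = if (is.null(co$defasc_animals)) list()
                                      else co$defasc_animals),
                spec_args)))
    for (p in profiles) {
      truth <- attr(p, "truth")
      sec <- stage_try("quantify", paste0(co$label, "/", p$animal_id),
        cross_sections(truth$traces$AWA, truth$traces$AFD,
                       truth$traces$ASE))
      write_distance_csv(sec, file.path(out, "distances",
        paste0(co$label, "_", p$animal_id, ".csv")))
    }
    cohort_profiles[[co$label]] <- profiles
    log_lines <- c(log_lines, sprintf("cohort %s: %d animals simulated",
                                      co$label, length(profiles)))
  }

  # classify against the reference cohort
  ref <- stage_try("classify", "reference cohort",
    reference_stats(cohort_profiles[[config$reference]],
                    stage = config$reference))
  ref_csv <- data.frame(bin = seq_len(ref$n_bins), mean_width = ref$mean,
                        sd_width = ref$sd)
  utils::write.csv(ref_csv, file.path(out, "reference_width.csv"),
                   row.names = FALSE)

  partitions <- list(); defasc_info <- list()
  for (lab in names(cohort_profiles)) {
    results <- lapply(cohort_profiles[[lab]], function(p)
      stage_try("classify", paste0(lab, "/", p$animal_id),
                classify_defasciculation(p, ref,
                                         z_threshold = config$z_threshold,
                                         run_length = config$run_length)))
    part <- exclude_defasciculated(cohort_profiles[[lab]], results)
    partitions[[lab]] <- part
    defasc_info[[lab]] <- list(
      excluded_animals = vapply(part$excluded, `[[`, "", "animal_id"),
      flagged_runs = lapply(results[vapply(results, `[[`, TRUE,
                                           "defasciculated")],
                            `[[`, "flagged_runs"))
  }
  jsonlite::write_json(defasc_info, file.path(out, "defasciculation.json"),
                       auto_unbox = TRUE, digits = NA)

  # stats
  populations <- list(); stats_out <- list(); switch_out <- list()
  for (lab in names(partitions)) {
    retained <- partitions[[lab]]$retained
    if (!length(retained))
      stop("stage 'stats' failed for cohort ", lab,
           ": every bundle was classified defasciculated; ",
           "no animals remain for order analysis")
    pop <- tabulate_population(retained, cohort = lab)
    populations[[lab]] <- pop
    utils::write.csv(
      data.frame(bin = seq_len(pop$n_bins), pop$counts),
      file.path(out, paste0("population_", lab, ".csv")), row.names = FALSE)

    rand <- with_seed(derive_seed(config$seed, 500000L + match(lab, names(partitions))),
      middle_population(
        matrix(sample(DENDRITES, pop$n_animals * pop$n_bins, replace = TRUE),
               pop$n_animals, pop$n_bins),
        cohort = "random"))
    vs_random <- compare_populations(pop, rand,
                                     iterations = config$iterations,
                                     seed = derive_seed(config$seed,
                                                        600000L + match(lab, names(partitions))))
    utils::write.csv(vs_random[, c("bin", "nominal_p", "rank", "tier")],
                     file.path(out, paste0("ranks_", lab, "_vs_random.csv")),
                     row.names = FALSE)

    chi <- NULL
    if (pop$n_animals / 3 >= 5) {
      chi <- do.call(rbind, lapply(seq_len(pop$n_bins), function(b) {
        cs <- chi_squared_vs_random(pop$counts[b, ])
        data.frame(bin = b, statistic = cs$statistic, p = cs$p)
      }))
      utils::write.csv(chi, file.path(out, paste0("chisq_", lab, ".csv")),
                       row.names = FALSE)
    }

    per_animal_switch <- lapply(retained, function(p)
      detect_switch_point(p$middle))
    sw <- data.frame(
      animal = vapply(retained, `[[`, "", "animal_id"),
      switch_bin = vapply(per_animal_switch, function(s)
        if (is.na(s$bin)) NA_integer_ else s$bin, 1L))
    utils::write.csv(sw, file.path(out, paste0("switch_", lab, ".csv")),
                     row.names = FALSE)
    switch_out[[lab]] <- list(
      per_animal = sw$switch_bin,
      majority = detect_switch_point(majority_middle(pop)))

    stats_out[[lab]] <- list(
      n_retained = length(retained),
      n_excluded = length(partitions[[lab]]$excluded),
      significant_bins_vs_random_p05 =
        sum(vs_random$tier != "ns"),
      vs_random_ranks = vs_random$rank,
      chi_squared = if (is.null(chi)) NULL else chi$statistic)
  }

  vs_ref <- list()
  for (lab in setdiff(names(populations), config$reference)) {
    cmp <- compare_populations(populations[[lab]],
                               populations[[config$reference]],
                               iterations = config$iterations,
                               seed = derive_seed(config$seed,
                                                  700000L + match(lab, names(populations))))
    utils::write.csv(cmp[, c("bin", "nominal_p", "rank", "tier")],
                     file.path(out, paste0("ranks_", lab, "_vs_",
                                           config$reference, ".csv")),
                     row.names = FALSE)
    vs_ref[[lab]] <- cmp$rank
    ks <- NULL
    a <- switch_out[[config$reference]]$per_animal
    b <- switch_out[[lab]]$per_animal
    if (sum(!is.na(a)) && sum(!is.na(b)))
      ks <- compare_switch_points(a[!is.na(a)], b[!is.na(b)])
    switch_out[[lab]]$ks_vs_reference <- ks
  }

  # report
  if (config$figures) {
    grDevices::png(file.path(out, "figures", "width_profiles.png"),
                   width = 900, height = 500, res = 120)
    print(plot_width_profiles(
      unlist(lapply(partitions, `[[`, "retained"), recursive = FALSE),
      unlist(lapply(partitions, `[[`, "excluded"), recursive = FALSE)))
    grDevices::dev.off()
    for (lab in names(populations)) {
      grDevices::png(file.path(out, "figures",
                               paste0("population_", lab, ".png")),
                     width = 700, height = 500, res = 120)
      print(plot_population(populations[[lab]]))
      grDevices::dev.off()
      grDevices::png(file.path(out, "figures",
                               paste0("summary_", lab, ".png")),
                     width = 700, height = 500, res = 120)
      print(plot_summary_fractions(populations[[lab]]))
      grDevices::dev.off()
    }
  }

  summary <- list(
    schema_version = "1.0",
    parameters = list(seed = config$seed, iterations = config$iterations,
                      z_threshold = config$z_threshold,
                      run_length = config$run_length,
                      n_bins = config$n_bins,
                      reference = config$reference),
    cohorts = stats_out,
    excluded = lapply(defasc_info, `[[`, "excluded_animals"),
    switch_points = lapply(switch_out, function(s)
      list(per_animal = s$per_animal, majority_bin = s$majority$bin,
           ks_vs_reference = s$ks_vs_reference)),
    vs_reference_ranks = vs_ref)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(log_lines, sprintf("finished %s", format(Sys.time())))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(summary)
}
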