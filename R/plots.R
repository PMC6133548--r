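#' Identity colors used in figures
#'
#' Conventional colors for the three dendrites: AWA yellow, AFD blue, ASE red.
#' @export
identity_colors <- function() {
  c(AWA = "#E3B505", AFD = "#1F5FA8", ASE = "#C0392B")
}

#' Bundle-width profiles of a cohort
#'
#' One line per animal (bundle width against normalized position); excluded
#' (defasciculated) animals overlaid in pink. Horizontal guides mark 2 um and
#' 6 um.
#'
#' @param retained,excluded Lists of [bundle_profile] objects.
#' @return A ggplot object.
#' @export
plot_width_profiles <- function(retained, excluded = list()) {
  df <- function(profiles, status) {
    if (!length(profiles)) return(NULL)
    do.call(rbind, lapply(profiles, function(p)
      data.frame(animal = p$animal_id, bin = seq_len(p$n_bins),
                 width = p$width, status = status)))
  }
  dat <- rbind(df(retained, "fasciculated"), df(excluded, "defasciculated"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$width,
                                    group = .data$animal,
                                    color = .data$status)) +
    ggplot2::geom_hline(yintercept = c(2, 6), color = "grey80",
                        linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(fasciculated = "grey30",
                                           defasciculated = "#F48FB1")) +
    ggplot2::labs(x = "normalized position (bin)",
                  y = "bundle width (um)", color = NULL) +
    ggplot2::theme_classic()
}

#' Population plot: per-animal middle-dendrite color columns
#'
#' Each column is one animal; each cell the middle-dendrite identity at that
#' bin (yellow AWA, blue AFD, red ASE).
#'
#' @param pop A [middle_population].
#' @return A ggplot object.
#' @export
plot_population <- function(pop) {
  stopifnot(pop$n_animals > 0)
  dat <- expand.grid(animal = seq_len(pop$n_animals),
                     bin = seq_len(pop$n_bins))
  dat$middle <- pop$labels[cbind(dat$animal, dat$bin)]
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$animal), y = .data$bin,
                                    fill = .data$middle)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = identity_colors()) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "animal", y = "normalized position (bin)",
                  fill = "middle", title = pop$cohort) +
    ggplot2::theme_classic()
}

#' Summary plot: per-bin fraction of animals with each dendrite in the middle
#'
#' @param pop A [middle_population].
#' @return A ggplot object.
#' @export
plot_summary_fractions <- function(pop) {
  fr <- population_fractions(pop)
  dat <- data.frame(bin = rep(seq_len(pop$n_bins), 3),
                    middle = rep(DENDRITES, each = pop$n_bins),
                    fraction = c(fr[, "AWA"], fr[, "AFD"], fr[, "ASE"]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                    color = .data$middle)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_color_manual(values = identity_colors()) +
    ggplot2::labs(x = "normalized position (bin)",
                  y = "fraction of animals", color = "middle",
                  title = pop$cohort) +
    ggplot2::theme_classic()
}

#' Permutation-rank color bar
#'
#' Per-bin p-value rankings on a log-scale color bar: dark cells mark low
#' ranks (observed order differing from the test population more than
#' sampling error allows). Blue bars conventionally show comparisons against
#' a simulated random population, red bars against a reference cohort.
#'
#' @param ranks Data.frame from [compare_populations()].
#' @param palette `"red"` or `"blue"`.
#' @param total Total p-values per bin (iterations + 1).
#' @return A ggplot object.
#' @export
plot_rank_bars <- function(ranks, palette = c("red", "blue"), total = 501L) {
  palette <- match.arg(palette)
  hi <- c(red = "#7F0000", blue = "#08306B")[[palette]]
  dat <- data.frame(bin = ranks$bin, logrank = log10(ranks$rank / total))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = 1,
                                    fill = .data$logrank)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = hi, high = "white",
                                 limits = c(log10(1 / total), 0),
                                 name = "log10(rank/total)") +
    ggplot2::labs(x = "normalized position (bin)", y = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}
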