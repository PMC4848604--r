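#' Plot binned strand-specific coverage profiles
#'
#' One curve per sample, shaded by time point (light early, dark late), one
#' panel per strand — the classic whole-genome transcription progression
#' view.
#'
#' @param bins Tibble from [bin_coverage()].
#' @param samples Optional sample metadata with `sample_id` and `time_min`
#'   used for the colour scale; sample IDs are used directly when absent.
#' @return A ggplot object.
#' @export
plot_coverage_profile <- function(bins, samples = NULL) {
  dat <- bins
  if (!is.null(samples)) {
    dat <- dat |>
      left_join(samples[, c("sample_id", "time_min")], by = "sample_id")
    p <- ggplot(dat, aes(bin_start, count, group = sample_id,
                         colour = time_min)) +
      scale_colour_gradient(low = "grey80", high = "black",
                            name = "time (min)")
  } else {
    p <- ggplot(dat, aes(bin_start, count, group = sample_id,
                         colour = sample_id))
  }
  p +
    geom_line(linewidth = 0.3) +
    facet_wrap(~strand, ncol = 1, labeller = label_both) +
    labs(x = "genome position (bp)", y = "reads per bin",
         title = "Strand-specific binned coverage over the time course") +
    theme_minimal()
}

#' Plot per-class average percent profiles
#'
#' Averages the percent-scaled phase profiles within each temporal class
#' (excluded genes dropped) and draws one curve per class over the
#' early/middle/late phases.
#'
#' @param calls A `"temporal_calls"` tibble from [classify_phage_genes()].
#' @return A ggplot object.
#' @export
plot_class_profiles <- function(calls) {
  dat <- tidy(calls) |>
    filter(class != "excluded") |>
    tidyr::pivot_longer(c(pct_early, pct_middle, pct_late),
                        names_to = "phase", values_to = "pct") |>
    mutate(phase = factor(sub("pct_", "", phase),
                          levels = c("early", "middle", "late"))) |>
    group_by(class, phase) |>
    summarise(pct = mean(pct), .groups = "drop")
  ggplot(dat, aes(phase, pct, group = class, colour = class)) +
    geom_line(linewidth = 0.8) +
    geom_point() +
    labs(x = "infection phase", y = "mean % of peak phase average",
         title = "Temporal class profiles") +
    theme_minimal()
}

#' Plot host log2 fold changes along the genome and by rank
#'
#' Left panel: per-gene log2FC ordered by genome position, with guide lines
#' at the +/- threshold. Right panel: the same values ordered by decreasing
#' log2FC, showing the balance of induced and repressed genes.
#'
#' @param calls A `"de_calls"` tibble.
#' @param genes Gene annotation with `gene_id` and `start` (genome order).
#' @param threshold Guide-line position (default the calls' own threshold).
#' @return A ggplot object.
#' @export
plot_de_genome <- function(calls, genes, threshold = NULL) {
  th <- threshold %||% attr(calls, "thresholds")$log2fc_threshold %||% 1.5
  dat <- tidy(calls) |>
    inner_join(genes[, c("gene_id", "start")], by = "gene_id")
  dat <- bind_rows(
    dat |> mutate(panel = "genome position", x = rank(start)),
    dat |> mutate(panel = "ranked log2FC", x = rank(-log2fc))
  )
  ggplot(dat, aes(x, log2fc, colour = status)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_hline(yintercept = c(-th, th), colour = "grey40",
               linetype = "dashed") +
    facet_wrap(~panel, scales = "free_x") +
    scale_colour_manual(values = c(up = "#c23b22", down = "#2b6ca3",
                                   ns = "grey60")) +
    labs(x = "gene order", y = "log2 fold change",
         title = unique(dat$comparison)) +
    theme_minimal()
}

#' @rdname plot_class_profiles
#' @param object,... `autoplot` method arguments.
#' @method autoplot temporal_calls
#' @export
autoplot.temporal_calls <- function(object, ...) {
  plot_class_profiles(object)
}

#' @rdname plot_de_genome
#' @param object,... `autoplot` method arguments (pass `genes`).
#' @method autoplot de_calls
#' @export
autoplot.de_calls <- function(object, genes, ...) {
  plot_de_genome(object, genes)
}
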