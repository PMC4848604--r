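#' Run the full time-course analysis pipeline
#'
#' Orchestrates every stage on a simulated data set: raw-count phage read
#' fractions, Total-Count normalization (scope `all_reads` for temporal
#' classification and host differential expression), temporal classification
#' of the phage genes, the three host DE comparisons
#' (early-vs-control, late-vs-control, late-vs-early) with their tallies,
#' 250-bp strand-specific coverage binning (scope `phage_only`
#' normalization), and ncRNA candidate detection with relation labelling.
#' All randomness lives in the simulation; given the same configuration the
#' pipeline output is byte-identical.
#'
#' @param config A [sim_config()] object (alternatively pass a ready-made
#'   `"infection_sim"` via `sim`).
#' @param sim Optional pre-built simulation; overrides `config`.
#' @param outdir Optional output directory; when given, all stage tables are
#'   written as TSV and the machine-readable summary as `summary.json`.
#' @param min_tgr,margin_threshold Temporal-classifier thresholds.
#' @param thresholds DE thresholds, a [de_thresholds()] object.
#' @param bin_width Coverage bin width in bp.
#' @param min_depth,min_length,merge_gap ncRNA detector thresholds.
#' @return A list of class `"phage_pipeline"` with elements `sim`,
#'   `fraction`, `temporal`, `de` (named list of the three call tables),
#'   `tallies`, `coverage_bins`, `ncrna`, and `summary` (the nested summary
#'   list written to JSON).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(seed = 1, library_size = 1e5))
#' res$summary$temporal_classes
#' }
run_pipeline <- function(config = sim_config(), sim = NULL, outdir = NULL,
                         min_tgr = 10, margin_threshold = 40,
                         thresholds = de_thresholds(), bin_width = 250,
                         min_depth = 10, min_length = 100, merge_gap = 50) {
  if (is.null(sim)) sim <- simulate_infection(config)
  genes <- sim$genes
  samples <- sim$samples

  fraction <- phage_read_fraction(sim$counts, genes)
  norm <- total_count_normalize(sim$counts, genes, scope = "all_reads")

  temporal <- classify_phage_genes(norm, samples, genes,
                                   min_tgr = min_tgr,
                                   margin_threshold = margin_threshold)

  de <- list(
    early_vs_control = de_call_vs_control(norm, samples, genes, "early",
                                          thresholds = thresholds),
    late_vs_control = de_call_vs_control(norm, samples, genes, "late",
                                         thresholds = thresholds),
    late_vs_early = de_call_late_vs_early(norm, samples, genes,
                                          thresholds = thresholds)
  )
  tallies <- bind_rows(lapply(de, tally_de))

  glen <- sim$config$phage_genome_len
  coverage_bins <- bin_coverage(sim$reads, glen, bin_width = bin_width,
                                normalize = TRUE)
  regions <- detect_transcribed_regions(
    sim$reads, genes[genes$organism == "phage", ], glen,
    samples = samples, min_depth = min_depth, min_length = min_length,
    merge_gap = merge_gap
  )
  ncrna <- classify_relation(regions, genes[genes$organism == "phage", ])

  cls <- glance(temporal)
  summary <- list(
    seed = sim$config$seed,
    version = as.character(utils::packageVersion("phagephase")),
    thresholds = list(
      min_tgr = min_tgr, margin_threshold = margin_threshold,
      log2fc_threshold = thresholds$log2fc_threshold,
      sd_multiplier = thresholds$sd_multiplier, alpha = thresholds$alpha,
      pseudocount = thresholds$pseudocount, bin_width = bin_width,
      min_depth = min_depth, min_length = min_length, merge_gap = merge_gap
    ),
    temporal_classes = as.list(cls[, c("n_early", "n_middle", "n_late",
                                       "n_constitutive", "n_excluded",
                                       "n_genes", "n_zero_reads")]),
    de_tallies = lapply(split(tallies, tallies$comparison), as.list),
    phage_fraction_pct = setNames(
      as.list(fraction$fraction_pct), fraction$sample_id
    ),
    ncrna = list(
      n_candidates = nrow(ncrna),
      n_antisense = sum(grepl("antisense", ncrna$relation)),
      n_intergenic = sum(ncrna$relation == "intergenic")
    )
  )

  bundle <- structure(
    list(sim = sim, fraction = fraction, temporal = temporal, de = de,
         tallies = tallies, coverage_bins = coverage_bins, ncrna = ncrna,
         summary = summary),
    class = "phage_pipeline"
  )
  if (!is.null(outdir)) write_pipeline_outputs(bundle, outdir)
  bundle
}

#' @export
print.phage_pipeline <- function(x, ...) {
  cat("<phage_pipeline>\n")
  cls <- x$summary$temporal_classes
  cat("  temporal classes:",
      sprintf("early %d, middle %d, late %d, constitutive %d, excluded %d",
              cls$n_early, cls$n_middle, cls$n_late, cls$n_constitutive,
              cls$n_excluded), "\n")
  for (i in seq_len(nrow(x$tallies))) {
    cat("  ", x$tallies$comparison[i], ": ",
        format_tally(x$tallies[i, ]), "\n", sep = "")
  }
  cat("  ncRNA candidates:", x$summary$ncrna$n_candidates,
      sprintf("(%d antisense, %d intergenic)\n",
              x$summary$ncrna$n_antisense, x$summary$ncrna$n_intergenic))
  invisible(x)
}

write_pipeline_outputs <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  note <- paste0(
    "phagephase ", as.character(utils::packageVersion("phagephase")),
    "; control comparisons rest on a single 0-min replicate ",
    "(susceptible to culture bias)"
  )
  write_stage_tsv <- function(tab, name, comment = note) {
    body <- sub("\n$", "", readr::format_tsv(as_tibble(as.data.frame(tab))))
    writeLines(c(paste0("# ", comment), body), file.path(outdir, name))
  }
  write_stage_tsv(bundle$fraction, "phage_fraction.tsv")
  write_stage_tsv(tidy(bundle$temporal), "temporal_calls.tsv")
  for (cmp in names(bundle$de)) {
    write_stage_tsv(tidy(bundle$de[[cmp]]), paste0("de_", cmp, ".tsv"))
  }
  write_stage_tsv(bundle$tallies, "de_tallies.tsv")
  write_stage_tsv(bundle$coverage_bins, "coverage_bins.tsv")
  write_stage_tsv(bundle$ncrna, "ncrna_candidates.tsv")
  jsonlite::write_json(bundle$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Write the pipeline's figures
#'
#' Produces (a) the per-strand binned coverage profile with one curve per
#' time point, (b) the per-class average percent-profile curves, and (c)
#' the host log2FC-vs-genome-position scatter with threshold guide lines
#' plus rank-ordered panels. A missing stage output skips that figure with
#' a warning rather than failing.
#'
#' @param bundle A `"phage_pipeline"` object.
#' @param outdir Directory to write PNG files into.
#' @return Character vector of the files written, invisibly.
#' @export
make_figures <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  save_fig <- function(plot, name, width = 8, height = 5) {
    p <- file.path(outdir, name)
    ggplot2::ggsave(p, plot, width = width, height = height, dpi = 120)
    written <<- c(written, p)
  }
  if (nrow(bundle$coverage_bins) > 0) {
    save_fig(plot_coverage_profile(bundle$coverage_bins,
                                   bundle$sim$samples),
             "coverage_profile.png")
  } else {
    warn("no coverage bins; skipping coverage figure")
  }
  if (nrow(bundle$temporal) > 0) {
    save_fig(plot_class_profiles(bundle$temporal), "temporal_classes.png")
  } else {
    warn("no temporal calls; skipping class-profile figure")
  }
  de_tab <- bundle$de$late_vs_control
  if (!is.null(de_tab) && nrow(de_tab) > 0) {
    save_fig(plot_de_genome(de_tab, bundle$sim$genes), "de_genome.png",
             width = 9)
  } else {
    warn("no DE calls; skipping DE figure")
  }
  invisible(written)
}
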