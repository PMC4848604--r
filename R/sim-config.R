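#' Default infection-phase grouping of sampling times
#'
#' The time points of the infection time course are grouped into a
#' pre-infection control and three infection phases. The default mirrors the
#' standard grouping for a 0--49 min course sampled at
#' 0, 2, 5, 10, 15, 21, 28, 35, 42 and 49 min: control = 0 min,
#' early = 2 and 5 min, middle = 10, 15 and 21 min, late = 28, 35, 42 and
#' 49 min. The grouping is configuration, not inference: downstream phase
#' averages consume whatever map is supplied here.
#'
#' @return A named list of numeric vectors with elements `control`, `early`,
#'   `middle` and `late`, giving the sampling times (minutes) in each group.
#' @export
#' @examples
#' phase_grouping()
phase_grouping <- function() {
  list(
    control = 0,
    early = c(2, 5),
    middle = c(10, 15, 21),
    late = c(28, 35, 42, 49)
  )
}

#' Assign phase groups to sampling times
#'
#' @param time_min Numeric vector of sampling times in minutes.
#' @param grouping Phase grouping map, as returned by [phase_grouping()].
#' @return Character vector of phase labels (`"control"`, `"early"`,
#'   `"middle"`, `"late"`), same length as `time_min`.
#' @export
assign_phases <- function(time_min, grouping = phase_grouping()) {
  lookup <- unlist(lapply(names(grouping), function(ph) {
    setNames(rep(ph, length(grouping[[ph]])), grouping[[ph]])
  }))
  out <- unname(lookup[as.character(time_min)])
  if (anyNA(out)) {
    abort(paste0(
      "time point(s) not covered by the phase grouping: ",
      paste(time_min[is.na(out)], collapse = ", ")
    ))
  }
  out
}

## Default phage-read-fraction curve over the default time points.
## Endpoints anchored at the canonical 3.27% (2 min) and 15.71% (49 min)
## dual RNA-seq values; interior points ramp monotonically within phases so
## that the phase means are consistent with the class expression budgets the
## generator solves for (see vignette).
default_fraction_curve <- function() {
  c(0, 0.0327, 0.0400, 0.0720, 0.0800, 0.0880, 0.1160, 0.1300, 0.1430, 0.1571)
}

#' Build a synthetic infection time-course configuration
#'
#' Collects and validates all parameters of the synthetic dual-organism
#' (phage + host) RNA-seq time-course generator. The defaults emulate the
#' study design of a lytic myovirus infecting an enterobacterial host at
#' MOI 10: nine infected time points plus a 0-min uninfected control, a
#' phage read fraction ramping from ~3% to ~16% of the library, phage genes
#' drawn from four temporal classes plus a low-expression excluded class in
#' proportions 92:8:94:147:26, and host genes with planted early and late
#' differential expression.
#'
#' @param seed Integer seed; all randomness in [simulate_infection()] derives
#'   from it.
#' @param phage_genome_len Phage genome length in bp.
#' @param n_phage_genes Number of phage genes to place (no overlaps).
#' @param n_host_genes Number of host genes.
#' @param time_points_min Strictly increasing sampling times in minutes;
#'   the first must be 0 (uninfected control).
#' @param class_proportions Named numeric vector of fractions for classes
#'   `early`, `middle`, `late`, `constitutive`, `excluded`; must sum to 1.
#' @param phage_fraction_curve Target fraction of reads mapping to the phage
#'   at each time point, in `[0, 1)`; must be 0 at t = 0.
#' @param host_de_config List with `n_early_down`, `n_early_up`, `n_late_up`,
#'   `n_late_down` (numbers of host genes with planted effects) and
#'   `effect_log2fc` (magnitude of the planted log2 fold change).
#' @param dispersion Negative-binomial size parameter for count noise;
#'   `Inf` gives the Poisson limit. Default 100 models technical replicates
#'   drawn from a single infection flask (mild overdispersion).
#' @param peak_fold Fold elevation of a temporal class's peak phase over its
#'   off phases, on the expected normalized-count scale.
#' @param n_asrna Number of planted antisense transcripts on the phage genome.
#' @param n_intergenic_rna Number of planted intergenic transcripts.
#' @param library_size Total mapped reads per sample.
#' @param grouping Phase grouping map; see [phase_grouping()].
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$class_proportions
sim_config <- function(seed = 1L,
                       phage_genome_len = 50000L,
                       n_phage_genes = 120L,
                       n_host_genes = 500L,
                       time_points_min = c(0, 2, 5, 10, 15, 21, 28, 35, 42, 49),
                       class_proportions = c(
                         early = 92, middle = 8, late = 94,
                         constitutive = 147, excluded = 26
                       ) / 367,
                       phage_fraction_curve = NULL,
                       host_de_config = list(
                         n_early_down = 13, n_early_up = 2,
                         n_late_up = 15, n_late_down = 13,
                         effect_log2fc = 2
                       ),
                       dispersion = 100,
                       peak_fold = 5,
                       n_asrna = 9L,
                       n_intergenic_rna = 1L,
                       library_size = 1e6,
                       grouping = phase_grouping()) {
  if (is.null(phage_fraction_curve)) {
    if (length(time_points_min) == 10 &&
        all(time_points_min == c(0, 2, 5, 10, 15, 21, 28, 35, 42, 49))) {
      phage_fraction_curve <- default_fraction_curve()
    } else {
      ## generic ramp 0 -> 0.03 ... 0.16 for non-default time points
      n_inf <- length(time_points_min) - 1
      phage_fraction_curve <- c(0, seq(0.03, 0.16, length.out = n_inf))
    }
  }
  cfg <- list(
    seed = as.integer(seed),
    phage_genome_len = as.integer(phage_genome_len),
    n_phage_genes = as.integer(n_phage_genes),
    n_host_genes = as.integer(n_host_genes),
    time_points_min = as.numeric(time_points_min),
    class_proportions = class_proportions,
    phage_fraction_curve = as.numeric(phage_fraction_curve),
    host_de_config = host_de_config,
    dispersion = dispersion,
    peak_fold = peak_fold,
    n_asrna = as.integer(n_asrna),
    n_intergenic_rna = as.integer(n_intergenic_rna),
    library_size = as.numeric(library_size),
    grouping = grouping
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  tp <- cfg$time_points_min
  if (length(tp) < 2 || tp[1] != 0) {
    abort("time_points_min must start with the 0-min control")
  }
  if (any(diff(tp) <= 0)) {
    abort("time_points_min must be strictly increasing")
  }
  cp <- cfg$class_proportions
  needed <- c("early", "middle", "late", "constitutive", "excluded")
  if (!all(needed %in% names(cp))) {
    abort(paste0(
      "class_proportions must name all of: ", paste(needed, collapse = ", ")
    ))
  }
  if (abs(sum(cp) - 1) > 1e-9) {
    abort("class_proportions must sum to 1 (tolerance 1e-9)")
  }
  if (any(cp < 0)) abort("class_proportions must be non-negative")
  pf <- cfg$phage_fraction_curve
  if (length(pf) != length(tp)) {
    abort("phage_fraction_curve must have one value per time point")
  }
  if (pf[1] != 0) abort("phage_fraction_curve must be 0 at t = 0")
  if (any(pf < 0 | pf >= 1)) abort("phage_fraction_curve values must lie in [0, 1)")
  ## mean gene length under the U(200, 500) layout model is 350 bp
  if (cfg$n_phage_genes * 350 +
      cfg$n_intergenic_rna * 400 > cfg$phage_genome_len) {
    abort(paste0(
      "cannot place ", cfg$n_phage_genes,
      " non-overlapping genes (mean length 350 bp) in a ",
      cfg$phage_genome_len, " bp genome"
    ))
  }
  hd <- cfg$host_de_config
  hneeded <- c("n_early_down", "n_early_up", "n_late_up", "n_late_down",
               "effect_log2fc")
  if (!all(hneeded %in% names(hd))) {
    abort(paste0("host_de_config must name: ", paste(hneeded, collapse = ", ")))
  }
  n_de <- hd$n_early_down + hd$n_early_up + hd$n_late_up + hd$n_late_down
  if (n_de > cfg$n_host_genes) {
    abort("more planted host effects than host genes")
  }
  if (cfg$dispersion <= 0) abort("dispersion (NB size) must be positive")
  if (cfg$peak_fold <= 1) abort("peak_fold must exceed 1")
  if (cfg$library_size < 1000) abort("library_size is implausibly small")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  phage:", x$n_phage_genes, "genes /", x$phage_genome_len, "bp\n")
  cat("  host:", x$n_host_genes, "genes\n")
  cat("  time points (min):", paste(x$time_points_min, collapse = ", "), "\n")
  cat("  library size:", format(x$library_size, big.mark = ","), "reads/sample\n")
  cat("  planted ncRNAs:", x$n_asrna, "antisense +", x$n_intergenic_rna,
      "intergenic\n")
  invisible(x)
}
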