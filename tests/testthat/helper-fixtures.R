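## Shared fixtures and independent oracles for the test suite.

default_times <- c(0, 2, 5, 10, 15, 21, 28, 35, 42, 49)

## one-gene long count table over the default time course
profile_counts <- function(values, gene_id = "g1") {
  stopifnot(length(values) == 10)
  tibble::tibble(
    gene_id = gene_id,
    sample_id = sprintf("t%02d", default_times),
    count = values
  )
}

default_samples <- function() {
  tibble::tibble(
    sample_id = sprintf("t%02d", default_times),
    time_min = default_times,
    phase_group = assign_phases(default_times)
  )
}

## random multi-gene count table
random_counts <- function(n_genes, seed) {
  withr::with_seed(seed, {
    tidyr::expand_grid(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      sample_id = sprintf("t%02d", default_times)
    ) |>
      dplyr::mutate(count = stats::rpois(dplyr::n(), lambda = 50))
  })
}

## Brute-force reimplementation of the temporal rule as nested conditionals,
## read directly off its verbal statement; deliberately scalar and naive.
oracle_classify <- function(avg_early, avg_middle, avg_late, mean_tgr,
                            min_tgr = 10, margin_threshold = 40) {
  if (mean_tgr < min_tgr) {
    return("excluded")
  }
  avgs <- c(early = avg_early, middle = avg_middle, late = avg_late)
  pct <- 100 * avgs / max(avgs)
  top <- names(which.max(pct))
  runner_up <- max(pct[names(pct) != top])
  if (100 - runner_up < margin_threshold) {
    return("constitutive")
  }
  top
}

## Textbook pooled-variance two-sample t-test, coded independently of
## stats::t.test.
oracle_pooled_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), df = nx + ny - 2)
}

## naive per-base depth: loop over reads, increment positions
oracle_depth <- function(reads, contig_length, strand) {
  depth <- numeric(contig_length)
  r <- reads[reads$strand == strand, ]
  for (i in seq_len(nrow(r))) {
    depth[r$start[i]:r$end[i]] <- depth[r$start[i]:r$end[i]] + 1
  }
  depth
}

## quick simulation at reduced depth for structural tests
quick_sim <- function(seed = 1, ...) {
  simulate_infection(sim_config(seed = seed, library_size = 1e5, ...))
}
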