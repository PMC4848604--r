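#' Differential-expression thresholds
#'
#' Bundle of the compound-rule parameters: the log2 fold-change gate
#' (|log2FC| > 1.5 by default), the control 2-standard-deviation rule
#' multiplier, the t-test significance level for the late-vs-early
#' comparison (p < 0.01), and the pseudocount added inside the log2 ratio to
#' both numerator and denominator (1 by default; 0 is allowed and produces
#' infinite fold changes that remain status-eligible).
#'
#' @param log2fc_threshold Positive log2FC gate.
#' @param sd_multiplier Number of group standard deviations the single
#'   control value must fall outside of.
#' @param alpha Significance level for the late-vs-early t-test.
#' @param pseudocount Count added to both sides of the fold-change ratio.
#' @return List of class `"de_thresholds"`.
#' @export
de_thresholds <- function(log2fc_threshold = 1.5, sd_multiplier = 2,
                          alpha = 0.01, pseudocount = 1) {
  if (log2fc_threshold <= 0 || sd_multiplier <= 0 || alpha <= 0) {
    abort("thresholds must be strictly positive")
  }
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  structure(
    list(
      log2fc_threshold = log2fc_threshold, sd_multiplier = sd_multiplier,
      alpha = alpha, pseudocount = pseudocount
    ),
    class = "de_thresholds"
  )
}

#' Log2 fold change with pseudocount
#'
#' `log2((group_mean + pseudocount) / (reference_value + pseudocount))`.
#' With a positive pseudocount the result is always finite; swapping the two
#' arguments negates it exactly.
#'
#' @param group_mean,reference_value Non-negative mean counts (vectorized).
#' @param pseudocount Count added to both numerator and denominator.
#' @return Numeric vector of log2 fold changes.
#' @export
#' @examples
#' log2_fold_change(79, 9) # log2(80 / 10) = 3
log2_fold_change <- function(group_mean, reference_value, pseudocount = 1) {
  if (any(group_mean < 0) || any(reference_value < 0)) {
    abort("means must be non-negative")
  }
  log2((group_mean + pseudocount) / (reference_value + pseudocount))
}

#' Call differential expression of a phase group against the control
#'
#' Implements the compound rule for comparisons against the single
#' uninfected control sample: a gene is `up` if its log2 fold change
#' (phase-group mean vs the control value) exceeds the threshold *and* the
#' control value lies outside the group mean plus/minus
#' `sd_multiplier` group standard deviations (sample SD, n-1 denominator);
#' `down` symmetrically; otherwise `ns`. Both gates must hold — the
#' fold-change gate alone never suffices. Because the control is a single
#' sample, the only dispersion available is the phase group's own; the
#' comparison is therefore susceptible to culture bias, which is recorded in
#' output headers downstream.
#'
#' @param norm_counts Long tibble (`gene_id`, `sample_id`, `count`) of
#'   normalized counts for the host genes (other genes may be present and
#'   are retained; restrict beforehand if desired).
#' @param samples Sample metadata with `sample_id` and `phase_group`.
#' @param genes Optional annotation with `gene_id` and `organism`; when
#'   supplied, only host genes are tested.
#' @param group Phase to test: `"early"` or `"late"`.
#' @param thresholds A [de_thresholds()] object.
#' @return A tibble of class `"de_calls"`: `gene_id`, `comparison`,
#'   `group_mean`, `group_sd`, `control_value`, `log2fc`,
#'   `control_outside_2sd`, `status`.
#' @export
de_call_vs_control <- function(norm_counts, samples, genes = NULL,
                               group = c("early", "late"),
                               thresholds = de_thresholds()) {
  group <- match.arg(group)
  check_counts_cols(norm_counts)
  counts <- restrict_to_host(norm_counts, genes)
  grp_samples <- samples$sample_id[samples$phase_group == group]
  ctl_samples <- samples$sample_id[samples$phase_group == "control"]
  if (length(grp_samples) < 2) {
    abort(paste0("phase group '", group,
                 "' needs >= 2 samples for a standard deviation"))
  }
  if (length(ctl_samples) != 1) {
    abort("exactly one control sample is required")
  }
  stats_tbl <- counts |>
    filter(sample_id %in% c(grp_samples, ctl_samples)) |>
    group_by(gene_id) |>
    summarise(
      group_mean = mean(count[sample_id %in% grp_samples]),
      group_sd = sd(count[sample_id %in% grp_samples]),
      control_value = count[sample_id == ctl_samples][1],
      .groups = "drop"
    )
  th <- thresholds
  out <- stats_tbl |>
    mutate(
      comparison = paste0(group, "_vs_control"),
      log2fc = log2_fold_change(group_mean, control_value, th$pseudocount),
      control_outside_2sd =
        control_value < group_mean - th$sd_multiplier * group_sd |
        control_value > group_mean + th$sd_multiplier * group_sd,
      status = case_when(
        control_outside_2sd & log2fc > th$log2fc_threshold ~ "up",
        control_outside_2sd & log2fc < -th$log2fc_threshold ~ "down",
        TRUE ~ "ns"
      )
    ) |>
    select(gene_id, comparison, group_mean, group_sd, control_value,
           log2fc, control_outside_2sd, status)
  new_de_calls(out, thresholds)
}

#' Call differential expression between the late and early phases
#'
#' Compares the late-phase group against the early-phase group per gene:
#' log2 fold change of the late mean over the early mean, combined with a
#' two-sided two-sample Student t-test (pooled variance by default; Welch
#' behind a flag). A gene is `up`/`down` only if both
#' |log2FC| > threshold and p < alpha hold. No multiple-testing correction
#' is applied by default, matching the raw p < 0.01 convention of
#' threshold-based callers; set `bh = TRUE` to add a Benjamini-Hochberg
#' adjusted column (`p_adj`) and gate on it instead.
#'
#' Degenerate variance convention: when the pooled variance is zero, p = 1
#' if the group means are equal, p = 0 (flagged via `zero_variance`)
#' otherwise.
#'
#' @inheritParams de_call_vs_control
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance Student test.
#' @param bh Apply Benjamini-Hochberg correction and gate on adjusted p.
#' @return A `"de_calls"` tibble: `gene_id`, `comparison`, `group_mean`
#'   (late), `group_sd` (late), `early_mean`, `log2fc`, `p_value`
#'   (and `p_adj` when `bh`), `zero_variance`, `status`.
#' @export
de_call_late_vs_early <- function(norm_counts, samples, genes = NULL,
                                  thresholds = de_thresholds(),
                                  welch = FALSE, bh = FALSE) {
  check_counts_cols(norm_counts)
  counts <- restrict_to_host(norm_counts, genes)
  early_s <- samples$sample_id[samples$phase_group == "early"]
  late_s <- samples$sample_id[samples$phase_group == "late"]
  if (length(early_s) < 2 || length(late_s) < 2) {
    abort("both phase groups need >= 2 samples")
  }
  per_gene <- counts |>
    filter(sample_id %in% c(early_s, late_s)) |>
    group_by(gene_id) |>
    summarise(
      early = list(count[sample_id %in% early_s]),
      late = list(count[sample_id %in% late_s]),
      .groups = "drop"
    )
  tt <- purrr::map2(per_gene$late, per_gene$early, two_sample_t,
                    welch = welch)
  th <- thresholds
  out <- per_gene |>
    mutate(
      comparison = "late_vs_early",
      group_mean = purrr::map_dbl(late, mean),
      group_sd = purrr::map_dbl(late, sd),
      early_mean = purrr::map_dbl(early, mean),
      log2fc = log2_fold_change(group_mean, early_mean, th$pseudocount),
      p_value = purrr::map_dbl(tt, "p_value"),
      zero_variance = purrr::map_lgl(tt, "zero_variance")
    ) |>
    select(-early, -late)
  p_gate <- if (bh) {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
    out$p_adj
  } else {
    out$p_value
  }
  out <- out |>
    mutate(
      status = case_when(
        p_gate < th$alpha & log2fc > th$log2fc_threshold ~ "up",
        p_gate < th$alpha & log2fc < -th$log2fc_threshold ~ "down",
        TRUE ~ "ns"
      )
    )
  new_de_calls(out, thresholds)
}

#' Tally differential-expression calls
#'
#' Summarises one comparison's calls into integer tallies and full-precision
#' percentages: number up, down and differentially expressed, the share of
#' the genome each represents, and the up/down shares among DE genes. Report
#' formatting (2 decimals for genome fractions, 1 decimal for shares of DE)
#' happens only in [format_tally()]; stored values are full precision.
#'
#' @param calls A `"de_calls"` tibble (one comparison).
#' @param n_total Total number of genes in the genome the percentages refer
#'   to; defaults to the number of genes in `calls`.
#' @return One-row tibble: `comparison`, `n_total`, `n_up`, `n_down`,
#'   `n_de`, `pct_de_genome`, `pct_up_genome`, `pct_down_genome`,
#'   `pct_up_of_de`, `pct_down_of_de`.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   gene_id = sprintf("h%04d", 1:4349),
#'   comparison = "early_vs_control",
#'   status = c(rep("down", 112), rep("up", 7), rep("ns", 4230))
#' )
#' tally_de(calls) # 2.58% of the genome down-regulated
tally_de <- function(calls, n_total = NULL) {
  if (!all(c("status", "comparison") %in% names(calls))) {
    abort("calls must have 'status' and 'comparison' columns")
  }
  cmp <- unique(calls$comparison)
  if (length(cmp) > 1) {
    abort("tally_de() expects calls from a single comparison")
  }
  if (length(cmp) == 0) cmp <- NA_character_
  n_total <- n_total %||% length(unique(calls$gene_id))
  n_up <- sum(calls$status == "up")
  n_down <- sum(calls$status == "down")
  n_de <- n_up + n_down
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  tibble(
    comparison = cmp,
    n_total = as.integer(n_total),
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    n_de = as.integer(n_de),
    pct_de_genome = pct(n_de, n_total),
    pct_up_genome = pct(n_up, n_total),
    pct_down_genome = pct(n_down, n_total),
    pct_up_of_de = pct(n_up, n_de),
    pct_down_of_de = pct(n_down, n_de)
  )
}

#' Format a DE tally the way reports print it
#'
#' Genome fractions are printed to 2 decimal places, shares of DE genes to
#' 1 decimal place.
#'
#' @param tally One-row tibble from [tally_de()].
#' @return Character scalar, e.g.
#'   `"129 up (54.2% of DE), 109 down; 238 DE (5.47% of 4349 genes)"`.
#' @export
format_tally <- function(tally) {
  sprintf(
    "%d up (%.1f%% of DE), %d down; %d DE (%.2f%% of %d genes)",
    tally$n_up, tally$pct_up_of_de, tally$n_down, tally$n_de,
    tally$pct_de_genome, tally$n_total
  )
}

#' @method glance de_calls
#' @export
glance.de_calls <- function(x, ...) {
  tally_de(x)
}

#' @method tidy de_calls
#' @export
tidy.de_calls <- function(x, ...) {
  attr(x, "thresholds") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

## ---- internals -----------------------------------------------------------

new_de_calls <- function(x, thresholds) {
  structure(
    x,
    class = c("de_calls", class(x)),
    thresholds = thresholds
  )
}

restrict_to_host <- function(counts, genes) {
  if (is.null(genes)) {
    return(counts)
  }
  host <- genes$gene_id[genes$organism == "host"]
  counts[counts$gene_id %in% host, , drop = FALSE]
}

## Two-sample t-test: pooled-variance Student by default, Welch optionally.
## Zero-variance convention: equal means -> p = 1, unequal -> p = 0.
two_sample_t <- function(x, y, welch = FALSE) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  scale2 <- mean(c(x, y))^2 + 1
  if ((vx + vy) <= 1e-24 * scale2) {
    eq <- abs(mean(x) - mean(y)) <= 1e-12 * sqrt(scale2)
    return(list(p_value = if (eq) 1 else 0, zero_variance = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(p_value = unname(ht$p.value), zero_variance = FALSE)
}
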