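#' Phase-averaged expression profiles of genes
#'
#' For each gene, computes the arithmetic mean of normalized TGR values over
#' the early, middle and late infection-phase samples, together with the
#' percent-scaled profile in which the highest phase average is set to 100%.
#' The 0-min control sample is excluded from all phase averages; the overall
#' infected-sample mean (`mean_tgr`) is taken over every infected sample and
#' feeds the downstream low-expression exclusion rule.
#'
#' @param norm_counts Long tibble (`gene_id`, `sample_id`, `count`) of
#'   normalized counts.
#' @param samples Sample metadata tibble with `sample_id` and `phase_group`
#'   (values `control`, `early`, `middle`, `late`).
#' @return Tibble with one row per gene: `gene_id`, `avg_early`,
#'   `avg_middle`, `avg_late`, `mean_tgr`, `pct_early`, `pct_middle`,
#'   `pct_late`. Percent values are `NA` for genes with zero reads in every
#'   infected sample.
#' @export
#' @examples
#' counts <- tidyr::expand_grid(
#'   gene_id = "g1",
#'   sample_id = sprintf("t%02d", c(0, 2, 5, 10, 15, 21, 28, 35, 42, 49))
#' )
#' counts$count <- c(5, 40, 60, 20, 20, 20, 0, 0, 0, 0)
#' samples <- tibble::tibble(
#'   sample_id = counts$sample_id,
#'   phase_group = assign_phases(c(0, 2, 5, 10, 15, 21, 28, 35, 42, 49))
#' )
#' phase_averages(counts, samples)
phase_averages <- function(norm_counts, samples) {
  check_counts_cols(norm_counts)
  if (!"phase_group" %in% names(samples)) {
    abort("samples must carry a 'phase_group' column")
  }
  for (ph in c("early", "middle", "late")) {
    if (!any(samples$phase_group == ph)) {
      abort(paste0("empty phase group: ", ph))
    }
  }
  prof <- norm_counts |>
    inner_join(samples[, c("sample_id", "phase_group")], by = "sample_id") |>
    filter(phase_group != "control") |>
    group_by(gene_id) |>
    summarise(
      avg_early = mean(count[phase_group == "early"]),
      avg_middle = mean(count[phase_group == "middle"]),
      avg_late = mean(count[phase_group == "late"]),
      mean_tgr = mean(count),
      .groups = "drop"
    )
  top <- pmax(prof$avg_early, prof$avg_middle, prof$avg_late)
  scale_pct <- function(avg) ifelse(top > 0, 100 * avg / top, NA_real_)
  prof |>
    mutate(
      pct_early = scale_pct(avg_early),
      pct_middle = scale_pct(avg_middle),
      pct_late = scale_pct(avg_late)
    )
}

#' Classify temporal expression profiles
#'
#' Applies the temporal classification rule to percent-scaled phase profiles:
#' a gene whose overall infected-sample mean TGR is below `min_tgr` is
#' `excluded`; otherwise the gene is assigned to the phase with the highest
#' average value, provided the percent-scale margin over the runner-up phase
#' (`100 - second-highest pct`) is at least `margin_threshold` — genes below
#' the margin are considered not regulated (`constitutive`). Exact ties
#' between the top two phases give margin 0, hence always `constitutive`;
#' there is no random tie-breaking.
#'
#' @param profiles Tibble from [phase_averages()].
#' @param min_tgr Exclusion threshold on the overall infected-sample mean
#'   normalized TGR (default 10).
#' @param margin_threshold Minimum percent-scale margin between the top phase
#'   and the runner-up for a phase call (default 40).
#' @return `profiles` with added columns `margin` (percent; `NA` when
#'   excluded) and `class` (`early`, `middle`, `late`, `constitutive`,
#'   `excluded`).
#' @export
classify_temporal <- function(profiles, min_tgr = 10, margin_threshold = 40) {
  need <- c("gene_id", "pct_early", "pct_middle", "pct_late", "mean_tgr")
  if (!all(need %in% names(profiles))) {
    abort("profiles must come from phase_averages()")
  }
  pct <- as.matrix(profiles[, c("pct_early", "pct_middle", "pct_late")])
  phase_names <- c("early", "middle", "late")
  top_idx <- max.col(replace(pct, is.na(pct), -Inf), ties.method = "first")
  second <- apply(pct, 1, function(p) {
    if (anyNA(p)) return(NA_real_)
    sort(p, decreasing = TRUE)[2]
  })
  margin <- 100 - second
  excluded <- profiles$mean_tgr < min_tgr
  cls <- ifelse(
    excluded, "excluded",
    ifelse(margin >= margin_threshold, phase_names[top_idx], "constitutive")
  )
  profiles |>
    mutate(
      margin = ifelse(excluded, NA_real_, margin),
      class = cls
    )
}

#' Classify all phage genes of a time course
#'
#' End-to-end temporal classification: restricts the matrix to phage genes,
#' computes phase averages and percent profiles, applies the classification
#' rule, and flags genes with zero reads in every sample (control included).
#' Zero-read genes fall in the `excluded` class and are additionally marked
#' in the `zero_reads` column so they can be reported separately.
#'
#' @inheritParams phase_averages
#' @param genes Gene annotation tibble with `gene_id` and `organism`.
#' @inheritParams classify_temporal
#' @return A tibble of class `"temporal_calls"`, one row per phage gene,
#'   with the profile columns, `margin`, `class` and `zero_reads`.
#'   [glance()] on the result gives the per-class size summary.
#' @export
classify_phage_genes <- function(norm_counts, samples, genes,
                                 min_tgr = 10, margin_threshold = 40) {
  phage_ids <- genes$gene_id[genes$organism == "phage"]
  sub <- norm_counts[norm_counts$gene_id %in% phage_ids, , drop = FALSE]
  if (nrow(sub) == 0) {
    out <- tibble(
      gene_id = character(), avg_early = numeric(), avg_middle = numeric(),
      avg_late = numeric(), mean_tgr = numeric(), pct_early = numeric(),
      pct_middle = numeric(), pct_late = numeric(), margin = numeric(),
      class = character(), zero_reads = logical()
    )
  } else {
    zero <- sub |>
      group_by(gene_id) |>
      summarise(zero_reads = all(count == 0), .groups = "drop")
    out <- phase_averages(sub, samples) |>
      classify_temporal(min_tgr = min_tgr,
                        margin_threshold = margin_threshold) |>
      left_join(zero, by = "gene_id")
  }
  structure(
    out,
    class = c("temporal_calls", class(out)),
    thresholds = list(min_tgr = min_tgr, margin_threshold = margin_threshold)
  )
}

#' Per-class size summary of temporal calls
#'
#' @param x A `"temporal_calls"` tibble from [classify_phage_genes()].
#' @param ... Unused.
#' @return One-row tibble with per-class gene counts (`n_early`, `n_middle`,
#'   `n_late`, `n_constitutive`, `n_excluded`), the total `n_genes`, the
#'   number of zero-read genes, and the thresholds used.
#' @method glance temporal_calls
#' @export
glance.temporal_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  lv <- c("early", "middle", "late", "constitutive", "excluded")
  n <- vapply(lv, function(cl) sum(x$class == cl), integer(1))
  tibble(
    n_early = n[["early"]], n_middle = n[["middle"]], n_late = n[["late"]],
    n_constitutive = n[["constitutive"]], n_excluded = n[["excluded"]],
    n_genes = nrow(x),
    n_zero_reads = sum(x$zero_reads %||% FALSE),
    min_tgr = th$min_tgr, margin_threshold = th$margin_threshold
  )
}

#' @method tidy temporal_calls
#' @export
tidy.temporal_calls <- function(x, ...) {
  attr(x, "thresholds") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
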