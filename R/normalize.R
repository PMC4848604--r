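#' Total-Count normalization of a TGR matrix
#'
#' Rescales each sample so that per-sample totals within the chosen scope are
#' equal across samples. The reference total is the mean of the per-sample
#' scope totals, which keeps normalized values near the raw scale. Values are
#' real-valued after normalization; no re-rounding is performed, because
#' downstream thresholds (e.g. the mean-TGR < 10 exclusion rule) operate on
#' the normalized scale and rounding would bias genes near the cut.
#'
#' The scope controls which genes contribute to the per-sample totals:
#' `all_reads` uses every gene, `phage_only`/`host_only` use only that
#' organism's genes (e.g. phage coverage profiles are conventionally
#' normalized phage-against-phage). The scale factor derived from the scope
#' totals is applied to all rows.
#'
#' @param counts Long tibble with columns `gene_id`, `sample_id`, `count`.
#' @param genes Gene annotation tibble with `gene_id` and `organism`
#'   (required for the organism-restricted scopes).
#' @param scope One of `"all_reads"`, `"phage_only"`, `"host_only"`.
#' @return A tibble like `counts` with normalized real-valued `count`, plus
#'   attributes `normalized = TRUE`, `scope`, and `scale_factors` (a tibble
#'   of per-sample totals and multipliers, see [scale_factors()]).
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   gene_id = rep(c("a", "b"), 2),
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   count = c(40, 60, 150, 150)
#' )
#' norm <- total_count_normalize(counts)
#' scale_factors(norm)
total_count_normalize <- function(counts, genes = NULL,
                                  scope = c("all_reads", "phage_only",
                                            "host_only")) {
  scope <- match.arg(scope)
  check_counts_cols(counts)
  scoped <- scope_counts(counts, genes, scope)
  totals <- scoped |>
    group_by(sample_id) |>
    summarise(total = sum(count), .groups = "drop")
  missing <- setdiff(unique(counts$sample_id), totals$sample_id)
  if (length(missing) > 0) {
    totals <- bind_rows(totals, tibble(sample_id = missing, total = 0))
  }
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero) > 0) {
    abort(paste0(
      "sample(s) with zero total within scope '", scope, "': ",
      paste(zero, collapse = ", ")
    ))
  }
  reference <- mean(totals$total)
  totals$scale_factor <- reference / totals$total
  out <- counts |>
    left_join(totals[, c("sample_id", "scale_factor")], by = "sample_id") |>
    mutate(count = count * scale_factor) |>
    select(-scale_factor)
  attr(out, "normalized") <- TRUE
  attr(out, "scope") <- scope
  attr(out, "scale_factors") <- totals[, c("sample_id", "total", "scale_factor")]
  out
}

#' Per-sample scale factors of a normalized count table
#'
#' @param x A tibble returned by [total_count_normalize()].
#' @return Tibble with `sample_id`, raw scope `total` and `scale_factor`.
#' @export
scale_factors <- function(x) {
  sf <- attr(x, "scale_factors")
  if (is.null(sf)) abort("no scale factors: was this normalized?")
  sf
}

#' Per-sample phage read fraction
#'
#' Computes, per sample, the share of mapped gene reads assigned to phage
#' genes, as a percentage. Intended for raw (pre-normalization) counts; on a
#' library-equalized matrix the fractions are unchanged only if totals were
#' already equal.
#'
#' @param counts Long tibble (`gene_id`, `sample_id`, `count`), raw counts.
#' @param genes Gene annotation tibble with `gene_id` and `organism`.
#' @return Tibble with `sample_id`, `phage_reads`, `host_reads` and
#'   `fraction_pct` in `[0, 100]`.
#' @export
phage_read_fraction <- function(counts, genes) {
  check_counts_cols(counts)
  if (!"organism" %in% names(genes)) {
    abort("genes must carry an 'organism' column")
  }
  tab <- counts |>
    left_join(genes[, c("gene_id", "organism")], by = "gene_id") |>
    group_by(sample_id) |>
    summarise(
      phage_reads = sum(count[organism == "phage"]),
      host_reads = sum(count[organism == "host"]),
      .groups = "drop"
    )
  zero <- tab$sample_id[tab$phage_reads + tab$host_reads == 0]
  if (length(zero) > 0) {
    abort(paste0(
      "sample(s) with zero mapped gene reads: ", paste(zero, collapse = ", ")
    ))
  }
  tab |>
    mutate(fraction_pct = 100 * phage_reads / (phage_reads + host_reads))
}

## ---- internals -----------------------------------------------------------

check_counts_cols <- function(counts) {
  need <- c("gene_id", "sample_id", "count")
  if (!all(need %in% names(counts))) {
    abort("counts must have columns gene_id, sample_id, count")
  }
  if (any(counts$count < 0)) abort("negative counts are not allowed")
  invisible(counts)
}

scope_counts <- function(counts, genes, scope) {
  if (scope == "all_reads") {
    return(counts)
  }
  if (is.null(genes) || !"organism" %in% names(genes)) {
    abort("organism-restricted scopes require a genes table with 'organism'")
  }
  org <- if (scope == "phage_only") "phage" else "host"
  keep <- genes$gene_id[genes$organism == org]
  counts[counts$gene_id %in% keep, , drop = FALSE]
}
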