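#' Bin stranded reads into fixed-width genome windows
#'
#' Summarises strand-specific read intervals into a per-sample, per-strand
#' count table over fixed-width genome bins (250 bp by default). Each read is
#' assigned to exactly one bin — the bin containing its 5' end (the interval
#' start on the plus strand, the interval end on the minus strand) — so the
#' binned totals conserve the stranded read counts exactly. Bins are
#' 1-based inclusive: `[1, 250]`, `[251, 500]`, ...
#'
#' @param reads Tibble of read intervals: `contig`, `start`, `end` (1-based
#'   inclusive), `strand`, `sample_id`.
#' @param contig_length Length of the (single) contig in bp.
#' @param bin_width Bin width in bp (default 250).
#' @param normalize If `TRUE`, Total-Count normalize the binned counts
#'   across samples (per sample, over both strands), so profiles from
#'   samples of unequal depth are comparable.
#' @return Tibble with `contig`, `sample_id`, `strand`, `bin`, `bin_start`,
#'   `bin_end`, `count`, complete over all
#'   `ceiling(contig_length / bin_width)` bins.
#' @export
#' @examples
#' reads <- tibble::tibble(
#'   contig = "phage", start = c(1, 251), end = c(90, 340),
#'   strand = "+", sample_id = "t02"
#' )
#' bin_coverage(reads, contig_length = 500)
bin_coverage <- function(reads, contig_length, bin_width = 250,
                         normalize = FALSE) {
  check_reads(reads, contig_length)
  n_bins <- ceiling(contig_length / bin_width)
  if (nrow(reads) == 0) {
    return(tibble(
      contig = character(), sample_id = character(), strand = character(),
      bin = integer(), bin_start = integer(), bin_end = integer(),
      count = numeric()
    ))
  }
  five_prime <- ifelse(reads$strand == "+", reads$start, reads$end)
  binned <- reads |>
    mutate(bin = ((five_prime - 1) %/% bin_width) + 1L) |>
    count(contig, sample_id, strand, bin, name = "count") |>
    tidyr::complete(
      tidyr::nesting(contig),
      sample_id = unique(reads$sample_id),
      strand = c("+", "-"),
      bin = seq_len(n_bins),
      fill = list(count = 0)
    ) |>
    mutate(
      bin_start = as.integer((bin - 1) * bin_width + 1),
      bin_end = as.integer(pmin(bin * bin_width, contig_length)),
      count = as.numeric(count)
    ) |>
    select(contig, sample_id, strand, bin, bin_start, bin_end, count) |>
    arrange(sample_id, strand, bin)
  if (normalize) {
    totals <- binned |>
      group_by(sample_id) |>
      summarise(total = sum(count), .groups = "drop")
    if (any(totals$total == 0)) {
      abort("cannot normalize: sample with zero binned reads")
    }
    fac <- setNames(mean(totals$total) / totals$total, totals$sample_id)
    binned <- binned |> mutate(count = count * fac[sample_id])
  }
  binned
}

#' Per-base strand-specific depth from read intervals
#'
#' @param reads Read-interval tibble (see [bin_coverage()]).
#' @param contig_length Contig length in bp.
#' @param strand Which strand, `"+"` or `"-"`.
#' @param sample_ids Samples to include; depth is the mean over them.
#'   `NULL` uses all samples present.
#' @return Numeric vector of length `contig_length`: mean per-base depth.
#' @export
per_base_depth <- function(reads, contig_length, strand,
                           sample_ids = NULL) {
  check_reads(reads, contig_length)
  sel <- reads$strand == strand
  if (!is.null(sample_ids)) {
    sel <- sel & reads$sample_id %in% sample_ids
    n_samp <- length(unique(sample_ids))
  } else {
    n_samp <- max(length(unique(reads$sample_id)), 1)
  }
  r <- reads[sel, , drop = FALSE]
  delta <- numeric(contig_length + 1)
  if (nrow(r) > 0) {
    add <- tapply(rep(1, nrow(r)), r$start, sum)
    sub <- tapply(rep(1, nrow(r)), r$end + 1, sum)
    delta[as.integer(names(add))] <- delta[as.integer(names(add))] + add
    idx <- as.integer(names(sub))
    keep <- idx <= contig_length + 1
    delta[idx[keep]] <- delta[idx[keep]] - sub[keep]
  }
  cumsum(delta)[seq_len(contig_length)] / n_samp
}

#' Detect unannotated transcribed regions from strand-specific coverage
#'
#' Scans mean per-base depth (over the late-phase samples by default, where
#' phage signal is strongest) for maximal runs of positions at or above
#' `min_depth`; runs separated by at most `merge_gap` bp are merged; merged
#' runs shorter than `min_length` are dropped; and runs explained by
#' same-strand annotation (at least 90% of the run covered by the union of
#' same-strand annotated genes) are removed, leaving antisense and
#' intergenic candidates.
#'
#' @param reads Read-interval tibble (see [bin_coverage()]).
#' @param genes Gene annotation tibble (`gene_id`, `contig`, `start`, `end`,
#'   `strand`); only genes on the reads' contig are considered.
#' @param contig_length Contig length in bp.
#' @param samples Optional sample metadata (`sample_id`, `phase_group`) used
#'   to select the `use_phase` samples; when `NULL`, all samples are used.
#' @param use_phase Phase whose samples are averaged (default `"late"`).
#' @param min_depth Minimum mean per-base depth (default 10).
#' @param min_length Minimum region length in bp (default 100).
#' @param merge_gap Maximum gap between runs that are merged (default 50).
#' @return Tibble of raw regions: `contig`, `start`, `end`, `strand`,
#'   `length`, `mean_depth`.
#' @export
detect_transcribed_regions <- function(reads, genes, contig_length,
                                       samples = NULL, use_phase = "late",
                                       min_depth = 10, min_length = 100,
                                       merge_gap = 50) {
  contig <- if (nrow(reads) > 0) reads$contig[1] else genes$contig[1]
  sample_ids <- if (!is.null(samples)) {
    samples$sample_id[samples$phase_group == use_phase]
  } else {
    NULL
  }
  ann <- genes[genes$contig == contig, , drop = FALSE]
  out <- list()
  for (str in c("+", "-")) {
    depth <- per_base_depth(reads, contig_length, str, sample_ids)
    regions <- depth_runs(depth, min_depth, merge_gap, min_length)
    if (nrow(regions) == 0) next
    same <- ann[ann$strand == str, , drop = FALSE]
    keep <- vapply(seq_len(nrow(regions)), function(i) {
      cov <- union_overlap(regions$start[i], regions$end[i],
                           same$start, same$end)
      cov / (regions$end[i] - regions$start[i] + 1) < 0.9
    }, logical(1))
    regions <- regions[keep, , drop = FALSE]
    if (nrow(regions) == 0) next
    regions$strand <- str
    regions$mean_depth <- vapply(seq_len(nrow(regions)), function(i) {
      mean(depth[regions$start[i]:regions$end[i]])
    }, numeric(1))
    out[[str]] <- regions
  }
  if (length(out) == 0) {
    return(tibble(
      contig = character(), start = integer(), end = integer(),
      strand = character(), length = integer(), mean_depth = numeric()
    ))
  }
  bind_rows(out) |>
    mutate(contig = contig, length = end - start + 1L) |>
    select(contig, start, end, strand, length, mean_depth) |>
    arrange(start)
}

#' Label a detected region's relation to the annotation
#'
#' For each region, every opposite-strand overlapping gene contributes a
#' label describing which part of *that gene* (in the gene's own 5'-to-3'
#' orientation) the overlap touches: the overlapped gene segment's midpoint
#' falls in the first third (5' end), last third (3' end) or middle of the
#' gene. A single opposite-strand overlap gives `antisense_5prime` /
#' `antisense_middle` / `antisense_3prime`; several give `antisense_multi`
#' with per-gene labels; no overlap with any gene on either strand gives
#' `intergenic` with the flanking gene pair as related genes. Regions whose
#' only overlap is same-strand are labelled `sense`.
#'
#' @param regions Tibble from [detect_transcribed_regions()] (needs
#'   `contig`, `start`, `end`, `strand`; `mean_depth` is carried through).
#' @param genes Gene annotation tibble.
#' @return Tibble of candidates: `name` (`misc_1`, `misc_2`, ... in genomic
#'   order), coordinates, `strand`, `relation`, `related_genes`
#'   (comma-separated, with per-gene part labels for `antisense_multi`),
#'   and `mean_expression`.
#' @export
classify_relation <- function(regions, genes) {
  if (nrow(regions) == 0) {
    return(tibble(
      name = character(), contig = character(), start = integer(),
      end = integer(), strand = character(), relation = character(),
      related_genes = character(), mean_expression = numeric()
    ))
  }
  regions <- regions |> arrange(start)
  res <- purrr::map(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    ann <- genes[genes$contig == r$contig, , drop = FALSE]
    ov <- ann$start <= r$end & ann$end >= r$start
    opp <- ov & ann$strand != r$strand
    if (any(opp)) {
      hits <- ann[opp, , drop = FALSE]
      labels <- vapply(seq_len(nrow(hits)), function(k) {
        gene_part_label(r$start, r$end, hits$start[k], hits$end[k],
                        hits$strand[k])
      }, character(1))
      if (nrow(hits) == 1) {
        rel <- paste0("antisense_", labels)
        related <- hits$gene_id
      } else {
        rel <- "antisense_multi"
        related <- paste(paste0(labels, "(", hits$gene_id, ")"),
                         collapse = ",")
      }
      return(tibble(relation = rel, related_genes = related))
    }
    if (!any(ov)) {
      left <- ann$gene_id[ann$end < r$start]
      right <- ann$gene_id[ann$start > r$end]
      left_id <- if (length(left) > 0) {
        ann$gene_id[which(ann$end < r$start)[which.max(ann$end[ann$end < r$start])]]
      } else NA_character_
      right_id <- if (length(right) > 0) {
        ann$gene_id[which(ann$start > r$end)[which.min(ann$start[ann$start > r$end])]]
      } else NA_character_
      related <- paste(stats::na.omit(c(left_id, right_id)), collapse = ",")
      return(tibble(relation = "intergenic", related_genes = related))
    }
    tibble(
      relation = "sense",
      related_genes = paste(ann$gene_id[ov], collapse = ",")
    )
  })
  bind_rows(res) |>
    bind_cols(regions[, intersect(
      c("contig", "start", "end", "strand", "mean_depth"), names(regions)
    )]) |>
    mutate(
      name = sprintf("misc_%d", dplyr::row_number()),
      mean_expression = if ("mean_depth" %in% names(regions)) {
        .data$mean_depth
      } else {
        NA_real_
      }
    ) |>
    select(name, contig, start, end, strand, relation, related_genes,
           mean_expression)
}

## ---- internals -----------------------------------------------------------

check_reads <- function(reads, contig_length) {
  need <- c("contig", "start", "end", "strand", "sample_id")
  if (!all(need %in% names(reads))) {
    abort("reads must have columns contig, start, end, strand, sample_id")
  }
  if (nrow(reads) > 0 &&
      (any(reads$start < 1) || any(reads$end > contig_length))) {
    abort("read interval outside the contig bounds")
  }
  invisible(reads)
}

## maximal runs of depth >= min_depth, merged across gaps <= merge_gap,
## shorter than min_length dropped
depth_runs <- function(depth, min_depth, merge_gap, min_length) {
  r <- rle(depth >= min_depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  merged <- list(c(runs$start[1], runs$end[1]))
  for (i in seq_len(nrow(runs))[-1]) {
    last <- merged[[length(merged)]]
    if (runs$start[i] - last[2] - 1 <= merge_gap) {
      merged[[length(merged)]][2] <- runs$end[i]
    } else {
      merged[[length(merged) + 1]] <- c(runs$start[i], runs$end[i])
    }
  }
  m <- do.call(rbind, merged)
  res <- tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  res[res$end - res$start + 1 >= min_length, , drop = FALSE]
}

## bases of [s, e] covered by the union of intervals [gs_i, ge_i]
union_overlap <- function(s, e, gs, ge) {
  if (length(gs) == 0) {
    return(0L)
  }
  cs <- pmax(gs, s)
  ce <- pmin(ge, e)
  keep <- cs <= ce
  if (!any(keep)) {
    return(0L)
  }
  iv <- cbind(cs[keep], ce[keep])
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0L
  cur_s <- iv[1, 1]
  cur_e <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur_e + 1) {
      cur_e <- max(cur_e, iv[i, 2])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- iv[i, 1]
      cur_e <- iv[i, 2]
    }
  }
  total + (cur_e - cur_s + 1L)
}

## which part of the gene (oriented 5'->3') does the overlap's midpoint hit
gene_part_label <- function(rs, re, gs, ge, gstrand) {
  os <- max(rs, gs)
  oe <- min(re, ge)
  mid <- (os + oe) / 2
  len <- ge - gs + 1
  rel <- if (gstrand == "+") (mid - gs + 0.5) / len else (ge - mid + 0.5) / len
  if (rel <= 1 / 3) {
    "5prime"
  } else if (rel >= 2 / 3) {
    "3prime"
  } else {
    "middle"
  }
}
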