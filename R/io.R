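#' Read gene features from a GFF3 file
#'
#' Parses gene-type records (1-based inclusive coordinates preserved) into a
#' tibble of gene features. rRNA genes (attribute `biotype=rRNA`) are
#' skipped, mirroring the convention that TGR matrices cover non-rRNA gene
#' features only. Malformed lines and missing `ID` attributes raise errors
#' naming the offending line number.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types (column 3) to keep (default `"gene"`).
#' @return Tibble with `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `organism` (from an `organism` attribute when present, else `NA`) and
#'   `product`.
#' @export
read_gff3 <- function(path, feature_types = "gene") {
  lines <- readLines(path)
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      abort(paste0("malformed GFF3 line ", i, ": expected 9 tab-separated ",
                   "columns, got ", length(f)))
    }
    if (!(f[3] %in% feature_types)) next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      abort(paste0("malformed GFF3 line ", i, ": non-numeric coordinates"))
    }
    if (end < start) {
      abort(paste0("malformed GFF3 line ", i, ": end < start"))
    }
    if (!(f[7] %in% c("+", "-"))) {
      abort(paste0("malformed GFF3 line ", i, ": strand must be + or -"))
    }
    attrs <- parse_gff3_attributes(f[9])
    if (is.na(attrs[["ID"]] %||% NA_character_)) {
      abort(paste0("GFF3 line ", i, ": missing ID attribute"))
    }
    if (identical(attrs[["biotype"]] %||% NA_character_, "rRNA")) next
    recs[[length(recs) + 1]] <- tibble(
      gene_id = attrs[["ID"]],
      contig = f[1],
      start = start,
      end = end,
      strand = f[7],
      organism = attrs[["organism"]] %||% NA_character_,
      product = attrs[["product"]] %||% NA_character_
    )
  }
  if (length(recs) == 0) {
    return(tibble(
      gene_id = character(), contig = character(), start = integer(),
      end = integer(), strand = character(), organism = character(),
      product = character()
    ))
  }
  out <- bind_rows(recs)
  if (anyDuplicated(out$gene_id)) {
    abort(paste0("duplicated gene IDs in annotation: ",
                 paste(unique(out$gene_id[duplicated(out$gene_id)]),
                       collapse = ", ")))
  }
  out
}

#' Write gene features as GFF3
#'
#' @param genes Tibble with `gene_id`, `contig`, `start`, `end`, `strand`,
#'   and optionally `organism` and `product` (written as attributes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  attrs <- paste0("ID=", genes$gene_id)
  if ("organism" %in% names(genes)) {
    attrs <- ifelse(is.na(genes$organism), attrs,
                    paste0(attrs, ";organism=", genes$organism))
  }
  if ("product" %in% names(genes)) {
    attrs <- ifelse(is.na(genes$product), attrs,
                    paste0(attrs, ";product=", genes$product))
  }
  lines <- paste(
    genes$contig, "phagephase", "gene", genes$start, genes$end, ".",
    genes$strand, ".", attrs,
    sep = "\t"
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a count matrix and its sample metadata
#'
#' Reads a tab-separated genes x samples matrix (first column `gene_id`,
#' one column per sample, `#`-prefixed header comments allowed) and a
#' sidecar sample-metadata TSV (`sample_id`, `time_min`, optionally
#' `phase_group` — derived from [phase_grouping()] when absent). Validates
#' that header sample IDs match the metadata, that gene IDs are unique, and
#' that every cell is a non-negative number, naming the offending row and
#' column otherwise.
#'
#' @param counts_path Path to the counts TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @return List with `counts` (long tibble `gene_id`, `sample_id`, `count`,
#'   sample order following the metadata) and `samples` (metadata tibble).
#' @export
read_counts <- function(counts_path, meta_path) {
  samples <- readr::read_tsv(meta_path, comment = "#",
                             show_col_types = FALSE)
  if (!all(c("sample_id", "time_min") %in% names(samples))) {
    abort("sample metadata must have columns sample_id and time_min")
  }
  if (!"phase_group" %in% names(samples)) {
    samples$phase_group <- assign_phases(samples$time_min)
  }
  wide <- readr::read_tsv(counts_path, comment = "#",
                          col_types = readr::cols(.default = "c"),
                          show_col_types = FALSE)
  if (names(wide)[1] != "gene_id") {
    abort("counts matrix must have 'gene_id' as its first column")
  }
  sample_cols <- names(wide)[-1]
  extra <- setdiff(sample_cols, samples$sample_id)
  if (length(extra) > 0) {
    abort(paste0("sample(s) in counts absent from metadata: ",
                 paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(wide$gene_id)) {
    abort(paste0("duplicated gene_id row(s): ",
                 paste(unique(wide$gene_id[duplicated(wide$gene_id)]),
                       collapse = ", ")))
  }
  for (cn in sample_cols) {
    vals <- suppressWarnings(as.numeric(wide[[cn]]))
    bad <- which(is.na(vals) | wide[[cn]] == ".")
    if (length(bad) > 0) {
      abort(paste0("non-numeric count for gene '", wide$gene_id[bad[1]],
                   "', sample '", cn, "'"))
    }
    if (any(vals < 0)) {
      abort(paste0("negative count for gene '",
                   wide$gene_id[which(vals < 0)[1]], "', sample '", cn, "'"))
    }
    wide[[cn]] <- vals
  }
  ## long form in metadata sample order
  keep <- samples$sample_id[samples$sample_id %in% sample_cols]
  counts <- wide |>
    tidyr::pivot_longer(-gene_id, names_to = "sample_id",
                        values_to = "count") |>
    mutate(sample_id = factor(sample_id, levels = keep)) |>
    arrange(sample_id) |>
    mutate(sample_id = as.character(sample_id))
  list(counts = counts, samples = samples)
}

#' Write a long count table as a genes x samples TSV
#'
#' @param counts Long tibble (`gene_id`, `sample_id`, `count`).
#' @param path Output path.
#' @param header_comment Optional character vector of comment lines written
#'   (prefixed `# `) above the table, typically recording pipeline version
#'   and parameters.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, header_comment = NULL) {
  wide <- counts |>
    tidyr::pivot_wider(names_from = sample_id, values_from = count)
  body <- sub("\n$", "", readr::format_tsv(wide))
  header <- if (!is.null(header_comment)) paste0("# ", header_comment)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' Parses a 4-column bedGraph (0-based half-open intervals) and converts to
#' the internal 1-based inclusive convention: `[a, b)` becomes
#' `[a + 1, b]`. Overlapping intervals and negative values are errors;
#' track definition lines and `#` comments are skipped.
#'
#' @param path Path to a bedGraph file.
#' @param contig_length Optional declared contig length; intervals beyond it
#'   raise an error.
#' @return Tibble with `contig`, `start`, `end` (1-based inclusive),
#'   `value`.
#' @export
read_bedgraph <- function(path, contig_length = NULL) {
  lines <- readLines(path)
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "track")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4) {
      abort(paste0("malformed bedGraph line ", i, ": expected 4 columns"))
    }
    s0 <- suppressWarnings(as.integer(f[2]))
    e0 <- suppressWarnings(as.integer(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s0) || is.na(e0) || is.na(v)) {
      abort(paste0("malformed bedGraph line ", i, ": non-numeric field"))
    }
    if (v < 0) {
      abort(paste0("bedGraph line ", i, ": negative value"))
    }
    if (e0 <= s0) {
      abort(paste0("bedGraph line ", i, ": empty or inverted interval"))
    }
    if (!is.null(contig_length) && e0 > contig_length) {
      abort(paste0("bedGraph line ", i, ": interval beyond contig length"))
    }
    recs[[length(recs) + 1]] <- tibble(
      contig = f[1], start = s0 + 1L, end = e0, value = v
    )
  }
  if (length(recs) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  value = numeric()))
  }
  out <- bind_rows(recs)
  by_contig <- split(out, out$contig)
  for (tr in by_contig) {
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1 && any(tr$start[-1] <= tr$end[-nrow(tr)])) {
      abort("overlapping intervals in bedGraph")
    }
  }
  out
}

#' Write a coverage track as bedGraph
#'
#' Internal 1-based inclusive intervals are emitted 0-based half-open:
#' `[a, b]` becomes `[a - 1, b)`.
#'
#' @param track Tibble with `contig`, `start`, `end` (1-based inclusive),
#'   `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- paste(track$contig, track$start - 1L, track$end, track$value,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a non-coding RNA candidate table
#'
#' Parses a TSV with columns `name`, `contig`, `start`, `end`, `strand` and
#' a free-text `relation` column (e.g. "antisense to 3' end of g048",
#' "intragenic region between g099 and g100"), deriving a
#' `relation_class` of `antisense` or `intergenic` from the text. The
#' packaged file `phiR1_37_ncrna.tsv` holds the ten candidates identified
#' in the bacteriophage phiR1-37 genome.
#'
#' @param path Path to the TSV.
#' @return Tibble with the parsed columns plus `relation_class` and
#'   `length`.
#' @export
#' @examples
#' tab <- read_ncrna_table(
#'   system.file("extdata", "phiR1_37_ncrna.tsv", package = "phagephase")
#' )
#' table(tab$relation_class)
read_ncrna_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("name", "contig", "start", "end", "strand", "relation")
  if (!all(need %in% names(tab))) {
    abort(paste0("ncRNA table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (any(tab$end < tab$start)) abort("ncRNA interval with end < start")
  if (!all(tab$strand %in% c("+", "-"))) abort("strand must be + or -")
  tab |>
    mutate(
      relation_class = ifelse(grepl("antisense", relation, fixed = TRUE),
                              "antisense", "intergenic"),
      length = end - start + 1L
    )
}

## ---- internals -----------------------------------------------------------

parse_gff3_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[parts != ""]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2) p[2] else NA_character_,
                 character(1))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  as.list(vals)
}
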