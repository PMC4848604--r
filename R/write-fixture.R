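#' Write a simulated data set to disk
#'
#' Serializes a [simulate_infection()] result as the pipeline's on-disk
#' interchange formats: the annotation as GFF3, the count matrix and sample
#' metadata as TSV, per-sample per-strand phage coverage as bedGraph
#' (0-based half-open), and the truth tables as TSV. Everything round-trips
#' losslessly through the package readers.
#'
#' @param sim An `"infection_sim"` object.
#' @param dir Output directory; created if absent. A non-empty existing
#'   directory is refused unless `force = TRUE`.
#' @param force Overwrite into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir, force = FALSE) {
  stopifnot(inherits(sim, "infection_sim"))
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE,
                                           no.. = TRUE)) > 0 && !force) {
    abort(paste0("directory '", dir, "' is not empty; use force = TRUE"))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)

  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  stamp <- paste0("phagephase ", as.character(utils::packageVersion("phagephase")),
                  "; seed=", sim$config$seed)
  write_counts(sim$counts, file.path(dir, "counts.tsv"),
               header_comment = stamp)
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$truth$phage_class,
                   file.path(dir, "truth_phage_class.tsv"))
  readr::write_tsv(sim$truth$host_effect,
                   file.path(dir, "truth_host_effect.tsv"))
  readr::write_tsv(sim$truth$ncrnas, file.path(dir, "truth_ncrna.tsv"))

  glen <- sim$config$phage_genome_len
  for (sid in sim$samples$sample_id) {
    for (str in c("+", "-")) {
      depth <- per_base_depth(sim$reads, glen, str, sample_ids = sid)
      track <- depth_to_track(depth, contig = "phage")
      suffix <- if (str == "+") "plus" else "minus"
      write_bedgraph(
        track,
        file.path(dir, "coverage", paste0(sid, "_", suffix, ".bedGraph"))
      )
    }
  }
  invisible(dir)
}

## run-length compress a per-base depth vector into 1-based intervals,
## dropping zero runs
depth_to_track <- function(depth, contig) {
  r <- rle(depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values > 0
  tibble(
    contig = contig,
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    value = r$values[keep]
  )
}
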