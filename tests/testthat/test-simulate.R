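test_that("invalid configurations are rejected", {
  expect_error(sim_config(time_points_min = c(2, 5)), "0-min control")
  expect_error(sim_config(time_points_min = c(0, 5, 2)), "increasing")
  expect_error(
    sim_config(class_proportions = c(early = 0.5, middle = 0.2, late = 0.2,
                                     constitutive = 0.2, excluded = 0)),
    "sum to 1"
  )
  expect_error(
    sim_config(phage_fraction_curve = c(0.1, rep(0.1, 9))),
    "0 at t = 0"
  )
  expect_error(
    sim_config(phage_fraction_curve = c(0, rep(1.2, 9))),
    "\\[0, 1\\)"
  )
  expect_error(
    sim_config(n_phage_genes = 400, phage_genome_len = 50000),
    "cannot place"
  )
})

test_that("the same seed and config give bit-identical output", {
  cfg <- sim_config(seed = 23, library_size = 5e4)
  s1 <- simulate_infection(cfg)
  s2 <- simulate_infection(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_infection(sim_config(seed = 24, library_size = 5e4))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("nothing is planted when ncRNA counts are zero", {
  sim <- simulate_infection(
    sim_config(seed = 2, n_asrna = 0, n_intergenic_rna = 0,
               library_size = 5e4)
  )
  expect_equal(nrow(sim$truth$ncrnas), 0)
  ## with nothing unassigned, gene counts account for the whole library
  tot <- sim$counts |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(t = sum(count))
  expect_true(all(tot$t == sim$config$library_size))
})

test_that("per-sample gene counts plus unassigned ncRNA reads equal the library size", {
  sim <- quick_sim(seed = 4)
  tot <- sim$counts |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(t = sum(count)) |>
    dplyr::left_join(sim$samples, by = "sample_id")
  ## organism split always sums to the library
  expect_true(all(tot$phage_reads + tot$host_reads ==
                    sim$config$library_size))
  ## unassigned = planted ncRNA reads, present only after infection
  unassigned <- sim$config$library_size - tot$t
  expect_true(all(unassigned >= 0))
  expect_equal(unassigned[tot$time_min == 0], 0)
  ## read intervals account for every phage-mapped read
  per_sample_reads <- sim$reads |> dplyr::count(sample_id)
  merged <- dplyr::left_join(tot, per_sample_reads, by = "sample_id") |>
    dplyr::mutate(n = ifelse(is.na(n), 0L, n))
  expect_equal(merged$n, merged$phage_reads)
})

test_that("realized phage read totals track the expected curve binomially", {
  sim <- quick_sim(seed = 8)
  q <- sim$truth$expected_fraction$expected_fraction
  L <- sim$config$library_size
  realized <- sim$samples$phage_reads / L
  sd3 <- 3 * sqrt(q * (1 - q) / L)
  expect_true(all(abs(realized - q) <= sd3 + 1e-12))
})

test_that("phage genes are laid out without overlap and inside the genome", {
  sim <- quick_sim(seed = 9)
  pg <- sim$genes[sim$genes$organism == "phage", ] |> dplyr::arrange(start)
  expect_true(all(pg$start[-1] > pg$end[-nrow(pg)]))
  expect_true(all(pg$start >= 1 & pg$end <= sim$config$phage_genome_len))
  ## planted ncRNAs lie within the genome
  nc <- sim$truth$ncrnas
  expect_true(all(nc$start >= 1 & nc$end <= sim$config$phage_genome_len))
  ## every phage gene carries exactly one class label
  expect_setequal(sim$truth$phage_class$gene_id, pg$gene_id)
})

test_that("a pure-constitutive Poisson simulation classifies as constitutive", {
  cfg <- sim_config(
    seed = 1, n_phage_genes = 200, phage_genome_len = 100000,
    class_proportions = c(early = 0, middle = 0, late = 0,
                          constitutive = 1, excluded = 0),
    dispersion = Inf, n_asrna = 0, n_intergenic_rna = 0,
    host_de_config = list(n_early_down = 0, n_early_up = 0, n_late_up = 0,
                          n_late_down = 0, effect_log2fc = 0),
    library_size = 2e5
  )
  sim <- simulate_infection(cfg)
  expect_false(sim$budget_feasible) # degenerate mix uses the implied curve
  norm <- total_count_normalize(sim$counts, sim$genes)
  calls <- classify_phage_genes(norm, sim$samples, sim$genes)
  expect_gte(mean(calls$class == "constitutive"), 0.95)
})

test_that("fixtures round-trip through the io module", {
  sim <- simulate_infection(sim_config(seed = 14, library_size = 2e4))
  dir <- file.path(withr::local_tempdir(), "fx")
  write_fixture(sim, dir)
  ## refuse to clobber without force
  expect_error(write_fixture(sim, dir), "not empty")
  expect_no_error(write_fixture(sim, dir, force = TRUE))

  genes <- read_gff3(file.path(dir, "genes.gff3"))
  expect_equal(nrow(genes), nrow(sim$genes))
  expect_equal(genes$start, sim$genes$start)
  expect_equal(genes$organism, sim$genes$organism)

  back <- read_counts(file.path(dir, "counts.tsv"),
                      file.path(dir, "samples.tsv"))
  expect_equal(
    back$counts |> dplyr::arrange(gene_id, sample_id) |>
      dplyr::pull(count),
    sim$counts |> dplyr::arrange(gene_id, sample_id) |>
      dplyr::pull(count) |> as.numeric()
  )

  ## bedGraph tracks are valid (non-overlapping, within the genome) and
  ## their area equals the read bases on that strand and sample
  bg <- read_bedgraph(
    file.path(dir, "coverage", "t49_plus.bedGraph"),
    contig_length = sim$config$phage_genome_len
  )
  area <- sum((bg$end - bg$start + 1) * bg$value)
  r49 <- sim$reads[sim$reads$sample_id == "t49" & sim$reads$strand == "+", ]
  expect_equal(area, sum(r49$end - r49$start + 1))
})
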