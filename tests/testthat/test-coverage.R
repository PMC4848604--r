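test_that("reads land in the bin containing their 5' end", {
  reads <- tibble::tibble(
    contig = "phage",
    start = c(1, 251, 200, 200),
    end = c(90, 340, 289, 251),
    strand = c("+", "+", "+", "-"),
    sample_id = "t02"
  )
  bins <- bin_coverage(reads, contig_length = 1000)
  plus <- bins[bins$strand == "+", ]
  minus <- bins[bins$strand == "-", ]
  expect_equal(plus$count[plus$bin == 1], 2) # 5' ends at 1 and 200
  expect_equal(plus$count[plus$bin == 2], 1) # boundary: 5' end at 251
  expect_equal(minus$count[minus$bin == 2], 1) # minus-strand 5' end = 251
  expect_equal(nrow(bins), 2 * ceiling(1000 / 250))
  expect_equal(bins$bin_start[bins$bin == 2][1], 251)
  expect_error(bin_coverage(reads, contig_length = 300), "outside")
})

test_that("binned counts conserve stranded read totals on random inputs", {
  withr::with_seed(77, {
    for (i in 1:5) {
      n <- 500
      s <- sample.int(9000, n, replace = TRUE)
      reads <- tibble::tibble(
        contig = "phage", start = s, end = s + 89,
        strand = sample(c("+", "-"), n, replace = TRUE),
        sample_id = sample(c("t02", "t49"), n, replace = TRUE)
      )
      bins <- bin_coverage(reads, contig_length = 10000)
      got <- bins |>
        dplyr::group_by(sample_id, strand) |>
        dplyr::summarise(n = sum(count), .groups = "drop")
      want <- reads |> dplyr::count(sample_id, strand)
      merged <- dplyr::inner_join(got, want, by = c("sample_id", "strand"),
                                  suffix = c("_bin", "_reads"))
      expect_equal(merged$n_bin, as.numeric(merged$n_reads))
    }
  })
})

test_that("per-base depth matches a naive per-read oracle", {
  withr::with_seed(15, {
    s <- sample.int(900, 100, replace = TRUE)
    reads <- tibble::tibble(
      contig = "c", start = s, end = pmin(s + sample.int(50, 100, TRUE), 1000),
      strand = sample(c("+", "-"), 100, replace = TRUE),
      sample_id = "t28"
    )
  })
  for (str in c("+", "-")) {
    expect_equal(per_base_depth(reads, 1000, str),
                 oracle_depth(reads, 1000, str))
  }
})

test_that("transcribed-region detection finds exactly the forced run", {
  ## no coverage at all
  empty <- tibble::tibble(
    contig = character(), start = integer(), end = integer(),
    strand = character(), sample_id = character()
  )
  genes <- tibble::tibble(
    gene_id = "g1", contig = "phage", start = 600, end = 900, strand = "+"
  )
  expect_equal(
    nrow(detect_transcribed_regions(empty, genes, 1000)), 0
  )

  ## uniform deep coverage 200-500 on the minus strand, no minus gene there
  reads <- tibble::tibble(
    contig = "phage",
    start = rep(200, 100), end = rep(500, 100),
    strand = "-", sample_id = "t28"
  )
  reg <- detect_transcribed_regions(reads, genes, 1000, min_depth = 10,
                                    min_length = 100)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end, reg$strand), c("200", "500", "-"))
  expect_equal(reg$mean_depth, 100)

  ## the same run fully inside a same-strand gene is removed
  sense_gene <- tibble::tibble(
    gene_id = "g2", contig = "phage", start = 180, end = 520, strand = "-"
  )
  expect_equal(
    nrow(detect_transcribed_regions(reads, sense_gene, 1000)), 0
  )
})

test_that("raising min_depth never yields more or longer regions", {
  withr::with_seed(31, {
    s <- sample.int(1900, 800, replace = TRUE)
    reads <- tibble::tibble(
      contig = "phage", start = s, end = pmin(s + 90, 2000),
      strand = "+", sample_id = "t28"
    )
  })
  genes <- tibble::tibble(gene_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          strand = character())
  lo <- detect_transcribed_regions(reads, genes, 2000, min_depth = 5,
                                   min_length = 50)
  hi <- detect_transcribed_regions(reads, genes, 2000, min_depth = 20,
                                   min_length = 50)
  expect_lte(nrow(hi), nrow(lo))
  expect_lte(sum(hi$length), sum(lo$length))
})

test_that("relation labels are oriented by the gene's own 5' end", {
  gene_plus <- tibble::tibble(
    gene_id = "gA", contig = "phage", start = 1000, end = 1899, strand = "+"
  )
  region <- tibble::tibble(
    contig = "phage", start = 1000, end = 1199, strand = "-",
    mean_depth = 50
  )
  lab <- classify_relation(region, gene_plus)
  expect_equal(lab$relation, "antisense_5prime")
  expect_equal(lab$related_genes, "gA")

  ## flipping the gene's strand turns the same overlap into a 3' label
  gene_minus <- dplyr::mutate(gene_plus, strand = "-")
  region_plus <- dplyr::mutate(region, strand = "+")
  expect_equal(classify_relation(region_plus, gene_minus)$relation,
               "antisense_3prime")

  ## middle overlap
  mid <- dplyr::mutate(region, start = 1400, end = 1500)
  expect_equal(classify_relation(mid, gene_plus)$relation,
               "antisense_middle")
})

test_that("multi-gene and intergenic relations are labelled with their genes", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), contig = "phage",
    start = c(100, 700), end = c(400, 1000), strand = "+"
  )
  spanning <- tibble::tibble(
    contig = "phage", start = 350, end = 750, strand = "-", mean_depth = 20
  )
  lab <- classify_relation(spanning, genes)
  expect_equal(lab$relation, "antisense_multi")
  expect_match(lab$related_genes, "3prime\\(g1\\)")
  expect_match(lab$related_genes, "5prime\\(g2\\)")

  between <- tibble::tibble(
    contig = "phage", start = 450, end = 650, strand = "+", mean_depth = 20
  )
  lab2 <- classify_relation(between, genes)
  expect_equal(lab2$relation, "intergenic")
  expect_equal(lab2$related_genes, "g1,g2")
})

test_that("planted ncRNAs are recovered end to end with correct relations", {
  sim <- simulate_infection(sim_config(seed = 11, library_size = 2e5))
  phage_genes <- sim$genes[sim$genes$organism == "phage", ]
  regions <- detect_transcribed_regions(
    sim$reads, phage_genes, sim$config$phage_genome_len,
    samples = sim$samples
  )
  cand <- classify_relation(regions, phage_genes)
  truth <- sim$truth$ncrnas
  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    match_i <- cand$strand == truth$strand[i] &
      abs(cand$start - truth$start[i]) <= 50 &
      abs(cand$end - truth$end[i]) <= 50
    if (any(match_i)) {
      hit[i] <- cand$relation[which(match_i)[1]] == truth$relation[i]
    }
  }
  expect_gte(mean(hit), 0.9)
})
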