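test_that("log2 fold change follows the pseudocount formula exactly", {
  expect_equal(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(79, 9, pseudocount = 1), 3)
  expect_equal(log2_fold_change(0, 0), 0)
  ## antisymmetry
  withr::with_seed(3, {
    a <- stats::runif(50, 0, 500)
    b <- stats::runif(50, 0, 500)
    expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  })
  expect_error(log2_fold_change(-1, 2), "non-negative")
})

de_fixture <- function(group_counts, control, group = "early") {
  phase <- phase_grouping()[[group]]
  stopifnot(length(group_counts) == length(phase))
  sid <- c("t00", sprintf("t%02d", phase))
  list(
    counts = tibble::tibble(
      gene_id = "h1", sample_id = sid, count = c(control, group_counts)
    ),
    samples = tibble::tibble(
      sample_id = sid, time_min = c(0, phase),
      phase_group = c("control", rep(group, length(phase)))
    )
  )
}

test_that("the compound control rule gates on both log2FC and the 2-SD window", {
  f <- de_fixture(c(100, 100), 100)
  call <- de_call_vs_control(f$counts, f$samples)
  expect_equal(call$log2fc, 0)
  expect_equal(call$group_sd, 0)
  expect_false(call$control_outside_2sd)
  expect_equal(call$status, "ns")

  f <- de_fixture(c(64, 64), 8)
  call <- de_call_vs_control(f$counts, f$samples)
  expect_equal(call$log2fc, log2(65 / 9))
  expect_true(call$control_outside_2sd)
  expect_equal(call$status, "up")

  ## control inside +/- 2 SD vetoes the call regardless of fold change
  f <- de_fixture(c(100, 20), 55)
  call <- de_call_vs_control(f$counts, f$samples)
  expect_equal(call$group_sd, stats::sd(c(100, 20)))
  expect_true(55 > 60 - 2 * call$group_sd && 55 < 60 + 2 * call$group_sd)
  expect_false(call$control_outside_2sd)
  expect_equal(call$status, "ns")
})

test_that("the 2-SD gate is jointly scale-invariant (pseudocount 0)", {
  th0 <- de_thresholds(pseudocount = 0)
  withr::with_seed(21, {
    for (i in 1:20) {
      g <- stats::runif(2, 10, 200)
      ctl <- stats::runif(1, 1, 200)
      k <- stats::runif(1, 0.1, 20)
      c1 <- de_call_vs_control(de_fixture(g, ctl)$counts,
                               de_fixture(g, ctl)$samples, thresholds = th0)
      c2 <- de_call_vs_control(de_fixture(g * k, ctl * k)$counts,
                               de_fixture(g, ctl)$samples, thresholds = th0)
      expect_equal(c1$control_outside_2sd, c2$control_outside_2sd)
      expect_equal(c1$log2fc, c2$log2fc, tolerance = 1e-12)
      expect_equal(c1$status, c2$status)
    }
  })
})

test_that("a phase group of one sample is rejected", {
  sid <- c("t00", "t02")
  counts <- tibble::tibble(gene_id = "h1", sample_id = sid, count = c(5, 9))
  samples <- tibble::tibble(
    sample_id = sid, time_min = c(0, 2), phase_group = c("control", "early")
  )
  expect_error(de_call_vs_control(counts, samples), ">= 2 samples")
})

le_fixture <- function(early, late) {
  sid <- c(sprintf("t%02d", c(2, 5)), sprintf("t%02d", c(28, 35, 42, 49)))
  list(
    counts = tibble::tibble(
      gene_id = "h1", sample_id = sid, count = c(early, late)
    ),
    samples = tibble::tibble(
      sample_id = sid, time_min = c(2, 5, 28, 35, 42, 49),
      phase_group = rep(c("early", "late"), c(2, 4))
    )
  )
}

test_that("late-vs-early combines the Student t-test with the fold gate", {
  ## identical groups: zero variance, equal means -> p = 1, ns
  f <- le_fixture(c(10, 10), c(10, 10, 10, 10))
  call <- de_call_late_vs_early(f$counts, f$samples)
  expect_equal(call$p_value, 1)
  expect_equal(call$status, "ns")

  ## strong shift with tiny jitter: p matches the textbook pooled formula
  withr::with_seed(5, {
    e <- 10 + stats::rnorm(2, sd = 0.1)
    l <- 80 + stats::rnorm(4, sd = 0.1)
  })
  f <- le_fixture(e, l)
  call <- de_call_late_vs_early(f$counts, f$samples)
  expect_equal(call$p_value, oracle_pooled_t(l, e), tolerance = 1e-10)
  expect_gt(call$log2fc, 1.5)
  expect_lt(call$p_value, 0.01)
  expect_equal(call$status, "up")

  ## sub-threshold fold change is ns regardless of p
  f <- le_fixture(c(10, 20), c(12, 18, 14, 16))
  call <- de_call_late_vs_early(f$counts, f$samples)
  expect_equal(call$log2fc, log2(16 / 16))
  expect_equal(call$status, "ns")

  ## zero variance with unequal means: p = 0 convention, flagged
  f <- le_fixture(c(10, 10), c(80, 80, 80, 80))
  call <- de_call_late_vs_early(f$counts, f$samples)
  expect_equal(call$p_value, 0)
  expect_true(call$zero_variance)
  expect_equal(call$status, "up")
})

test_that("Welch and BH options change only what they should", {
  withr::with_seed(9, {
    e <- stats::rnorm(2, 50, 10)
    l <- stats::rnorm(4, 200, 40)
  })
  f <- le_fixture(e, l)
  student <- de_call_late_vs_early(f$counts, f$samples)
  welch <- de_call_late_vs_early(f$counts, f$samples, welch = TRUE)
  expect_false(isTRUE(all.equal(student$p_value, welch$p_value)))
  bh <- de_call_late_vs_early(f$counts, f$samples, bh = TRUE)
  expect_true("p_adj" %in% names(bh))
  expect_equal(bh$p_adj, stats::p.adjust(bh$p_value, "BH"))
})

test_that("up and down calls are mutually exclusive and tallies recompute", {
  sim <- quick_sim(seed = 12)
  norm <- total_count_normalize(sim$counts, sim$genes)
  for (grp in c("early", "late")) {
    calls <- de_call_vs_control(norm, sim$samples, sim$genes, grp)
    expect_true(all(calls$status %in% c("up", "down", "ns")))
    expect_true(all(abs(calls$log2fc[calls$status != "ns"]) > 1.5))
    expect_true(all(calls$control_outside_2sd[calls$status != "ns"]))
    tl <- tally_de(calls)
    expect_equal(tl$n_de, tl$n_up + tl$n_down)
    expect_equal(tl$pct_de_genome, 100 * tl$n_de / tl$n_total)
  }
  ## empty input tallies to zeros
  empty <- tibble::tibble(gene_id = character(), comparison = character(),
                          status = character())
  tl0 <- tally_de(empty)
  expect_equal(tl0$n_de, 0L)
  expect_equal(tl0$pct_up_of_de, 0)
})

test_that("planted host effects are recovered with high sensitivity and specificity", {
  sim <- simulate_infection(sim_config(seed = 3, library_size = 2e5))
  norm <- total_count_normalize(sim$counts, sim$genes)
  calls <- dplyr::bind_rows(
    tidy(de_call_vs_control(norm, sim$samples, sim$genes, "early")),
    tidy(de_call_vs_control(norm, sim$samples, sim$genes, "late"))
  )
  truth <- sim$truth$host_effect |>
    dplyr::mutate(true_status = ifelse(effect_log2fc > 0, "up", "down"))
  joined <- dplyr::left_join(calls, truth, by = c("gene_id", "comparison"))
  planted <- joined[!is.na(joined$true_status), ]
  nulls <- joined[is.na(joined$true_status), ]
  expect_gte(mean(planted$status == planted$true_status), 0.9)
  expect_gte(mean(nulls$status == "ns"), 0.95)
})
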