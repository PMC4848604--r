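#' Simulate a dual-organism phage infection RNA-seq time course
#'
#' Generates a complete synthetic data set with known ground truth: phage and
#' host gene annotations, a genes x samples read-count (TGR) matrix over the
#' configured time course, strand-specific read intervals on the phage genome,
#' and a truth table recording every planted temporal class, host
#' differential-expression effect and non-coding RNA.
#'
#' Per-gene expected counts follow class-specific temporal profiles that are
#' constant across the three infection phases up to a common within-phase ramp
#' whose phase mean is exactly 1, so the planted phase-average contrasts are
#' exact. Per-class expression budgets are solved from the configured
#' phage-read-fraction curve so that expected per-sample phage totals match
#' the curve; per-sample phage read totals are then drawn binomially and
#' allocated to genes by a gamma-weighted multinomial, giving
#' negative-binomial count marginals (size = `dispersion`) with exact
#' per-sample count conservation. Antisense transcripts emit reads on the
#' strand opposite their host gene; their reads appear in the coverage table
#' but not in any gene's count row.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"infection_sim"` with elements
#'   \describe{
#'     \item{genes}{tibble of gene features (`gene_id`, `contig`, `start`,
#'       `end`, `strand`, `organism`, `product`).}
#'     \item{samples}{tibble of sample metadata (`sample_id`, `time_min`,
#'       `phase_group`, `phage_reads`, `host_reads`).}
#'     \item{counts}{long tibble (`gene_id`, `sample_id`, `count`) of raw
#'       integer TGR values.}
#'     \item{reads}{tibble of stranded read intervals on the phage genome
#'       (`contig`, `start`, `end`, `strand`, `sample_id`).}
#'     \item{truth}{list with `phage_class`, `host_effect`, `ncrnas` and
#'       `expected_fraction` tibbles.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' sim <- simulate_infection(sim_config(seed = 1, library_size = 5e4))
#' dplyr::count(sim$truth$phage_class, class)
simulate_infection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_infection_impl(config))
}

simulate_infection_impl <- function(cfg) {
  L <- cfg$library_size
  tp <- cfg$time_points_min
  infected <- tp[-1]
  phases <- assign_phases(tp, cfg$grouping)
  sample_id <- sprintf("t%02d", tp)

  ## ---- class sizes (largest-remainder rounding) ----
  n_class <- largest_remainder(cfg$class_proportions, cfg$n_phage_genes)

  ## ---- phage genome layout ----
  layout <- layout_phage_genes(cfg)
  phage_genes <- layout$genes
  classes <- sample(rep(names(n_class), n_class))
  phage_genes$class <- classes

  ## ---- host annotation ----
  host_genes <- layout_host_genes(cfg)

  ## ---- ncRNA planting ----
  nc <- plant_ncrnas(cfg, phage_genes, layout$reserved_gaps)

  ## ---- expression model ----
  pf <- cfg$phage_fraction_curve[-1]
  phase_inf <- phases[-1]
  phase_means <- tapply(pf, phase_inf, mean)[c("early", "middle", "late")]
  nc_total_share <- (cfg$n_asrna + cfg$n_intergenic_rna) * 6e-4
  nc_prof <- c(early = 0.1, middle = 0.3, late = 1)
  excl_share <- n_class[["excluded"]] * 3 / L

  budget <- solve_class_budgets(
    phase_means, n_class, cfg$peak_fold,
    nc_share = nc_total_share * nc_prof, excl_share = excl_share
  )

  ## within-phase ramp, phase mean exactly 1 (flat when budgets infeasible)
  if (budget$feasible) {
    rho <- pf / phase_means[phase_inf]
  } else {
    rho <- rep(1, length(pf))
  }

  ## per-gene expected counts (phage), infected samples only
  xg <- gene_heterogeneity(classes, sdlog = 0.4)
  per_gene_base <- L * budget$share[classes, , drop = FALSE] /
    pmax(n_class[classes], 1) * xg # genes x 3 phases
  mu_phage <- per_gene_base[, phase_inf, drop = FALSE] *
    rep(rho, each = nrow(per_gene_base))

  ## ncRNA expected reads
  n_nc <- nrow(nc$ncrnas)
  if (n_nc > 0) {
    mu_nc <- outer(rep(L * 6e-4, n_nc), nc_prof[phase_inf] * rho)
  } else {
    mu_nc <- matrix(0, 0, length(infected))
  }

  ## expected phage fraction per infected sample
  q <- (colSums(mu_phage) + colSums(mu_nc)) / L
  if (any(q >= 1)) abort("expected phage fraction reaches 1; lower budgets")

  ## ---- host expression model ----
  hw <- rlnorm(cfg$n_host_genes, meanlog = 0, sdlog = 1)
  eff <- plant_host_effects(cfg, host_genes$gene_id)
  ## per-sample host weight matrix (all time points, control included)
  w_host <- matrix(hw, cfg$n_host_genes, length(tp))
  if (nrow(eff) > 0) {
    for (i in seq_len(nrow(eff))) {
      ph <- if (eff$comparison[i] == "early_vs_control") "early" else "late"
      idx <- match(eff$gene_id[i], host_genes$gene_id)
      w_host[idx, phases == ph] <-
        w_host[idx, phases == ph] * 2^eff$effect_log2fc[i]
    }
  }

  ## ---- draw counts ----
  phage_total <- c(0, rbinom(length(infected), size = round(L), prob = q))
  host_total <- round(L) - phage_total

  counts_phage <- matrix(0L, cfg$n_phage_genes, length(tp))
  counts_nc <- matrix(0L, max(n_nc, 0), length(tp))
  counts_host <- matrix(0L, cfg$n_host_genes, length(tp))
  for (j in seq_along(tp)) {
    if (j > 1) {
      mu_all <- c(mu_phage[, j - 1], if (n_nc > 0) mu_nc[, j - 1])
      drawn <- draw_pool(phage_total[j], mu_all, cfg$dispersion)
      counts_phage[, j] <- drawn[seq_len(cfg$n_phage_genes)]
      if (n_nc > 0) counts_nc[, j] <- drawn[-seq_len(cfg$n_phage_genes)]
    }
    counts_host[, j] <- draw_pool(host_total[j], w_host[, j], cfg$dispersion)
  }

  ## ---- read intervals on the phage genome ----
  reads <- make_reads(
    phage_genes, counts_phage, nc$ncrnas, counts_nc, sample_id,
    cfg$phage_genome_len
  )

  ## ---- assemble outputs ----
  genes <- bind_rows(
    phage_genes[, c("gene_id", "contig", "start", "end", "strand")] |>
      mutate(organism = "phage", product = NA_character_),
    host_genes |> mutate(organism = "host", product = NA_character_)
  )

  samples <- tibble(
    sample_id = sample_id,
    time_min = tp,
    phase_group = phases,
    phage_reads = as.integer(phage_total),
    host_reads = as.integer(host_total)
  )

  ## stack phage then host rows, column-major over samples (matches `genes`)
  counts <- tibble(
    gene_id = rep(genes$gene_id, times = length(tp)),
    sample_id = rep(sample_id, each = nrow(genes)),
    count = as.integer(as.vector(rbind(counts_phage, counts_host)))
  )

  truth <- list(
    phage_class = tibble(gene_id = phage_genes$gene_id, class = classes),
    host_effect = eff,
    ncrnas = nc$ncrnas,
    expected_fraction = tibble(
      sample_id = sample_id, time_min = tp,
      expected_fraction = c(0, q)
    )
  )

  structure(
    list(genes = genes, samples = samples, counts = counts, reads = reads,
         truth = truth, config = cfg, budget_feasible = budget$feasible),
    class = "infection_sim"
  )
}

#' @export
print.infection_sim <- function(x, ...) {
  cat("<infection_sim>\n")
  cat(" ", nrow(x$genes), "genes (",
      sum(x$genes$organism == "phage"), "phage /",
      sum(x$genes$organism == "host"), "host ),",
      nrow(x$samples), "samples\n")
  cat(" ", nrow(x$reads), "phage read intervals,",
      nrow(x$truth$ncrnas), "planted ncRNAs\n")
  invisible(x)
}

## ---- internals -----------------------------------------------------------

largest_remainder <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

layout_phage_genes <- function(cfg) {
  n <- cfg$n_phage_genes
  n_long <- min(cfg$n_asrna, n)
  lens <- c(
    round(runif(n_long, 420, 500)),
    round(runif(n - n_long, 200, 500))
  )
  lens <- sample(lens)
  slack <- cfg$phage_genome_len - sum(lens) - cfg$n_intergenic_rna * 400L
  if (slack < n + 1) {
    abort("cannot place genes without overlap: genome too short for gene count")
  }
  gaps <- as.vector(rmultinom(1, slack - (n + 1), rep(1, n + 1))) + 1L
  reserved_slot <- if (cfg$n_intergenic_rna > 0) {
    sample(2:n, cfg$n_intergenic_rna)
  } else {
    integer(0)
  }
  starts <- integer(n)
  ends <- integer(n)
  reserved <- matrix(NA_integer_, cfg$n_intergenic_rna, 2)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    if (i %in% reserved_slot) {
      reserved[match(i, reserved_slot), ] <- c(pos + 1L, pos + 400L)
      pos <- pos + 400L
    }
    starts[i] <- pos + 1L
    pos <- pos + lens[i]
    ends[i] <- pos
  }
  genes <- tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    contig = "phage",
    start = starts,
    end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
  list(genes = genes, reserved_gaps = reserved)
}

layout_host_genes <- function(cfg) {
  n <- cfg$n_host_genes
  lens <- round(runif(n, 600, 1200))
  starts <- cumsum(c(101, lens[-n] + 100))
  tibble(
    gene_id = sprintf("h%04d", seq_len(n)),
    contig = "host",
    start = as.integer(starts),
    end = as.integer(starts + lens - 1)
  ) |>
    mutate(strand = sample(c("+", "-"), n, replace = TRUE))
}

## Solve per-class total expression budgets (as fractions of the library)
## from the fraction curve's phase means. See the methods vignette for the
## derivation; infeasible mixes fall back to canonical profiles scaled to the
## overall mean fraction.
solve_class_budgets <- function(phase_means, n_class, peak_fold,
                                nc_share, excl_share) {
  F <- peak_fold
  V <- phase_means - nc_share - excl_share
  cls <- c("early", "middle", "late", "constitutive")
  feasible <- all(n_class[cls] > 0) && all(V > 0)
  if (feasible) {
    u <- 0.25 * V[["early"]] / F
    v <- u + (V[["middle"]] - V[["early"]]) / (F - 1)
    rem <- V[["early"]] - F * u - v
    k <- rem / 2
    w <- rem / 2
    f <- if (w > 0) (V[["late"]] - u - v - k) / w else -1
    feasible <- v > 0 && rem > 0 && f >= 2.5
  }
  if (feasible) {
    share <- rbind(
      early        = c(F * u, u, u),
      middle       = c(v, F * v, v),
      late         = c(w, w, f * w),
      constitutive = c(k, k, k),
      excluded     = rep(excl_share, 3)
    )
  } else {
    prof <- rbind(
      early        = c(F, 1, 1),
      middle       = c(1, F, 1),
      late         = c(1, 1, F),
      constitutive = c(1, 1, 1)
    )
    tot_unit <- colSums(prof * n_class[cls]) # per unit base share
    target <- mean(phase_means)
    b <- target / mean(tot_unit)
    share <- rbind(prof * b * n_class[cls], excluded = rep(excl_share, 3))
    rownames(share) <- c(cls, "excluded")
  }
  colnames(share) <- c("early", "middle", "late")
  list(share = share, feasible = feasible)
}

## Per-gene lognormal heterogeneity, rescaled to mean 1 within each class so
## class budgets are preserved exactly.
gene_heterogeneity <- function(classes, sdlog) {
  x <- rlnorm(length(classes), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  for (cl in unique(classes)) {
    idx <- classes == cl
    x[idx] <- x[idx] / mean(x[idx])
  }
  x
}

plant_host_effects <- function(cfg, host_ids) {
  hd <- cfg$host_de_config
  n_eff <- hd$n_early_down + hd$n_early_up + hd$n_late_up + hd$n_late_down
  if (n_eff == 0) {
    return(tibble(
      gene_id = character(), comparison = character(),
      effect_log2fc = numeric()
    ))
  }
  picked <- sample(host_ids, n_eff)
  tibble(
    gene_id = picked,
    comparison = rep(
      c("early_vs_control", "early_vs_control",
        "late_vs_control", "late_vs_control"),
      times = c(hd$n_early_down, hd$n_early_up, hd$n_late_up, hd$n_late_down)
    ),
    effect_log2fc = rep(
      c(-hd$effect_log2fc, hd$effect_log2fc,
        hd$effect_log2fc, -hd$effect_log2fc),
      times = c(hd$n_early_down, hd$n_early_up, hd$n_late_up, hd$n_late_down)
    )
  )
}

## Antisense transcripts sit inside a long (>= 420 bp) gene, 60 bp clear of
## its ends so their coverage runs never merge with neighbouring same-strand
## genes; position within the gene encodes the planted relation label.
plant_ncrnas <- function(cfg, phage_genes, reserved_gaps) {
  recs <- list()
  if (cfg$n_asrna > 0) {
    eligible <- which(phage_genes$end - phage_genes$start + 1 >= 420)
    if (length(eligible) < cfg$n_asrna) {
      abort("not enough long genes to host antisense transcripts")
    }
    hosts <- sample(eligible, cfg$n_asrna)
    parts <- sample(c("5prime", "middle", "3prime"), cfg$n_asrna,
                    replace = TRUE)
    for (i in seq_len(cfg$n_asrna)) {
      g <- phage_genes[hosts[i], ]
      len <- g$end - g$start + 1
      ## oriented offsets: the 5' end of a "-" gene is at `end`
      part <- parts[i]
      geom <- if (g$strand == "-") {
        c("5prime" = "right", "middle" = "mid", "3prime" = "left")[[part]]
      } else {
        c("5prime" = "left", "middle" = "mid", "3prime" = "right")[[part]]
      }
      iv <- switch(geom,
        left = c(g$start + 60L, g$start + 179L),
        mid = {
          a <- g$start + as.integer(floor((len - 120) / 2))
          c(a, a + 119L)
        },
        right = c(g$end - 179L, g$end - 60L)
      )
      recs[[length(recs) + 1]] <- tibble(
        contig = "phage", start = iv[1], end = iv[2],
        strand = if (g$strand == "+") "-" else "+",
        relation = paste0("antisense_", part),
        related_genes = g$gene_id
      )
    }
  }
  if (cfg$n_intergenic_rna > 0) {
    for (i in seq_len(cfg$n_intergenic_rna)) {
      gap <- reserved_gaps[i, ]
      iv <- c(gap[1] + 125L, gap[1] + 274L)
      left <- phage_genes$gene_id[max(which(phage_genes$end < iv[1]))]
      right <- phage_genes$gene_id[min(which(phage_genes$start > iv[2]))]
      recs[[length(recs) + 1]] <- tibble(
        contig = "phage", start = iv[1], end = iv[2],
        strand = sample(c("+", "-"), 1),
        relation = "intergenic",
        related_genes = paste(left, right, sep = ",")
      )
    }
  }
  if (length(recs) == 0) {
    ncrnas <- tibble(
      name = character(), contig = character(), start = integer(),
      end = integer(), strand = character(), relation = character(),
      related_genes = character()
    )
  } else {
    ncrnas <- bind_rows(recs) |>
      arrange(start) |>
      mutate(name = sprintf("misc_%d", dplyr::row_number()), .before = 1)
  }
  list(ncrnas = ncrnas)
}

## Gamma-weighted multinomial allocation: negative-binomial marginals with
## exact conservation of the pool total.
draw_pool <- function(total, mu, size) {
  if (total <= 0) {
    return(integer(length(mu)))
  }
  lam <- if (is.finite(size)) {
    ifelse(mu > 0, rgamma(length(mu), shape = size, rate = size / pmax(mu, 1e-12)), 0)
  } else {
    mu
  }
  if (sum(lam) <= 0) abort("degenerate pool: all expected counts are zero")
  as.integer(rmultinom(1, total, lam))
}

make_reads <- function(phage_genes, counts_phage, ncrnas, counts_nc,
                       sample_id, genome_len) {
  out <- vector("list", length(sample_id))
  feat <- bind_rows(
    phage_genes[, c("start", "end", "strand")],
    if (nrow(ncrnas) > 0) ncrnas[, c("start", "end", "strand")]
  )
  lens <- feat$end - feat$start + 1
  rl <- pmin(90L, lens)
  for (j in seq_along(sample_id)) {
    cnt <- c(counts_phage[, j], if (nrow(ncrnas) > 0) counts_nc[, j])
    tot <- sum(cnt)
    if (tot == 0) {
      out[[j]] <- NULL
      next
    }
    idx <- rep.int(seq_len(nrow(feat)), cnt)
    span <- lens[idx] - rl[idx] + 1L
    offs <- floor(runif(tot) * span)
    s <- feat$start[idx] + as.integer(offs)
    out[[j]] <- tibble(
      contig = "phage",
      start = s,
      end = s + rl[idx] - 1L,
      strand = feat$strand[idx],
      sample_id = sample_id[j]
    )
  }
  reads <- bind_rows(out)
  stopifnot(all(reads$end <= genome_len), all(reads$start >= 1))
  reads
}
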