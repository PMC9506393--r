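test_that("gamete formation follows the no-interference meiosis model", {
  set.seed(101)
  # zero-recombination chromosome: gamete is always one unrecombined parent
  g0 <- genome_spec("c1", 1e6, lengths_cm = 0, n_markers = 2)
  lines0 <- simulate_bril(g0, n_lines = 1, n_backcross = 0, n_self = 0)
  for (i in 1:20) {
    gam <- simulate_gamete(lines0[[1]], g0)
    expect_length(gam$c1$origin, 1L)
  }

  # 1 Morgan chromosome: crossover count is Poisson(1); transmission at a
  # heterozygous locus is Mendelian
  g1 <- genome_spec("c1", 1e7, lengths_cm = 100, n_markers = 2)
  f1 <- simulate_bril(g1, n_lines = 1, n_backcross = 0, n_self = 0)[[1]]
  n_gam <- 20000
  xo <- integer(n_gam)
  allele <- integer(n_gam)
  for (i in seq_len(n_gam)) {
    gam <- simulate_gamete(f1, g1)
    xo[i] <- length(gam$c1$origin) - 1L
    allele[i] <- brilqtl:::.hap_at(gam$c1, 5e6)
  }
  expect_lt(abs(mean(xo) - 1), 3 * sqrt(1 / n_gam))
  expect_lt(abs(mean(allele) - 0.5), 3 * sqrt(0.25 / n_gam))
})

test_that("gamete mosaics tile the chromosome exactly", {
  set.seed(102)
  g <- small_genome()
  lines <- simulate_bril(g, n_lines = 20)
  for (ln in lines) {
    for (nm in names(ln$h1)) {
      for (h in list(ln$h1[[nm]], ln$h2[[nm]])) {
        L <- g$chrom$length_bp[g$chrom$name == nm]
        expect_equal(h$ends[length(h$ends)], L)
        expect_true(all(diff(h$ends) > 0))
        if (length(h$origin) > 1) {
          expect_true(all(diff(h$origin) != 0))  # adjacent runs differ
        }
      }
    }
  }
})

test_that("BRIL pedigree expectations hold: donor share and heterozygosity", {
  set.seed(103)
  g <- small_genome()
  lines <- simulate_bril(g, n_lines = 300, n_backcross = 1, n_self = 8)
  comp <- vapply(lines, line_composition, numeric(2))
  expect_lt(abs(mean(comp["donor", ]) - 0.25), 0.05)
  # residual heterozygosity: 0.5 * (1/2)^8 of the genome in expectation
  expected_het <- 0.5 * 0.5^8
  se <- stats::sd(comp["het", ]) / sqrt(ncol(comp))
  expect_lt(abs(mean(comp["het", ]) - expected_het), 3 * se + 1e-4)

  # no backcross, no selfing: the F1 itself, fully heterozygous
  f1 <- simulate_bril(g, n_lines = 1, n_backcross = 0, n_self = 0)[[1]]
  expect_equal(unname(line_composition(f1)["het"]), 1)
})

test_that("GBS observation noise matches its planted rates", {
  set.seed(104)
  g <- small_genome(n_chrom = 2, n_markers = 50)
  lines <- simulate_bril(g, n_lines = 60)
  clean <- observe_gbs(lines, g, 0, 0, 0)
  expect_identical(clean$calls, true_genotypes(lines, g))

  noisy <- observe_gbs(lines, g, missing_rate = 0.3, het_miscall_rate = 0,
                       hom_error_rate = 0)
  n <- length(noisy$calls)
  expect_lt(abs(mean(is.na(noisy$calls)) - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  allhet <- observe_gbs(lines, g, 0, het_miscall_rate = 1, hom_error_rate = 0)
  expect_false(any(allhet$calls == "H", na.rm = TRUE))
})

test_that("liability phenotype model behaves as specified", {
  set.seed(105)
  g <- small_genome(n_chrom = 2, n_markers = 20)
  lines <- simulate_bril(g, n_lines = 200)
  null_q <- data.frame(chrom = "c1", pos = 1e6, effect = 0)
  ph <- simulate_phenotype(lines, null_q, residual_sd = 0, n_seedlings = 30)
  expect_true(all(attr(ph, "truth")$prob == 0.5))
  expect_true(all(ph$survival_rate >= 0 & ph$survival_rate <= 1))

  # strong positive donor effect: donor homozygotes survive better
  q <- data.frame(chrom = "c1", pos = 15e6, effect = 2)
  ph2 <- simulate_phenotype(lines, q, residual_sd = 0.5, n_seedlings = 30)
  dos <- attr(ph2, "truth")$dosage[, 1]
  expect_gt(mean(ph2$survival_rate[dos == 2]),
            mean(ph2$survival_rate[dos == 0]))

  # many seedlings: observed rate converges to the survival probability
  ph3 <- simulate_phenotype(lines[1:30], q, residual_sd = 1,
                            n_seedlings = 1e6)
  expect_true(all(abs(ph3$survival_rate - attr(ph3, "truth")$prob) < 0.01))

  # QTL off the simulated genome is a configuration error
  bad <- data.frame(chrom = "c9", pos = 1e6, effect = 1)
  expect_error(simulate_phenotype(lines, bad), "not covered")
})

test_that("realized heritability grows with planted effect size", {
  g <- small_genome(n_chrom = 2, n_markers = 20)
  r2 <- vapply(c(0.3, 0.8, 1.6), function(eff) {
    set.seed(106)
    lines <- simulate_bril(g, n_lines = 150)
    q <- data.frame(chrom = c("c1", "c2"), pos = c(10e6, 20e6), effect = eff)
    ph <- simulate_phenotype(lines, q, residual_sd = 1)
    summary(lm(ph$survival_rate ~ attr(ph, "truth")$dosage))$r.squared
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("simulated counts follow the planted NB model and truth labels", {
  set.seed(107)
  # near-Poisson limit with flat fold-changes: sample means hit the planted
  # mean scale
  sp <- counts_spec(n_genes = 400, dispersion = 1e-8)
  sp$baseline <- rep(1e5, sp$n_genes)
  sp$lfc[] <- 0
  sp$size_factors <- rep(1, 6)
  sim <- simulate_counts(sp)
  gene_means <- rowMeans(sim$counts)
  expect_true(all(abs(gene_means / 1e5 - 1) < 0.01))
  expect_equal(nrow(sim$truth), 0L)

  # truth bookkeeping: exactly the planted genes, with their directions
  sp2 <- counts_spec(n_genes = 1000, n_up_4 = 0, n_down_4 = 0,
                     n_up_12 = 200, n_down_12 = 0)
  sim2 <- simulate_counts(sp2)
  up12 <- sim2$truth[sim2$truth$contrast == "0_12" &
                       sim2$truth$direction == "up", "gene"]
  expect_length(up12, 200)
  expect_setequal(up12, rownames(sim2$counts)[sp2$lfc[, "12h"] > 0])

  # NB moment check: variance ~ mu + dispersion * mu^2
  sp3 <- counts_spec(n_genes = 10000, dispersion = 0.2)
  sp3$baseline <- rep(100, sp3$n_genes)
  sp3$lfc[] <- 0
  sp3$size_factors <- rep(1, 6)
  sim3 <- simulate_counts(sp3)
  v <- var(as.vector(sim3$counts[, 1]))
  expect_lt(abs(v / (100 + 0.2 * 100^2) - 1), 0.1)
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_study(seed = 5, genome = small_genome(), n_lines = 20)
  b <- simulate_study(seed = 5, genome = small_genome(), n_lines = 20)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$truth$qtls, b$truth$qtls)
})
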