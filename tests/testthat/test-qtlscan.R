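make_scan_df <- function(p, beta = rep(1, length(p)), chrom = "c1") {
  structure(data.frame(
    bin_id = sprintf("bin%05d", seq_along(p)), chrom = chrom,
    start = (seq_along(p) - 1) * 1e6, end = seq_along(p) * 1e6,
    beta = beta, se = 1, p = p),
    class = c("scan_result", "data.frame"))
}

test_that("ridge with lambda 0 reduces to OLS when bins are estimable", {
  set.seed(401)
  n <- 60
  calls <- matrix(sample(c("A", "B"), n * 10, TRUE), 10, n,
                  dimnames = list(NULL, sprintf("L%03d", seq_len(n))))
  bm <- as_bin_map(calls, "c1", seq_len(10) * 1e6)
  ph <- data.frame(line = colnames(calls), survival_rate = runif(n),
                   reps = 30)
  sc <- ridge_scan(bm, ph, lambda = 0)
  X <- scale(t(ifelse(calls == "B", 2, 0)))
  y <- ph$survival_rate - mean(ph$survival_rate)
  ols <- lm.fit(X, y)$coefficients
  expect_equal(unname(sc$beta), unname(ols), tolerance = 1e-10)

  # lambda -> infinity shrinks every coefficient to zero
  sc_inf <- ridge_scan(bm, ph, lambda = 1e8)
  expect_true(all(abs(sc_inf$beta) < 1e-6))

  # lambda = 0 with more bins than lines is singular
  calls_wide <- matrix(sample(c("A", "B"), 30 * 80, TRUE), 80, 30,
                       dimnames = list(NULL, sprintf("L%03d", 1:30)))
  bm_wide <- as_bin_map(calls_wide, "c1", seq_len(80) * 1e5)
  ph_wide <- data.frame(line = colnames(calls_wide),
                        survival_rate = runif(30), reps = 30)
  expect_error(ridge_scan(bm_wide, ph_wide, lambda = 0), "lambda")
})

test_that("scan predictions are invariant to bin order", {
  set.seed(402)
  g <- small_genome(n_chrom = 2, n_markers = 30)
  lines <- simulate_bril(g, n_lines = 50)
  bm <- true_bin_map(lines, g)
  ph <- data.frame(line = colnames(bm$calls),
                   survival_rate = runif(50), reps = 30)
  sc <- ridge_scan(bm, ph, lambda = 10)
  perm <- sample(nrow(bm$calls))
  bm_p <- bm
  bm_p$calls <- bm$calls[perm, ]
  bm_p$bins <- bm$bins[perm, ]
  sc_p <- ridge_scan(bm_p, ph, lambda = 10)
  expect_equal(sc_p$beta, sc$beta[perm], tolerance = 1e-9)
})

test_that("a strong planted QTL attains the genome-wide minimum p", {
  g <- rice_genome(markers_per_chrom = 17)  # ~200 loci genome wide
  seeds <- 1:25
  hits <- vapply(seeds, function(s) {
    set.seed(s)
    lines <- simulate_bril(g, n_lines = 132)
    bm <- true_bin_map(lines, g)
    q <- data.frame(chrom = "chr3", pos = 18e6, effect = 1.2)
    ph <- simulate_phenotype(lines, q, residual_sd = 1)
    sc <- ridge_scan(bm, ph)
    on_c3 <- g$markers$chrom == "chr3"
    planted_bin <- which(on_c3 & abs(g$markers$pos - 18e6) ==
                           min(abs(g$markers$pos[on_c3] - 18e6)))
    which.min(sc$p) == planted_bin
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("QTL calling follows the contiguous-run peak-bin rule", {
  expect_equal(nrow(call_qtls(make_scan_df(rep(0.5, 5)))), 0L)

  sc <- make_scan_df(c(0.3, 0.004, 0.001, 0.3, 0.002),
                     beta = c(1, 1, 1, 1, -1), chrom = "chr3")
  q <- call_qtls(sc)
  expect_equal(nrow(q), 2L)
  expect_equal(q$peak_bin, c("bin00003", "bin00005"))
  expect_equal(q$name, c("qSCT3.1", "qSCT3.2"))
  expect_equal(q$effect, c("donor-increases", "donor-decreases"))
  expect_true(all(q$peak_p < 0.005))
  # interval contains the peak
  expect_true(all(q$interval_start <= sc$start[c(3, 5)] &
                    q$interval_end >= sc$end[c(3, 5)]))
})

test_that("planted QTLs of large effect are recovered near their bins", {
  g <- small_genome(n_chrom = 4, length_bp = 35e6, length_cm = 150,
                    n_markers = 50)
  seeds <- 1:20
  rec <- vapply(seeds, function(s) {
    set.seed(s)
    lines <- simulate_bril(g, n_lines = 132)
    bm <- true_bin_map(lines, g)
    q <- data.frame(chrom = c("c1", "c2", "c4"),
                    pos = c(20e6, 15e6, 12e6), effect = 0.9)
    ph <- simulate_phenotype(lines, q, residual_sd = 1)
    sc <- ridge_scan(bm, ph)
    called <- call_qtls(sc)
    mean(qtl_recovery(called, bm$bins, q, tol_bins = 2))
  }, numeric(1))
  expect_gte(mean(rec), 0.7)
})

test_that("LMG shares match the factorial brute-force oracle", {
  set.seed(403)
  # correlated predictors, k = 4: subset enumeration equals the explicit
  # average over all 24 orderings
  n <- 200
  Z <- matrix(rnorm(n * 4), n, 4)
  X <- Z %*% chol(0.5 + 0.5 * diag(4))
  y <- X %*% c(0.5, -0.3, 0.2, 0) + rnorm(n)
  lmg <- decompose_pve(X, y)
  expect_equal(as.numeric(lmg), lmg_bruteforce(X, y), tolerance = 1e-10)
  expect_equal(sum(lmg), 100 * attr(lmg, "r2_full"), tolerance = 1e-12)

  # orthogonal (centered) predictors: shares equal marginal R-squared
  Xo <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  yo <- Xo %*% c(1, 2, 3) + rnorm(n, sd = 0.5)
  lmg_o <- decompose_pve(Xo, yo)
  marg <- vapply(1:3, function(j) {
    summary(lm(yo ~ Xo[, j]))$r.squared
  }, numeric(1))
  expect_equal(as.numeric(lmg_o) / 100, marg, tolerance = 1e-6)

  # single predictor: LMG is the simple-regression R-squared
  lmg_1 <- decompose_pve(Xo[, 1, drop = FALSE], yo)
  expect_equal(as.numeric(lmg_1) / 100,
               summary(lm(yo ~ Xo[, 1]))$r.squared, tolerance = 1e-12)

  expect_error(decompose_pve(matrix(rnorm(32), 2), rnorm(2)), "15")
})

test_that("detection power is monotone in planted effect size", {
  g <- small_genome(n_chrom = 4, n_markers = 40)
  power <- vapply(c(0.3, 0.7, 1.4), function(eff) {
    hits <- vapply(1:12, function(s) {
      set.seed(1000 + s)
      lines <- simulate_bril(g, n_lines = 100)
      bm <- true_bin_map(lines, g)
      q <- data.frame(chrom = "c2", pos = 15e6, effect = eff)
      ph <- simulate_phenotype(lines, q, residual_sd = 1)
      sc <- ridge_scan(bm, ph)
      any(sc$p[sc$chrom == "c2"] < 0.005)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], power[1])
})

test_that("scan report carries -log10 p and threshold flags", {
  sc <- make_scan_df(c(0.5, 0.001))
  rep_df <- scan_report(sc)
  expect_equal(rep_df$neglog10p, -log10(c(0.5, 0.001)))
  expect_equal(rep_df$significant, c(FALSE, TRUE))
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot_scan(sc))
  grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
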