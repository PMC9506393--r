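test_that("sliding-window smoothing absorbs isolated miscalls", {
  calls <- rep("A", 40)
  calls[20] <- "B"
  sm <- smooth_line(calls, window = 15, majority = 0.7)
  expect_true(all(sm == "A"))

  # window = 1 disables smoothing entirely
  expect_identical(smooth_line(calls, window = 1, majority = 0.5), calls)

  # all-missing input stays all missing
  expect_true(all(is.na(smooth_line(rep(NA_character_, 30)))))

  # clean A-block then B-block: exactly two runs, transition within a
  # half-window of the true boundary (compare to the naive run-length
  # oracle on the error-free input)
  calls2 <- c(rep("A", 50), rep("B", 50))
  pos <- seq_len(100) * 1000
  sm2 <- smooth_line(calls2, window = 15, majority = 0.7)
  # ambiguous windows straddling the transition go missing; the informative
  # runs are exactly A then B
  runs <- rle(sm2[!is.na(sm2)])
  expect_equal(runs$values, c("A", "B"))
  bp <- detect_breakpoints(sm2, pos)
  truth <- naive_breakpoints(calls2, pos)
  expect_length(bp, 1L)
  expect_lte(abs(bp - truth), 7 * 1000)
})

test_that("block masking is a conjunction of span and support conditions", {
  pos_a <- c(seq(0, 100e3, length.out = 3), seq(200e3, 1e6, length.out = 20))
  calls_a <- c(rep("B", 3), rep("A", 20))
  masked <- mask_small_blocks(calls_a, pos_a)
  expect_true(all(is.na(masked[1:3])))        # 100 kb span, 3 SNPs: masked
  expect_true(all(masked[4:23] == "A"))

  pos_b <- c(seq(0, 100e3, length.out = 8), seq(200e3, 1e6, length.out = 20))
  calls_b <- c(rep("B", 8), rep("A", 20))
  expect_true(all(mask_small_blocks(calls_b, pos_b)[1:8] == "B"))  # 8 SNPs

  pos_c <- c(0, 300e3, seq(400e3, 1e6, length.out = 20))
  calls_c <- c("B", "B", rep("A", 20))
  expect_true(all(mask_small_blocks(calls_c, pos_c)[1:2] == "B"))  # 300 kb
})

test_that("breakpoints sit at midpoints between informative markers", {
  expect_length(detect_breakpoints(rep("A", 20), seq_len(20) * 1e5), 0L)
  calls <- c(rep("A", 3), rep("B", 2))
  pos <- c(8e5, 9e5, 1.0e6, 1.1e6, 1.2e6)
  expect_equal(detect_breakpoints(calls, pos), 1050000)
  # missing markers between runs are skipped when placing the midpoint
  calls2 <- c("A", "A", NA, NA, "B")
  expect_equal(detect_breakpoints(calls2, pos), (9e5 + 1.2e6) / 2)
})

test_that("bins are the union of breakpoints and chromosome ends", {
  expect_equal(nrow(build_bins(list(c1 = numeric(0), c2 = numeric(0)),
                               c(c1 = 3e7, c2 = 2e7))), 2L)
  bins <- build_bins(list(c1 = c(10e6, 20e6)), c(c1 = 30e6))
  expect_equal(bins$start, c(0, 10e6, 20e6))
  expect_equal(bins$end, c(10e6, 20e6, 30e6))

  # counting identity on a simulated population
  set.seed(201)
  g <- small_genome(n_chrom = 2, n_markers = 80)
  lines <- simulate_bril(g, n_lines = 50)
  sm <- observe_gbs(lines, g, 0, 0, 0)
  cl <- setNames(g$chrom$length_bp, g$chrom$name)
  bm <- suppressMessages(build_bin_map(sm, cl, window = 1, majority = 0.5))
  n_unique_bp <- sum(vapply(unique(g$markers$chrom), function(nm) {
    length(unique(unlist(lapply(bm$breakpoints, `[[`, nm))))
  }, numeric(1)))
  expect_equal(nrow(bm$bins), n_unique_bp + nrow(g$chrom))
  # bins tile each chromosome exactly
  widths <- tapply(bm$bins$end - bm$bins$start,
                   factor(bm$bins$chrom, g$chrom$name), sum)
  expect_equal(as.numeric(widths), g$chrom$length_bp)
})

test_that("bin genotyping carries track calls and flags masked regions", {
  markers <- data.frame(chrom = "c1", pos = seq_len(10) * 1e5)
  bins <- build_bins(list(c1 = numeric(0)), c(c1 = 1.1e6))
  tracks <- list(L1 = list(c1 = rep("B", 10)))
  gb <- genotype_bins(tracks, bins, markers)
  expect_equal(unname(gb[, "L1"]), "B")

  bins2 <- build_bins(list(c1 = c(3.5e5, 6.5e5)), c(c1 = 1.1e6))
  tracks2 <- list(L1 = list(c1 = c("A", "A", "A", NA, NA, NA, "B", "B",
                                   "B", "B")))
  gb2 <- genotype_bins(tracks2, bins2, markers)
  expect_equal(unname(gb2[, "L1"]), c("A", NA, "B"))
})

test_that("nearest-flank imputation fills every cell with stated tie rule", {
  bins <- build_bins(list(c1 = c(10, 20, 30) * 1e6), c(c1 = 40e6))
  calls <- matrix(c("A", NA, "A", "B"), 4, 1,
                  dimnames = list(bins$bin_id, "L1"))
  imp <- impute_bins(calls, bins)
  expect_equal(unname(imp[2, 1]), "A")

  # equidistant between A (left) and B (right): tie goes left
  bins2 <- build_bins(list(c1 = c(10, 20) * 1e6), c(c1 = 30e6))
  calls2 <- matrix(c("A", NA, "B"), 3, 1,
                   dimnames = list(bins2$bin_id, "L1"))
  expect_equal(unname(impute_bins(calls2, bins2)[2, 1]), "A")

  # mask-and-recover on simulated data: >= 95% of masked cells restored
  set.seed(202)
  g <- small_genome(n_chrom = 2, n_markers = 80)
  lines <- simulate_bril(g, n_lines = 40)
  sm <- observe_gbs(lines, g, 0, 0, 0)
  cl <- setNames(g$chrom$length_bp, g$chrom$name)
  bm <- suppressMessages(build_bin_map(sm, cl, window = 1, majority = 0.5))
  full <- bm$calls
  holes <- which(runif(length(full)) < 0.1)
  damaged <- full
  damaged[holes] <- NA
  restored <- impute_bins(damaged, bm$bins)
  expect_false(anyNA(restored))
  expect_gte(mean(restored[holes] == full[holes]), 0.95)
  # untouched cells unchanged
  expect_identical(restored[-holes], full[-holes])
})

test_that("bin summary is plain arithmetic on widths", {
  bins <- data.frame(bin_id = c("b1", "b2", "b3"), chrom = "c1",
                     start = c(0, 100e3, 300e3), end = c(100e3, 300e3, 600e3))
  s <- bin_summary(bins)
  expect_equal(s$count, 3)
  expect_equal(s$mean_bp, 200e3)
  expect_equal(s$min_bp, 100e3)
  expect_equal(s$max_bp, 300e3)
  one <- bin_summary(bins[1, ])
  expect_equal(one$mean_bp, one$min_bp)
  expect_equal(one$mean_bp, one$max_bp)
})

test_that("bin map construction is equivariant under line relabeling", {
  set.seed(203)
  g <- small_genome(n_chrom = 2, n_markers = 60)
  lines <- simulate_bril(g, n_lines = 25)
  sm <- observe_gbs(lines, g, 0.1, 0.3, 0.01)
  cl <- setNames(g$chrom$length_bp, g$chrom$name)
  bm <- suppressMessages(build_bin_map(sm, cl))
  perm <- sample(ncol(sm$calls))
  sm_p <- snp_matrix(sm$markers, sm$calls[, perm], sm$lines[perm])
  bm_p <- suppressMessages(build_bin_map(sm_p, cl))
  expect_identical(bm_p$bins, bm$bins)
  expect_identical(bm_p$calls, bm$calls[, perm])
})

test_that("masking is a pure filter on clean data", {
  set.seed(204)
  g <- small_genome(n_chrom = 1, n_markers = 80)
  lines <- simulate_bril(g, n_lines = 15)
  sm <- observe_gbs(lines, g, 0, 0, 0)
  cl <- setNames(g$chrom$length_bp, g$chrom$name)
  bm_off <- suppressMessages(build_bin_map(sm, cl, window = 1,
                                           majority = 0.5, min_block_bp = 0,
                                           min_block_snps = 0))
  bm_def <- suppressMessages(build_bin_map(sm, cl, window = 1,
                                           majority = 0.5))
  truth <- true_genotypes(lines, g)
  for (ln in sm$lines) {
    # with masking disabled, every clean breakpoint is present
    expect_identical(bm_off$breakpoints[[ln]]$c1,
                     naive_breakpoints(truth[, ln], g$markers$pos))
    # masking can only merge runs, never create extra breakpoints
    expect_lte(length(bm_def$breakpoints[[ln]]$c1),
               length(bm_off$breakpoints[[ln]]$c1))
  }
})
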