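# Shared fixtures and independent oracles for the test suite.

# minimal multi-chromosome genome for fast simulations
small_genome <- function(n_chrom = 3, length_bp = 30e6, length_cm = 150,
                         n_markers = 60) {
  genome_spec(paste0("c", seq_len(n_chrom)), rep(length_bp, n_chrom),
              lengths_cm = rep(length_cm, n_chrom), n_markers = n_markers)
}

# wrap a plain calls matrix (loci x lines) as the bin_map surface consumed
# by the scan: one bin per locus
as_bin_map <- function(calls, chrom, pos) {
  bins <- data.frame(bin_id = sprintf("bin%05d", seq_len(nrow(calls))),
                     chrom = chrom, start = pos - 1, end = pos)
  rownames(calls) <- bins$bin_id
  structure(list(bins = bins, calls = calls, raw_calls = calls,
                 breakpoints = list(),
                 summary = bin_summary(bins)), class = "bin_map")
}

# true genotypes of a simulated population wrapped as marker-level "bins"
true_bin_map <- function(lines, genome) {
  as_bin_map(true_genotypes(lines, genome), genome$markers$chrom,
             genome$markers$pos)
}

# naive run-length breakpoint oracle on clean calls: midpoints between
# consecutive markers whose calls differ
naive_breakpoints <- function(calls, pos) {
  ch <- which(calls[-1] != calls[-length(calls)])
  (pos[ch] + pos[ch + 1]) / 2
}

# brute-force LMG: explicit average over all k! orderings of sequential
# R-squared increments
lmg_bruteforce <- function(X, y) {
  k <- ncol(X)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    f <- lm.fit(scale(X[, cols, drop = FALSE], scale = FALSE), yc)
    1 - sum(f$residuals^2) / syy
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  shares <- numeric(k)
  all_p <- perms(seq_len(k))
  for (ord in all_p) {
    prev <- 0
    for (i in seq_along(ord)) {
      cur <- r2_of(ord[seq_len(i)])
      shares[ord[i]] <- shares[ord[i]] + (cur - prev)
      prev <- cur
    }
  }
  100 * shares / length(all_p)
}

# exhaustive hypergeometric upper tail P(X >= k)
hyper_uppertail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# random snp_matrix fixture with planted missingness
random_snp_matrix <- function(n_markers = 200, n_lines = 50, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(c("A", "B", "H", NA), n_markers * n_lines,
                         replace = TRUE, prob = c(0.55, 0.2, 0.05, 0.2)),
                  n_markers, n_lines,
                  dimnames = list(NULL, sprintf("L%03d", seq_len(n_lines))))
  snp_matrix(data.frame(chrom = "c1", pos = seq_len(n_markers) * 1000), calls)
}
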