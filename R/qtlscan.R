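# Ridge-regression genome scan on bin genotypes, QTL declaration by the
# peak-bin rule, and LMG relative-importance decomposition of the
# phenotypic variance explained.

.dosage_matrix <- function(bm, lines = colnames(bm$calls)) {
  code <- c(A = 0, H = 1, B = 2)
  calls <- bm$calls[, lines, drop = FALSE]
  X <- matrix(code[calls], nrow = nrow(calls), dimnames = dimnames(calls))
  t(X)
}

#' Ridge-regression genome scan
#'
#' Fits all bins jointly by linear ridge regression on donor-allele dosage
#' (A = 0, H = 1, B = 2; columns standardized, phenotype centered), which
#' tempers the multicollinearity of adjacent bins. Coefficients are
#' `(X'X + lambda I)^-1 X'y` computed via the SVD; the shrinkage parameter
#' is chosen by generalized cross-validation (GCV) unless supplied.
#' Per-bin standard errors come from the ridge sandwich covariance with the
#' residual variance estimated on the effective residual degrees of freedom
#' `n - tr(H)`, and two-sided p-values from the t distribution on those df.
#'
#' @param bm a `bin_map` ([build_bin_map()]) with an imputed call matrix.
#' @param ph phenotype data frame (`line`, `survival_rate`); every
#'   phenotyped line must be present in the bin matrix.
#' @param lambda fixed ridge penalty; `NULL` (default) selects it by GCV
#'   over a log-spaced grid.
#' @param transform `"none"` scans the raw survival proportion;
#'   `"arcsine"` applies the angular transform `asin(sqrt(p))`.
#' @return Object of class `scan_result`: data frame (`bin_id`, `chrom`,
#'   `start`, `end`, `beta`, `se`, `p`) with attributes `lambda`, `edf`
#'   (effective model df, tr(H)), `sigma2` and `n`.
#' @export
ridge_scan <- function(bm, ph, lambda = NULL,
                       transform = c("none", "arcsine")) {
  transform <- match.arg(transform)
  stopifnot(all(ph$line %in% colnames(bm$calls)))
  n <- nrow(ph)
  if (n < 30) stop("at least 30 phenotyped lines are required")
  y <- ph$survival_rate
  stopifnot(all(y >= 0 & y <= 1))
  if (transform == "arcsine") y <- asin(sqrt(y))
  y <- y - mean(y)
  X <- .dosage_matrix(bm, ph$line)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  Xs <- scale(X[, keep, drop = FALSE])
  p_eff <- ncol(Xs)
  if (!is.null(lambda) && lambda == 0 && p_eff >= n) {
    stop("lambda = 0 requires fewer bins than lines; use lambda > 0")
  }
  sv <- svd(Xs)
  d <- sv$d
  uty <- crossprod(sv$u, y)
  if (is.null(lambda)) {
    # GCV is minimized over penalties keeping tr(H) <= n/2: when bins
    # outnumber lines the unconstrained criterion degenerates to the
    # interpolating fit (tr(H) -> n, RSS -> 0), which carries no
    # information; the constraint keeps the search in the regime where
    # the residual variance is estimable.
    grid <- 10^seq(-2, 8, length.out = 120)
    stats_l <- vapply(grid, function(l) {
      shrink <- d^2 / (d^2 + l)
      fit <- sv$u %*% (shrink * uty)
      rss <- sum((y - fit)^2)
      c(gcv = n * rss / (n - sum(shrink))^2, edf = sum(shrink))
    }, numeric(2))
    ok <- stats_l["edf", ] <= n / 2
    if (!any(ok)) ok <- rep(TRUE, length(grid))
    lambda <- grid[ok][which.min(stats_l["gcv", ok])]
  }
  shrink <- d^2 / (d^2 + lambda)
  beta_s <- sv$v %*% ((d / (d^2 + lambda)) * uty)
  fit <- sv$u %*% (shrink * uty)
  rss <- sum((y - fit)^2)
  edf <- sum(shrink)
  df_res <- n - edf
  if (df_res <= 0) stop("non-positive residual degrees of freedom")
  sigma2 <- rss / df_res
  var_b <- sigma2 * rowSums(sweep(sv$v^2, 2, (d / (d^2 + lambda))^2, `*`))
  se <- sqrt(var_b)
  tval <- beta_s / se
  pval <- 2 * stats::pt(-abs(tval), df = df_res)
  out <- bm$bins
  out$beta <- out$se <- rep(NA_real_, nrow(out))
  out$p <- rep(1, nrow(out))
  out$beta[keep] <- beta_s
  out$se[keep] <- se
  out$p[keep] <- pval
  out$beta[!keep] <- 0
  structure(out, class = c("scan_result", "data.frame"), lambda = lambda,
            edf = edf, sigma2 = sigma2, n = n,
            r2 = 1 - rss / sum(y^2))
}

#' @method print scan_result
#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d bins, lambda = %.3g, edf = %.1f, min p = %.3g\n",
              nrow(x), attr(x, "lambda"), attr(x, "edf"), min(x$p)))
  invisible(x)
}

#' Call QTLs from a genome scan by the peak-bin rule
#'
#' Each maximal run of contiguous bins with p below the threshold on one
#' chromosome yields one QTL, tentatively located at the bin with the
#' lowest p-value (the peak bin). The effect direction is the sign of the
#' peak bin's coefficient on donor dosage (positive: donor alleles increase
#' the trait). QTLs are named `q<trait><chromosome number>` with `.1`,
#' `.2`, ... suffixes when one chromosome carries several. When `bm` and
#' `ph` are supplied and at most `max_pve_qtls` QTLs are called, the
#' phenotypic variance explained is apportioned among the peak bins by the
#' LMG decomposition ([decompose_pve()]).
#'
#' @param scan a `scan_result` ([ridge_scan()]).
#' @param bm,ph bin map and phenotype table used for the scan (optional;
#'   needed for the PVE column).
#' @param threshold genome-wide per-bin significance threshold
#'   (default 0.005).
#' @param trait trait tag used in QTL names (default `"SCT"`).
#' @param max_pve_qtls largest QTL count for which exact LMG enumeration is
#'   attempted (default 15).
#' @return Object of class `qtl_table`: data frame with `name`, `chrom`,
#'   `peak_bin`, `interval_start`, `interval_end`, `n_bins`, `peak_p`,
#'   `effect` (`donor-increases`/`donor-decreases`), `pve_pct`; attributes
#'   `total_pve_pct` and `r2_full` when PVE was computed.
#' @export
call_qtls <- function(scan, bm = NULL, ph = NULL, threshold = 0.005,
                      trait = "SCT", max_pve_qtls = 15) {
  sig <- scan$p < threshold
  rows <- list()
  for (nm in unique(scan$chrom)) {
    idx <- which(scan$chrom == nm)
    s <- sig[idx]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    chrom_num <- sub("^[^0-9]*", "", nm)
    for (j in seq_along(runs)) {
      ii <- idx[starts[runs[j]]:ends[runs[j]]]
      peak <- ii[which.min(scan$p[ii])]
      nm_q <- paste0("q", trait, chrom_num)
      if (length(runs) > 1) nm_q <- paste0(nm_q, ".", j)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm_q, chrom = nm, peak_bin = scan$bin_id[peak],
        interval_start = min(scan$start[ii]),
        interval_end = max(scan$end[ii]), n_bins = length(ii),
        peak_p = scan$p[peak],
        effect = if (scan$beta[peak] >= 0) "donor-increases" else
          "donor-decreases")
    }
  }
  if (!length(rows)) {
    out <- data.frame(name = character(0), chrom = character(0),
                      peak_bin = character(0), interval_start = numeric(0),
                      interval_end = numeric(0), n_bins = integer(0),
                      peak_p = numeric(0), effect = character(0),
                      pve_pct = numeric(0))
    return(structure(out, class = c("qtl_table", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out$pve_pct <- NA_real_
  if (!is.null(bm) && !is.null(ph)) {
    if (nrow(out) > max_pve_qtls) {
      warning("more than ", max_pve_qtls,
              " QTLs; skipping exact LMG decomposition")
    } else {
      X <- .dosage_matrix(bm, ph$line)[, out$peak_bin, drop = FALSE]
      pve <- decompose_pve(X, ph$survival_rate)
      out$pve_pct <- as.numeric(pve)
      attr(out, "total_pve_pct") <- sum(pve)
      attr(out, "r2_full") <- attr(pve, "r2_full")
    }
  }
  structure(out, class = c("qtl_table", "data.frame"),
            total_pve_pct = attr(out, "total_pve_pct"),
            r2_full = attr(out, "r2_full"))
}

#' LMG decomposition of the phenotypic variance explained
#'
#' Apportions the R-squared of the joint OLS model on the peak-bin dosages
#' among the QTLs by the LMG relative-importance statistic: the average,
#' over all predictor orderings, of the sequential R-squared increment when
#' a predictor enters. Computed by exact enumeration over all 2^k predictor
#' subsets with factorial weights (equivalent to, and far cheaper than,
#' averaging over all k! orderings). Shares sum to the full-model
#' R-squared.
#'
#' @param X numeric predictor matrix (lines x QTL peak bins).
#' @param y phenotype vector.
#' @return Named numeric vector of per-QTL PVE in percent, with attribute
#'   `r2_full` (full-model R-squared).
#' @export
decompose_pve <- function(X, y) {
  X <- as.matrix(X)
  k <- ncol(X)
  stopifnot(k >= 1, nrow(X) == length(y))
  if (k > 15) {
    stop("exact LMG enumeration supports at most 15 predictors; ",
         "reduce the QTL set (ordering-sampling mode is not implemented)")
  }
  yc <- y - mean(y)
  Xc <- scale(X, scale = FALSE)
  syy <- sum(yc^2)
  n_sub <- bitwShiftL(1L, k)
  r2 <- numeric(n_sub)
  members <- lapply(seq_len(n_sub) - 1L, function(s) {
    which(bitwAnd(s, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
  })
  for (s in 2:n_sub) {
    cols <- members[[s]]
    f <- stats::lm.fit(Xc[, cols, drop = FALSE], yc)
    r2[s] <- 1 - sum(f$residuals^2) / syy
  }
  lfac <- lgamma(seq_len(k + 1))  # lfac[i+1] = log(i!)
  w_size <- exp(lfac[seq_len(k)] - lfac[k + 1] +
                  lfac[k - seq_len(k) + 1])  # weight for |S| = i-1
  lmg <- numeric(k)
  for (j in seq_len(k)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    for (s in seq_len(n_sub) - 1L) {
      if (bitwAnd(s, bit_j) != 0L) next
      sz <- length(members[[s + 1L]])
      lmg[j] <- lmg[j] +
        w_size[sz + 1L] * (r2[bitwOr(s, bit_j) + 1L] - r2[s + 1L])
    }
  }
  out <- 100 * lmg
  names(out) <- colnames(X)
  attr(out, "r2_full") <- r2[n_sub]
  out
}

#' Manhattan-style scan report
#'
#' @param scan a `scan_result`.
#' @param threshold significance threshold drawn/flagged (default 0.005).
#' @return Data frame (`bin_id`, `chrom`, `mid_bp`, `neglog10p`,
#'   `significant`).
#' @export
scan_report <- function(scan, threshold = 0.005) {
  data.frame(bin_id = scan$bin_id, chrom = scan$chrom,
             mid_bp = (scan$start + scan$end) / 2,
             neglog10p = -log10(scan$p), significant = scan$p < threshold)
}

#' Manhattan plot of a genome scan
#'
#' Plots -log10(p) per bin against cumulative genome position with
#' alternating chromosome colors and the declaration threshold as a dashed
#' line.
#'
#' @param scan a `scan_result`.
#' @param threshold significance threshold (default 0.005).
#' @param ... passed to [graphics::plot()].
#' @export
plot_scan <- function(scan, threshold = 0.005, ...) {
  chroms <- unique(scan$chrom)
  offs <- c(0, cumsum(tapply(scan$end, factor(scan$chrom, chroms), max)))
  xpos <- (scan$start + scan$end) / 2 +
    offs[match(scan$chrom, chroms)]
  col <- c("grey30", "steelblue")[1 + match(scan$chrom, chroms) %% 2]
  graphics::plot(xpos, -log10(scan$p), pch = 20, col = col,
                 xlab = "genome position (bp)",
                 ylab = expression(-log[10](italic(p))), ...)
  graphics::abline(h = -log10(threshold), lty = 2, col = "red")
  invisible(NULL)
}

#' Write a scan result as TSV
#'
#' @param scan a `scan_result`.
#' @param path output file.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a QTL table as TSV
#'
#' @param qtls a `qtl_table` ([call_qtls()]).
#' @param path output file.
#' @export
write_qtl_tsv <- function(qtls, path) {
  utils::write.table(as.data.frame(qtls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score QTL recovery against planted truth
#'
#' A planted QTL counts as recovered when a called QTL on the same
#' chromosome has its peak bin within `tol_bins` bins of the bin containing
#' the planted position.
#'
#' @param qtls a `qtl_table` ([call_qtls()]).
#' @param bins bin data frame the scan ran on.
#' @param truth data frame of planted QTLs (`chrom`, `pos`).
#' @param tol_bins tolerance in bins (default 2).
#' @return Logical vector, one element per planted QTL.
#' @export
qtl_recovery <- function(qtls, bins, truth, tol_bins = 2) {
  bin_index <- function(chrom, pos) {
    idx <- which(bins$chrom == chrom)
    idx[findInterval(pos, bins$start[idx])]
  }
  peak_idx <- match(qtls$peak_bin, bins$bin_id)
  vapply(seq_len(nrow(truth)), function(j) {
    tb <- bin_index(truth$chrom[j], truth$pos[j])
    any(qtls$chrom == truth$chrom[j] & abs(peak_idx - tb) <= tol_bins)
  }, logical(1))
}
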