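# Recombination bin-map construction: per-line sliding-window genotype
# smoothing, masking of weakly supported blocks (false double-recombination
# guard), breakpoint detection at inter-marker midpoints, population-wide
# bin building, bin genotyping and nearest-flank imputation.
#
# Coordinates: marker positions are 1-based bp; bins are half-open
# [start, end) intervals with the first bin starting at 0 and the last bin
# ending at the chromosome length, so bin widths sum exactly to the
# chromosome length.

.CALL_LEVELS <- c("A", "H", "B")

#' Sliding-window smoothing of one line's calls on one chromosome
#'
#' Each marker is assigned the majority non-missing call of its centered
#' window of `window` markers (truncated at chromosome ends) provided that
#' call's share of the non-missing window calls is at least `majority`;
#' otherwise the marker is set missing. `window = 1` with `majority <= 1`
#' disables smoothing (every call kept as observed). On a chromosome with
#' fewer markers than the window the whole-chromosome majority is used.
#'
#' @param calls character vector of calls (`A/H/B/NA`) in marker order.
#' @param window odd window size in markers (default 15).
#' @param majority minimum share of non-missing window calls (default 0.7).
#' @return Character vector of smoothed calls (with NA where no call wins).
#' @export
smooth_line <- function(calls, window = 15, majority = 0.7) {
  stopifnot(window >= 1, window %% 2 == 1, majority > 0, majority <= 1)
  n <- length(calls)
  if (n == 0L) return(calls)
  if (n < window) {
    message("chromosome has fewer markers (", n, ") than the window (",
            window, "); using whole-chromosome majority")
    tab <- table(factor(calls, .CALL_LEVELS))
    if (sum(tab) == 0) return(rep(NA_character_, n))
    win <- names(tab)[which.max(tab)]
    keep <- max(tab) / sum(tab) >= majority
    return(rep(if (keep) win else NA_character_, n))
  }
  h <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  cnt <- vapply(.CALL_LEVELS, function(lv) {
    cs <- cumsum(c(0L, !is.na(calls) & calls == lv))
    cs[hi + 1L] - cs[lo]
  }, numeric(n))
  nonmiss <- rowSums(cnt)
  best <- max.col(cnt, ties.method = "first")
  share <- cnt[cbind(seq_len(n), best)] / pmax(nonmiss, 1L)
  out <- .CALL_LEVELS[best]
  out[nonmiss == 0L | share < majority] <- NA
  out
}

#' Mask weakly supported genotype blocks
#'
#' A run of identical non-missing calls is masked (set missing) when its
#' physical span is below `min_len_bp` AND its supporting SNP count is below
#' `min_snps` (conjunction: a short but well-sequenced block, or a long but
#' sparse one, is kept). Support is the number of sequenced (non-missing)
#' raw calls inside the run when `raw_calls` is given, else the number of
#' markers in the run.
#'
#' @param calls smoothed calls for one line/chromosome ([smooth_line()]).
#' @param pos marker positions in bp.
#' @param min_len_bp physical span threshold (default 250 kb).
#' @param min_snps supporting SNP count threshold (default 5).
#' @param raw_calls optional unsmoothed calls used to count sequenced SNPs.
#' @return Calls with weakly supported runs set to NA.
#' @export
mask_small_blocks <- function(calls, pos, min_len_bp = 250000, min_snps = 5,
                              raw_calls = NULL) {
  stopifnot(length(calls) == length(pos))
  if (length(calls) == 0L) return(calls)
  r <- rle(ifelse(is.na(calls), ".", calls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == ".") next
    idx <- starts[k]:ends[k]
    span <- pos[ends[k]] - pos[starts[k]]
    supp <- if (is.null(raw_calls)) length(idx) else sum(!is.na(raw_calls[idx]))
    if (span < min_len_bp && supp < min_snps) calls[idx] <- NA
  }
  calls
}

#' Detect recombination breakpoints of one line on one chromosome
#'
#' One breakpoint is placed at each transition between distinct non-missing
#' calls (A-H and H-B transitions count, as residual heterozygosity is a
#' real third state in a BC1-derived RIL), at the midpoint between the two
#' flanking informative markers.
#'
#' @param calls masked, smoothed calls ([mask_small_blocks()]).
#' @param pos marker positions in bp.
#' @return Numeric vector of breakpoint positions in bp (possibly empty).
#' @export
detect_breakpoints <- function(calls, pos) {
  inf <- which(!is.na(calls))
  if (length(inf) < 2L) return(numeric(0))
  v <- calls[inf]
  tr <- which(v[-1] != v[-length(v)])
  (pos[inf[tr]] + pos[inf[tr + 1L]]) / 2
}

#' Build recombination bins from pooled breakpoints
#'
#' Bin boundaries are the sorted unique breakpoints of all lines plus the
#' chromosome ends; the resulting half-open [start, end) bins tile each
#' chromosome exactly, and every line's smoothed genotype is constant within
#' every bin by construction.
#'
#' @param breakpoints named list (chromosome -> numeric vector of pooled
#'   breakpoint positions in bp).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @return Data frame with `bin_id`, `chrom`, `start`, `end`.
#' @export
build_bins <- function(breakpoints, chrom_lengths) {
  stopifnot(all(names(breakpoints) %in% names(chrom_lengths)))
  rows <- lapply(names(chrom_lengths), function(nm) {
    bp <- sort(unique(breakpoints[[nm]]))
    L <- chrom_lengths[[nm]]
    if (length(bp) && (min(bp) <= 0 || max(bp) >= L)) {
      stop("breakpoint outside chromosome bounds on ", nm)
    }
    edges <- c(0, bp, L)
    data.frame(chrom = nm, start = edges[-length(edges)], end = edges[-1])
  })
  out <- do.call(rbind, rows)
  out <- data.frame(bin_id = sprintf("bin%05d", seq_len(nrow(out))), out)
  stopifnot(all(out$end > out$start))
  out
}

#' Genotype bins from smoothed tracks
#'
#' The call of a (bin, line) cell is the track call covering that bin; bins
#' containing no marker, or overlapping a masked region of the line's track,
#' are missing. Conflicting calls within one bin indicate the bins were not
#' built from these tracks and raise an error.
#'
#' @param tracks list per line of lists per chromosome of masked smoothed
#'   calls (parallel to the marker table).
#' @param bins data frame from [build_bins()].
#' @param markers marker data frame (`chrom`, `pos`).
#' @return Character matrix (bins x lines), possibly with NA.
#' @export
genotype_bins <- function(tracks, bins, markers) {
  lines <- names(tracks)
  out <- matrix(NA_character_, nrow(bins), length(lines),
                dimnames = list(bins$bin_id, lines))
  for (nm in unique(bins$chrom)) {
    b_idx <- which(bins$chrom == nm)
    m_idx <- which(markers$chrom == nm)
    if (!length(m_idx)) next
    marker_bin <- findInterval(markers$pos[m_idx], bins$start[b_idx])
    by_bin <- split(seq_along(m_idx),
                    factor(marker_bin, levels = seq_along(b_idx)))
    for (ln in lines) {
      calls <- tracks[[ln]][[nm]]
      out[b_idx, ln] <- vapply(by_bin, function(ii) {
        if (!length(ii)) return(NA_character_)
        u <- unique(calls[ii])
        if (anyNA(u)) return(NA_character_)
        if (length(u) > 1L) {
          stop("internal consistency error: conflicting calls in one bin")
        }
        u
      }, character(1))
    }
  }
  out
}

#' Impute missing bin calls from the nearest flanking bin
#'
#' Every missing cell is filled with the call of the nearest non-missing
#' flanking bin on the same chromosome, distance measured between bin
#' midpoints, ties going to the left flank. A line with a fully missing
#' chromosome is filled with the per-bin population majority call (logged
#' as a warning).
#'
#' @param calls bins x lines character matrix ([genotype_bins()]).
#' @param bins data frame from [build_bins()].
#' @return Matrix of the same shape with no missing cells; non-missing
#'   cells unchanged.
#' @export
impute_bins <- function(calls, bins) {
  mid <- (bins$start + bins$end) / 2
  for (nm in unique(bins$chrom)) {
    b_idx <- which(bins$chrom == nm)
    m <- mid[b_idx]
    for (ln in colnames(calls)) {
      x <- calls[b_idx, ln]
      miss <- which(is.na(x))
      if (!length(miss)) next
      ok <- which(!is.na(x))
      if (!length(ok)) {
        warning("line ", ln, " fully missing on ", nm,
                "; using population-majority calls")
        maj <- apply(calls[b_idx, , drop = FALSE], 1, function(row) {
          tab <- table(factor(row, .CALL_LEVELS))
          if (sum(tab) == 0) "A" else names(tab)[which.max(tab)]
        })
        calls[b_idx, ln] <- maj
        next
      }
      j <- findInterval(m[miss], m[ok])
      left <- ifelse(j >= 1L, ok[pmax(j, 1L)], NA)
      right <- ifelse(j < length(ok), ok[pmin(j + 1L, length(ok))], NA)
      dl <- ifelse(is.na(left), Inf, m[miss] - m[left])
      dr <- ifelse(is.na(right), Inf, m[right] - m[miss])
      pick <- ifelse(dl <= dr, left, right)
      calls[b_idx[miss], ln] <- x[pick]
    }
  }
  calls
}

#' Bin size summary
#'
#' @param bins data frame from [build_bins()].
#' @return List with `count`, `mean_bp`, `min_bp`, `max_bp`.
#' @export
bin_summary <- function(bins) {
  w <- bins$end - bins$start
  list(count = nrow(bins), mean_bp = mean(w), min_bp = min(w), max_bp = max(w))
}

#' Build a recombination bin map from a SNP matrix
#'
#' Runs the whole per-line chain (smoothing, block masking, breakpoint
#' detection) followed by population-wide bin building, bin genotyping and
#' nearest-flank imputation.
#'
#' @param m a [snp_matrix()] (typically post [filter_snps()]).
#' @param chrom_lengths named chromosome lengths in bp; defaults to the last
#'   marker position per chromosome.
#' @param window,majority smoothing parameters ([smooth_line()]).
#' @param min_block_bp,min_block_snps masking parameters
#'   ([mask_small_blocks()]).
#' @param het_policy `"keep"` treats H as a third genotype state;
#'   `"missing"` sets observed heterozygote calls missing before smoothing.
#' @return Object of class `bin_map`: list with `bins`, `calls` (imputed
#'   bins x lines matrix), `raw_calls` (pre-imputation), `breakpoints`
#'   (per line, per chromosome), and `summary` ([bin_summary()]).
#' @export
build_bin_map <- function(m, chrom_lengths = NULL, window = 15,
                          majority = 0.7, min_block_bp = 250000,
                          min_block_snps = 5,
                          het_policy = c("keep", "missing")) {
  het_policy <- match.arg(het_policy)
  calls <- m$calls
  if (het_policy == "missing") calls[calls == "H"] <- NA
  chroms <- unique(m$markers$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(m$markers$pos, factor(m$markers$chrom, chroms), max)
  }
  stopifnot(all(chroms %in% names(chrom_lengths)))
  m_idx <- split(seq_len(nrow(calls)), factor(m$markers$chrom, chroms))
  tracks <- lapply(m$lines, function(ln) {
    tr <- lapply(chroms, function(nm) {
      idx <- m_idx[[nm]]
      sm <- smooth_line(calls[idx, ln], window = window, majority = majority)
      mask_small_blocks(sm, m$markers$pos[idx], min_len_bp = min_block_bp,
                        min_snps = min_block_snps, raw_calls = calls[idx, ln])
    })
    names(tr) <- chroms
    tr
  })
  names(tracks) <- m$lines
  brk <- lapply(m$lines, function(ln) {
    b <- lapply(chroms, function(nm) {
      detect_breakpoints(tracks[[ln]][[nm]], m$markers$pos[m_idx[[nm]]])
    })
    names(b) <- chroms
    b
  })
  names(brk) <- m$lines
  pooled <- lapply(chroms, function(nm) {
    unlist(lapply(brk, `[[`, nm), use.names = FALSE)
  })
  names(pooled) <- chroms
  bins <- build_bins(pooled, chrom_lengths[chroms])
  raw <- genotype_bins(tracks, bins, m$markers)
  imputed <- impute_bins(raw, bins)
  structure(list(bins = bins, calls = imputed, raw_calls = raw,
                 breakpoints = brk, summary = bin_summary(bins)),
            class = "bin_map")
}

#' @method print bin_map
#' @export
print.bin_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("bin_map: %d bins x %d lines; mean bin %.1f kb ",
                     "(range %.1f kb - %.2f Mb)\n"),
              s$count, ncol(x$calls), s$mean_bp / 1e3, s$min_bp / 1e3,
              s$max_bp / 1e6))
  invisible(x)
}

#' Write bins as BED (0-based half-open)
#'
#' @param bins data frame from [build_bins()].
#' @param path output file.
#' @export
write_bins_bed <- function(bins, path) {
  df <- data.frame(bins$chrom, format(bins$start, scientific = FALSE,
                                      trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE),
                   bins$bin_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bin matrix as TSV
#'
#' Columns `bin_id`, `chrom`, `start`, `end` then one column per line.
#'
#' @param bm a `bin_map` ([build_bin_map()]).
#' @param path output file.
#' @export
write_bin_matrix_tsv <- function(bm, path) {
  calls <- bm$calls
  calls[is.na(calls)] <- "."
  df <- cbind(bm$bins, as.data.frame(calls, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
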