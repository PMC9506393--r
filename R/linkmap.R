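# Genetic map construction: recombination fractions between adjacent bins,
# with the selfed-RIL map-expansion correction, converted to additive cM by
# the Haldane mapping function (no crossover interference).

#' Recombination fractions between adjacent bins
#'
#' For each pair of adjacent bins on a chromosome, the observed mismatch
#' frequency R is computed over informative lines (both calls homozygous,
#' A or B; heterozygotes are excluded since their phase at fixation is
#' ambiguous) and converted to the meiotic recombination fraction r.
#' For a backcross R estimates r directly. For selfed RILs from an F1,
#' R = 2r/(1+2r) (inverted as r = R/(2-2R)). For BC1-derived selfed RILs
#' the exact two-point transition is R = 3r/(2+4r): the BC1 plant is a
#' double heterozygote (behaving like a selfed-RIL founder) with
#' probability (1-r)/2, and a single heterozygote that fixes a recombinant
#' genotype half the time with probability r; the inversion is
#' r = 2R/(3-4R). r is clamped to [0, 0.49]. Pairs with fewer than 10
#' informative lines get a missing r.
#'
#' @param bm a `bin_map` ([build_bin_map()]).
#' @param pop_type population type: `"BC"`, `"RIL_self"` or `"BC1_RIL"`.
#' @return Data frame with one row per adjacent pair: `chrom`, `bin_left`,
#'   `bin_right`, `n_informative`, `R_obs`, `r`.
#' @export
adjacent_rec_frac <- function(bm, pop_type = c("BC1_RIL", "RIL_self", "BC")) {
  pop_type <- match.arg(pop_type)
  calls <- bm$calls
  bins <- bm$bins
  rows <- lapply(unique(bins$chrom), function(nm) {
    idx <- which(bins$chrom == nm)
    if (length(idx) < 2L) return(NULL)
    l <- idx[-length(idx)]
    r_ <- idx[-1]
    n_inf <- numeric(length(l)); R <- numeric(length(l))
    for (k in seq_along(l)) {
      a <- calls[l[k], ]; b <- calls[r_[k], ]
      inf <- !is.na(a) & !is.na(b) & a != "H" & b != "H"
      n_inf[k] <- sum(inf)
      R[k] <- if (n_inf[k] > 0) mean(a[inf] != b[inf]) else NA
    }
    data.frame(chrom = nm, bin_left = bins$bin_id[l],
               bin_right = bins$bin_id[r_], n_informative = n_inf, R_obs = R)
  })
  out <- do.call(rbind, rows)
  R <- out$R_obs
  r <- switch(pop_type,
              BC = R,
              RIL_self = R / (2 - 2 * R),
              BC1_RIL = 2 * R / (3 - 4 * R))
  r[!is.na(r) & r < 0] <- 0.49  # mismatch beyond the model's range
  r <- pmin(pmax(r, 0), 0.49)
  low <- !is.na(out$R_obs) & out$n_informative < 10
  if (any(low)) {
    message(sum(low), " adjacent pair(s) with < 10 informative lines; ",
            "r set missing")
  }
  r[out$n_informative < 10] <- NA
  out$r <- r
  out
}

#' Haldane mapping function
#'
#' Converts a recombination fraction to additive genetic distance assuming
#' no crossover interference: d = -50 ln(1 - 2r) cM.
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @return Genetic distance(s) in cM.
#' @export
haldane_cm <- function(r) {
  if (any(!is.na(r) & (r < 0 | r >= 0.5))) {
    stop("recombination fraction must be in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}

#' Inverse Haldane mapping function
#'
#' @param d genetic distance(s) in cM.
#' @return Recombination fraction(s): r = (1 - exp(-d/50)) / 2.
#' @export
haldane_inv <- function(d) {
  stopifnot(all(is.na(d) | d >= 0))
  (1 - exp(-d / 50)) / 2
}

#' Build a Haldane genetic map from a bin map
#'
#' Cumulative cM positions of bin midpoints per chromosome: adjacent-pair
#' recombination fractions ([adjacent_rec_frac()]) are converted with
#' [haldane_cm()] and summed. Pairs with missing r are interpolated from
#' their physical distance times the chromosome-average cM/bp of the
#' estimated pairs.
#'
#' @param bm a `bin_map`.
#' @param pop_type population type (see [adjacent_rec_frac()]).
#' @return Object of class `genetic_map`: data frame (`chrom`, `bin_id`,
#'   `mid_bp`, `cm`) with attributes `total_cm` and `mean_interval_cm`.
#' @export
build_map <- function(bm, pop_type = c("BC1_RIL", "RIL_self", "BC")) {
  pop_type <- match.arg(pop_type)
  rf <- adjacent_rec_frac(bm, pop_type)
  bins <- bm$bins
  mid <- (bins$start + bins$end) / 2
  rows <- lapply(unique(bins$chrom), function(nm) {
    idx <- which(bins$chrom == nm)
    if (length(idx) < 2L) {
      return(data.frame(chrom = nm, bin_id = bins$bin_id[idx],
                        mid_bp = mid[idx], cm = 0))
    }
    p <- rf[rf$chrom == nm, ]
    d <- haldane_cm(p$r)
    phys <- diff(mid[idx])
    known <- !is.na(d)
    if (!any(known)) stop("no estimable recombination fraction on ", nm)
    rate <- sum(d[known]) / sum(phys[known])
    d[!known] <- phys[!known] * rate
    data.frame(chrom = nm, bin_id = bins$bin_id[idx], mid_bp = mid[idx],
               cm = c(0, cumsum(d)))
  })
  out <- do.call(rbind, rows)
  chrom_len <- tapply(out$cm, factor(out$chrom, unique(out$chrom)), max)
  n_int <- nrow(out) - length(unique(out$chrom))
  structure(out, class = c("genetic_map", "data.frame"),
            total_cm = sum(chrom_len),
            mean_interval_cm = if (n_int > 0) sum(chrom_len) / n_int else NA)
}

#' @method print genetic_map
#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d bins on %d chromosomes, %.1f cM total, %.2f cM mean interval\n",
              nrow(x), length(unique(x$chrom)), attr(x, "total_cm"),
              attr(x, "mean_interval_cm")))
  invisible(x)
}

#' Write a genetic map as CSV
#'
#' @param map a `genetic_map` ([build_map()]).
#' @param path output file.
#' @export
write_genetic_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
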