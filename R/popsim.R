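# Population simulator: meiosis without crossover interference (Poisson
# crossover counts on the genetic scale), backcross + single-seed-descent
# pedigrees, GBS-style observation noise, liability-scale phenotypes and
# negative-binomial cold time-course counts with ground-truth labels.
#
# Haplotypes are run-length step functions over [0, L]: list(ends, origin)
# where `ends` are segment right edges in bp (last == chromosome length) and
# `origin` is 0 (recurrent parent, A) or 1 (donor, B). Segments tile the
# chromosome exactly by construction.

.pure_hap <- function(length_bp, origin) {
  list(ends = as.numeric(length_bp), origin = as.integer(origin))
}

# evaluate parental origin of a haplotype at physical positions
.hap_at <- function(h, pos) {
  k <- length(h$ends)
  if (k == 1L) return(rep(h$origin, length(pos)))
  idx <- pmin(findInterval(pos, h$ends[-k]) + 1L, k)
  h$origin[idx]
}

# slice of a haplotype restricted to the half-open window (from, to]
.hap_slice <- function(h, from, to) {
  starts <- c(0, h$ends[-length(h$ends)])
  keep <- which(h$ends > from & starts < to)
  list(ends = pmin(h$ends[keep], to), origin = h$origin[keep])
}

.merge_runs <- function(h) {
  n <- length(h$origin)
  if (n <= 1L) return(h)
  first <- c(TRUE, h$origin[-1] != h$origin[-n])
  last <- c(which(first[-1]), n)
  list(ends = h$ends[last], origin = h$origin[first])
}

# recombine two haplotypes at sorted crossover positions, starting from
# haplotype `first` (1 or 2)
.splice_haps <- function(h1, h2, xo, first) {
  L <- h1$ends[length(h1$ends)]
  if (length(xo) == 0L) return(if (first == 1L) h1 else h2)
  cuts <- c(sort.int(xo), L)
  ends <- numeric(0); origin <- integer(0)
  from <- 0
  active <- first
  for (to in cuts) {
    if (to > from) {
      s <- .hap_slice(if (active == 1L) h1 else h2, from, to)
      ends <- c(ends, s$ends); origin <- c(origin, s$origin)
      from <- to
    }
    active <- 3L - active
  }
  .merge_runs(list(ends = ends, origin = origin))
}

.bril_line <- function(h1, h2, generation) {
  structure(list(h1 = h1, h2 = h2, generation = generation),
            class = "bril_line")
}

#' Simulate one gamete from a phased diplotype
#'
#' Meiosis without crossover interference: the number of crossovers per
#' chromosome is Poisson with mean equal to the chromosome's genetic length
#' in Morgans, and crossover positions are uniform on the genetic scale
#' (equivalently, uniform in bp, since the recombination rate is uniform
#' within each simulated chromosome). This is the no-interference model that
#' matches the Haldane mapping function used downstream.
#'
#' @param line a `bril_line` (phased diplotype; see [simulate_bril()]).
#' @param genome a [genome_spec()]; must cover every chromosome of `line`.
#' @return A haplotype: named list (one element per chromosome) of
#'   run-length segment lists `(ends, origin)` with origin 0 = recurrent
#'   parent, 1 = donor.
#' @export
simulate_gamete <- function(line, genome) {
  chrom <- genome$chrom
  if (!setequal(names(line$h1), chrom$name)) {
    stop("genome does not cover all chromosomes of the line")
  }
  out <- lapply(seq_len(nrow(chrom)), function(i) {
    nm <- chrom$name[i]
    h1 <- line$h1[[nm]]
    h2 <- line$h2[[nm]]
    # a chromosome pair fixed for the same mosaic transmits itself
    if (identical(h1, h2)) return(h1)
    n_xo <- stats::rpois(1L, chrom$length_cm[i] / 100)
    xo <- stats::runif(n_xo, 0, chrom$length_bp[i])
    first <- sample.int(2L, 1L)
    .splice_haps(h1, h2, xo, first)
  })
  names(out) <- chrom$name
  out
}

#' Simulate a backcross recombinant inbred line population
#'
#' Each line descends from the F1 between a donor and a recurrent parent by
#' `n_backcross` backcrosses to the recurrent parent followed by `n_self`
#' generations of single-seed descent selfing. With one backcross the
#' expected donor genome share is 25%, and residual heterozygosity halves
#' with every selfing generation.
#'
#' @param genome a [genome_spec()].
#' @param n_lines number of lines (default 132).
#' @param n_backcross number of backcross generations (default 1).
#' @param n_self number of selfing generations (default 8).
#' @return A named list of `bril_line` objects (`L001`, `L002`, ...), each a
#'   phased diplotype whose two haplotypes are mosaics of donor (origin 1)
#'   and recurrent-parent (origin 0) segments.
#' @export
simulate_bril <- function(genome, n_lines = 132, n_backcross = 1, n_self = 8) {
  stopifnot(n_lines >= 1, n_backcross >= 0, n_self >= 0)
  chrom <- genome$chrom
  hap_a <- lapply(chrom$length_bp, .pure_hap, origin = 0L)
  hap_b <- lapply(chrom$length_bp, .pure_hap, origin = 1L)
  names(hap_a) <- names(hap_b) <- chrom$name
  gen <- sprintf("BC%dF%d", n_backcross, n_self + 1L)
  f1 <- .bril_line(hap_a, hap_b, "F1")
  lines <- lapply(seq_len(n_lines), function(i) {
    dip <- f1
    for (b in seq_len(n_backcross)) {
      dip <- .bril_line(simulate_gamete(dip, genome), hap_a, gen)
    }
    for (s in seq_len(n_self)) {
      dip <- .bril_line(simulate_gamete(dip, genome),
                        simulate_gamete(dip, genome), gen)
    }
    dip$generation <- gen
    dip
  })
  names(lines) <- sprintf("L%03d", seq_len(n_lines))
  lines
}

#' True marker genotypes of simulated lines
#'
#' @param lines list of `bril_line` objects.
#' @param genome the [genome_spec()] the lines were simulated on.
#' @return Character matrix (markers x lines) with values `"A"` (recurrent
#'   homozygote), `"H"`, `"B"` (donor homozygote).
#' @export
true_genotypes <- function(lines, genome) {
  mk <- genome$markers
  g <- vapply(lines, function(ln) {
    unlist(lapply(split(seq_len(nrow(mk)), factor(mk$chrom, unique(mk$chrom))),
                  function(idx) {
                    nm <- mk$chrom[idx[1]]
                    .hap_at(ln$h1[[nm]], mk$pos[idx]) +
                      .hap_at(ln$h2[[nm]], mk$pos[idx])
                  }), use.names = FALSE)
  }, numeric(nrow(mk)))
  matrix(c("A", "H", "B")[g + 1L], nrow = nrow(mk),
         dimnames = list(NULL, names(lines)))
}

#' Donor genome fraction and heterozygosity of a simulated line
#'
#' Length-weighted genome shares computed exactly from the segment mosaics.
#'
#' @param line a `bril_line`.
#' @return Named numeric vector with `donor` (donor-allele genome fraction)
#'   and `het` (fraction of the genome heterozygous for parental origin).
#' @export
line_composition <- function(line) {
  tot <- 0; donor <- 0; het <- 0
  for (nm in names(line$h1)) {
    h1 <- line$h1[[nm]]; h2 <- line$h2[[nm]]
    ends <- sort(unique(c(h1$ends, h2$ends)))
    starts <- c(0, ends[-length(ends)])
    mid <- (starts + ends) / 2
    o1 <- .hap_at(h1, mid); o2 <- .hap_at(h2, mid)
    w <- ends - starts
    tot <- tot + sum(w)
    donor <- donor + sum(w * (o1 + o2) / 2)
    het <- het + sum(w * (o1 != o2))
  }
  c(donor = donor / tot, het = het / tot)
}

#' Observe simulated genotypes with GBS-style noise
#'
#' Emulates low-coverage genotyping-by-sequencing calls: each true marker
#' genotype is independently set missing, surviving heterozygotes are
#' miscalled to a random homozygote (the dominant error mode when only one
#' allele is sampled at ~2x depth), and homozygotes are flipped to the other
#' homozygote at a low rate.
#'
#' @param lines list of `bril_line` objects.
#' @param genome the [genome_spec()] used for simulation.
#' @param missing_rate per-call missingness probability.
#' @param het_miscall_rate probability that an observed heterozygote is
#'   called as a random homozygote.
#' @param hom_error_rate probability that a homozygote is flipped.
#' @return A [snp_matrix()] of observed calls.
#' @export
observe_gbs <- function(lines, genome, missing_rate = 0.15,
                        het_miscall_rate = 0.4, hom_error_rate = 0.01) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            het_miscall_rate >= 0, het_miscall_rate <= 1,
            hom_error_rate >= 0, hom_error_rate <= 1)
  calls <- true_genotypes(lines, genome)
  n <- length(calls)
  calls[stats::runif(n) < missing_rate] <- NA
  het <- which(!is.na(calls) & calls == "H")
  mis <- het[stats::runif(length(het)) < het_miscall_rate]
  calls[mis] <- sample(c("A", "B"), length(mis), replace = TRUE)
  hom <- which(!is.na(calls) & calls != "H")
  flip <- hom[stats::runif(length(hom)) < hom_error_rate]
  calls[flip] <- ifelse(calls[flip] == "A", "B", "A")
  snp_matrix(genome$markers, calls, colnames(calls))
}

#' Plant additive QTLs with target variance shares
#'
#' Converts target phenotypic-variance-explained (PVE) shares on the
#' liability scale into additive allele-substitution effects, assuming
#' near-complete fixation at a donor-allele frequency `p_donor` (dosage
#' variance 4 p (1 - p)). The residual SD is set so the total liability
#' variance is 1, hence effect i explains `pve[i]` of it. By default one
#' randomly chosen QTL gets a negative (donor-decreases) effect and the rest
#' are positive, and QTLs are placed on 10 distinct-ish chromosomes
#' (chromosome 11 carrying two), mirroring a typical multi-QTL architecture
#' for seedling cold tolerance.
#'
#' @param genome a [genome_spec()].
#' @param pve per-QTL target variance shares (default ten QTLs, 2-7%).
#' @param chroms chromosome names for each QTL; default spreads them over
#'   chromosomes 1, 2, 3, 4, 7, 8, 9, 11 (twice) and 12.
#' @param n_negative how many QTLs have donor-decreases effects (default 1).
#' @param p_donor expected donor allele frequency (0.25 for one backcross).
#' @return List with `qtls` (data frame: `chrom`, `pos`, `effect`, `pve`),
#'   `residual_sd`, and `intercept` (centers the population mean liability
#'   at 0 so survival probabilities straddle 0.5).
#' @export
plant_qtls <- function(genome, pve = seq(0.02, 0.07, length.out = 10),
                       chroms = NULL, n_negative = 1, p_donor = 0.25) {
  n <- length(pve)
  stopifnot(all(pve > 0), sum(pve) < 1)
  if (is.null(chroms)) {
    idx <- c(1, 2, 3, 4, 7, 8, 9, 11, 11, 12)
    idx <- idx[idx <= nrow(genome$chrom)]
    if (!length(idx)) idx <- seq_len(nrow(genome$chrom))
    chroms <- genome$chrom$name[rep_len(idx, n)]
  }
  L <- .chrom_length(genome, chroms)
  pos <- round(stats::runif(n, 0.1, 0.9) * L)
  vd <- 4 * p_donor * (1 - p_donor)
  effect <- sqrt(pve / vd)
  sgn <- rep(1, n)
  if (n_negative > 0) sgn[sample.int(n, n_negative)] <- -1
  effect <- effect * sgn
  list(qtls = data.frame(chrom = chroms, pos = pos, effect = effect, pve = pve),
       residual_sd = sqrt(1 - sum(pve)),
       intercept = -sum(effect) * 2 * p_donor)
}

#' QTL donor dosage of simulated lines
#'
#' @param lines list of `bril_line` objects.
#' @param qtls data frame with `chrom` and `pos`.
#' @return Integer matrix (lines x QTLs) of donor-allele dosages 0/1/2.
#' @export
qtl_dosage <- function(lines, qtls) {
  d <- vapply(lines, function(ln) {
    if (!all(qtls$chrom %in% names(ln$h1))) {
      stop("QTL position on a chromosome not covered by the simulated genome")
    }
    vapply(seq_len(nrow(qtls)), function(j) {
      nm <- qtls$chrom[j]
      .hap_at(ln$h1[[nm]], qtls$pos[j]) + .hap_at(ln$h2[[nm]], qtls$pos[j])
    }, numeric(1))
  }, numeric(nrow(qtls)))
  t(matrix(d, nrow = nrow(qtls), dimnames = list(NULL, names(lines))))
}

#' Simulate survival-rate phenotypes from planted QTLs
#'
#' Liability model: per line, liability = sum(effect x donor dosage) +
#' intercept + Normal(0, residual_sd); survival probability is the inverse
#' logit of the liability; the observed survival rate is a binomial draw
#' over `n_seedlings` germinated seeds divided by `n_seedlings`, giving a
#' bounded proportion in [0, 1] as scored in a cold-treatment survival assay.
#'
#' @param lines list of `bril_line` objects.
#' @param qtls data frame with `chrom`, `pos`, `effect` ([plant_qtls()]).
#' @param residual_sd SD of the polygenic/environmental liability residual.
#' @param n_seedlings seedlings scored per line (default 30).
#' @param intercept liability intercept (default 0).
#' @return Data frame (`line`, `survival_rate`, `reps`) with attribute
#'   `truth`: list of the latent `liability`, `prob` and the dosage matrix.
#' @export
simulate_phenotype <- function(lines, qtls, residual_sd = 1, n_seedlings = 30,
                               intercept = 0) {
  stopifnot(n_seedlings >= 1, all(is.finite(qtls$effect)))
  dos <- qtl_dosage(lines, qtls)
  liability <- as.vector(dos %*% qtls$effect) + intercept +
    stats::rnorm(length(lines), 0, residual_sd)
  p <- stats::plogis(liability)
  rate <- stats::rbinom(length(lines), n_seedlings, p) / n_seedlings
  out <- data.frame(line = names(lines), survival_rate = rate,
                    reps = n_seedlings)
  attr(out, "truth") <- list(liability = liability, prob = p, dosage = dos)
  out
}

#' Specification for simulated cold time-course RNA-seq counts
#'
#' Defines a 0 h / 4 h / 12 h cold time course in duplicate with planted
#' log2 fold-changes relative to 0 h. Default DE-gene counts scale the
#' up/down counts observed in rice cold time courses (about 0.7% / 1.5% of
#' genes DE at 4 h up/down and 3.2% / 5.3% at 12 h) to `n_genes`, with ~94%
#' of 4 h up-regulated and ~87% of 4 h down-regulated genes sustained at
#' 12 h in the same direction.
#'
#' @param n_genes number of genes.
#' @param reps replicates per timepoint (default 2).
#' @param dispersion negative-binomial dispersion (variance = mu + disp mu^2).
#' @param n_up_4,n_down_4,n_up_12,n_down_12 planted DE gene counts per
#'   direction and timepoint (defaults scale with `n_genes`).
#' @param frac_sustained_up,frac_sustained_down fraction of 4 h DE genes
#'   whose response is sustained at 12 h.
#' @param lfc_range magnitude range for planted log2 fold-changes.
#' @return List of class `counts_spec` consumed by [simulate_counts()].
#' @export
counts_spec <- function(n_genes = 5000, reps = 2, dispersion = 0.05,
                        n_up_4 = round(n_genes * 291 / 40000),
                        n_down_4 = round(n_genes * 607 / 40000),
                        n_up_12 = round(n_genes * 1294 / 40000),
                        n_down_12 = round(n_genes * 2119 / 40000),
                        frac_sustained_up = 0.94, frac_sustained_down = 0.87,
                        lfc_range = c(1.5, 4)) {
  stopifnot(dispersion > 0, reps >= 2,
            n_up_12 >= n_up_4, n_down_12 >= n_down_4)
  pool <- sample.int(n_genes)
  up12 <- pool[seq_len(n_up_12)]
  down12 <- pool[n_up_12 + seq_len(n_down_12)]
  rest <- pool[-seq_len(n_up_12 + n_down_12)]
  n_sus_up <- round(frac_sustained_up * n_up_4)
  n_sus_down <- round(frac_sustained_down * n_down_4)
  n_new_up <- n_up_4 - n_sus_up
  up4 <- c(up12[seq_len(n_sus_up)], rest[seq_len(n_new_up)])
  if (n_new_up > 0) rest <- rest[-seq_len(n_new_up)]
  down4 <- c(down12[seq_len(n_sus_down)], rest[seq_len(n_down_4 - n_sus_down)])
  lfc <- matrix(0, n_genes, 3, dimnames = list(NULL, c("0h", "4h", "12h")))
  draw <- function(k, sign) sign * stats::runif(k, lfc_range[1], lfc_range[2])
  lfc[up4, "4h"] <- draw(length(up4), 1)
  lfc[down4, "4h"] <- draw(length(down4), -1)
  lfc[up12, "12h"] <- draw(length(up12), 1)
  lfc[down12, "12h"] <- draw(length(down12), -1)
  structure(list(
    n_genes = n_genes, reps = reps, dispersion = dispersion, lfc = lfc,
    baseline = stats::rlnorm(n_genes, meanlog = 3.5, sdlog = 1.2),
    lengths = sample(400:6000, n_genes, replace = TRUE),
    size_factors = stats::runif(3 * reps, 0.8, 1.25)
  ), class = "counts_spec")
}

#' Simulate negative-binomial cold time-course counts with truth labels
#'
#' Counts for gene g in a sample at timepoint t are NB with mean
#' `baseline_g x 2^lfc_gt x size factor` and the requested dispersion. The
#' truth table lists every gene with a nonzero planted log2 fold-change for
#' each contrast (`0_4`, `0_12`, `4_12`) with its direction, playing the
#' role of an external DE call set with known ground truth.
#'
#' @param spec a [counts_spec()].
#' @return List of class `sim_counts`: `counts` (genes x samples integer
#'   matrix), `lengths` (bp), `samples` (data frame: `sample`, `timepoint`,
#'   `rep`), and `truth` (DEG table: `gene`, `contrast`, `direction`,
#'   `log2fc`, `fdr`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "counts_spec"))
  tps <- c("0h", "4h", "12h")
  samples <- data.frame(
    sample = paste0("T", rep(c(0, 4, 12), each = spec$reps), "_r",
                    rep(seq_len(spec$reps), 3)),
    timepoint = rep(tps, each = spec$reps),
    rep = rep(seq_len(spec$reps), 3))
  counts <- vapply(seq_len(nrow(samples)), function(s) {
    mu <- spec$baseline * 2^spec$lfc[, samples$timepoint[s]] *
      spec$size_factors[s]
    stats::rnbinom(spec$n_genes, mu = mu, size = 1 / spec$dispersion)
  }, numeric(spec$n_genes))
  dimnames(counts) <- list(paste0("gene", seq_len(spec$n_genes)),
                           samples$sample)
  lfc4 <- spec$lfc[, "4h"]
  lfc12 <- spec$lfc[, "12h"]
  truth_rows <- function(contrast, lfc) {
    de <- which(lfc != 0)
    data.frame(gene = rownames(counts)[de],
               contrast = rep(contrast, length(de)),
               direction = ifelse(lfc[de] > 0, "up", "down"),
               log2fc = lfc[de], fdr = rep(0, length(de)))
  }
  truth <- rbind(truth_rows("0_4", lfc4), truth_rows("0_12", lfc12),
                 truth_rows("4_12", lfc12 - lfc4))
  structure(list(counts = counts, lengths = stats::setNames(
    spec$lengths, rownames(counts)), samples = samples, truth = truth),
    class = "sim_counts")
}
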