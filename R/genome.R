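#' Genome specification for simulation
#'
#' Defines the chromosome structure (physical and genetic lengths) and a
#' deterministic, evenly spaced marker grid used by the population simulator.
#' Genetic length is apportioned to chromosomes proportionally to physical
#' length when not given explicitly, so the recombination rate (cM/bp) is
#' uniform within and across chromosomes.
#'
#' @param names character vector of chromosome names.
#' @param lengths_bp physical chromosome lengths in bp (strictly positive).
#' @param lengths_cm genetic lengths in cM; if `NULL`, `total_cm` is
#'   apportioned by physical length.
#' @param n_markers number of markers per chromosome (recycled).
#' @param total_cm total genetic map length used when `lengths_cm` is `NULL`.
#' @return An object of class `genome_spec`: a list with elements
#'   `chrom` (data frame: `name`, `length_bp`, `length_cm`) and `markers`
#'   (data frame: `chrom`, `pos`; positions 1-based, strictly increasing
#'   within chromosome).
#' @export
genome_spec <- function(names, lengths_bp, lengths_cm = NULL, n_markers = 150,
                        total_cm = 2341.9) {
  stopifnot(length(names) == length(lengths_bp), all(lengths_bp > 0))
  if (is.null(lengths_cm)) {
    lengths_cm <- total_cm * lengths_bp / sum(lengths_bp)
  }
  stopifnot(length(lengths_cm) == length(names), all(lengths_cm >= 0))
  n_markers <- rep_len(as.integer(n_markers), length(names))
  stopifnot(all(n_markers >= 2))
  markers <- do.call(rbind, lapply(seq_along(names), function(i) {
    pos <- round(seq_len(n_markers[i]) * lengths_bp[i] / (n_markers[i] + 1))
    data.frame(chrom = names[i], pos = as.numeric(pos))
  }))
  stopifnot(!any(unlist(tapply(markers$pos, markers$chrom, diff)) <= 0))
  structure(list(
    chrom = data.frame(name = names, length_bp = as.numeric(lengths_bp),
                       length_cm = as.numeric(lengths_cm)),
    markers = markers
  ), class = "genome_spec")
}

#' Desk-scale rice-like genome
#'
#' Twelve chromosomes with physical sizes scaled to the rice genome
#' (23-45 Mb each, ~373 Mb total) and a total genetic length of 2341.9 cM
#' apportioned by physical length. The default marker grid (150 markers per
#' chromosome, 1800 genome wide) is a desk-scale stand-in for a dense GBS
#' marker set; increase `markers_per_chrom` for higher resolution.
#'
#' @param markers_per_chrom markers per chromosome.
#' @param total_cm total genetic length in cM.
#' @return A [genome_spec()] object.
#' @export
rice_genome <- function(markers_per_chrom = 150, total_cm = 2341.9) {
  sizes_mb <- c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
                29.7, 28.4, 23.0, 23.2, 29.0, 27.5)
  genome_spec(paste0("chr", 1:12), sizes_mb * 1e6,
              n_markers = markers_per_chrom, total_cm = total_cm)
}

#' @method print genome_spec
#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosomes, %.1f Mb, %.1f cM, %d markers\n",
              nrow(x$chrom), sum(x$chrom$length_bp) / 1e6,
              sum(x$chrom$length_cm), nrow(x$markers)))
  invisible(x)
}

.chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$chrom$length_bp[i]
}
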