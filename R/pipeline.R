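#' @keywords internal
"_PACKAGE"

#' Simulate a complete mapping study with known ground truth
#'
#' Convenience generator for the study conditions emulated by this package:
#' a BC1F9 backcross-RIL population (default 132 lines), GBS-style observed
#' genotypes on a rice-like 12-chromosome genome, and survival-rate
#' phenotypes (30 seedlings per line) driven by 10 planted QTLs of 2-7%
#' liability-scale PVE each.
#'
#' @param seed integer seed (all randomness flows from it).
#' @param genome a [genome_spec()] (default [rice_genome()]).
#' @param n_lines number of lines.
#' @param pve per-QTL target variance shares (see [plant_qtls()]).
#' @param n_seedlings seedlings scored per line.
#' @param missing_rate,het_miscall_rate,hom_error_rate GBS noise rates
#'   (see [observe_gbs()]).
#' @return List with `genome`, `lines`, `truth` (planted QTLs and noise-free
#'   genotypes), `genotypes` (observed [snp_matrix()]), `phenotype`.
#' @export
simulate_study <- function(seed = 1, genome = rice_genome(), n_lines = 132,
                           pve = seq(0.02, 0.07, length.out = 10),
                           n_seedlings = 30, missing_rate = 0.15,
                           het_miscall_rate = 0.4, hom_error_rate = 0.01) {
  set.seed(seed)
  lines <- simulate_bril(genome, n_lines = n_lines)
  planted <- plant_qtls(genome, pve = pve)
  ph <- simulate_phenotype(lines, planted$qtls,
                           residual_sd = planted$residual_sd,
                           n_seedlings = n_seedlings,
                           intercept = planted$intercept)
  geno <- observe_gbs(lines, genome, missing_rate = missing_rate,
                      het_miscall_rate = het_miscall_rate,
                      hom_error_rate = hom_error_rate)
  list(genome = genome, lines = lines,
       truth = list(qtls = planted$qtls, residual_sd = planted$residual_sd,
                    intercept = planted$intercept),
       genotypes = geno, phenotype = ph)
}

#' Run the genotype-to-QTL pipeline
#'
#' Chains SNP filtering, bin-map construction, Haldane genetic-map building,
#' the ridge-regression scan and peak-bin QTL calling with LMG variance
#' decomposition.
#'
#' @param genotypes a [snp_matrix()].
#' @param phenotype phenotype data frame (`line`, `survival_rate`).
#' @param chrom_lengths named chromosome lengths in bp (e.g.
#'   `genome$chrom$length_bp` named by chromosome).
#' @param max_missing,min_maf SNP filter thresholds ([filter_snps()]).
#' @param window,majority,min_block_bp,min_block_snps bin-map parameters
#'   ([build_bin_map()]).
#' @param pop_type population type for the genetic map ([build_map()]).
#' @param threshold QTL declaration threshold ([call_qtls()]).
#' @param lambda optional fixed ridge penalty ([ridge_scan()]).
#' @return List with `filter`, `bin_map`, `genetic_map`, `scan`, `qtls`.
#' @export
run_qtl_pipeline <- function(genotypes, phenotype, chrom_lengths = NULL,
                             max_missing = 0.5, min_maf = 0.05, window = 15,
                             majority = 0.7, min_block_bp = 250000,
                             min_block_snps = 5, pop_type = "BC1_RIL",
                             threshold = 0.005, lambda = NULL) {
  flt <- filter_snps(genotypes, max_missing = max_missing, min_maf = min_maf)
  bm <- build_bin_map(flt$genotypes, chrom_lengths = chrom_lengths,
                      window = window, majority = majority,
                      min_block_bp = min_block_bp,
                      min_block_snps = min_block_snps)
  gmap <- build_map(bm, pop_type = pop_type)
  scan <- ridge_scan(bm, phenotype, lambda = lambda)
  qtls <- call_qtls(scan, bm, phenotype, threshold = threshold)
  list(filter = flt, bin_map = bm, genetic_map = gmap, scan = scan,
       qtls = qtls)
}
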