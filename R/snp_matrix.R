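# SNP genotype matrix container and I/O (TSV and minimal VCF dialects).
# Calls use the biparental alphabet A (recurrent-parent homozygote),
# B (donor homozygote), H (heterozygote), NA (missing).

#' SNP genotype matrix
#'
#' @param markers data frame with `chrom` and `pos` (1-based, strictly
#'   increasing within chromosome).
#' @param calls character matrix (markers x lines) over `{A, B, H, NA}`.
#' @param lines line identifiers (column names).
#' @return Object of class `snp_matrix`: list with `markers`, `calls`,
#'   `lines`.
#' @export
snp_matrix <- function(markers, calls, lines = colnames(calls)) {
  calls <- as.matrix(calls)
  stopifnot(nrow(markers) == nrow(calls), length(lines) == ncol(calls))
  bad <- !is.na(calls) & !(calls %in% c("A", "B", "H"))
  if (any(bad)) {
    stop("invalid genotype call(s): ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  if (any(unlist(tapply(markers$pos, factor(markers$chrom,
                                            unique(markers$chrom)),
                        function(p) diff(p) <= 0)))) {
    stop("marker positions must be strictly increasing within chromosome")
  }
  colnames(calls) <- lines
  structure(list(markers = data.frame(chrom = as.character(markers$chrom),
                                      pos = as.numeric(markers$pos)),
                 calls = calls, lines = lines),
            class = "snp_matrix")
}

#' @method print snp_matrix
#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d markers x %d lines (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$calls)

.subset_snp_matrix <- function(m, idx) {
  snp_matrix(m$markers[idx, , drop = FALSE],
             m$calls[idx, , drop = FALSE], m$lines)
}

#' Write genotypes as TSV
#'
#' Columns `chrom`, `pos`, then one column per line with calls `A/B/H` and
#' `.` for missing.
#'
#' @param m a [snp_matrix()].
#' @param path output file.
#' @export
write_genotypes_tsv <- function(m, path) {
  calls <- m$calls
  calls[is.na(calls)] <- "."
  df <- cbind(m$markers, as.data.frame(calls, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from TSV
#'
#' @param path TSV written by [write_genotypes_tsv()].
#' @return A [snp_matrix()].
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("chrom", "pos"))) {
    stop("malformed genotype TSV: expected columns chrom, pos, <lines>")
  }
  calls <- as.matrix(df[, -(1:2), drop = FALSE])
  unknown <- !is.na(calls) & !(calls %in% c("A", "B", "H", "."))
  if (any(unknown)) {
    stop(sprintf("parse error at line %d: unknown genotype symbol '%s'",
                 which(rowSums(unknown) > 0)[1] + 1L,
                 calls[unknown][1]))
  }
  calls[calls == "."] <- NA
  snp_matrix(data.frame(chrom = df$chrom, pos = as.numeric(df$pos)), calls)
}

#' Write genotypes as a minimal VCF
#'
#' GT-only VCF v4.2: A is encoded `0/0` (REF = recurrent-parent allele),
#' B `1/1`, H `0/1`, missing `./.`. REF/ALT bases are placeholders (`A`/`G`)
#' since the biparental calls carry no base identity.
#'
#' @param m a [snp_matrix()].
#' @param path output file.
#' @export
write_genotypes_vcf <- function(m, path) {
  gt <- m$calls
  enc <- c(A = "0/0", H = "0/1", B = "1/1")
  gt[] <- ifelse(is.na(m$calls), "./.", enc[m$calls])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(m$markers$chrom)),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", m$lines), collapse = "\t")), con)
  body <- cbind(m$markers$chrom, format(m$markers$pos, scientific = FALSE,
                                        trim = TRUE),
                ".", "A", "G", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses GT fields of a biallelic VCF: `0/0` (or `0|0`) maps to A, `1/1`
#' to B, `0/1`/`1/0` to H, `./.` to missing. Records with more than one ALT
#' allele are skipped with a warning.
#'
#' @param path VCF file.
#' @return A [snp_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " non-biallelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  core <- gsub("\\|", "/", gt)
  map <- c("0/0" = "A", "1/1" = "B", "0/1" = "H", "1/0" = "H")
  calls <- matrix(map[core], nrow = nrow(core), dimnames = dimnames(gt))
  unknown <- !is.na(core) & core != "./." & is.na(calls)
  if (any(unknown)) {
    stop("parse error: unexpected GT value '", core[unknown][1], "'")
  }
  snp_matrix(data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS)), calls)
}

#' Load a genotype matrix
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`; default guesses from the extension.
#' @return A [snp_matrix()].
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  switch(format, vcf = read_genotypes_vcf(path), tsv = read_genotypes_tsv(path))
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' A marker is retained when its missing-call fraction is <= `max_missing`
#' AND its minor allele frequency is >= `min_maf` (so markers strictly above
#' 50% missingness or strictly below 5% MAF are removed under the defaults).
#' MAF is computed on allele counts over non-missing calls, a heterozygote
#' contributing one allele of each kind.
#'
#' @param m a [snp_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @param min_maf minimum tolerated minor allele frequency (default 0.05).
#' @return List with `genotypes` (filtered [snp_matrix()]) and `report`
#'   (data frame `chrom`, `pos`, `reason` for every removed marker; reasons
#'   `missingness`, `maf`, or both comma-joined).
#' @export
filter_snps <- function(m, max_missing = 0.5, min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  calls <- m$calls
  miss_frac <- rowMeans(is.na(calls))
  n_a <- rowSums(calls == "A", na.rm = TRUE)
  n_b <- rowSums(calls == "B", na.rm = TRUE)
  n_h <- rowSums(calls == "H", na.rm = TRUE)
  a <- 2 * n_a + n_h
  b <- 2 * n_b + n_h
  tot <- a + b
  maf <- ifelse(tot == 0, 0, pmin(a, b) / tot)
  fail_miss <- miss_frac > max_missing
  fail_maf <- maf < min_maf
  drop <- fail_miss | fail_maf
  reason <- paste0(ifelse(fail_miss, "missingness", ""),
                   ifelse(fail_miss & fail_maf, ",", ""),
                   ifelse(fail_maf, "maf", ""))[drop]
  if (all(drop)) warning("no markers pass the filters")
  list(genotypes = .subset_snp_matrix(m, !drop),
       report = data.frame(chrom = m$markers$chrom[drop],
                           pos = m$markers$pos[drop], reason = reason))
}
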