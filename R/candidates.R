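# Candidate-gene screening for a QTL interval: annotation intersection,
# expression/cold-response prioritization, promoter allele comparison by
# global alignment, and literal motif-disruption testing.

#' Read gene models from GFF3 or BED
#'
#' GFF3: records of type `gene` are kept (all records if none are typed
#' `gene`); the gene id is taken from the `ID` (falling back to `Name`)
#' attribute. BED: the `name` column is the gene id. Coordinates are
#' returned 1-based inclusive (GFF3 convention; BED is converted on read).
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  id <- if (!is.null(md$ID)) as.character(md$ID) else
    if (!is.null(md$Name)) as.character(md$Name) else
      if (!is.null(md$name)) as.character(md$name) else
        paste0("gene", seq_along(gr))
  data.frame(gene_id = id, chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Genes overlapping a physical interval
#'
#' Returns every gene whose span overlaps the interval by at least 1 bp
#' (coordinates 1-based inclusive on both sides), sorted by start.
#'
#' @param annot gene models: data frame with `gene_id`, `chrom`, `start`,
#'   `end` (see [read_gene_models()]).
#' @param chrom chromosome of the interval.
#' @param start,end interval bounds in bp (1-based inclusive).
#' @return Subset of `annot`, sorted by `start`.
#' @export
genes_in_interval <- function(annot, chrom, start, end) {
  stopifnot(start <= end)
  if (!chrom %in% annot$chrom) stop("unknown chromosome: ", chrom)
  gr <- GenomicRanges::GRanges(annot$chrom,
                               IRanges::IRanges(annot$start, annot$end))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- S4Vectors::queryHits(GenomicRanges::findOverlaps(gr, q))
  out <- annot[sort(unique(hits)), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Prioritize candidate genes in a QTL interval
#'
#' Tiers: (1) expressed (max TPM over samples >= `expressed_tpm_min`) and
#' differentially expressed under cold in any contrast; (2) expressed but
#' not DE; (3) not detectably expressed. Within a tier, genes are ordered
#' by best (smallest) FDR, then by largest absolute log2 fold-change.
#'
#' @param genes character vector of gene ids (e.g. from
#'   [genes_in_interval()]`$gene_id`).
#' @param tpm_mat genes x samples TPM matrix ([tpm()]); genes absent from
#'   it are treated as not expressed.
#' @param deg DEG table (`gene`, `contrast`, `direction`, `log2fc`, `fdr`).
#' @param expressed_tpm_min expression threshold in TPM (default 1).
#' @return Data frame sorted by rank: `gene`, `tier`, `max_tpm`, `de`,
#'   `best_fdr`, `best_lfc`, `rank`.
#' @export
prioritize <- function(genes, tpm_mat, deg, expressed_tpm_min = 1.0) {
  genes <- unique(genes)
  max_tpm <- vapply(genes, function(g) {
    if (g %in% rownames(tpm_mat)) max(tpm_mat[g, ]) else 0
  }, numeric(1))
  de <- genes %in% deg$gene
  best_fdr <- vapply(genes, function(g) {
    v <- deg$fdr[deg$gene == g]
    if (length(v)) min(v) else Inf
  }, numeric(1))
  best_lfc <- vapply(genes, function(g) {
    v <- deg$log2fc[deg$gene == g]
    if (length(v)) v[which.max(abs(v))] else 0
  }, numeric(1))
  expressed <- max_tpm >= expressed_tpm_min
  tier <- ifelse(expressed & de, 1L, ifelse(expressed, 2L, 3L))
  ord <- order(tier, best_fdr, -abs(best_lfc))
  out <- data.frame(gene = genes, tier = tier, max_tpm = max_tpm, de = de,
                    best_fdr = best_fdr, best_lfc = best_lfc,
                    row.names = NULL)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.check_dna <- function(s, what) {
  s <- toupper(s)
  if (!nzchar(s)) stop(what, " sequence is empty")
  if (grepl("[^ACGTN]", s)) stop(what, " contains non-DNA characters")
  s
}

# global alignment of two promoter alleles; returns aligned strings and
# coordinate maps between the alleles (gaps mapped to the last preceding
# base of the other allele, 0 before its start)
.align_promoters <- function(seq_a, seq_b) {
  seq_a <- .check_dna(seq_a, "allele A")
  seq_b <- .check_dna(seq_b, "allele B")
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 5, gapExtension = 1)
  if (Biostrings::pid(pa) < 50) {
    stop("alignment identity below 50%; sequences are likely not homologous")
  }
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  apos <- cumsum(al_a != "-")
  bpos <- cumsum(al_b != "-")
  map_a2b <- bpos[al_a != "-"]
  map_b2a <- apos[al_b != "-"]
  list(al_a = al_a, al_b = al_b, apos = apos, bpos = bpos,
       map_a2b = map_a2b, map_b2a = map_b2a)
}

#' Variants between two promoter alleles
#'
#' Globally aligns the two allele sequences (match +1, mismatch -1, gap
#' open -5, gap extend -1) and classifies aligned columns into SNPs,
#' insertions (bases present only in allele B) and deletions (bases present
#' only in allele A); contiguous gap columns form one indel event.
#' Positions are reported on allele-A coordinates relative to the predicted
#' start codon: position -1 is the base immediately 5' of the A of ATG, so
#' a 2-kb promoter spans -2000..-1 (the default `offset`).
#'
#' @param seq_a,seq_b allele A and allele B promoter sequences (DNA,
#'   A/C/G/T/N).
#' @param offset position of the first base of `seq_a` relative to the
#'   start codon (default `-nchar(seq_a)`).
#' @return Data frame with `position`, `type` (`SNP`/`insertion`/
#'   `deletion`), `ref` (allele A), `alt` (allele B). Insertions carry the
#'   position of the allele-A base immediately 5' of the inserted bases.
#' @export
allele_variants <- function(seq_a, seq_b, offset = -nchar(seq_a)) {
  al <- .align_promoters(seq_a, seq_b)
  rel <- function(apos) offset + apos - 1
  n_col <- length(al$al_a)
  events <- list()
  i <- 1L
  while (i <= n_col) {
    a <- al$al_a[i]; b <- al$al_b[i]
    if (a != "-" && b != "-") {
      if (a != b) {
        events[[length(events) + 1L]] <- data.frame(
          position = rel(al$apos[i]), type = "SNP", ref = a, alt = b)
      }
      i <- i + 1L
    } else if (a == "-") {
      j <- i
      while (j < n_col && al$al_a[j + 1L] == "-") j <- j + 1L
      events[[length(events) + 1L]] <- data.frame(
        position = rel(al$apos[i]), type = "insertion", ref = "-",
        alt = paste(al$al_b[i:j], collapse = ""))
      i <- j + 1L
    } else {
      j <- i
      while (j < n_col && al$al_b[j + 1L] == "-") j <- j + 1L
      events[[length(events) + 1L]] <- data.frame(
        position = rel(al$apos[i]), type = "deletion",
        ref = paste(al$al_a[i:j], collapse = ""), alt = "-")
      i <- j + 1L
    }
  }
  if (!length(events)) {
    return(data.frame(position = numeric(0), type = character(0),
                      ref = character(0), alt = character(0)))
  }
  do.call(rbind, events)
}

.motif_hits <- function(seq, motif, offset) {
  s <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(motif), s)
  rev <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)), s)
  df <- rbind(
    data.frame(start = BiocGenerics::start(fwd), end = BiocGenerics::end(fwd),
               strand = rep("+", length(fwd))),
    data.frame(start = BiocGenerics::start(rev), end = BiocGenerics::end(rev),
               strand = rep("-", length(rev))))
  df$rel_start <- offset + df$start - 1
  df$rel_end <- offset + df$end - 1
  df[order(df$start), , drop = FALSE]
}

#' Test promoter alleles for disruption of a literal motif
#'
#' Scans both alleles for exact matches of the motif and of its reverse
#' complement, then tests whether a hit present in one allele has no hit at
#' the homologous location (mapped through the global alignment of the two
#' alleles) in the other. Variants falling inside a lost hit's span are
#' reported as the putative disrupting variants.
#'
#' @param seq_a,seq_b allele A and allele B promoter sequences.
#' @param motif literal DNA motif (length >= 4), e.g. a MADS-box element.
#' @param offset_a,offset_b position of the first base of each allele
#'   relative to its start codon (defaults: promoter ends at -1).
#' @return List with `hits_a`, `hits_b` (data frames: `start`, `end`,
#'   `strand`, `rel_start`, `rel_end`), `disrupted` (logical), `lost`
#'   (hits without a homologous counterpart, with an `allele` column), and
#'   `disrupting_variants` (subset of [allele_variants()] inside lost
#'   hits, on allele-A relative coordinates).
#' @export
motif_disruption <- function(seq_a, seq_b, motif,
                             offset_a = -nchar(seq_a),
                             offset_b = -nchar(seq_b)) {
  stopifnot(nchar(motif) >= 4)
  al <- .align_promoters(seq_a, seq_b)
  hits_a <- .motif_hits(seq_a, motif, offset_a)
  hits_b <- .motif_hits(seq_b, motif, offset_b)
  variants <- allele_variants(seq_a, seq_b, offset = offset_a)
  overlaps <- function(hits, lo, hi) {
    any(hits$start <= hi & hits$end >= lo)
  }
  lost <- list()
  if (nrow(hits_a)) {
    for (i in seq_len(nrow(hits_a))) {
      span_b <- range(al$map_a2b[hits_a$start[i]:hits_a$end[i]])
      if (!overlaps(hits_b, span_b[1], span_b[2])) {
        lost[[length(lost) + 1L]] <- cbind(allele = "B",
                                           hits_a[i, , drop = FALSE])
      }
    }
  }
  if (nrow(hits_b)) {
    for (i in seq_len(nrow(hits_b))) {
      span_a <- range(al$map_b2a[hits_b$start[i]:hits_b$end[i]])
      if (!overlaps(hits_a, span_a[1], span_a[2])) {
        h <- hits_b[i, , drop = FALSE]
        h$start <- span_a[1]; h$end <- span_a[2]
        h$rel_start <- offset_a + span_a[1] - 1
        h$rel_end <- offset_a + span_a[2] - 1
        lost[[length(lost) + 1L]] <- cbind(allele = "A", h)
      }
    }
  }
  lost <- if (length(lost)) do.call(rbind, lost) else
    data.frame(allele = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), rel_start = numeric(0),
               rel_end = numeric(0))
  disrupting <- variants[rep(FALSE, nrow(variants)), , drop = FALSE]
  if (nrow(lost) && nrow(variants)) {
    inside <- vapply(variants$position, function(p) {
      any(p >= lost$rel_start & p <= lost$rel_end)
    }, logical(1))
    disrupting <- variants[inside, , drop = FALSE]
  }
  list(hits_a = hits_a, hits_b = hits_b, disrupted = nrow(lost) > 0,
       lost = lost, disrupting_variants = disrupting)
}
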