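# Expression-side utilities: TPM quantification, DEG set algebra and
# time-course classification, 2^-ddCt relative quantification and
# hypergeometric term enrichment.

# round half up to one decimal (reporting convention for percentages)
.round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Transcripts per million (TPM)
#'
#' TPM_gs = 1e6 (count_gs / length_g) / sum_g (count_gs / length_g);
#' corrects for gene length then sequencing depth, so every sample column
#' sums to one million.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param lengths per-gene effective lengths in bp (> 0), aligned to the
#'   rows of `counts`.
#' @return Matrix of TPM values with the shape of `counts`.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0),
            all(counts >= 0))
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[denom == 0], collapse = ", "))
  }
  sweep(rate, 2, denom / 1e6, `/`)
}

#' Overlap statistics of two DEG sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return List with `n_a`, `n_b`, `n_common`, `pct_a_in_b` (percentage of
#'   A found in B) and `pct_b_not_in_a` (percentage of B absent from A),
#'   percentages rounded half-up to one decimal.
#' @export
deg_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  common <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_common = common,
       pct_a_in_b = if (length(a)) .round1(100 * common / length(a)) else NA,
       pct_b_not_in_a = if (length(b)) {
         .round1(100 * (length(b) - common) / length(b))
       } else NA)
}

#' Classify DE genes by time-course behavior
#'
#' Partitions the genes DE in either the 0h-vs-4h or the 0h-vs-12h contrast:
#' `early-only` (DE at 4 h only), `sustained` (DE at both, same direction),
#' `late-only` (DE at 12 h only), `reversed` (DE at both, opposite
#' directions).
#'
#' @param deg DEG table: data frame with `gene`, `contrast` (`0_4`,
#'   `0_12`, ...), `direction` (`up`/`down`).
#' @return Data frame (`gene`, `class`); every DE gene appears exactly once.
#' @export
classify_timecourse <- function(deg) {
  stopifnot(all(c("gene", "contrast", "direction") %in% names(deg)))
  d4 <- deg[deg$contrast == "0_4", ]
  d12 <- deg[deg$contrast == "0_12", ]
  genes <- union(d4$gene, d12$gene)
  dir4 <- d4$direction[match(genes, d4$gene)]
  dir12 <- d12$direction[match(genes, d12$gene)]
  cls <- ifelse(is.na(dir12), "early-only",
                ifelse(is.na(dir4), "late-only",
                       ifelse(dir4 == dir12, "sustained", "reversed")))
  data.frame(gene = genes, class = cls)
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene between a treated and a calibrator
#' condition, normalized to a reference gene:
#' fold = 2^-[(Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control].
#' Replicate Ct values are averaged per gene and condition.
#'
#' @param ct data frame with `gene`, `condition`, `ct`.
#' @param target target gene id.
#' @param reference reference (housekeeping) gene id.
#' @param treated,control condition labels.
#' @return Fold change (numeric scalar).
#' @export
ddct <- function(ct, target, reference, treated, control) {
  get_ct <- function(g, cond) {
    v <- ct$ct[ct$gene == g & ct$condition == cond]
    if (!length(v)) {
      stop("no Ct for gene '", g, "' in condition '", cond, "'")
    }
    mean(v)
  }
  dct_t <- get_ct(target, treated) - get_ct(reference, treated)
  dct_c <- get_ct(target, control) - get_ct(reference, control)
  2^(-(dct_t - dct_c))
}

#' Hypergeometric term enrichment with BH correction
#'
#' Upper-tail hypergeometric test per term: with a universe of N genes, a
#' query of n and K universe genes annotated to the term, the p-value is
#' P(X >= k) for the observed overlap k. Term-to-gene maps are
#' user-supplied (e.g. GO or KEGG exports); q-values are Benjamini-Hochberg
#' over the tested terms.
#'
#' @param query character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of background gene ids.
#' @param term2gene data frame with columns `term` and `gene`.
#' @return Data frame sorted by `q`: `term`, `n_term` (K), `n_overlap` (k),
#'   `p`, `q`.
#' @export
enrich <- function(query, universe, term2gene) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe)) {
    stop("query contains genes absent from the universe")
  }
  stopifnot(all(c("term", "gene") %in% names(term2gene)))
  t2g <- unique(term2gene[term2gene$gene %in% universe, c("term", "gene")])
  terms <- split(t2g$gene, t2g$term)
  N <- length(universe)
  n <- length(query)
  K <- vapply(terms, length, integer(1))
  k <- vapply(terms, function(g) length(intersect(g, query)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = names(terms), n_term = K, n_overlap = k,
                    p = p, q = q, row.names = NULL)
  out[order(out$q, out$p), ]
}
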