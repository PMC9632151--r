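## Expression normalization, body-site summaries, sample similarity, and
## the generic two-group differential-expression contract.

#' Transcripts-per-million normalization
#'
#' `tpm[i,s] = 1e6 * (counts[i,s]/len[i]) / sum_j(counts[j,s]/len[j])`.
#' Columns with no reads at all stay all-zero.
#'
#' @param counts loci x samples non-negative count matrix.
#' @param effective_length per-locus effective length in bp (> 0),
#'   recycled by row name when named.
#' @return TPM matrix of the same shape; non-zero columns sum to 1e6.
#' @export
compute_tpm <- function(counts, effective_length) {
  if (any(counts < 0)) stop("negative counts")
  if (!is.null(names(effective_length)) && !is.null(rownames(counts)))
    effective_length <- effective_length[rownames(counts)]
  if (any(effective_length <= 0)) stop("effective lengths must be > 0")
  rate <- counts / effective_length
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom == 0, 1, denom), "/") * 1e6
  tpm[, denom == 0] <- 0
  tpm
}

#' Body-site specificity and ubiquity of expression
#'
#' A locus is `site-specific` iff expressed in exactly one body site,
#' `shared` otherwise (among expressed loci); it is flagged ubiquitous
#' iff expressed in at least `ubiquity_min` sites.
#'
#' @param expressed logical matrix, loci x body sites, as returned by
#'   [call_expressed()].
#' @param ubiquity_min site count for the ubiquity flag (default 40).
#' @return `data.frame` with `locus_id`, `n_sites`, `label`
#'   (`"site-specific"`, `"shared"`, or `"silent"`), `ubiquitous`.
#' @export
site_specificity <- function(expressed, ubiquity_min = 40) {
  n_sites <- rowSums(expressed)
  label <- ifelse(n_sites == 1, "site-specific",
                  ifelse(n_sites == 0, "silent", "shared"))
  data.frame(locus_id = rownames(expressed), n_sites = n_sites,
             label = label, ubiquitous = n_sites >= ubiquity_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sample-to-sample distance
#'
#' `d(a, b) = 1 - Spearman correlation` of the two samples' expression
#' profiles (typically `log2(TPM + 1)`).  Ties get average ranks.  A
#' constant column has undefined correlation; it is treated as
#' correlation 0 (distance 1) against every other sample, with a
#' warning.
#'
#' @param expr loci x samples numeric matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
sample_distance <- function(expr) {
  const <- apply(expr, 2, function(x) stats::sd(x) == 0)
  suppressWarnings(rho <- stats::cor(expr, method = "spearman"))
  if (any(const)) {
    warning("constant expression column(s): ",
            paste(colnames(expr)[const], collapse = ", "),
            "; correlation treated as 0")
    rho[const, ] <- 0; rho[, const] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Classical multidimensional scaling of a sample distance matrix
#'
#' @param distance symmetric distance matrix (see [sample_distance()]).
#' @param k embedding dimension (default 2).
#' @return samples x k coordinate matrix.
#' @export
embed_mds <- function(distance, k = 2) {
  if (nrow(distance) < 3) stop("MDS needs at least 3 samples")
  coords <- stats::cmdscale(stats::as.dist(distance), k = k)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  coords
}

#' Two-group differential expression (rank-sum reference engine)
#'
#' The reference engine compares `log2(TPM + 1)` between the two groups
#' with a two-sided Wilcoxon rank-sum test per locus and controls FDR
#' with Benjamini-Hochberg across loci; the log2 fold change is the mean
#' difference of `log2(TPM + 1)` (`group_a` minus `group_b`).  The
#' engine name is recorded in the output so alternative engines can be
#' plugged in behind the same contract.
#'
#' @param tpm loci x samples TPM matrix.
#' @param group_a,group_b disjoint character vectors of sample ids, each
#'   of length >= 2.
#' @return `data.frame` with `locus_id`, `lfc`, `p`, `fdr`, `engine`.
#' @export
pairwise_de <- function(tpm, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  la <- log2(tpm[, group_a, drop = FALSE] + 1)
  lb <- log2(tpm[, group_b, drop = FALSE] + 1)
  n <- nrow(tpm)
  p <- numeric(n); lfc <- numeric(n)
  for (i in seq_len(n)) {
    a <- la[i, ]; b <- lb[i, ]
    lfc[i] <- mean(a) - mean(b)
    if (stats::sd(c(a, b)) == 0) {
      p[i] <- 1
    } else {
      p[i] <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE)$p.value)
      if (is.na(p[i])) p[i] <- 1
    }
  }
  data.frame(locus_id = rownames(tpm), lfc = lfc, p = p,
             fdr = stats::p.adjust(p, "BH"), engine = "ranksum",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Preferentially expressed loci in one body site
#'
#' A locus is preferentially expressed in `site` iff it is expressed
#' there and, against every other site where it is expressed, the
#' two-group test is significant (FDR < `alpha`) with a positive fold
#' change in favour of `site`.
#'
#' @param tpm loci x samples TPM matrix.
#' @param expressed logical loci x sites matrix from [call_expressed()].
#' @param groups named character vector mapping sample id to body site.
#' @param site the focal body site.
#' @param alpha FDR threshold (default 0.05).
#' @return character vector of locus ids.
#' @export
preferential_expression <- function(tpm, expressed, groups, site,
                                    alpha = 0.05) {
  groups <- groups[colnames(tpm)]
  focal <- names(groups)[groups == site]
  cand <- rownames(expressed)[expressed[, site]]
  others <- setdiff(colnames(expressed), site)
  for (o in others) {
    expressed_here <- rownames(expressed)[expressed[, o]]
    test_ids <- intersect(cand, expressed_here)
    if (length(test_ids) == 0) next
    de <- pairwise_de(tpm[test_ids, , drop = FALSE], focal,
                      names(groups)[groups == o])
    ok <- de$locus_id[de$fdr < alpha & de$lfc > 0]
    cand <- setdiff(cand, setdiff(test_ids, ok))
  }
  cand
}
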