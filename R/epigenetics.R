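## TSS-window association of hervRNA expression with histone peaks and
## DNA methylation.

#' Strand-aware transcription start sites of loci
#'
#' The TSS of a `+` locus is the first base of its span; the TSS of a
#' `-` locus is the last base (`end - 1` in 0-based coordinates).
#'
#' @param loci a `herv_loci` object.
#' @return `data.frame` with `locus_id`, `chrom`, `strand`, `tss`.
#' @export
locus_tss <- function(loci) {
  df <- loci$loci
  tss <- vapply(seq_len(nrow(df)), function(i) {
    sp <- blocks_span(df$blocks[i])
    if (df$strand[i] == "-") sp[2] - 1 else sp[1]
  }, numeric(1))
  data.frame(locus_id = df$locus_id, chrom = df$chrom,
             strand = df$strand, tss = tss, stringsAsFactors = FALSE)
}

#' Histone peaks near locus TSSs
#'
#' Flags a (locus, mark, body site, individual) combination iff any
#' peak of that track overlaps the window of `window` bp on either side
#' of the locus TSS (positions `TSS - window .. TSS + window`,
#' inclusive; any overlap counts).
#'
#' @param loci a `herv_loci` object.
#' @param peaks peak table from [read_peaks()] (columns `chrom`,
#'   `start`, `end`, `mark`, `body_site`, `individual`).
#' @param window half-window in bp (default 5000).
#' @return `data.frame` with `locus_id`, `mark`, `body_site`,
#'   `individual`, `flagged`.
#' @export
peaks_near_tss <- function(loci, peaks, window = 5000) {
  tss <- locus_tss(loci)
  tracks <- unique(peaks[, c("mark", "body_site", "individual")])
  out <- list()
  for (t in seq_len(nrow(tracks))) {
    pk <- peaks[peaks$mark == tracks$mark[t] &
                  identical_or_na(peaks$body_site, tracks$body_site[t]) &
                  identical_or_na(peaks$individual, tracks$individual[t]),
                , drop = FALSE]
    flagged <- vapply(seq_len(nrow(tss)), function(i) {
      p <- pk[pk$chrom == tss$chrom[i], , drop = FALSE]
      if (nrow(p) == 0) return(FALSE)
      lo <- tss$tss[i] - window; hi <- tss$tss[i] + window + 1  # half-open
      any(pmin(p$end, hi) - pmax(p$start, lo) > 0)
    }, logical(1))
    out[[t]] <- data.frame(locus_id = tss$locus_id,
                           mark = tracks$mark[t],
                           body_site = tracks$body_site[t],
                           individual = tracks$individual[t],
                           flagged = flagged, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

identical_or_na <- function(x, v) {
  if (is.na(v)) is.na(x) else !is.na(x) & x == v
}

#' Peak-vs-expression association tests
#'
#' For each (mark, body site) cell, compares the expression of flagged
#' vs unflagged loci with a two-sided Wilcoxon rank-sum test; p-values
#' are BH-adjusted across all tested cells.  Cells where either group
#' has fewer than `min_group` loci are skipped.
#'
#' @param expr loci x body-sites expression matrix (e.g., per-site
#'   median `log2(TPM + 1)`).
#' @param flags output of [peaks_near_tss()].
#' @param min_group minimum loci per group (default 3).
#' @return `data.frame` with `mark`, `body_site`, `individual`,
#'   `n_flagged`, `n_unflagged`, `median_diff`, `p`, `fdr`.
#' @export
peak_expression_test <- function(expr, flags, min_group = 3) {
  cells <- unique(flags[, c("mark", "body_site", "individual")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    f <- flags[flags$mark == cells$mark[i] &
                 identical_or_na(flags$body_site, cells$body_site[i]) &
                 identical_or_na(flags$individual, cells$individual[i]),
               , drop = FALSE]
    site <- cells$body_site[i]
    col <- if (!is.na(site) && site %in% colnames(expr)) site else 1
    e <- expr[f$locus_id, col]
    a <- e[f$flagged]; b <- e[!f$flagged]
    if (length(a) < min_group || length(b) < min_group) {
      message("peak_expression_test: cell skipped (group too small): ",
              cells$mark[i], "/", site)
      next
    }
    p <- if (stats::sd(c(a, b)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    rows[[length(rows) + 1]] <-
      data.frame(mark = cells$mark[i], body_site = site,
                 individual = cells$individual[i],
                 n_flagged = length(a), n_unflagged = length(b),
                 median_diff = stats::median(a) - stats::median(b),
                 p = ifelse(is.na(p), 1, p), stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mark = character(0), body_site = character(0),
               individual = character(0), n_flagged = integer(0),
               n_unflagged = integer(0), median_diff = numeric(0),
               p = numeric(0))
  res$fdr <- stats::p.adjust(res$p, "BH")
  res
}

#' DNA methylation level around a TSS
#'
#' Coverage-weighted mean methylation beta over CpG records within
#' `window` bp of the TSS (inclusive on both sides); `NA` when the
#' window contains no record.
#'
#' @param track methylation table from [read_methylation()].
#' @param chrom,tss locus TSS coordinates.
#' @param window half-window in bp (default 5000).
#' @return beta in `[0, 1]`, or `NA`.
#' @export
methylation_level <- function(track, chrom, tss, window = 5000) {
  r <- track[track$chrom == chrom & track$pos >= tss - window &
               track$pos <= tss + window, , drop = FALSE]
  if (nrow(r) == 0 || sum(r$coverage) == 0) return(NA_real_)
  sum(r$beta * r$coverage) / sum(r$coverage)
}

#' Methylation levels for all loci
#' @param track methylation table.
#' @param loci a `herv_loci` object.
#' @param window half-window in bp (default 5000).
#' @return named numeric vector (locus id -> beta).
#' @export
methylation_levels <- function(track, loci, window = 5000) {
  tss <- locus_tss(loci)
  out <- vapply(seq_len(nrow(tss)), function(i)
    methylation_level(track, tss$chrom[i], tss$tss[i], window),
    numeric(1))
  names(out) <- tss$locus_id
  out
}

#' Methylation-vs-expression tests
#'
#' (a) Per body site, compares the methylation of expressed loci
#' (TPM >= `tpm_expressed`) against silent loci (TPM == 0) with a
#' two-sided Wilcoxon rank-sum test; loci with intermediate TPM are
#' excluded.  (b) Per locus, the Pearson correlation between
#' methylation and expression across body sites (>= `min_obs`
#' complete pairs).  Each test family is BH-adjusted separately.
#'
#' @param meth loci x body-sites methylation matrix (may contain `NA`).
#' @param tpm loci x body-sites TPM matrix.
#' @param tpm_expressed expressed threshold (default 0.1).
#' @param min_obs minimum sites for the per-locus correlation (default 3).
#' @return list with `by_site` and `by_locus` data frames.
#' @export
methylation_expression_tests <- function(meth, tpm, tpm_expressed = 0.1,
                                         min_obs = 3) {
  stopifnot(identical(dim(meth), dim(tpm)))
  by_site <- list()
  for (s in colnames(tpm)) {
    expressed <- tpm[, s] >= tpm_expressed
    silent <- tpm[, s] == 0
    a <- meth[expressed, s]; b <- meth[silent, s]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) next
    p <- if (stats::sd(c(a, b)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    by_site[[length(by_site) + 1]] <-
      data.frame(body_site = s, n_expressed = length(a),
                 n_silent = length(b),
                 median_expressed = stats::median(a),
                 median_silent = stats::median(b),
                 p = ifelse(is.na(p), 1, p), stringsAsFactors = FALSE)
  }
  by_site <- if (length(by_site)) do.call(rbind, by_site) else
    data.frame(body_site = character(0), n_expressed = integer(0),
               n_silent = integer(0), median_expressed = numeric(0),
               median_silent = numeric(0), p = numeric(0))
  by_site$fdr <- stats::p.adjust(by_site$p, "BH")
  by_locus <- list()
  for (l in rownames(meth)) {
    ok <- !is.na(meth[l, ]) & !is.na(tpm[l, ])
    if (sum(ok) < min_obs) next
    m <- meth[l, ok]; e <- log2(tpm[l, ok] + 1)
    if (stats::sd(m) == 0 || stats::sd(e) == 0) next
    ct <- stats::cor.test(m, e)
    by_locus[[length(by_locus) + 1]] <-
      data.frame(locus_id = l, r = unname(ct$estimate),
                 p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }
  by_locus <- if (length(by_locus)) do.call(rbind, by_locus) else
    data.frame(locus_id = character(0), r = numeric(0), p = numeric(0),
               n = integer(0))
  by_locus$fdr <- stats::p.adjust(by_locus$p, "BH")
  list(by_site = by_site, by_locus = by_locus)
}
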