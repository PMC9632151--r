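## Presence-aware genotyping, variant QC, TMM and inverse-normal
## normalization, cis-QTL mapping with permutation-based empirical
## p-values, LD utilities, and matched-background enrichment.

#' Presence calls from assembled-contig mapping
#'
#' A locus is present in an individual iff at least one assembled
#' whole-genome contig for that (locus, individual) pair maps uniquely;
#' pairs with no contigs, or only multi-mapping contigs, are absent.
#'
#' @param contig_hits `data.frame` with columns `locus_id`,
#'   `individual_id`, `mapped_uniquely` (logical), one row per contig.
#' @param loci_ids,individual_ids the full sets to enumerate; pairs
#'   without any contig row are called absent.
#' @return `data.frame` with `locus_id`, `individual_id`, `present`.
#' @export
presence_from_contigs <- function(contig_hits, loci_ids, individual_ids) {
  grid <- expand.grid(locus_id = loci_ids, individual_id = individual_ids,
                      stringsAsFactors = FALSE)
  if (nrow(contig_hits)) {
    uniq <- contig_hits[contig_hits$mapped_uniquely, , drop = FALSE]
    key <- paste(uniq$locus_id, uniq$individual_id, sep = "\r")
    grid$present <- paste(grid$locus_id, grid$individual_id,
                          sep = "\r") %in% key
  } else grid$present <- FALSE
  grid
}

#' Mask expression of absent loci
#'
#' Sets the expression of a locus to `NA` in every sample belonging to
#' an individual in which the locus is absent, so that downstream fits
#' behave exactly as if those observations were removed.
#'
#' @param expr loci x samples matrix.
#' @param presence output of [presence_from_contigs()].
#' @param sample_individual named character vector mapping sample id to
#'   individual id.
#' @return the masked matrix.
#' @export
mask_expression <- function(expr, presence, sample_individual) {
  absent <- presence[!presence$present, , drop = FALSE]
  for (i in seq_len(nrow(absent))) {
    lid <- absent$locus_id[i]
    if (!lid %in% rownames(expr)) next
    cols <- names(sample_individual)[sample_individual ==
                                       absent$individual_id[i]]
    cols <- intersect(cols, colnames(expr))
    expr[lid, cols] <- NA
  }
  expr
}

hwe_pvalue <- function(d) {
  d <- d[!is.na(d)]
  obs <- c(sum(d == 0), sum(d == 1), sum(d == 2))
  n <- sum(obs)
  if (n == 0) return(NA_real_)
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (any(e == 0)) return(1)
  chisq <- sum((obs - e)^2 / e)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Variant quality control
#'
#' Keeps a variant iff its missing fraction is below `max_missing`, its
#' minor allele frequency is at least `min_maf`, and its Hardy-Weinberg
#' chi-square (1 df) p-value is at least `hwe_alpha`.
#'
#' @param g a `genotype_study`.
#' @param max_missing maximum missing fraction (strict `<`; default 0.05).
#' @param min_maf minimum MAF (default 0.01).
#' @param hwe_alpha HWE p-value floor (default 1e-6).
#' @return character vector of retained variant ids.
#' @export
variant_qc <- function(g, max_missing = 0.05, min_maf = 0.01,
                       hwe_alpha = 1e-6) {
  if (length(g$individuals) < 10) stop("variant QC needs >= 10 individuals")
  miss <- rowMeans(is.na(g$dosage))
  maf <- apply(g$dosage, 1, dosage_maf)
  hwe <- apply(g$dosage, 1, hwe_pvalue)
  keep <- miss < max_missing & !is.na(maf) & maf >= min_maf &
    !is.na(hwe) & hwe >= hwe_alpha
  rownames(g$dosage)[keep]
}

#' Per-body-site variant filter
#'
#' Keeps a variant iff its minor allele is carried by at least
#' `min_minor_carriers` samples and its MAF is at least `min_maf`.
#'
#' @param g a `genotype_study` restricted to the site's individuals.
#' @param min_minor_carriers carrier-count threshold (default 10).
#' @param min_maf MAF threshold (default 0.01).
#' @return character vector of retained variant ids.
#' @export
site_variant_filter <- function(g, min_minor_carriers = 10,
                                min_maf = 0.01) {
  keep <- apply(g$dosage, 1, function(d) {
    dd <- d[!is.na(d)]
    if (length(dd) == 0) return(FALSE)
    af <- sum(dd) / (2 * length(dd))
    carriers <- if (af <= 0.5) sum(dd >= 1) else sum(dd <= 1)
    maf <- min(af, 1 - af)
    carriers >= min_minor_carriers && maf >= min_maf
  })
  rownames(g$dosage)[keep]
}

#' Subset a genotype study by variants and/or individuals
#' @param g a `genotype_study`.
#' @param variant_ids,individual_ids subsets to keep (NULL = all).
#' @return the subsetted `genotype_study`.
#' @export
subset_genotypes <- function(g, variant_ids = NULL, individual_ids = NULL) {
  if (!is.null(variant_ids)) {
    idx <- match(variant_ids, rownames(g$dosage))
    g$dosage <- g$dosage[idx, , drop = FALSE]
    g$variants <- g$variants[idx, , drop = FALSE]
  }
  if (!is.null(individual_ids)) {
    g$dosage <- g$dosage[, individual_ids, drop = FALSE]
    g$individuals <- individual_ids
    g$variants$maf <- apply(g$dosage, 1, dosage_maf)
  }
  g
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample composition normalization: the reference sample is the
#' one whose upper-quartile (of library-size-scaled counts) is closest
#' to the mean upper-quartile; each sample's factor is `2^f` where `f`
#' is the precision-weighted mean of the log2 expression ratios (M)
#' against the reference after trimming the top and bottom 30% of M and
#' 5% of A values; genes with a zero count in either sample of a pair
#' are excluded; the factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @param logratio_trim,sum_trim trim fractions (defaults 0.3, 0.05).
#' @return named numeric vector of scaling factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample column")
  f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  r <- counts[, ref]; libr <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(0)
    x <- counts[, s]; libx <- lib[s]
    pos <- x > 0 & r > 0
    if (!any(pos)) return(0)
    xp <- x[pos]; rp <- r[pos]
    M <- log2((xp / libx) / (rp / libr))
    A <- 0.5 * log2((xp / libx) * (rp / libr))
    # precision weights: inverse asymptotic variance of M (delta method)
    w <- 1 / ((libx - xp) / (libx * xp) + (libr - rp) / (libr * rp))
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep) || sum(w[keep]) == 0) return(0)
    sum(w[keep] * M[keep]) / sum(w[keep])
  }, numeric(1))
  fac <- 2^f
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(counts)
  fac
}

#' Rank-based inverse normal transform
#'
#' Maps each non-missing value to `qnorm((rank - 0.5) / n)` with average
#' ranks for ties; missing values are preserved.  A constant vector
#' maps to all zeros with a warning.
#'
#' @param x numeric vector (one locus across samples).
#' @return transformed vector of the same length.
#' @export
inverse_normal <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 3) stop("inverse normal transform needs >= 3 values")
  if (length(unique(v)) == 1)
    warning("constant input to inverse normal transform; all map to 0")
  out <- x
  out[ok] <- stats::qnorm((rank(v) - 0.5) / length(v))
  out
}

#' Row-wise inverse normal transform of an expression matrix
#' @param expr loci x samples matrix (may contain `NA`).
#' @return matrix of the same shape.
#' @export
inverse_normal_matrix <- function(expr) {
  t(apply(expr, 1, inverse_normal))
}

#' Squared genotype correlation between two variants
#'
#' Pearson r-squared over complete pairs; 0 (with a message) when either
#' vector is constant.
#'
#' @param d1,d2 dosage vectors.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(d1, d2) {
  ok <- !is.na(d1) & !is.na(d2)
  if (sum(ok) < 3) stop("ld_r2 needs >= 3 complete pairs")
  a <- d1[ok]; b <- d2[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    message("constant dosage vector; r2 defined as 0")
    return(0)
  }
  stats::cor(a, b)^2
}

#' Window-based LD pruning
#'
#' Slides a window of `window` variants in steps of `step` along each
#' chromosome (variants in position order) and greedily drops the
#' later-positioned variant of any remaining pair with `r2 > r2_max`.
#'
#' @param g a `genotype_study`.
#' @param window window size in variants (default 200).
#' @param step step size in variants (default 100).
#' @param r2_max r-squared ceiling (default 0.2).
#' @return character vector of kept variant ids.
#' @export
prune_ld <- function(g, window = 200, step = 100, r2_max = 0.2) {
  kept <- character(0)
  for (chrom in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chrom)
    idx <- idx[order(g$variants$pos[idx])]
    alive <- rep(TRUE, length(idx))
    starts <- seq(1, max(1, length(idx)), by = step)
    for (w0 in starts) {
      w <- seq(w0, min(w0 + window - 1, length(idx)))
      for (ii in seq_along(w)) {
        if (!alive[w[ii]]) next
        for (jj in seq_len(ii - 1L)) {
          if (!alive[w[jj]]) next
          r2 <- tryCatch(
            suppressMessages(ld_r2(g$dosage[idx[w[jj]], ],
                                   g$dosage[idx[w[ii]], ])),
            error = function(e) 0)
          if (r2 > r2_max) { alive[w[ii]] <- FALSE; break }
        }
      }
      if (w0 + window - 1 >= length(idx)) break
    }
    kept <- c(kept, rownames(g$dosage)[idx[alive]])
  }
  kept
}

#' Genotype principal components
#'
#' Top-k principal components of the centered, mean-imputed dosage
#' matrix (individuals in rows).  Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is made
#' positive.
#'
#' @param g a `genotype_study` (ideally LD-pruned).
#' @param k number of components (default 3).
#' @return individuals x k score matrix.
#' @export
genotype_pcs <- function(g, k = 3) {
  X <- t(g$dosage)  # individuals x variants
  for (j in seq_len(ncol(X))) {
    m <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- m
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k >= rank) stop("k must be < rank of the dosage matrix (", rank, ")")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- g$individuals
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Hidden-factor count schedule
#'
#' Number of expression hidden factors as a function of sample size:
#' 15 for n < 150, 30 for 150 <= n < 250, 45 for 250 <= n < 350, 60 for
#' n >= 350.
#'
#' @param n sample count.
#' @return factor count.
#' @export
factor_count_schedule <- function(n) {
  if (n < 150) 15L else if (n < 250) 30L else if (n < 350) 45L else 60L
}

#' Expression hidden factors
#'
#' Top-k principal components of the sample-space expression matrix, a
#' stand-in for latent-factor methods behind the same covariate
#' contract.  `k` defaults to [factor_count_schedule()] of the sample
#' count and is clipped to `n - 1` with a warning when too large.
#'
#' @param expr loci x samples matrix (typically log2(TPM+1)).
#' @param k factor count (default from the schedule).
#' @return samples x k factor matrix.
#' @export
hidden_factors <- function(expr, k = factor_count_schedule(ncol(expr))) {
  n <- ncol(expr)
  if (k >= n) {
    warning("factor count ", k, " clipped to n - 1 = ", n - 1)
    k <- n - 1L
  }
  X <- t(expr)
  X[is.na(X)] <- mean(X, na.rm = TRUE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("F", seq_len(k))
  scores
}

## residualize columns of Y on covariate matrix C (intercept added)
residualize <- function(Y, C) {
  Y <- as.matrix(Y)
  D <- cbind(Intercept = rep(1, nrow(Y)), C)
  qr_d <- qr(D)
  Y - D %*% qr.coef(qr_d, Y)
}

#' Nominal cis-QTL scan
#'
#' For every (locus, variant) pair with the variant within `window` bp
#' of the locus TSS: residualize both the inverse-normal expression and
#' the dosage on the covariates, then take the least-squares slope of
#' the expression residual on the dosage residual.  The two-sided t
#' p-value uses `n - n_cov - 2` degrees of freedom (Frisch-Waugh
#' equivalence with the full multiple regression).  Pairs with fewer
#' than `min_obs` complete observations, or degenerate dosage, are
#' skipped with a reason.
#'
#' @param expr loci x individuals matrix on the inverse-normal scale
#'   (`NA` = masked/absent).
#' @param g a `genotype_study` over the same individuals.
#' @param covariates individuals x c numeric matrix (may be NULL).
#' @param loci_tss `data.frame` with `locus_id`, `chrom`, `tss`.
#' @param window cis window in bp from the TSS (default 1e6).
#' @param min_obs minimum complete observations per fit (default 20).
#' @return `data.frame` with `locus_id`, `variant_id`, `beta`, `se`,
#'   `p_nominal`; skipped pairs in `attr(, "skipped")`.
#' @export
cis_scan <- function(expr, g, covariates = NULL, loci_tss,
                     window = 1e6, min_obs = 20) {
  indiv <- g$individuals
  stopifnot(all(indiv %in% colnames(expr)))
  out <- list(); skipped <- list()
  for (i in seq_len(nrow(loci_tss))) {
    lid <- loci_tss$locus_id[i]
    if (!lid %in% rownames(expr)) next
    vsel <- which(g$variants$chrom == loci_tss$chrom[i] &
                    abs(g$variants$pos - loci_tss$tss[i]) <= window)
    if (length(vsel) == 0) next
    y_all <- expr[lid, indiv]
    for (v in vsel) {
      d <- g$dosage[v, ]
      ok <- !is.na(y_all) & !is.na(d)
      n <- sum(ok)
      if (n < min_obs) {
        skipped[[length(skipped) + 1]] <-
          data.frame(locus_id = lid,
                     variant_id = g$variants$variant_id[v],
                     reason = "too_few_obs")
        next
      }
      C <- if (is.null(covariates)) NULL else
        covariates[indiv, , drop = FALSE][ok, , drop = FALSE]
      yr <- residualize(y_all[ok], C)
      gr <- residualize(d[ok], C)
      sxx <- sum(gr^2)
      if (sxx < 1e-12) {
        skipped[[length(skipped) + 1]] <-
          data.frame(locus_id = lid,
                     variant_id = g$variants$variant_id[v],
                     reason = "degenerate_design")
        next
      }
      beta <- sum(gr * yr) / sxx
      df <- n - (if (is.null(C)) 0 else ncol(C)) - 2
      rss <- sum((yr - beta * gr)^2)
      se <- sqrt(rss / df / sxx)
      tval <- beta / se
      out[[length(out) + 1]] <-
        data.frame(locus_id = lid, variant_id = g$variants$variant_id[v],
                   beta = beta, se = se,
                   p_nominal = 2 * stats::pt(-abs(tval), df),
                   stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), variant_id = character(0),
               beta = numeric(0), se = numeric(0), p_nominal = numeric(0))
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else NULL
  res
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutation pass of the cis scan
#'
#' Per locus, the test statistic is the minimum nominal p over cis
#' variants (equivalently the maximum absolute partial correlation).
#' Sample labels of the residualized expression are permuted `n_perm`
#' times and the empirical p-value is the add-one rank
#' `(1 + #\{perm min-p <= observed\}) / (1 + n_perm)`; with
#' `exhaustive = TRUE` all `n!` permutations (identity included) are
#' enumerated and the empirical p is the exact rank
#' `#\{perm min-p <= observed\} / n!`.  Missing dosages are mean-imputed
#' within the locus so that every cis variant shares one complete
#' design; individuals with masked (absent) expression are dropped.
#'
#' @param expr,g,covariates,loci_tss,window as in [cis_scan()].
#' @param n_perm number of permutations (default 1000; a warning is
#'   issued below 100).
#' @param seed integer seed for the permutation draws.
#' @param exhaustive enumerate all permutations (requires <= 8
#'   individuals).
#' @param alpha level at which the per-locus nominal threshold is
#'   interpolated (default 0.05).
#' @return `data.frame` with `locus_id`, `n_variants`, `best_variant`,
#'   `beta`, `p_nominal_best`, `p_perm`, `nominal_threshold`.
#' @export
permutation_pass <- function(expr, g, covariates = NULL, loci_tss,
                             window = 1e6, n_perm = 1000, seed = 1,
                             exhaustive = FALSE, alpha = 0.05) {
  if (!exhaustive && n_perm < 100)
    warning("n_perm < 100 gives a coarse empirical p-value")
  indiv <- g$individuals
  rng <- local_rng(seed)
  on.exit(rng$restore())
  out <- list()
  for (i in seq_len(nrow(loci_tss))) {
    lid <- loci_tss$locus_id[i]
    if (!lid %in% rownames(expr)) next
    vsel <- which(g$variants$chrom == loci_tss$chrom[i] &
                    abs(g$variants$pos - loci_tss$tss[i]) <= window)
    if (length(vsel) == 0) next
    y <- expr[lid, indiv]
    ok <- !is.na(y)
    n <- sum(ok)
    if (n < 5) next
    G <- t(g$dosage[vsel, ok, drop = FALSE])  # n x m
    for (j in seq_len(ncol(G))) {
      m <- mean(G[, j], na.rm = TRUE)
      G[is.na(G[, j]), j] <- m
    }
    C <- if (is.null(covariates)) NULL else
      covariates[indiv, , drop = FALSE][ok, , drop = FALSE]
    yr <- drop(residualize(y[ok], C))
    Gr <- residualize(G, C)
    sdG <- apply(Gr, 2, stats::sd)
    keepv <- sdG > 1e-10
    if (!any(keepv)) next
    Gr <- Gr[, keepv, drop = FALSE]
    vsel <- vsel[keepv]
    Gn <- scale(Gr)  # unit-variance columns, mean 0
    df <- n - (if (is.null(C)) 0 else ncol(C)) - 2
    abscor_to_p <- function(r2) {
      r2 <- pmin(r2, 1 - 1e-12)
      tval <- sqrt(r2 * df / (1 - r2))
      2 * stats::pt(-tval, df)
    }
    yn <- (yr - mean(yr)) / stats::sd(yr)
    obs_r <- abs(crossprod(Gn, yn) / (n - 1))
    obs_max <- max(obs_r)
    best <- which.max(obs_r)
    perm_idx <- if (exhaustive) {
      if (n > 8) stop("exhaustive enumeration limited to <= 8 samples")
      t(all_permutations(n))
    } else {
      vapply(seq_len(n_perm), function(p) sample.int(n), integer(n))
    }
    Yp <- matrix(yn[perm_idx], nrow = n)
    perm_max <- apply(abs(crossprod(Gn, Yp) / (n - 1)), 2, max)
    # count ties as exceedances, robust to float noise in the statistic
    n_ge <- sum(perm_max >= obs_max - 1e-12)
    if (exhaustive) {
      p_perm <- n_ge / ncol(perm_idx)
    } else {
      p_perm <- (1 + n_ge) / (1 + n_perm)
    }
    # nominal threshold: perm quantile of min-p achieving empirical p = alpha
    perm_minp <- abscor_to_p(perm_max^2)
    kstar <- alpha * (1 + length(perm_minp)) - 1
    thr <- if (kstar < 0) 0 else
      unname(stats::quantile(perm_minp, probs = kstar / length(perm_minp),
                             type = 7))
    # observed beta of the best variant on the residualized scale
    beta <- sum(Gr[, best] * yr) / sum(Gr[, best]^2)
    out[[length(out) + 1]] <- data.frame(
      locus_id = lid, n_variants = ncol(Gn),
      best_variant = g$variants$variant_id[vsel[best]],
      beta = beta,
      p_nominal_best = abscor_to_p(obs_max^2),
      p_perm = p_perm, nominal_threshold = thr,
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), n_variants = integer(0),
               best_variant = character(0), beta = numeric(0),
               p_nominal_best = numeric(0), p_perm = numeric(0),
               nominal_threshold = numeric(0))
}

#' Call eHERVs from permutation p-values
#'
#' Benjamini-Hochberg adjustment of the empirical permutation p-values
#' across loci; a locus is an eHERV iff its adjusted value is at most
#' `alpha`.
#'
#' @param perm output of [permutation_pass()].
#' @param alpha FDR level (default 0.05).
#' @return `perm` with added `fdr` and `is_eherv` columns.
#' @export
call_ehervs <- function(perm, alpha = 0.05) {
  perm$fdr <- stats::p.adjust(perm$p_perm, "BH")
  perm$is_eherv <- perm$fdr <= alpha
  perm
}

#' Matched background variant set
#'
#' Matches each target variant to one pool variant from the same
#' chromosome, the same MAF quantile bin, and the same
#' `log10(1 + TSS distance)` quantile bin, sampling without
#' replacement.  Empty bins fall back to the nearest non-empty bin on
#' the same chromosome (logged); targets that cannot be matched at all
#' are dropped from both sets.
#'
#' @param targets,pool `data.frame`s with `variant_id`, `chrom`, `pos`,
#'   `maf`; the pool must exclude the targets.
#' @param tss_positions numeric vector of TSS positions for the distance
#'   covariate.
#' @param n_bins_maf,n_bins_dist quantile bin counts (defaults 20).
#' @param seed integer seed.
#' @return list with `matched` (`data.frame` `target_id`, `matched_id`),
#'   `unmatched` (character vector of dropped target ids).
#' @export
matched_background <- function(targets, pool, tss_positions,
                               n_bins_maf = 20, n_bins_dist = 20,
                               seed = 1) {
  if (any(targets$variant_id %in% pool$variant_id))
    stop("pool must exclude the target variants")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  qbreaks <- function(x, k) {
    b <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1)))
    if (length(b) < 2) b <- c(min(x) - 1, max(x) + 1)
    b[1] <- -Inf; b[length(b)] <- Inf
    b
  }
  all_maf <- c(targets$maf, pool$maf)
  dist_t <- log10(1 + nearest_tss_distance(targets$pos, tss_positions))
  dist_p <- log10(1 + nearest_tss_distance(pool$pos, tss_positions))
  bm <- qbreaks(c(all_maf), n_bins_maf)
  bd <- qbreaks(c(dist_t, dist_p), n_bins_dist)
  t_m <- as.integer(cut(targets$maf, bm)); t_d <- as.integer(cut(dist_t, bd))
  p_m <- as.integer(cut(pool$maf, bm)); p_d <- as.integer(cut(dist_p, bd))
  used <- rep(FALSE, nrow(pool))
  matched <- character(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    cand <- which(!used & pool$chrom == targets$chrom[i] &
                    p_m == t_m[i] & p_d == t_d[i])
    if (length(cand) == 0) {
      # fall back to the nearest non-empty bin on the same chromosome
      onchrom <- which(!used & pool$chrom == targets$chrom[i])
      if (length(onchrom) == 0) { matched[i] <- NA_character_; next }
      bin_dist <- abs(p_m[onchrom] - t_m[i]) + abs(p_d[onchrom] - t_d[i])
      cand <- onchrom[bin_dist == min(bin_dist)]
      message("matched_background: fallback bin for target ",
              targets$variant_id[i])
    }
    pick <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    used[pick] <- TRUE
    matched[i] <- pool$variant_id[pick]
  }
  ok <- !is.na(matched)
  list(matched = data.frame(target_id = targets$variant_id[ok],
                            matched_id = matched[ok],
                            stringsAsFactors = FALSE),
       unmatched = targets$variant_id[!ok])
}

#' Category enrichment of a variant set against a matched background
#'
#' Per category, a 2x2 table (in/out of category x target/background) is
#' tested with a two-tailed Fisher exact test; the reported odds ratio
#' is the sample cross-product `ad/bc` (with 0.5 added to every cell
#' when any cell is zero).  P-values are BH-adjusted across categories.
#' Categories listed in `drop_categories` are removed before testing;
#' categories absent from both sets are skipped.
#'
#' @param targets,background character vectors of variant ids (disjoint).
#' @param annotation `data.frame` with `variant_id`, `category` (a
#'   variant may carry several categories).
#' @param drop_categories categories to remove before testing.
#' @return `data.frame` with `category`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `fdr`.
#' @export
enrichment_test <- function(targets, background, annotation,
                            drop_categories = c("ncRNA_splicing",
                                                "splicing", "stopgain",
                                                "stoploss")) {
  if (length(intersect(targets, background)) > 0)
    stop("target and background sets must be disjoint")
  ann <- annotation[!annotation$category %in% drop_categories, ,
                    drop = FALSE]
  cats <- sort(unique(ann$category))
  rows <- list()
  for (cc in cats) {
    inset <- unique(ann$variant_id[ann$category == cc])
    a <- sum(targets %in% inset); b <- length(targets) - a
    c2 <- sum(background %in% inset); d <- length(background) - c2
    if (a + c2 == 0) next
    p <- stats::fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE),
                            alternative = "two.sided")$p.value
    tab <- c(a, b, c2, d)
    if (any(tab == 0)) tab <- tab + 0.5
    or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
    rows[[length(rows) + 1]] <- data.frame(category = cc, a = a, b = b,
                                           c = c2, d = d,
                                           odds_ratio = or, p = p,
                                           stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), a = integer(0), b = integer(0),
               c = integer(0), d = integer(0), odds_ratio = numeric(0),
               p = numeric(0))
  res$fdr <- stats::p.adjust(res$p, "BH")
  res
}

#' Expand genome-wide significant GWAS hits by LD
#'
#' Filters hits at `p < p_thresh` (strict) and returns the union of the
#' filtered hits and every panel variant with `r2 > r2_thresh` to any
#' hit.  Hits absent from the genotype panel are kept without expansion
#' (logged).
#'
#' @param gwas_hits `data.frame` with `variant_id`, `p`.
#' @param g a `genotype_study` providing the LD panel.
#' @param p_thresh significance threshold (default 5e-8).
#' @param r2_thresh LD threshold (default 0.8).
#' @return character vector of variant ids.
#' @export
expand_gwas_ld <- function(gwas_hits, g, p_thresh = 5e-8,
                           r2_thresh = 0.8) {
  hits <- gwas_hits$variant_id[gwas_hits$p < p_thresh]
  out <- hits
  for (h in hits) {
    row <- match(h, rownames(g$dosage))
    if (is.na(row)) {
      message("GWAS hit not in genotype panel, kept unexpanded: ", h)
      next
    }
    chrom <- g$variants$chrom[row]
    others <- which(g$variants$chrom == chrom)
    others <- setdiff(others, row)
    for (o in others) {
      r2 <- tryCatch(
        suppressMessages(ld_r2(g$dosage[row, ], g$dosage[o, ])),
        error = function(e) 0)
      if (r2 > r2_thresh) out <- c(out, rownames(g$dosage)[o])
    }
  }
  sort(unique(out))
}
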