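## Biological-factor analyses: per-site sex/ethnicity differential
## expression, per-site age correlation, and a global linear mixed model
## H_ijk = site_i + individual_j(random) + factor_k + error for loci
## observed across many body sites.

#' Sex-specific body sites excluded from sex analyses by default
#' @export
SEX_SPECIFIC_SITES <- c("ovary", "prostate", "testis", "uterus", "vagina")

#' Per-body-site factor differential expression
#'
#' Runs the two-group expression contract ([pairwise_de()]) between the
#' two levels of `factor` within each body site; FDR is controlled per
#' site.  For sex, sex-specific body sites are excluded by default.
#' Sites where either level has fewer than 2 samples are skipped with a
#' message.
#'
#' @param tpm loci x samples TPM matrix.
#' @param meta sample metadata (see [read_sample_meta()]).
#' @param factor `"sex"` or `"ethnicity"`.
#' @param exclude_sites body sites to skip (default:
#'   [SEX_SPECIFIC_SITES] when `factor == "sex"`, none otherwise).
#' @return `data.frame` with `locus_id`, `body_site`, `level_a`,
#'   `level_b`, `lfc` (a minus b), `p`, `fdr`.
#' @export
per_site_factor_de <- function(tpm, meta, factor = c("sex", "ethnicity"),
                               exclude_sites = NULL) {
  factor <- match.arg(factor)
  if (is.null(exclude_sites) && factor == "sex")
    exclude_sites <- SEX_SPECIFIC_SITES
  meta <- meta[meta$sample_id %in% colnames(tpm), , drop = FALSE]
  out <- list()
  for (s in setdiff(sort(unique(meta$body_site)), exclude_sites)) {
    m <- meta[meta$body_site == s, , drop = FALSE]
    levs <- sort(unique(m[[factor]]))
    if (length(levs) != 2) {
      message("per_site_factor_de: site skipped (needs 2 levels): ", s)
      next
    }
    ga <- m$sample_id[m[[factor]] == levs[1]]
    gb <- m$sample_id[m[[factor]] == levs[2]]
    if (length(ga) < 2 || length(gb) < 2) {
      message("per_site_factor_de: site skipped (level too small): ", s)
      next
    }
    de <- pairwise_de(tpm[, m$sample_id, drop = FALSE], ga, gb)
    de$body_site <- s; de$level_a <- levs[1]; de$level_b <- levs[2]
    out[[length(out) + 1]] <-
      de[, c("locus_id", "body_site", "level_a", "level_b", "lfc", "p",
             "fdr")]
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), body_site = character(0),
               level_a = character(0), level_b = character(0),
               lfc = numeric(0), p = numeric(0), fdr = numeric(0))
}

#' Per-body-site age correlation
#'
#' Pearson correlation between `log2(TPM + 1)` and age, per locus within
#' each body site with at least `min_n` aged samples; BH per site;
#' FDR-significant records get a direction label.
#'
#' @param tpm loci x samples TPM matrix.
#' @param meta sample metadata.
#' @param min_n minimum samples per site (default 10).
#' @param alpha FDR level for the direction label (default 0.05).
#' @return `data.frame` with `locus_id`, `body_site`, `r`, `p`, `fdr`,
#'   `direction` (`"increasing"`, `"decreasing"` or `NA`).
#' @export
age_correlation <- function(tpm, meta, min_n = 10, alpha = 0.05) {
  meta <- meta[meta$sample_id %in% colnames(tpm) & !is.na(meta$age), ,
               drop = FALSE]
  out <- list()
  for (s in sort(unique(meta$body_site))) {
    m <- meta[meta$body_site == s, , drop = FALSE]
    if (nrow(m) < min_n) next
    e <- log2(tpm[, m$sample_id, drop = FALSE] + 1)
    rows <- list()
    for (l in rownames(e)) {
      if (stats::sd(e[l, ]) == 0) next
      ct <- stats::cor.test(e[l, ], m$age)
      rows[[length(rows) + 1]] <-
        data.frame(locus_id = l, body_site = s, r = unname(ct$estimate),
                   p = ct$p.value, stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    df <- do.call(rbind, rows)
    df$fdr <- stats::p.adjust(df$p, "BH")
    df$direction <- ifelse(df$fdr < alpha,
                           ifelse(df$r > 0, "increasing", "decreasing"),
                           NA_character_)
    out[[length(out) + 1]] <- df
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character(0), body_site = character(0),
               r = numeric(0), p = numeric(0), fdr = numeric(0),
               direction = character(0))
}

#' Global linear mixed model for one locus
#'
#' Fits `value ~ body_site + factor + (1 | individual)` by maximum
#' likelihood and tests the factor term with a likelihood-ratio test
#' against the nested model without it.  Sex and ethnicity enter as
#' fixed factors; age as a numeric covariate.
#'
#' @param df long `data.frame` with columns `value`, `body_site`,
#'   `individual`, and the factor column.
#' @param factor name of the factor column.
#' @return list with `estimate`, `se`, `p`, `singular`, `n_sites`,
#'   `n_individuals`.
#' @export
fit_global_lmm <- function(df, factor) {
  df$body_site <- base::factor(df$body_site)
  df$individual <- base::factor(df$individual)
  if (!is.numeric(df[[factor]])) df[[factor]] <- base::factor(df[[factor]])
  full_f <- stats::as.formula(paste("value ~ body_site +", factor,
                                    "+ (1 | individual)"))
  null_f <- stats::as.formula("value ~ body_site + (1 | individual)")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- suppressMessages(lme4::lmer(full_f, data = df, REML = FALSE,
                                      control = ctrl))
  null <- suppressMessages(lme4::lmer(null_f, data = df, REML = FALSE,
                                      control = ctrl))
  lrt <- 2 * (stats::logLik(full) - stats::logLik(null))
  dfree <- attr(stats::logLik(full), "df") - attr(stats::logLik(null), "df")
  p <- stats::pchisq(max(0, as.numeric(lrt)), df = dfree,
                     lower.tail = FALSE)
  co <- summary(full)$coefficients
  term_rows <- grep(paste0("^", factor), rownames(co))
  est <- co[term_rows[1], "Estimate"]
  se <- co[term_rows[1], "Std. Error"]
  list(estimate = unname(est), se = unname(se), p = p,
       singular = lme4::isSingular(full),
       n_sites = length(unique(df$body_site)),
       n_individuals = length(unique(df$individual)))
}

#' Global factor effects across body sites
#'
#' Applies [fit_global_lmm()] to every locus observed in at least
#' `min_sites` body sites with at least 2 individuals per factor level,
#' on the `log2(TPM + 1)` scale, and BH-adjusts the likelihood-ratio
#' p-values across loci.  Singular fits are flagged, not dropped.
#'
#' @param tpm loci x samples TPM matrix.
#' @param meta sample metadata.
#' @param factor `"sex"`, `"ethnicity"`, or `"age"`.
#' @param min_sites minimum body sites per locus (default 6).
#' @return `data.frame` with `locus_id`, `estimate`, `se`, `p`, `fdr`,
#'   `n_sites`, `n_individuals`, `singular`.
#' @export
global_factor_lmm <- function(tpm, meta, factor, min_sites = 6) {
  meta <- meta[meta$sample_id %in% colnames(tpm), , drop = FALSE]
  rows <- list()
  for (l in rownames(tpm)) {
    df <- data.frame(value = log2(tpm[l, meta$sample_id] + 1),
                     body_site = meta$body_site,
                     individual = meta$individual_id,
                     stringsAsFactors = FALSE)
    df[[factor]] <- meta[[factor]]
    df <- df[!is.na(df$value) & !is.na(df[[factor]]), , drop = FALSE]
    if (length(unique(df$body_site)) < min_sites) next
    if (!is.numeric(df[[factor]])) {
      tab <- table(unique(df[, c("individual", factor)])[[factor]])
      if (length(tab) < 2 || any(tab < 2)) next
    }
    fit <- tryCatch(fit_global_lmm(df, factor), error = function(e) NULL)
    if (is.null(fit)) {
      message("global_factor_lmm: fit failed for ", l)
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(locus_id = l, estimate = fit$estimate, se = fit$se,
                 p = fit$p, n_sites = fit$n_sites,
                 n_individuals = fit$n_individuals,
                 singular = fit$singular, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), estimate = numeric(0),
               se = numeric(0), p = numeric(0), n_sites = integer(0),
               n_individuals = integer(0), singular = logical(0))
  res$fdr <- stats::p.adjust(res$p, "BH")
  res
}
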