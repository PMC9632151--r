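## Seeded generators for every input the pipeline consumes, with
## machine-readable truth for parameter-recovery and classification
## tests.  Geometry is fully deterministic given the configuration;
## randomness (counts, genotypes, noise) is confined to seeded draws.

#' Simulation configuration
#'
#' Defaults describe the fixture used throughout the test suite: one toy
#' chromosome carrying 12 planted loci (3 per origin class, locations
#' cycling through intergenic/antisense/inserted, the three full-length
#' structural subtypes) and 10 decoys that each violate exactly one
#' detection gate, observed in 8 samples.
#'
#' @param seed integer seed fixing every random draw.
#' @param n_samples samples per body site (default 8).
#' @param frac_present fraction of samples in which a planted locus is
#'   observed (default 0.75).
#' @param support_count,identity read support and alignment identity of
#'   planted transcripts (defaults 20 and 0.99).
#' @param base_mean,dispersion negative-binomial mean and size for
#'   expressed loci (defaults 50 and 10).
#' @param sex_delta planted sex effect, log2 units (default 1).
#' @param age_slope planted age slope, log2 units per year (default 0.02).
#' @param qtl_beta planted additive cis effect, inverse-normal-sd units
#'   per alt allele (default 1).
#' @param qtl_maf MAF of planted causal variants (default 0.3).
#' @param peak_p_active,peak_p_background peak placement probabilities
#'   near high- vs low-expression loci (defaults 0.9, 0.1).
#' @param methylation_diff planted methylation difference, expressed
#'   minus silent (default 0.15).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_samples = 8, frac_present = 0.75,
                       support_count = 20, identity = 0.99,
                       base_mean = 50, dispersion = 10,
                       sex_delta = 1, age_slope = 0.02,
                       qtl_beta = 1, qtl_maf = 0.3,
                       peak_p_active = 0.9, peak_p_background = 0.1,
                       methylation_diff = 0.15) {
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 frac_present = frac_present,
                 support_count = support_count, identity = identity,
                 base_mean = base_mean, dispersion = dispersion,
                 sex_delta = sex_delta, age_slope = age_slope,
                 qtl_beta = qtl_beta, qtl_maf = qtl_maf,
                 peak_p_active = peak_p_active,
                 peak_p_background = peak_p_background,
                 methylation_diff = methylation_diff),
            class = "sim_config")
}

## planted design: one 30-kb tile per slot on a single toy chromosome
planted_design <- function() {
  origins <- c(rep("solo-LTR", 3), rep("truncated", 3),
               rep("chimeric", 3), rep("full-length", 3))
  locations <- rep(c("intergenic", "antisense", "inserted"), 4)
  subtypes <- c(rep(NA, 9), "unit-length", "upstream-TSS",
                "3'-readthrough")
  # full-length subtype slots stay intergenic so subtype geometry is the
  # only moving part
  locations[10:12] <- "intergenic"
  data.frame(slot = sprintf("planted_%02d", 1:12), origin = origins,
             location = locations, fl_subtype = subtypes,
             is_decoy = FALSE, decoy_gate = NA_character_,
             stringsAsFactors = FALSE)
}

decoy_design <- function() {
  gates <- rep(c("low_identity", "low_count", "short", "low_recurrence",
                 "multi_hit"), each = 2)
  data.frame(slot = sprintf("decoy_%02d", seq_along(gates)),
             origin = NA_character_, location = NA_character_,
             fl_subtype = NA_character_, is_decoy = TRUE,
             decoy_gate = gates, stringsAsFactors = FALSE)
}

#' Simulate the toy annotation
#'
#' Emits HERV elements (solo LTRs, LTR-INT-LTR proviruses, neighbouring
#' element pairs), host genes creating the planned same-strand,
#' opposite-strand, and no-overlap relations, and the truth table of
#' planted loci and single-gate decoys.  Geometry is deterministic.
#'
#' @param cfg a [sim_config()].
#' @return list with `herv` (element table), `genes` (`gene_models`),
#'   `truth` (`data.frame` incl. expected consensus `blocks`), `chrom`.
#' @export
simulate_annotation <- function(cfg = sim_config()) {
  chrom <- "chrS1"
  truth <- rbind(planted_design(), decoy_design())
  truth$chrom <- chrom
  truth$strand <- "+"
  truth$blocks <- NA_character_
  herv <- list(); genes <- list(); exons <- list()
  add_el <- function(id, s, e, family, comp, pv = NA_character_)
    herv[[length(herv) + 1]] <<- data.frame(
      element_id = id, chrom = chrom, start = s, end = e, strand = "+",
      family = family, component = comp, provirus_id = pv,
      stringsAsFactors = FALSE)
  add_gene <- function(id, s, e, strand) {
    genes[[length(genes) + 1]] <<- data.frame(
      gene_id = id, chrom = chrom, start = s, end = e, strand = strand,
      biotype = "protein_coding", stringsAsFactors = FALSE)
    # terminal exons only, clear of the tile centre where loci live
    exons[[length(exons) + 1]] <<- data.frame(
      gene_id = id, transcript_id = paste0(id, ".t1"), chrom = chrom,
      start = c(s, e - 200), end = c(s + 200, e), strand = strand,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth))) {
    base <- 50000 + (i - 1) * 30000
    slot <- truth$slot[i]
    if (truth$is_decoy[i]) {
      if (truth$decoy_gate[i] == "short") {
        add_el(paste0("ERV_D", i), base + 10000, base + 10150, "LTR12C",
               "LTR")
        truth$blocks[i] <- encode_blocks(base + 10000, base + 10150)
      } else {
        add_el(paste0("ERV_D", i), base + 10000, base + 10600, "LTR12C",
               "LTR")
        truth$blocks[i] <- encode_blocks(base + 9950, base + 10800)
      }
      next
    }
    if (truth$origin[i] == "solo-LTR") {
      add_el(paste0("ERV_S", i), base + 10000, base + 10600, "LTR12C",
             "LTR")
      truth$blocks[i] <- encode_blocks(base + 9950, base + 10650)
    } else if (truth$origin[i] == "truncated") {
      pv <- paste0("PV", i)
      add_el(paste0("ERV_T", i, "a"), base + 10000, base + 10600,
             "HERVK9", "LTR", pv)
      add_el(paste0("ERV_T", i, "b"), base + 10600, base + 14000,
             "HERVK9-int", "INT", pv)
      add_el(paste0("ERV_T", i, "c"), base + 14000, base + 14600,
             "HERVK9", "LTR", pv)
      truth$blocks[i] <- encode_blocks(base + 9900, base + 12000)
    } else if (truth$origin[i] == "chimeric") {
      add_el(paste0("ERV_C", i, "a"), base + 10000, base + 10600,
             "LTR12C", "LTR")
      add_el(paste0("ERV_C", i, "b"), base + 10800, base + 11400,
             "MLT2B4", "LTR")
      truth$blocks[i] <- encode_blocks(base + 9950, base + 11500)
    } else {  # full-length
      pv <- paste0("PV", i)
      add_el(paste0("ERV_F", i, "a"), base + 10000, base + 10600,
             "HERVH", "LTR", pv)
      add_el(paste0("ERV_F", i, "b"), base + 10600, base + 14000,
             "HERVH-int", "INT", pv)
      add_el(paste0("ERV_F", i, "c"), base + 14000, base + 14600,
             "HERVH", "LTR", pv)
      truth$blocks[i] <- switch(truth$fl_subtype[i],
        "unit-length" = encode_blocks(base + 10000, base + 14600),
        "upstream-TSS" = encode_blocks(base + 9500, base + 14600),
        "3'-readthrough" = encode_blocks(base + 10000, base + 15600))
    }
    if (truth$location[i] == "antisense")
      add_gene(paste0("GENE_AS", i), base + 9000, base + 18000, "-")
    if (truth$location[i] == "inserted")
      add_gene(paste0("GENE_IN", i), base + 9000, base + 18000, "+")
  }
  # background genes far from every planted tile
  add_gene("GENE_BG1", 1000, 9000, "+")
  add_gene("GENE_BG2", 900000, 920000, "-")
  gm <- structure(list(genes = do.call(rbind, genes),
                       exons = do.call(rbind, exons)),
                  class = "gene_models")
  list(herv = do.call(rbind, herv), genes = gm, truth = truth,
       chrom = chrom)
}

#' Simulate per-sample assembled-transcript alignments
#'
#' Planted loci are observed in `frac_present` of samples (the first
#' sample carries the full exon chain, so the cluster union equals the
#' planted consensus exactly); each decoy violates exactly its planted
#' gate and passes all others.
#'
#' @param cfg a [sim_config()].
#' @param ann output of [simulate_annotation()].
#' @return `data.frame` of transcript hits (one row per hit) suitable
#'   for [filter_candidates()].
#' @export
simulate_transcripts <- function(cfg, ann) {
  n <- cfg$n_samples
  samples <- sprintf("S%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(nrow(ann$truth))) {
    tr <- ann$truth[i, ]
    n_present <- if (isTRUE(tr$decoy_gate == "low_recurrence"))
      ceiling(0.5 * n) - 1 else round(cfg$frac_present * n)
    count <- if (isTRUE(tr$decoy_gate == "low_count")) 5 else
      cfg$support_count
    ident <- if (isTRUE(tr$decoy_gate == "low_identity")) 0.95 else
      cfg$identity
    span <- blocks_span(tr$blocks)
    for (s in seq_len(n_present)) {
      # first supporting sample carries the full chain; later samples a
      # slightly trimmed one, so the union is exact
      trim <- if (s == 1) 0 else min(20 * s, (span[2] - span[1]) %/% 4)
      blocks <- encode_blocks(span[1] + trim, span[2])
      rows[[length(rows) + 1]] <- data.frame(
        transcript_id = paste0(tr$slot, "_tx_", samples[s]),
        sample_id = samples[s], support_count = count,
        chrom = tr$chrom, strand = tr$strand, blocks = blocks,
        identity = ident, score = round(ident * 1000),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate genome re-mapping hits for merged loci
#'
#' Matches each merged locus back to the planted truth by chain overlap
#' and emits one self-hit; loci descending from `multi_hit` decoys get a
#' second equal-scoring hit at a shifted location, voiding uniqueness.
#'
#' @param loci a `herv_loci` object from [merge_candidates()].
#' @param ann output of [simulate_annotation()].
#' @param cfg a [sim_config()].
#' @return remap-hit `data.frame` for [assign_unique_locus()].
#' @export
simulate_remap_hits <- function(loci, ann, cfg = sim_config()) {
  rows <- list()
  for (i in seq_len(nrow(loci$loci))) {
    lr <- loci$loci[i, ]
    ov <- vapply(seq_len(nrow(ann$truth)), function(j) {
      if (ann$truth$chrom[j] != lr$chrom) return(0)
      blocks_overlap_blocks(lr$blocks, ann$truth$blocks[j])
    }, numeric(1))
    match_j <- if (any(ov > 0)) which.max(ov) else NA
    rows[[length(rows) + 1]] <- data.frame(
      locus_id = lr$locus_id, chrom = lr$chrom, strand = lr$strand,
      blocks = lr$blocks, identity = cfg$identity,
      score = round(cfg$identity * 1000), stringsAsFactors = FALSE)
    if (!is.na(match_j) &&
        isTRUE(ann$truth$decoy_gate[match_j] == "multi_hit")) {
      sp <- blocks_span(lr$blocks)
      rows[[length(rows) + 1]] <- data.frame(
        locus_id = lr$locus_id, chrom = lr$chrom, strand = lr$strand,
        blocks = encode_blocks(sp[1] + 1e6, sp[2] + 1e6),
        identity = cfg$identity, score = round(cfg$identity * 1000),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the detection stages on a transcript table
#'
#' Convenience wrapper chaining [filter_candidates()],
#' [merge_candidates()], and [assign_unique_locus()].  When
#' `remap_hits` is `NULL` every merged locus receives a perfect
#' self-hit.
#'
#' @param transcripts transcript-hit table.
#' @param herv HERV element table.
#' @param n_samples recurrence denominator.
#' @param remap_hits optional remap-hit table.
#' @param min_count,min_identity,min_sample_fraction,min_len detection
#'   thresholds (defaults 5, 0.96, 0.5, 200).
#' @return a `herv_loci` object; stage drop logs in
#'   `attr(, "drop_log")`.
#' @export
run_detection <- function(transcripts, herv,
                          n_samples = length(unique(transcripts$sample_id)),
                          remap_hits = NULL, min_count = 5,
                          min_identity = 0.96, min_sample_fraction = 0.5,
                          min_len = 200) {
  filt <- filter_candidates(transcripts, min_count, min_identity)
  merged <- merge_candidates(filt, n_samples, min_sample_fraction,
                             min_len)
  if (is.null(remap_hits)) {
    remap_hits <- merged$loci[, c("locus_id", "chrom", "strand",
                                  "blocks")]
    remap_hits$identity <- 1; remap_hits$score <- 1000
  }
  final <- assign_unique_locus(merged, remap_hits, herv, min_identity)
  attr(final, "drop_log") <- list(
    filtered_out = setdiff(unique(transcripts$transcript_id),
                           unique(filt$transcript_id)),
    merge_dropped = attr(merged, "dropped"),
    assign_dropped = attr(final, "dropped"))
  final
}

#' Simulate sample metadata
#'
#' Each individual contributes one sample per body site (paired design,
#' as the global mixed model requires); sex alternates, ethnicity
#' alternates in pairs, ages spread uniformly over 21-70 years.
#'
#' @param cfg a [sim_config()].
#' @param n_sites number of body sites (default 3).
#' @param n_individuals individuals (default `cfg$n_samples`).
#' @return metadata `data.frame` (one row per sample).
#' @export
simulate_meta <- function(cfg = sim_config(), n_sites = 3,
                          n_individuals = cfg$n_samples) {
  sites <- sprintf("site%02d", seq_len(n_sites))
  ind <- sprintf("IND%03d", seq_len(n_individuals))
  df <- expand.grid(individual_id = ind, body_site = sites,
                    stringsAsFactors = FALSE)
  df$sample_id <- paste(df$individual_id, df$body_site, sep = ".")
  idx <- match(df$individual_id, ind)
  df$sex <- c("male", "female")[1 + idx %% 2]
  df$ethnicity <- c("EA", "AA")[1 + (idx %/% 2) %% 2]
  df$age <- 21 + (idx - 1) %% 50
  df[, c("sample_id", "individual_id", "body_site", "sex", "ethnicity",
         "age")]
}

nb_draw <- function(n, mean, size) {
  mean <- pmax(mean, 1e-8)
  stats::rnbinom(n, mu = mean, size = size)
}

#' Simulate a count matrix with planted effects
#'
#' Negative-binomial counts with per-site means and optional planted
#' site-specific, sex, and age effects on the log2 scale.
#'
#' @param cfg a [sim_config()].
#' @param loci_ids character vector of locus ids.
#' @param meta metadata from [simulate_meta()].
#' @param effects optional `data.frame` with columns `locus_id`,
#'   `effect` (`"site"`, `"sex"`, `"age"`), `target` (the specific site,
#'   or the favoured sex level, or `NA` for age).
#' @param effective_length per-locus lengths (default 1000).
#' @return list with `counts`, `tpm`, `effects`.
#' @export
simulate_counts <- function(cfg, loci_ids, meta, effects = NULL,
                            effective_length = NULL) {
  rng <- local_rng(child_seed(cfg$seed, 11L))
  on.exit(rng$restore())
  if (is.null(effective_length))
    effective_length <- stats::setNames(rep(1000, length(loci_ids)),
                                        loci_ids)
  n <- nrow(meta)
  counts <- matrix(0L, length(loci_ids), n,
                   dimnames = list(loci_ids, meta$sample_id))
  for (l in loci_ids) {
    log2mu <- rep(log2(cfg$base_mean), n)
    eff <- if (is.null(effects)) NULL else
      effects[effects$locus_id == l, , drop = FALSE]
    if (!is.null(eff)) for (k in seq_len(nrow(eff))) {
      if (eff$effect[k] == "site") {
        log2mu[meta$body_site != eff$target[k]] <- log2(0.05)
      } else if (eff$effect[k] == "sex") {
        log2mu[meta$sex == eff$target[k]] <-
          log2mu[meta$sex == eff$target[k]] + cfg$sex_delta
      } else if (eff$effect[k] == "age") {
        log2mu <- log2mu + cfg$age_slope * (meta$age - mean(meta$age))
      }
    }
    counts[l, ] <- nb_draw(n, 2^log2mu, cfg$dispersion)
  }
  list(counts = counts,
       tpm = compute_tpm(counts, effective_length),
       effects = effects)
}

#' Simulate genotypes with planted cis effects
#'
#' Each locus sits on its own toy chromosome with `n_cis` biallelic
#' Hardy-Weinberg variants in the cis window; for planted loci the
#' middle variant carries an additive effect of `cfg$qtl_beta`
#' (inverse-normal-sd units) on a unit-variance expression value.  A
#' configurable fraction of (locus, individual) pairs is marked absent,
#' with no uniquely mapping contig and masked expression.
#'
#' @param cfg a [sim_config()].
#' @param n_individuals individuals (default 100).
#' @param n_qtl planted loci (default 50).
#' @param n_null null loci (default 500).
#' @param n_cis cis variants per locus (default 50).
#' @param absent_fraction fraction of pairs absent (default 0).
#' @return list with `genotypes` (`genotype_study`), `expr` (loci x
#'   individuals, masked), `loci_tss`, `truth`, `contigs`, `presence`.
#' @export
simulate_genotypes <- function(cfg, n_individuals = 100, n_qtl = 50,
                               n_null = 500, n_cis = 50,
                               absent_fraction = 0) {
  rng <- local_rng(child_seed(cfg$seed, 23L))
  on.exit(rng$restore())
  ind <- sprintf("IND%03d", seq_len(n_individuals))
  n_loci <- n_qtl + n_null
  loci <- sprintf("HERV_%08d", seq_len(n_loci))
  tss <- 1.1e6
  dos <- list(); vmeta <- list()
  expr <- matrix(NA_real_, n_loci, n_individuals,
                 dimnames = list(loci, ind))
  truth <- list()
  causal_idx <- (n_cis + 1) %/% 2
  for (i in seq_len(n_loci)) {
    chrom <- paste0("chrQ", i)
    maf <- stats::runif(n_cis, 0.05, 0.5)
    planted <- i <= n_qtl
    if (planted) maf[causal_idx] <- cfg$qtl_maf
    d <- vapply(maf, function(m) stats::rbinom(n_individuals, 2, m),
                integer(n_individuals))
    d <- t(d)  # variants x individuals
    vid <- sprintf("var_%d_%d", i, seq_len(n_cis))
    rownames(d) <- vid; colnames(d) <- ind
    dos[[i]] <- d
    vmeta[[i]] <- data.frame(
      variant_id = vid, chrom = chrom,
      pos = round(seq(tss - 9e5, tss + 9e5, length.out = n_cis)),
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    y <- stats::rnorm(n_individuals)
    if (planted) {
      y <- y + cfg$qtl_beta * d[causal_idx, ]
      truth[[length(truth) + 1]] <- data.frame(
        locus_id = loci[i], variant_id = vid[causal_idx],
        beta = cfg$qtl_beta, stringsAsFactors = FALSE)
    }
    expr[i, ] <- y
  }
  dosage <- do.call(rbind, dos)
  variants <- do.call(rbind, vmeta)
  variants$maf <- apply(dosage, 1, dosage_maf)
  g <- structure(list(dosage = dosage, variants = variants,
                      individuals = ind, n_skipped = 0L),
                 class = "genotype_study")
  loci_tss <- data.frame(locus_id = loci,
                         chrom = paste0("chrQ", seq_len(n_loci)),
                         tss = tss, stringsAsFactors = FALSE)
  # presence calls: absent pairs carry only multi-mapping contigs
  contigs <- list(); pres <- NULL
  if (absent_fraction > 0) {
    grid <- expand.grid(locus_id = loci, individual_id = ind,
                        stringsAsFactors = FALSE)
    absent <- stats::runif(nrow(grid)) < absent_fraction
    contigs <- data.frame(locus_id = grid$locus_id,
                          individual_id = grid$individual_id,
                          mapped_uniquely = !absent,
                          stringsAsFactors = FALSE)
    pres <- presence_from_contigs(contigs, loci, ind)
    expr <- mask_expression(expr, pres,
                            stats::setNames(ind, ind))
  } else {
    contigs <- data.frame(locus_id = character(0),
                          individual_id = character(0),
                          mapped_uniquely = logical(0))
  }
  list(genotypes = g, expr = expr, loci_tss = loci_tss,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       contigs = contigs, presence = pres)
}

#' Simulate histone peaks and methylation correlated with expression
#'
#' For active marks, a peak lands within the TSS window of
#' high-expression loci with probability `peak_p_active` and near other
#' loci with `peak_p_background`; inactive marks use the background
#' probability everywhere.  CpG methylation around the TSS carries the
#' planted expressed-vs-silent difference.
#'
#' @param cfg a [sim_config()].
#' @param loci a `herv_loci` object.
#' @param high_expression named logical vector (locus id -> high?).
#' @param marks mark names (default the six-mark vocabulary).
#' @param active_marks marks coupled to expression (default H3K27ac,
#'   H3K36me3).
#' @param body_site,individual labels for the emitted tracks.
#' @return list with `peaks` and `methylation` tables.
#' @export
simulate_epigenome <- function(cfg, loci, high_expression,
                               marks = c("H3K27ac", "H3K27me3",
                                         "H3K36me3", "H3K4me1",
                                         "H3K4me3", "H3K9me3"),
                               active_marks = c("H3K27ac", "H3K36me3"),
                               body_site = "site01",
                               individual = "IND001") {
  rng <- local_rng(child_seed(cfg$seed, 37L))
  on.exit(rng$restore())
  tss <- locus_tss(loci)
  hi <- high_expression[tss$locus_id]
  peaks <- list()
  for (mk in marks) {
    p <- if (mk %in% active_marks)
      ifelse(hi, cfg$peak_p_active, cfg$peak_p_background)
    else rep(cfg$peak_p_background, nrow(tss))
    hit <- stats::runif(nrow(tss)) < p
    if (!any(hit)) next
    peaks[[length(peaks) + 1]] <- data.frame(
      chrom = tss$chrom[hit], start = tss$tss[hit] - 1000,
      end = tss$tss[hit] + 1000, mark = mk, body_site = body_site,
      individual = individual, stringsAsFactors = FALSE)
  }
  meth <- list()
  for (i in seq_len(nrow(tss))) {
    pos <- seq(tss$tss[i] - 4500, tss$tss[i] + 4500, by = 500)
    mu <- 0.6 + if (hi[i]) cfg$methylation_diff else 0
    beta <- pmin(1, pmax(0, stats::rnorm(length(pos), mu, 0.05)))
    meth[[i]] <- data.frame(chrom = tss$chrom[i], pos = pos,
                            coverage = 30L,
                            beta = beta, stringsAsFactors = FALSE)
  }
  list(peaks = do.call(rbind, peaks),
       methylation = do.call(rbind, meth))
}

## ---- fixture writers ------------------------------------------------------

#' Write a HERV element table as HERVd-dialect BED
#' @param herv element table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hervd_bed <- function(herv, path) {
  lines <- sprintf("%s\t%d\t%d\t%s_%s\t0\t%s\t%s\t%s",
                   herv$chrom, as.integer(herv$start),
                   as.integer(herv$end), herv$element_id, herv$family,
                   herv$strand, herv$component,
                   ifelse(is.na(herv$provirus_id), "",
                          herv$provirus_id))
  writeLines(sub("\t$", "", lines), path)
  invisible(path)
}

#' Write a genotype study as a minimal VCF
#' @param g a `genotype_study`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", g$individuals),
                     collapse = "\t")), con)
  gt <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L], nrow(g$dosage))
  gt[is.na(g$dosage)] <- "./."
  for (i in seq_len(nrow(g$dosage))) {
    writeLines(paste(c(g$variants$chrom[i],
                       as.integer(g$variants$pos[i]) + 1L,
                       g$variants$variant_id[i], g$variants$ref[i],
                       g$variants$alt[i], ".", "PASS", ".", "GT",
                       gt[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a transcript-hit table as per-sample GTF
#'
#' Exon rows carry `support_count`, `identity` and `n_hits` attributes.
#' @param transcripts transcript-hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## hervtools assembled-transcript alignments", con)
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    ex <- decode_blocks(tr$blocks)
    at <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                         'sample_id "%s"; support_count "%d"; ',
                         'identity "%.4f"; n_hits "1";'),
                  tr$transcript_id, tr$transcript_id, tr$sample_id,
                  as.integer(tr$support_count), tr$identity)
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\thervtools\texon\t%d\t%d\t%d\t%s\t.\t%s",
                         tr$chrom, as.integer(ex$start[j]) + 1L,
                         as.integer(ex$end[j]), as.integer(tr$score),
                         tr$strand, at), con)
  }
  invisible(path)
}

#' Materialize a complete fixture directory
#'
#' Writes every input the pipeline consumes — annotation (HERVd BED,
#' gene GTF), per-sample transcript GTF, counts and metadata TSV,
#' genotype VCF, peaks (narrowPeak), methylation TSV — plus
#' `truth.json`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
simulate_study <- function(cfg = sim_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  write_hervd_bed(ann$herv, file.path(dir, "herv_elements.bed"))
  write_genes_gtf(ann$genes, file.path(dir, "genes.gtf"))
  tx <- simulate_transcripts(cfg, ann)
  write_transcript_gtf(tx, file.path(dir, "transcripts.gtf"))
  filt <- filter_candidates(tx)
  merged <- merge_candidates(filt, n_samples = cfg$n_samples)
  rh <- simulate_remap_hits(merged, ann, cfg)
  data.table::fwrite(rh, file.path(dir, "remap_hits.tsv"), sep = "\t")
  loci <- assign_unique_locus(merged, rh, ann$herv)
  meta <- simulate_meta(cfg)
  data.table::fwrite(meta, file.path(dir, "samples.tsv"), sep = "\t")
  cm <- simulate_counts(cfg, loci$loci$locus_id, meta)
  write_matrix_tsv(cm$counts, file.path(dir, "counts.tsv"), "locus_id")
  gsim <- simulate_genotypes(cfg, n_individuals = 30, n_qtl = 2,
                             n_null = 3, n_cis = 10)
  write_vcf(gsim$genotypes, file.path(dir, "genotypes.vcf"))
  dir.create(file.path(dir, "qtl"), showWarnings = FALSE)
  write_matrix_tsv(gsim$expr, file.path(dir, "qtl", "expression_int.tsv"),
                   "locus_id")
  data.table::fwrite(gsim$loci_tss, file.path(dir, "qtl", "loci_tss.tsv"),
                     sep = "\t")
  epi <- simulate_epigenome(cfg, loci,
                            stats::setNames(seq_len(nrow(loci$loci)) %%
                                              2 == 1,
                                            loci$loci$locus_id))
  pk <- epi$peaks
  data.table::fwrite(data.frame(chrom = pk$chrom,
                                start = as.integer(pk$start),
                                end = as.integer(pk$end),
                                name = pk$mark, score = 0L,
                                strand = "."),
                     file.path(dir, "peaks.bed"), sep = "\t",
                     col.names = FALSE)
  me <- epi$methylation
  data.table::fwrite(data.frame(chrom = me$chrom,
                                pos = as.integer(me$pos),
                                coverage = me$coverage,
                                percent = round(me$beta * 100, 4)),
                     file.path(dir, "methylation.tsv"), sep = "\t")
  jsonlite::write_json(ann$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(dir)
}

#' Write a `gene_models` object as GTF
#' @param genes a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gtf <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## hervtools gene annotation", con)
  g <- genes$genes
  for (i in seq_len(nrow(g))) {
    at <- sprintf('gene_id "%s"; gene_type "%s";', g$gene_id[i],
                  ifelse(is.na(g$biotype[i]), "unknown", g$biotype[i]))
    writeLines(sprintf("%s\thervtools\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom[i], as.integer(g$start[i]) + 1L,
                       as.integer(g$end[i]), g$strand[i], at), con)
    ex <- genes$exons[genes$exons$gene_id == g$gene_id[i], ,
                      drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      at2 <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id[i],
                     ex$transcript_id[j])
      writeLines(sprintf("%s\thervtools\texon\t%d\t%d\t.\t%s\t.\t%s",
                         ex$chrom[j], as.integer(ex$start[j]) + 1L,
                         as.integer(ex$end[j]), ex$strand[j], at2), con)
    }
  }
  invisible(path)
}
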