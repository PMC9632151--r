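test_that("presence calls and expression masking follow contig logic", {
  hits <- data.frame(locus_id = c("L1", "L2", "L2", "L2"),
                     individual_id = c("I1", "I1", "I1", "I2"),
                     mapped_uniquely = c(TRUE, FALSE, FALSE, TRUE))
  p <- presence_from_contigs(hits, c("L1", "L2"), c("I1", "I2"))
  get <- function(l, i) p$present[p$locus_id == l & p$individual_id == i]
  expect_true(get("L1", "I1"))
  expect_false(get("L2", "I1"))   # only multi-mapping contigs
  expect_false(get("L1", "I2"))   # no contigs at all
  expect_true(get("L2", "I2"))
  expr <- matrix(1, 2, 2, dimnames = list(c("L1", "L2"), c("s1", "s2")))
  m <- mask_expression(expr, p, c(s1 = "I1", s2 = "I2"))
  expect_true(is.na(m["L2", "s1"]) && is.na(m["L1", "s2"]))
  expect_identical(m["L1", "s1"], 1)
})

test_that("variant QC applies missingness, MAF and HWE thresholds", {
  # exact HWE: 25/50/25
  d_hwe <- rep(c(0L, 1L, 2L), c(25, 50, 25))
  # gross HWE violation: 50/0/50 has chi-square 100 (oracle: sum (O-E)^2/E
  # with E = (25, 50, 25))
  d_bad <- rep(c(0L, 2L), c(50, 50))
  e <- c(25, 50, 25)
  chisq_oracle <- sum((c(50, 0, 50) - e)^2 / e)
  expect_equal(chisq_oracle, 100)
  expect_lt(pchisq(100, 1, lower.tail = FALSE), 1e-6)
  d_miss <- d_hwe; d_miss[1:6] <- NA    # 6% missing
  g <- make_genotype_study(rbind(hwe = d_hwe, bad = d_bad,
                                 miss = d_miss))
  expect_identical(variant_qc(g), "hwe")
  # monomorphic variant drops on MAF
  g2 <- make_genotype_study(rbind(mono = rep(0L, 100), hwe = d_hwe))
  expect_identical(variant_qc(g2), "hwe")
})

test_that("per-site filter needs 10 minor carriers and MAF >= 1%", {
  n <- 400
  mk <- function(carriers, dose = 1L) {
    d <- rep(0L, n); d[seq_len(carriers)] <- dose; d
  }
  g <- make_genotype_study(rbind(ok = mk(10, 2L),     # MAF 0.025
                                 few = mk(9, 2L),      # 9 carriers
                                 rare = mk(7, 1L)))    # MAF 0.00875
  expect_identical(site_variant_filter(g), "ok")
})

test_that("TMM factors behave on depth-only and constant-M data", {
  counts <- matrix(rep(c(100, 50, 80, 20, 60), 4), 5, 4,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_equal(unname(tmm_factors(counts)), rep(1, 4), tolerance = 1e-12)
  # pure depth difference: B = 2 x A
  c2 <- cbind(A = c(100, 50, 80, 20, 60), B = 2 * c(100, 50, 80, 20, 60))
  expect_equal(unname(tmm_factors(c2)), c(1, 1), tolerance = 1e-12)
  # engineered so every shared gene's library-normalized ratio B/A = 2
  c3 <- cbind(A = c(10, 20, 30, 40, 50, 50),
              B = c(10, 20, 30, 40, 0, 0))
  f <- tmm_factors(c3)
  expect_equal(unname(f["B"] / f["A"]), 2, tolerance = 1e-9)
  expect_equal(exp(mean(log(tmm_factors(c3)))), 1, tolerance = 1e-9)
  expect_error(tmm_factors(cbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("TMM matches the edgeR implementation on random counts", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  counts <- matrix(rnbinom(200 * 6, mu = 100, size = 2), 200, 6)
  counts[sample(length(counts), 50)] <- 0
  colnames(counts) <- paste0("s", 1:6)
  ours <- tmm_factors(counts)
  theirs <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("inverse normal transform hits the exact n = 3 quantiles", {
  got <- inverse_normal(c(5, 1, 9))
  expect_equal(got, qnorm(c(3, 1, 5) / 6), tolerance = 1e-4)
  expect_equal(sort(got), c(-0.9674, 0, 0.9674), tolerance = 1e-4)
  # rank-preserving and idempotent
  set.seed(31)
  x <- rnorm(50)
  y <- inverse_normal(x)
  expect_identical(order(y), order(x))
  expect_equal(inverse_normal(y), y, tolerance = 1e-12)
  # missing preserved, constant warns to zero
  z <- inverse_normal(c(1, NA, 2, 3))
  expect_true(is.na(z[2]) && !anyNA(z[-2]))
  expect_warning(w <- inverse_normal(c(2, 2, 2)), "constant")
  expect_equal(w, c(0, 0, 0))
})

test_that("ld_r2 and pruning keep one of each linked pair", {
  set.seed(41)
  d1 <- rbinom(200, 2, 0.3)
  expect_equal(ld_r2(d1, d1), 1)
  d2 <- rbinom(10000, 2, 0.3); d3 <- rbinom(10000, 2, 0.3)
  expect_lt(ld_r2(d2, d3), 0.01)
  expect_message(r0 <- ld_r2(d1, rep(1L, 200)), "constant")
  expect_equal(r0, 0)
  g <- make_genotype_study(rbind(a = d1, b = d1,
                                 c = rbinom(200, 2, 0.3)),
                           pos = c(100, 200, 300))
  kept <- prune_ld(g)
  expect_identical(kept, c("a", "c"))  # later-positioned twin dropped
})

test_that("genotype PCs separate divergent clusters deterministically", {
  set.seed(51)
  n1 <- 25; n2 <- 25; m <- 80
  dos <- cbind(vapply(1:n1, function(i) rbinom(m, 2, 0.1), integer(m)),
               vapply(1:n2, function(i) rbinom(m, 2, 0.6), integer(m)))
  g <- make_genotype_study(dos)
  sc <- genotype_pcs(g, k = 3)
  lab <- rep(1:2, c(n1, n2))
  # silhouette on PC1
  sil <- vapply(seq_len(n1 + n2), function(i) {
    same <- setdiff(which(lab == lab[i]), i)
    own <- mean(abs(sc[i, 1] - sc[same, 1]))
    oth <- mean(abs(sc[i, 1] - sc[lab != lab[i], 1]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  # orthogonal scores
  cp <- crossprod(sc)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  # duplicating every variant rescales scores by sqrt(2)
  g2 <- make_genotype_study(rbind(dos, dos),
                            pos = seq_len(2 * m) * 1000)
  sc2 <- genotype_pcs(g2, k = 2)
  expect_equal(unname(sc2[, 1]), unname(sc[, 1] * sqrt(2)),
               tolerance = 1e-6)
  expect_error(genotype_pcs(make_genotype_study(dos[1:3, ]), k = 3),
               "rank")
})

test_that("hidden-factor schedule matches the sample-size breakpoints", {
  expect_identical(factor_count_schedule(149), 15L)
  expect_identical(factor_count_schedule(150), 30L)
  expect_identical(factor_count_schedule(249), 30L)
  expect_identical(factor_count_schedule(250), 45L)
  expect_identical(factor_count_schedule(349), 45L)
  expect_identical(factor_count_schedule(350), 60L)
  expr <- matrix(rnorm(200), 20, 10)
  expect_warning(hf <- hidden_factors(expr), "clipped")
  expect_identical(ncol(hf), 9L)
})

test_that("cis_scan recovers a planted additive effect", {
  cfg <- sim_config(seed = 6, qtl_beta = 1, qtl_maf = 0.3)
  gs <- simulate_genotypes(cfg, n_individuals = 100, n_qtl = 5,
                           n_null = 0, n_cis = 11)
  nom <- cis_scan(gs$expr, gs$genotypes, NULL, gs$loci_tss)
  hit <- merge(nom, gs$truth, by = c("locus_id", "variant_id"))
  expect_identical(nrow(hit), 5L)
  expect_true(all(abs(hit$beta.x - 1) < 2 * hit$se))
})

test_that("cis window excludes variants beyond 1 Mb from the TSS", {
  set.seed(61)
  dos <- matrix(rbinom(3 * 50, 2, 0.4), 3, 50)
  g <- make_genotype_study(dos, chrom = "chr1",
                           pos = c(2e6 - 1e6,        # exactly at the edge
                                   2e6 + 1e6 + 1,    # 1 bp beyond
                                   2e6))
  expr <- matrix(rnorm(50), 1, 50,
                 dimnames = list("L1", g$individuals))
  tss <- data.frame(locus_id = "L1", chrom = "chr1", tss = 2e6)
  nom <- cis_scan(expr, g, NULL, tss)
  expect_setequal(nom$variant_id, c("v001", "v003"))
})

test_that("cis_scan p-values are uniform under the null", {
  set.seed(71)
  n <- 60; nl <- 200
  dos <- matrix(rbinom(nl * n, 2, 0.3), nl, n)
  g <- make_genotype_study(dos, chrom = paste0("c", seq_len(nl)),
                           pos = rep(500, nl))
  expr <- matrix(rnorm(nl * n), nl, n,
                 dimnames = list(paste0("L", seq_len(nl)),
                                 g$individuals))
  tss <- data.frame(locus_id = paste0("L", seq_len(nl)),
                    chrom = paste0("c", seq_len(nl)), tss = 500)
  nom <- cis_scan(expr, g, NULL, tss)
  expect_equal(nrow(nom), nl)
  ks <- suppressWarnings(ks.test(nom$p_nominal, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("exhaustive permutation p equals an independent enumeration", {
  set.seed(81)
  n <- 5
  dos <- matrix(rbinom(3 * n, 2, 0.5), 3, n)
  dos[1, ] <- c(0L, 1L, 2L, 0L, 1L)  # guarantee non-constant
  g <- make_genotype_study(dos, chrom = "c1", pos = c(100, 200, 300))
  y <- c(0.3, -1.2, 2.1, 0.4, -0.6)
  expr <- matrix(y, 1, n, dimnames = list("L1", g$individuals))
  tss <- data.frame(locus_id = "L1", chrom = "c1", tss = 200)
  res <- permutation_pass(expr, g, NULL, tss, exhaustive = TRUE)
  # oracle: enumerate all 120 permutations independently
  perms <- NULL
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  allp <- permute(seq_len(n))
  expect_length(allp, 120)
  keep <- apply(dos, 1, sd) > 0
  stat <- function(yy) max(abs(cor(t(dos[keep, , drop = FALSE]), yy)))
  obs <- stat(y)
  cnt <- sum(vapply(allp, function(p) stat(y[p]) >= obs - 1e-12,
                    logical(1)))
  expect_equal(res$p_perm, cnt / 120)
})

test_that("permutation pass calls a strong planted effect", {
  cfg <- sim_config(seed = 7, qtl_beta = 2)
  gs <- simulate_genotypes(cfg, n_individuals = 100, n_qtl = 1,
                           n_null = 4, n_cis = 10)
  perm <- permutation_pass(gs$expr, gs$genotypes, NULL, gs$loci_tss,
                           n_perm = 1000, seed = 9)
  called <- call_ehervs(perm)
  planted <- called[called$locus_id == gs$truth$locus_id, ]
  expect_equal(planted$p_perm, 1 / 1001)
  expect_true(planted$is_eherv)
  # null loci sit well above the floor
  expect_true(all(called$p_perm >= 1 / 1001))
  expect_warning(permutation_pass(gs$expr, gs$genotypes, NULL,
                                  gs$loci_tss[1, , drop = FALSE],
                                  n_perm = 50, seed = 1), "coarse")
})

test_that("masking absent individuals equals removing them", {
  cfg <- sim_config(seed = 8)
  gs <- simulate_genotypes(cfg, n_individuals = 60, n_qtl = 2,
                           n_null = 2, n_cis = 8)
  expr <- gs$expr
  drop_ind <- gs$genotypes$individuals[1:10]
  masked <- expr
  masked[, drop_ind] <- NA
  nom_masked <- cis_scan(masked, gs$genotypes, NULL, gs$loci_tss)
  g_sub <- subset_genotypes(gs$genotypes,
                            individual_ids = setdiff(
                              gs$genotypes$individuals, drop_ind))
  nom_drop <- cis_scan(expr[, g_sub$individuals, drop = FALSE], g_sub,
                       NULL, gs$loci_tss)
  expect_equal(nom_masked$beta, nom_drop$beta, tolerance = 1e-12)
  expect_equal(nom_masked$p_nominal, nom_drop$p_nominal,
               tolerance = 1e-12)
})

test_that("matched backgrounds reproduce covariate distributions", {
  set.seed(91)
  n <- 500
  targets <- data.frame(variant_id = paste0("t", 1:n), chrom = "chr1",
                        pos = sample(1:5e6, n),
                        maf = runif(n, 0.01, 0.5))
  # pool: five shifted copies of the targets
  pool <- do.call(rbind, lapply(1:5, function(k) {
    p <- targets
    p$variant_id <- paste0("p", k, "_", 1:n)
    p$pos <- p$pos + sample(-50:50, n, replace = TRUE)
    p$maf <- pmin(0.5, pmax(0.01, p$maf +
                              runif(n, -0.005, 0.005)))
    p
  }))
  tsspos <- sample(1:5e6, 300)
  mb <- matched_background(targets, pool, tsspos, seed = 123)
  expect_equal(nrow(mb$matched), n)
  expect_length(mb$unmatched, 0)
  got <- pool[match(mb$matched$matched_id, pool$variant_id), ]
  expect_gt(suppressWarnings(ks.test(got$maf, targets$maf))$p.value,
            0.05)
  dt <- log10(1 + nearest_tss_distance(targets$pos, tsspos))
  dg <- log10(1 + nearest_tss_distance(got$pos, tsspos))
  expect_gt(suppressWarnings(ks.test(dg, dt))$p.value, 0.05)
  # seeds change the draw, not the feasibility
  mb2 <- matched_background(targets, pool, tsspos, seed = 124)
  expect_equal(nrow(mb2$matched), n)
  expect_false(identical(mb$matched$matched_id, mb2$matched$matched_id))
  # identical seed reproduces the matching exactly
  mb3 <- matched_background(targets, pool, tsspos, seed = 123)
  expect_identical(mb3$matched, mb$matched)
  expect_error(matched_background(targets, targets, tsspos), "exclude")
})

test_that("enrichment matches the hypergeometric oracle", {
  # sample odds ratio for (10, 90; 1, 99) is 11.0
  targets <- paste0("t", 1:100)
  background <- paste0("b", 1:100)
  ann <- data.frame(variant_id = c(targets[1:10], background[1]),
                    category = "enh")
  res <- enrichment_test(targets, background, ann)
  expect_equal(res$odds_ratio[res$category == "enh"], 11.0)
  # oracle: two-sided Fisher p by enumerating the hypergeometric tail
  fisher_oracle <- function(a, b, c2, d) {
    m <- a + b; nn <- c2 + d; k <- a + c2
    lo <- max(0, k - nn); hi <- min(k, m)
    probs <- dhyper(lo:hi, m, nn, k)
    sum(probs[probs <= dhyper(a, m, nn, k) * (1 + 1e-7)])
  }
  set.seed(101)
  for (i in 1:50) {
    a <- sample(0:40, 1); b <- sample(1:500, 1)
    c2 <- sample(0:40, 1); d <- sample(1:500, 1)
    got <- fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE))$p.value
    expect_equal(got, fisher_oracle(a, b, c2, d), tolerance = 1e-6)
  }
  # identical frequencies: OR 1, p 1
  ann2 <- data.frame(variant_id = c(targets[1:10], background[1:10]),
                     category = "x")
  res2 <- enrichment_test(targets, background, ann2)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)
  # stated drop categories never reach the output
  ann3 <- rbind(ann, data.frame(variant_id = targets[1:5],
                                category = "splicing"))
  res3 <- enrichment_test(targets, background, ann3)
  expect_false(any(res3$category %in%
                     c("ncRNA_splicing", "splicing", "stopgain",
                       "stoploss")))
})

test_that("GWAS LD expansion applies strict p and r2 thresholds", {
  set.seed(111)
  d1 <- rbinom(100, 2, 0.4)
  g <- make_genotype_study(rbind(hit = d1, twin = d1,
                                 far = rbinom(100, 2, 0.4)),
                           pos = c(100, 200, 300))
  gwas <- data.frame(variant_id = c("hit", "edge"),
                     p = c(1e-9, 5e-8))
  out <- expand_gwas_ld(gwas, g)
  expect_setequal(out, c("hit", "twin"))  # edge excluded (strict <)
  # a hit missing from the panel is kept without expansion
  gwas2 <- data.frame(variant_id = "ghost", p = 1e-10)
  expect_message(out2 <- expand_gwas_ld(gwas2, g), "not in genotype")
  expect_identical(out2, "ghost")
})
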