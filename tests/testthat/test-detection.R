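test_that("alignment_identity matches its definition and gates", {
  expect_equal(alignment_identity(960, 40), 0.96)
  expect_true(alignment_identity(960, 40) >= 0.96)
  expect_false(alignment_identity(959, 41) >= 0.96)
  expect_equal(alignment_identity(100, 0, 0, 0), 1)
  expect_equal(alignment_identity(90, 5, 3, 2), 0.9)
  expect_error(alignment_identity(0, 0), "aligned")
  expect_error(alignment_identity(-1, 5), "non-negative")
})

test_that("filter_candidates applies strict count and non-strict identity", {
  tx <- rbind(make_tx("t1", "S1", 0, 500, support_count = 6,
                      identity = 0.97),
              make_tx("t2", "S1", 0, 500, support_count = 5,
                      identity = 0.99),
              make_tx("t3", "S1", 0, 500, support_count = 100,
                      identity = 0.95),
              make_tx("t4", "S1", 0, 500, support_count = 10,
                      identity = 0.96))
  kept <- filter_candidates(tx)
  expect_setequal(kept$transcript_id, c("t1", "t4"))
})

test_that("filter_candidates returns only the best hit per transcript", {
  tx <- rbind(make_tx("t1", "S1", 0, 500, identity = 0.99, score = 990),
              make_tx("t1", "S1", 1000, 1500, identity = 0.97,
                      score = 970))
  kept <- filter_candidates(tx)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$blocks, "0-500")
})

test_that("merge_candidates enforces recurrence and length boundaries", {
  mk <- function(samples, s, e)
    do.call(rbind, lapply(samples, function(x)
      make_tx(paste0("t", x, s), paste0("S", x), s, e)))
  # 4 of 8 samples, length 300: kept (>= 50%, >= 200 bp)
  m1 <- merge_candidates(mk(1:4, 0, 300), n_samples = 8)
  expect_identical(nrow(m1$loci), 1L)
  expect_identical(m1$loci$n_supporting, 4L)
  # 3 of 8 samples: dropped
  m2 <- merge_candidates(mk(1:3, 0, 300), n_samples = 8)
  expect_identical(nrow(m2$loci), 0L)
  expect_identical(attr(m2, "dropped")$reason, "recurrence")
  # 4 of 8 but union 150 bp: dropped
  m3 <- merge_candidates(mk(1:4, 0, 150), n_samples = 8)
  expect_identical(nrow(m3$loci), 0L)
  expect_identical(attr(m3, "dropped")$reason, "length")
})

test_that("merge clustering equals brute-force connected components", {
  set.seed(13)
  for (rep in 1:10) {
    k <- sample(10:30, 1)
    tx <- do.call(rbind, lapply(seq_len(k), function(i) {
      s <- sample(seq(0, 5000, 100), 1)
      make_tx(paste0("t", i), paste0("S", sample(1:4, 1)), s,
              s + sample(c(150, 300, 500), 1),
              strand = sample(c("+", "-"), 1))
    }))
    m <- merge_candidates(tx, n_samples = 4, min_sample_fraction = 0,
                          min_len = 1)
    # oracle: adjacency over same-strand chain overlap, DFS components
    adj <- matrix(FALSE, k, k)
    for (i in 1:k) for (j in 1:k)
      adj[i, j] <- tx$strand[i] == tx$strand[j] &&
        blocks_overlap_blocks(tx$blocks[i], tx$blocks[j]) > 0
    comp <- rep(NA_integer_, k); cid <- 0
    for (i in 1:k) if (is.na(comp[i])) {
      cid <- cid + 1; stack <- i
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        stack <- c(stack, which(adj[v, ] & is.na(comp)))
      }
    }
    expect_identical(nrow(m$loci), length(unique(comp)))
    # each oracle component's union must appear among merged loci
    unions <- vapply(split(seq_len(k), comp), function(ii)
      union_blocks(tx$blocks[ii]), character(1))
    expect_setequal(unname(unions), m$loci$blocks)
  }
})

test_that("assign_unique_locus demands a unique qualifying HERV hit", {
  herv <- make_herv_element("ERV_1", "chr1", 100, 700)
  loci <- make_loci("chr1", "+", "50-800", "LOC1")
  hit <- function(id, blocks, identity, score = identity * 1000)
    data.frame(locus_id = id, chrom = "chr1", strand = "+",
               blocks = blocks, identity = identity, score = score,
               stringsAsFactors = FALSE)
  # one qualifying hit overlapping the LTR: retained
  r1 <- assign_unique_locus(loci, hit("LOC1", "50-800", 0.99), herv)
  expect_identical(nrow(r1$loci), 1L)
  # two equal-score qualifying hits: dropped
  r2 <- assign_unique_locus(loci, rbind(hit("LOC1", "50-800", 0.99),
                                        hit("LOC1", "5000-5750", 0.99)),
                            herv)
  expect_identical(nrow(r2$loci), 0L)
  expect_identical(attr(r2, "dropped")$reason, "multi_hit")
  # a second hit within the 1% identity margin also voids uniqueness
  r3 <- assign_unique_locus(loci, rbind(hit("LOC1", "50-800", 0.99),
                                        hit("LOC1", "5000-5750", 0.985)),
                            herv)
  expect_identical(nrow(r3$loci), 0L)
  # qualifying hit overlapping no HERV element: dropped
  r4 <- assign_unique_locus(loci, hit("LOC1", "5000-5750", 0.99), herv)
  expect_identical(attr(r4, "dropped")$reason, "no_herv_overlap")
  # zero hits: dropped with logged reason
  r5 <- assign_unique_locus(loci,
                            hit("OTHER", "50-800", 0.99), herv)
  expect_identical(attr(r5, "dropped")$reason, "no_hit")
})

test_that("call_expressed applies the count/TPM/fraction thresholds", {
  counts <- matrix(0, 3, 10, dimnames = list(paste0("L", 1:3),
                                             paste0("S", 1:10)))
  tpm <- counts
  counts[1, 1:5] <- 6;   tpm[1, 1:5] <- 0.1    # exactly half qualify
  counts[2, ] <- 5;      tpm[2, ] <- 5         # count never > 5
  counts[3, ] <- 100;    tpm[3, ] <- 0.09      # TPM below threshold
  groups <- stats::setNames(rep("siteA", 10), colnames(counts))
  e <- call_expressed(counts, tpm, groups)
  expect_identical(unname(e[, "siteA"]), c(TRUE, FALSE, FALSE))
  expect_error(call_expressed(counts, tpm,
                              stats::setNames(rep(NA_character_, 10),
                                              colnames(counts))))
})

test_that("deduplicate_loci merges identical or contained chains", {
  a <- make_loci("chr1", "+", c("100-400", "1000-1500"),
                 c("T1", "T2"))
  b <- make_loci("chr1", "+", c("100-400", "1100-1400", "9000-9500"),
                 c("L1", "L2", "L3"))
  d <- deduplicate_loci(list(testis = a, liver = b))
  # identical chains unify; contained chain folds into its container
  expect_identical(nrow(d$loci$loci), 3L)
  expect_true(all(grepl("^HERV_\\d{8}$", d$loci$loci$locus_id)))
  m <- d$membership
  expect_identical(length(unique(m$global_id[m$locus_id %in%
                                               c("T1", "L1")])), 1L)
  shared <- m$global_id[m$locus_id == "T2"]
  expect_identical(m$global_id[m$locus_id == "L2"], shared)
  # representative of the contained pair is the longer chain
  rep_blocks <- d$loci$loci$blocks[d$loci$loci$locus_id == shared]
  expect_identical(rep_blocks, "1000-1500")
  # opposite strand never merges
  c2 <- make_loci("chr1", "-", "100-400", "M1")
  d2 <- deduplicate_loci(list(s1 = a, s2 = c2))
  expect_identical(nrow(d2$loci$loci), 3L)
})

test_that("deduplication agrees with an exhaustive clustering oracle", {
  set.seed(29)
  for (rep in 1:5) {
    n <- sample(6:20, 1)
    blocks <- vapply(seq_len(n), function(i) {
      s <- sample(seq(0, 3000, 250), 1)
      encode_blocks(s, s + sample(c(100, 200, 400), 1))
    }, character(1))
    sets <- split(seq_len(n),
                  sample(c("s1", "s2"), n, replace = TRUE))
    per_site <- lapply(sets, function(ii)
      make_loci("chr1", "+", blocks[ii], sprintf("X%02d", ii)))
    d <- deduplicate_loci(per_site)
    # oracle: exhaustive pairwise identical-or-contained clustering
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n)
      adj[i, j] <- blocks[i] == blocks[j] ||
        blocks_contained_in(blocks[i], blocks[j]) ||
        blocks_contained_in(blocks[j], blocks[i])
    comp <- rep(NA_integer_, n); cid <- 0
    for (i in 1:n) if (is.na(comp[i])) {
      cid <- cid + 1; stack <- i
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        stack <- c(stack, which(adj[v, ] & is.na(comp)))
      }
    }
    expect_identical(nrow(d$loci$loci), length(unique(comp)))
  }
})

test_that("raising any threshold never enlarges the retained set", {
  cfg <- sim_config(seed = 17)
  ann <- simulate_annotation(cfg)
  tx <- simulate_transcripts(cfg, ann)
  base <- filter_candidates(tx, 5, 0.96)
  expect_true(all(filter_candidates(tx, 10, 0.96)$transcript_id %in%
                    base$transcript_id))
  expect_true(all(filter_candidates(tx, 5, 0.98)$transcript_id %in%
                    base$transcript_id))
  m_base <- merge_candidates(base, 8, 0.5, 200)
  m_len <- merge_candidates(base, 8, 0.5, 900)
  m_frac <- merge_candidates(base, 8, 0.75, 200)
  expect_true(all(m_len$loci$blocks %in% m_base$loci$blocks))
  expect_true(all(m_frac$loci$blocks %in% m_base$loci$blocks))
})
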