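genes_one <- function(strand, s = 1000, e = 9000)
  make_gene_models(data.frame(gene_id = "G1", chrom = "chr1", start = s,
                              end = e, strand = strand,
                              biotype = "protein_coding",
                              stringsAsFactors = FALSE))

test_that("location classes follow the stated priority", {
  loc <- make_loci("chr1", "-", "2000-3000", "L1")$loci[1, ]
  expect_identical(classify_location(loc, genes_one("+")), "antisense")
  loc2 <- make_loci("chr1", "+", "2000-3000", "L2")$loci[1, ]
  expect_identical(classify_location(loc2, genes_one("+")), "inserted")
  expect_identical(classify_location(loc2, genes_one("-")), "antisense")
  loc3 <- make_loci("chr1", "+", "20000-21000", "L3")$loci[1, ]
  expect_identical(classify_location(loc3, genes_one("+")), "intergenic")
  # same-strand overlap wins over opposite-strand overlap
  both <- make_gene_models(data.frame(
    gene_id = c("Gp", "Gm"), chrom = "chr1", start = 1000, end = 9000,
    strand = c("+", "-"), biotype = NA, stringsAsFactors = FALSE))
  expect_identical(classify_location(loc2, both), "inserted")
  un <- make_loci("chr1", ".", "2000-3000", "L4")$loci[1, ]
  expect_error(classify_location(un, genes_one("+")), "unstranded")
})

prov <- function(chrom = "chr1", base = 10000, pv = "PV1")
  rbind(make_herv_element("ERV_A", chrom, base, base + 600,
                          family = "HERVH", component = "LTR",
                          provirus_id = pv),
        make_herv_element("ERV_B", chrom, base + 600, base + 4000,
                          family = "HERVH-int", component = "INT",
                          provirus_id = pv),
        make_herv_element("ERV_C", chrom, base + 4000, base + 4600,
                          family = "HERVH", component = "LTR",
                          provirus_id = pv))

test_that("origin classes follow element and provirus structure", {
  solo <- make_herv_element("ERV_S", "chr1", 100, 700)
  herv <- rbind(solo, prov(base = 10000))
  l_solo <- make_loci("chr1", "+", "50-750", "L1")$loci[1, ]
  expect_identical(classify_origin(l_solo, herv), "solo-LTR")
  l_full <- make_loci("chr1", "+", "10000-14600", "L2")$loci[1, ]
  expect_identical(classify_origin(l_full, herv), "full-length")
  l_trunc <- make_loci("chr1", "+", "9900-12000", "L3")$loci[1, ]
  expect_identical(classify_origin(l_trunc, herv), "truncated")
  # one LTR of a provirus that has an INT annotation: truncated
  l_oneltr <- make_loci("chr1", "+", "10000-10500", "L4")$loci[1, ]
  expect_identical(classify_origin(l_oneltr, herv), "truncated")
  # elements of two provirus groups: chimeric
  herv2 <- rbind(solo,
                 make_herv_element("ERV_S2", "chr1", 800, 1400,
                                   family = "MLT2B4"))
  l_chim <- make_loci("chr1", "+", "50-1450", "L5")$loci[1, ]
  expect_identical(classify_origin(l_chim, herv2), "chimeric")
  l_none <- make_loci("chr1", "+", "90000-90500", "L6")$loci[1, ]
  expect_error(classify_origin(l_none, herv), "no HERV element")
})

test_that("full-length subtypes follow strand-aware geometry", {
  herv <- prov(base = 10000)
  g_empty <- make_gene_models(data.frame(gene_id = character(0),
                                         chrom = character(0),
                                         start = numeric(0),
                                         end = numeric(0),
                                         strand = character(0),
                                         biotype = character(0)))
  sub <- function(blocks, strand = "+", genes = g_empty)
    classify_fl_subtype(make_loci("chr1", strand, blocks)$loci[1, ],
                        herv, genes)
  expect_identical(sub("10000-14600"), "unit-length")
  expect_identical(sub("9500-14600"), "upstream-TSS")
  expect_identical(sub("10000-15600"), "3'-readthrough")
  # on the minus strand, upstream means a larger coordinate
  expect_identical(sub("10000-15600", strand = "-"), "upstream-TSS")
  expect_identical(sub("9500-14600", strand = "-"), "3'-readthrough")
  # containment in a host transcript wins over either extension
  host <- make_gene_models(
    data.frame(gene_id = "H", chrom = "chr1", start = 9000, end = 16000,
               strand = "+", biotype = NA, stringsAsFactors = FALSE),
    data.frame(gene_id = "H", transcript_id = "H.t1", chrom = "chr1",
               start = 9000, end = 16000, strand = "+",
               stringsAsFactors = FALSE))
  expect_identical(sub("9500-14600", genes = host), "host-chimeric")
  expect_error(classify_fl_subtype(
    make_loci("chr1", "+", "10000-10500")$loci[1, ], herv, g_empty),
    "non-full-length")
})

test_that("classification is a partition and is translation-invariant", {
  cfg <- sim_config(seed = 4)
  ann <- simulate_annotation(cfg)
  tx <- simulate_transcripts(cfg, ann)
  loci <- run_detection(tx, ann$herv, n_samples = cfg$n_samples,
                        remap_hits = NULL)
  loci$loci <- loci$loci[!vapply(seq_len(nrow(loci$loci)), function(i)
    nrow(hervtools:::overlapped_elements(loci$loci[i, ], ann$herv)) == 0,
    logical(1)), ]
  cl <- classify_loci(loci, ann$herv, ann$genes)
  expect_true(all(cl$loci$location %in% c("antisense", "intergenic",
                                          "inserted")))
  expect_true(all(cl$loci$origin %in% c("solo-LTR", "truncated",
                                        "chimeric", "full-length")))
  expect_identical(sum(table(cl$loci$location)), nrow(cl$loci))
  expect_identical(is.na(cl$loci$fl_subtype),
                   cl$loci$origin != "full-length")
  # translate every coordinate and rename the chromosome
  shift <- 12345
  shift_blocks <- function(b) {
    d <- decode_blocks(b); encode_blocks(d$start + shift, d$end + shift)
  }
  l2 <- loci
  l2$loci$chrom <- "chrZ"
  l2$loci$blocks <- vapply(l2$loci$blocks, shift_blocks, character(1))
  h2 <- ann$herv
  h2$chrom <- "chrZ"; h2$start <- h2$start + shift; h2$end <- h2$end + shift
  g2 <- ann$genes
  g2$genes$chrom <- "chrZ"
  g2$genes$start <- g2$genes$start + shift
  g2$genes$end <- g2$genes$end + shift
  g2$exons$chrom <- "chrZ"
  g2$exons$start <- g2$exons$start + shift
  g2$exons$end <- g2$exons$end + shift
  cl2 <- classify_loci(l2, h2, g2)
  expect_identical(cl2$loci$location, cl$loci$location)
  expect_identical(cl2$loci$origin, cl$loci$origin)
  expect_identical(cl2$loci$fl_subtype, cl$loci$fl_subtype)
})
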