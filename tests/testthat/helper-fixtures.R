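# Shared fixtures, built in code at test time.

make_loci <- function(chrom, strand, blocks, ids = NULL) {
  n <- length(blocks)
  if (is.null(ids)) ids <- sprintf("L%03d", seq_len(n))
  out <- hervtools:::empty_loci()
  out$loci <- data.frame(locus_id = ids, chrom = rep_len(chrom, n),
                         strand = rep_len(strand, n), blocks = blocks,
                         length = blocks_length(blocks),
                         n_supporting = 1L, stringsAsFactors = FALSE)
  out$supporting <- data.frame(locus_id = ids, sample_id = "S01")
  out
}

make_gene_models <- function(genes, exons = NULL) {
  if (is.null(exons))
    exons <- data.frame(gene_id = genes$gene_id,
                        transcript_id = if (nrow(genes))
                          paste0(genes$gene_id, ".t1") else character(0),
                        chrom = genes$chrom, start = genes$start,
                        end = genes$end, strand = genes$strand,
                        stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

make_herv_element <- function(element_id, chrom, start, end,
                              strand = "+", family = "LTR12C",
                              component = "LTR",
                              provirus_id = NA_character_) {
  data.frame(element_id = element_id, chrom = chrom, start = start,
             end = end, strand = strand, family = family,
             component = component, provirus_id = provirus_id,
             stringsAsFactors = FALSE)
}

# transcript-hit row builder
make_tx <- function(transcript_id, sample_id, start, end, chrom = "chr1",
                    strand = "+", support_count = 20, identity = 0.99,
                    score = identity * 1000) {
  data.frame(transcript_id = transcript_id, sample_id = sample_id,
             support_count = support_count, chrom = chrom,
             strand = strand, blocks = encode_blocks(start, end),
             identity = identity, score = score,
             stringsAsFactors = FALSE)
}

make_genotype_study <- function(dosage, chrom = "chr1",
                                pos = seq_len(nrow(dosage)) * 1000) {
  ids <- rownames(dosage)
  if (is.null(ids)) {
    ids <- sprintf("v%03d", seq_len(nrow(dosage)))
    rownames(dosage) <- ids
  }
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("I%03d", seq_len(ncol(dosage)))
  variants <- data.frame(variant_id = ids,
                         chrom = rep_len(chrom, nrow(dosage)),
                         pos = pos, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  variants$maf <- apply(dosage, 1, hervtools:::dosage_maf)
  structure(list(dosage = dosage, variants = variants,
                 individuals = colnames(dosage), n_skipped = 0L),
            class = "genotype_study")
}
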