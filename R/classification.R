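## Taxonomy of expressed-HERV loci: genomic location relative to host
## genes, retroviral origin relative to the element annotation, and
## structural subtype for full-length proviral transcripts.

#' Classify a locus by genomic location
#'
#' `inserted` if the locus overlaps any gene body on the same strand;
#' otherwise `antisense` if it overlaps any gene body on the opposite
#' strand; otherwise `intergenic`.  Gene-body (not exon-only) overlap is
#' used, since antisense HERVs typically sit in introns.  Overlap of at
#' least `min_overlap` bp counts.
#'
#' @param locus one row of a `herv_loci` table (with `chrom`, `strand`,
#'   `blocks`).
#' @param genes a `gene_models` object.
#' @param min_overlap minimum bp of overlap (default 1).
#' @return one of `"inserted"`, `"antisense"`, `"intergenic"`.
#' @export
classify_location <- function(locus, genes, min_overlap = 1) {
  if (locus$strand == ".") stop("unstranded locus: ", locus$locus_id)
  g <- genes$genes[genes$genes$chrom == locus$chrom, , drop = FALSE]
  if (nrow(g) == 0) return("intergenic")
  ov <- vapply(seq_len(nrow(g)), function(j)
    blocks_overlap_interval(locus$blocks, g$start[j], g$end[j]),
    numeric(1))
  hit <- ov >= min_overlap
  if (!any(hit)) return("intergenic")
  rel <- strand_relation(data.frame(strand = rep(locus$strand, nrow(g))),
                         data.frame(strand = g$strand))
  if (any(hit & rel == "same")) return("inserted")
  if (any(hit & rel == "opposite")) return("antisense")
  "intergenic"
}

## provirus grouping key: explicit provirus_id when present, otherwise
## each lone element is its own group
provirus_key <- function(herv) {
  ifelse(is.na(herv$provirus_id) | !nzchar(herv$provirus_id),
         paste0("lone:", herv$element_id), herv$provirus_id)
}

overlapped_elements <- function(locus, herv, min_overlap = 1) {
  h <- herv[herv$chrom == locus$chrom, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  ov <- vapply(seq_len(nrow(h)), function(j)
    blocks_overlap_interval(locus$blocks, h$start[j], h$end[j]),
    numeric(1))
  h[ov >= min_overlap, , drop = FALSE]
}

#' Classify a locus by retroviral origin
#'
#' Origin classes, from the elements the locus exon chain overlaps:
#' * `chimeric` — elements from two or more distinct provirus groups;
#' * `full-length` — one provirus whose 5' LTR, internal region, and
#'   3' LTR are all overlapped;
#' * `solo-LTR` — only LTR components overlapped and the provirus group
#'   has no internal-region annotation (the genomic solo-LTR state);
#' * `truncated` — everything else (partial overlap of a provirus that
#'   does have an internal region).
#'
#' @param locus one row of a `herv_loci` table.
#' @param herv HERV element table.
#' @param min_overlap minimum bp of overlap (default 1).
#' @return one of `"solo-LTR"`, `"truncated"`, `"chimeric"`,
#'   `"full-length"`.
#' @export
classify_origin <- function(locus, herv, min_overlap = 1) {
  hit <- overlapped_elements(locus, herv, min_overlap)
  if (nrow(hit) == 0)
    stop("locus overlaps no HERV element (detection contract violated): ",
         locus$locus_id)
  keys <- unique(provirus_key(hit))
  if (length(keys) >= 2) return("chimeric")
  group <- herv[provirus_key(herv) == keys, , drop = FALSE]
  hit_comp <- hit$component
  if (all(hit_comp == "LTR") && !any(group$component == "INT"))
    return("solo-LTR")
  # full provirus: both LTRs and the internal region overlapped
  n_ltr_group <- sum(group$component == "LTR")
  ltr_hit <- sum(hit_comp == "LTR")
  int_hit <- any(hit_comp == "INT")
  if (int_hit && n_ltr_group >= 2 && ltr_hit >= 2) return("full-length")
  "truncated"
}

#' Classify the subtype of a full-length locus
#'
#' Mutually exclusive subtypes, in priority order:
#' * `host-chimeric` — the locus exon chain is contained within a host
#'   gene transcript's exon chain on the same strand;
#' * `upstream-TSS` — the locus 5' end lies strictly upstream
#'   (strand-aware) of the provirus span;
#' * `3'-readthrough` — the locus 3' end lies strictly downstream of the
#'   provirus span;
#' * `unit-length` — the transcript matches the provirus structure.
#'
#' @param locus one row of a `herv_loci` table with origin
#'   `"full-length"`.
#' @param herv HERV element table.
#' @param genes a `gene_models` object.
#' @param min_overlap minimum bp of overlap (default 1).
#' @return one of `"unit-length"`, `"upstream-TSS"`, `"3'-readthrough"`,
#'   `"host-chimeric"`.
#' @export
classify_fl_subtype <- function(locus, herv, genes, min_overlap = 1) {
  if (classify_origin(locus, herv, min_overlap) != "full-length")
    stop("fl subtype requested for a non-full-length locus: ",
         locus$locus_id)
  hit <- overlapped_elements(locus, herv, min_overlap)
  key <- unique(provirus_key(hit))
  group <- herv[provirus_key(herv) == key, , drop = FALSE]
  pv_start <- min(group$start); pv_end <- max(group$end)
  # host-chimeric: exon chain contained in a same-strand transcript
  ex <- genes$exons[genes$exons$chrom == locus$chrom &
                      genes$exons$strand == locus$strand, , drop = FALSE]
  for (tid in unique(ex$transcript_id)) {
    te <- ex[ex$transcript_id == tid, , drop = FALSE]
    chain <- encode_blocks(te$start, te$end)
    if (blocks_contained_in(locus$blocks, chain)) return("host-chimeric")
  }
  span <- blocks_span(locus$blocks)
  if (locus$strand == "+") {
    five_up <- span[1] < pv_start
    three_down <- span[2] > pv_end
  } else {
    five_up <- span[2] > pv_end
    three_down <- span[1] < pv_start
  }
  if (five_up) return("upstream-TSS")
  if (three_down) return("3'-readthrough")
  "unit-length"
}

#' Classify all loci
#'
#' Adds `location`, `origin`, and (for full-length loci) `fl_subtype`
#' columns to a `herv_loci` object.
#'
#' @param loci a `herv_loci` object.
#' @param herv HERV element table.
#' @param genes a `gene_models` object.
#' @param min_overlap minimum bp of overlap (default 1).
#' @return the annotated `herv_loci`.
#' @export
classify_loci <- function(loci, herv, genes, min_overlap = 1) {
  df <- loci$loci
  n <- nrow(df)
  df$location <- character(n)
  df$origin <- character(n)
  df$fl_subtype <- NA_character_
  for (i in seq_len(n)) {
    row <- df[i, , drop = FALSE]
    df$location[i] <- classify_location(row, genes, min_overlap)
    df$origin[i] <- classify_origin(row, herv, min_overlap)
    if (df$origin[i] == "full-length")
      df$fl_subtype[i] <- classify_fl_subtype(row, herv, genes,
                                              min_overlap)
  }
  loci$loci <- df
  loci
}
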