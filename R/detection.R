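## Detection of candidate expressed-HERV loci from alignment abstractions.
## The upstream aligners/assemblers (splice-aware alignment, de novo
## assembly, meta-assembly) are consumed as tabular summaries; the
## decision logic around them — read selection, identity/count gating,
## recurrence/length merging, unique-locus assignment, expression
## calling — is implemented here.

#' Select HERV-informative reads
#'
#' A read is selected iff at least one aligned block overlaps a HERV
#' element and no block overlaps any annotated gene exon.  Strand is
#' ignored at this stage.
#'
#' @param reads `data.frame` with columns `read_id`, `sample_id`,
#'   `chrom`, `blocks` (encoded exon/block chain, see [encode_blocks()]).
#' @param herv HERV element table as returned by
#'   `read_annotation(format = "HERVd-BED")`.
#' @param genes a `gene_models` object.
#' @return the selected subset of `reads`.
#' @export
select_herv_reads <- function(reads, herv, genes) {
  exons <- genes$exons
  sel <- vapply(seq_len(nrow(reads)), function(i) {
    b <- reads$blocks[i]; chrom <- reads$chrom[i]
    h <- herv[herv$chrom == chrom, , drop = FALSE]
    hit_herv <- nrow(h) > 0 && any(vapply(seq_len(nrow(h)), function(j)
      blocks_overlap_interval(b, h$start[j], h$end[j]) > 0, logical(1)))
    if (!hit_herv) return(FALSE)
    e <- exons[exons$chrom == chrom, , drop = FALSE]
    hit_exon <- nrow(e) > 0 && any(vapply(seq_len(nrow(e)), function(j)
      blocks_overlap_interval(b, e$start[j], e$end[j]) > 0, logical(1)))
    !hit_exon
  }, logical(1))
  reads[sel, , drop = FALSE]
}

#' Alignment identity
#'
#' Fraction of aligned columns that match the reference:
#' `matched / (matched + mismatched + inserted + deleted)`.
#'
#' @param matched,mismatched,inserted,deleted non-negative counts.
#' @return identity fraction in `[0, 1]`.
#' @export
alignment_identity <- function(matched, mismatched, inserted = 0,
                               deleted = 0) {
  if (any(c(matched, mismatched, inserted, deleted) < 0))
    stop("alignment counts must be non-negative")
  if (all(matched + mismatched == 0))
    stop("no aligned bases: matched + mismatched must be > 0")
  matched / (matched + mismatched + inserted + deleted)
}

#' Filter assembled-transcript alignments
#'
#' Retains transcripts with a read-support count strictly greater than
#' `min_count` and a best-hit identity of at least `min_identity`, and
#' returns only the best hit (highest score) per retained transcript.
#'
#' @param alignments `data.frame` with one row per hit: `transcript_id`,
#'   `sample_id`, `support_count`, `chrom`, `strand`, `blocks`,
#'   `identity`, `score`.
#' @param min_count support-count threshold (strict `>`; default 5).
#' @param min_identity identity threshold (non-strict `>=`; default 0.96).
#' @return the retained best-hit rows.
#' @export
filter_candidates <- function(alignments, min_count = 5,
                              min_identity = 0.96) {
  if (nrow(alignments) == 0) return(alignments)
  o <- order(alignments$transcript_id, alignments$sample_id,
             -alignments$score)
  a <- alignments[o, , drop = FALSE]
  key <- paste(a$transcript_id, a$sample_id, sep = "\r")
  best <- a[!duplicated(key), , drop = FALSE]
  keep <- best$support_count > min_count & best$identity >= min_identity
  rownames(best) <- NULL
  best[keep, , drop = FALSE]
}

#' Merge per-sample candidates into consensus loci
#'
#' Transcripts are clustered by single-linkage on same-strand exon-chain
#' overlap (>= 1 bp); the consensus exon chain of a cluster is the union
#' of its members' exons.  A locus is kept iff it is supported by at
#' least `ceiling(min_sample_fraction * n_samples)` samples and its
#' consensus length is at least `min_len` bp.
#'
#' @param candidates best-hit rows from [filter_candidates()].
#' @param n_samples size of the sample group being processed (the
#'   recurrence denominator); defaults to the number of distinct samples
#'   in `candidates`.
#' @param min_sample_fraction recurrence threshold (default 0.5).
#' @param min_len minimum consensus length in bp (default 200).
#' @param id_prefix prefix for generated locus ids.
#' @return a `herv_loci` object: list with `loci`
#'   (`locus_id`, `chrom`, `strand`, `blocks`, `length`, `n_supporting`)
#'   and `supporting` (`locus_id`, `sample_id`); dropped clusters are
#'   recorded in `attr(, "dropped")`.
#' @export
merge_candidates <- function(candidates,
                             n_samples = length(unique(candidates$sample_id)),
                             min_sample_fraction = 0.5, min_len = 200,
                             id_prefix = "LOCUS") {
  empty <- empty_loci()
  if (nrow(candidates) == 0) return(empty)
  comp <- rep(NA_integer_, nrow(candidates))
  next_comp <- 0L
  groups <- split(seq_len(nrow(candidates)),
                  paste(candidates$chrom, candidates$strand, sep = "\r"))
  for (g in groups) {
    # union-find over pairwise chain overlaps within one (chrom, strand)
    parent <- seq_along(g)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (length(g) > 1) {
      for (i in seq_along(g)[-1]) for (j in seq_len(i - 1)) {
        if (blocks_overlap_blocks(candidates$blocks[g[i]],
                                  candidates$blocks[g[j]]) > 0) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_along(g), find, integer(1))
    comp[g] <- next_comp + match(roots, unique(roots))
    next_comp <- next_comp + length(unique(roots))
  }
  min_support <- ceiling(min_sample_fraction * n_samples)
  loci <- list(); supporting <- list(); dropped <- list()
  for (cl in sort(unique(comp))) {
    rows <- candidates[comp == cl, , drop = FALSE]
    blocks <- union_blocks(rows$blocks)
    len <- blocks_length(blocks)
    samples <- sort(unique(rows$sample_id))
    rec <- data.frame(chrom = rows$chrom[1], strand = rows$strand[1],
                      blocks = blocks, length = len,
                      n_supporting = length(samples),
                      stringsAsFactors = FALSE)
    if (length(samples) < min_support) {
      rec$reason <- "recurrence"
      dropped[[length(dropped) + 1]] <- rec
    } else if (len < min_len) {
      rec$reason <- "length"
      dropped[[length(dropped) + 1]] <- rec
    } else {
      loci[[length(loci) + 1]] <- rec
      supporting[[length(supporting) + 1]] <-
        data.frame(sample_id = samples, stringsAsFactors = FALSE)
    }
  }
  out <- empty
  if (length(loci)) {
    df <- do.call(rbind, loci)
    # deterministic genomic order before id assignment
    starts <- vapply(df$blocks, function(b) blocks_span(b)[1], numeric(1))
    o <- order(df$chrom, starts, df$strand)
    df <- df[o, , drop = FALSE]
    df$locus_id <- sprintf("%s_%05d", id_prefix, seq_len(nrow(df)))
    sup <- do.call(rbind, lapply(seq_along(o), function(k)
      data.frame(locus_id = df$locus_id[k],
                 sample_id = supporting[[o[k]]]$sample_id,
                 stringsAsFactors = FALSE)))
    rownames(df) <- NULL
    out$loci <- df[, c("locus_id", "chrom", "strand", "blocks", "length",
                       "n_supporting")]
    out$supporting <- sup
  }
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
                          else NULL
  out
}

empty_loci <- function() {
  structure(list(
    loci = data.frame(locus_id = character(0), chrom = character(0),
                      strand = character(0), blocks = character(0),
                      length = numeric(0), n_supporting = integer(0),
                      stringsAsFactors = FALSE),
    supporting = data.frame(locus_id = character(0),
                            sample_id = character(0),
                            stringsAsFactors = FALSE)),
    class = "herv_loci")
}

#' @export
print.herv_loci <- function(x, ...) {
  cat("herv_loci: ", nrow(x$loci), " loci\n", sep = "")
  if (nrow(x$loci)) print(utils::head(x$loci, 10))
  invisible(x)
}

#' Enforce unique HERV-locus assignment
#'
#' After re-mapping merged loci to the genome, a locus is retained iff
#' exactly one hit passes the identity gate, no other hit lies within
#' `margin` identity of the best hit (guarding against score ties), and
#' the unique hit's exon chain overlaps at least one HERV element.
#' Retained loci take their final coordinates from the unique hit.
#'
#' @param loci a `herv_loci` object.
#' @param remap_hits `data.frame` with columns `locus_id`, `chrom`,
#'   `strand`, `blocks`, `identity`, `score` (one row per hit).
#' @param herv HERV element table.
#' @param min_identity identity gate (default 0.96).
#' @param margin uniqueness margin on identity (default 0.01).
#' @return the retained `herv_loci`, with per-locus drop reasons in
#'   `attr(, "dropped")`.
#' @export
assign_unique_locus <- function(loci, remap_hits, herv,
                                min_identity = 0.96, margin = 0.01) {
  keep <- logical(nrow(loci$loci))
  reason <- character(nrow(loci$loci))
  newgeom <- loci$loci
  for (i in seq_len(nrow(loci$loci))) {
    lid <- loci$loci$locus_id[i]
    hits <- remap_hits[remap_hits$locus_id == lid, , drop = FALSE]
    if (nrow(hits) == 0) { reason[i] <- "no_hit"; next }
    qual <- hits[hits$identity >= min_identity, , drop = FALSE]
    if (nrow(qual) == 0) { reason[i] <- "identity"; next }
    if (nrow(qual) > 1) { reason[i] <- "multi_hit"; next }
    near <- sum(hits$identity >= qual$identity[1] - margin)
    if (near > 1) { reason[i] <- "multi_hit"; next }
    h <- herv[herv$chrom == qual$chrom[1], , drop = FALSE]
    ov <- nrow(h) > 0 && any(vapply(seq_len(nrow(h)), function(j)
      blocks_overlap_interval(qual$blocks[1], h$start[j], h$end[j]) > 0,
      logical(1)))
    if (!ov) { reason[i] <- "no_herv_overlap"; next }
    keep[i] <- TRUE
    newgeom$chrom[i] <- qual$chrom[1]
    newgeom$strand[i] <- qual$strand[1]
    newgeom$blocks[i] <- qual$blocks[1]
    newgeom$length[i] <- blocks_length(qual$blocks[1])
  }
  out <- empty_loci()
  out$loci <- newgeom[keep, , drop = FALSE]
  rownames(out$loci) <- NULL
  out$supporting <- loci$supporting[
    loci$supporting$locus_id %in% out$loci$locus_id, , drop = FALSE]
  dropped <- data.frame(locus_id = loci$loci$locus_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "dropped") <- if (nrow(dropped)) dropped else NULL
  out
}

#' Call per-body-site expression
#'
#' A locus is expressed in a body site iff the fraction of that site's
#' samples with raw count strictly greater than `min_count` and TPM of at
#' least `min_tpm` reaches `min_fraction`.
#'
#' @param counts,tpm loci x samples matrices sharing dimnames.
#' @param groups named character vector mapping sample id to body site.
#' @param min_count raw-count threshold (strict `>`; default 5).
#' @param min_tpm TPM threshold (non-strict `>=`; default 0.1).
#' @param min_fraction fraction-of-samples threshold (default 0.5).
#' @return logical matrix, loci x body sites.
#' @export
call_expressed <- function(counts, tpm, groups, min_count = 5,
                           min_tpm = 0.1, min_fraction = 0.5) {
  stopifnot(identical(dim(counts), dim(tpm)),
            identical(colnames(counts), colnames(tpm)))
  groups <- groups[colnames(counts)]
  if (anyNA(groups) || anyNA(names(groups)))
    stop("every sample needs a body-site assignment")
  sites <- sort(unique(groups))
  pass <- counts > min_count & tpm >= min_tpm
  out <- vapply(sites, function(s) {
    cols <- which(groups == s)
    if (length(cols) == 0) stop("body site with 0 samples: ", s)
    rowMeans(pass[, cols, drop = FALSE]) >= min_fraction
  }, logical(nrow(counts)))
  if (nrow(counts) == 1) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(counts),
                                                       sites))
  out
}

#' Deduplicate loci across body sites
#'
#' Loci from different body sites are clustered whenever their exon
#' chains are identical, or one is contained in the other, on the same
#' strand (single linkage).  The representative of a cluster is its
#' longest chain; global ids `HERV_xxxxxxxx` are assigned in
#' deterministic genomic sort order.
#'
#' @param per_site_loci named list, body site -> `herv_loci` object.
#' @return list with `loci` (a unified `herv_loci`) and `membership`
#'   (`data.frame` mapping `global_id` to `body_site` and the original
#'   `locus_id`).
#' @export
deduplicate_loci <- function(per_site_loci) {
  rows <- do.call(rbind, lapply(names(per_site_loci), function(s) {
    df <- per_site_loci[[s]]$loci
    if (nrow(df) == 0) return(NULL)
    df$body_site <- s
    df
  }))
  if (is.null(rows) || nrow(rows) == 0)
    return(list(loci = empty_loci(),
                membership = data.frame(global_id = character(0),
                                        body_site = character(0),
                                        locus_id = character(0))))
  n <- nrow(rows)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (rows$chrom[i] != rows$chrom[j] || rows$strand[i] != rows$strand[j])
      next
    a <- rows$blocks[i]; b <- rows$blocks[j]
    if (a == b || blocks_contained_in(a, b) || blocks_contained_in(b, a)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(seq_len(n), roots), function(idx)
    idx[which.max(rows$length[idx])], integer(1))
  rep_rows <- rows[reps, , drop = FALSE]
  starts <- vapply(rep_rows$blocks, function(b) blocks_span(b)[1],
                   numeric(1))
  o <- order(rep_rows$chrom, starts, rep_rows$strand)
  rep_rows <- rep_rows[o, , drop = FALSE]
  rep_rows$global_id <- sprintf("HERV_%08d", seq_len(nrow(rep_rows)))
  cluster_of <- match(roots, as.integer(names(split(seq_len(n), roots))))
  # map each original row to its representative's global id
  root_ids <- roots[reps][o]
  gid <- rep_rows$global_id[match(roots, root_ids)]
  membership <- data.frame(global_id = gid, body_site = rows$body_site,
                           locus_id = rows$locus_id,
                           stringsAsFactors = FALSE)
  out <- empty_loci()
  out$loci <- data.frame(locus_id = rep_rows$global_id,
                         chrom = rep_rows$chrom, strand = rep_rows$strand,
                         blocks = rep_rows$blocks,
                         length = rep_rows$length,
                         n_supporting = rep_rows$n_supporting,
                         stringsAsFactors = FALSE)
  out$supporting <- data.frame(locus_id = character(0),
                               sample_id = character(0))
  list(loci = out, membership = membership)
}
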