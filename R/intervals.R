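#' Genomic interval constructor
#'
#' Builds a data frame of genomic intervals in the package-internal
#' convention: 0-based half-open `[start, end)`, strand one of `"+"`,
#' `"-"`, `"."`.  All public functions in the package exchange intervals
#' in this shape; conversion to and from 1-based formats (GTF, VCF)
#' happens only inside the readers and writers.
#'
#' @param chrom chromosome name(s).
#' @param start 0-based inclusive start(s).
#' @param end 0-based exclusive end(s); must satisfy `start < end`.
#' @param strand strand symbol(s), `"+"`, `"-"` or `"."`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
gi <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (any(df$start < 0)) stop("start must be >= 0")
  if (any(df$start >= df$end)) stop("interval start must be < end")
  df
}

#' Overlap length of two intervals
#'
#' Number of shared base pairs between two half-open intervals; 0 when the
#' chromosomes differ or the intervals abut or are disjoint.  Vectorised
#' over rows; symmetric in its arguments.
#'
#' @param a,b interval data frames as built by [gi()] (recycled row-wise).
#' @return integer vector of overlap lengths in bp (>= 0).
#' @export
overlap_len <- function(a, b) {
  same <- a$chrom == b$chrom
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  as.integer(ifelse(same, pmax(0, ov), 0))
}

#' Strand relation between two intervals
#'
#' `"same"` iff both strands are equal and known; `"opposite"` for a
#' `{+,-}` pair; `"undefined"` whenever either strand is `"."`.  An
#' unknown strand never counts as same or opposite, keeping downstream
#' antisense/sense classification conservative.
#'
#' @param a,b interval data frames (recycled row-wise).
#' @return character vector in `{"same", "opposite", "undefined"}`.
#' @export
strand_relation <- function(a, b) {
  sa <- a$strand; sb <- b$strand
  out <- rep("undefined", max(length(sa), length(sb)))
  known <- sa != "." & sb != "."
  out[known & sa == sb] <- "same"
  out[known & sa != sb] <- "opposite"
  out
}

#' Distance to the nearest transcription start site
#'
#' @param pos query position(s), bp.
#' @param tss_positions numeric vector of TSS positions (need not be sorted).
#' @return minimum absolute distance for each `pos`.
#' @export
nearest_tss_distance <- function(pos, tss_positions) {
  if (length(tss_positions) == 0) stop("no TSS available")
  tss <- sort(as.numeric(tss_positions))
  vapply(as.numeric(pos), function(p) min(abs(p - tss)), numeric(1))
}

## ---- exon-chain block encoding -------------------------------------------
## Exon chains travel inside flat tables as "start-end;start-end" strings
## (0-based half-open, sorted, disjoint), so every intermediate product is
## a plain TSV-serialisable data frame.

#' Encode an exon chain as a compact block string
#'
#' @param start,end numeric vectors of 0-based half-open exon coordinates.
#' @return single string `"s1-e1;s2-e2;..."` with exons sorted by start.
#' @export
encode_blocks <- function(start, end) {
  o <- order(start)
  paste(sprintf("%d-%d", as.integer(start[o]), as.integer(end[o])),
        collapse = ";")
}

#' Decode a block string into an exon table
#'
#' @param blocks a block string produced by [encode_blocks()].
#' @return `data.frame` with columns `start`, `end`, sorted by start.
#' @export
decode_blocks <- function(blocks) {
  parts <- strsplit(blocks, ";", fixed = TRUE)[[1]]
  m <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
  df <- data.frame(start = as.numeric(m[, 1]), end = as.numeric(m[, 2]))
  if (any(df$start >= df$end)) stop("malformed block string: ", blocks)
  df[order(df$start), , drop = FALSE]
}

#' Total length of an encoded exon chain
#' @param blocks block string(s).
#' @return numeric vector of summed exon lengths.
#' @export
blocks_length <- function(blocks) {
  vapply(blocks, function(b) {
    d <- decode_blocks(b); sum(d$end - d$start)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Genomic span of an encoded exon chain
#' @param blocks a block string.
#' @return numeric `c(start, end)` of the chain's outermost coordinates.
#' @export
blocks_span <- function(blocks) {
  d <- decode_blocks(blocks)
  c(min(d$start), max(d$end))
}

#' Union of several exon chains
#'
#' Merges overlapping or abutting exons into a minimal disjoint chain.
#'
#' @param block_list character vector of block strings on one chromosome.
#' @return a single block string covering the union.
#' @export
union_blocks <- function(block_list) {
  d <- do.call(rbind, lapply(block_list, decode_blocks))
  d <- d[order(d$start, d$end), , drop = FALSE]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(d))) {
    if (length(out_s) && d$start[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], d$end[i])
    } else {
      out_s <- c(out_s, d$start[i]); out_e <- c(out_e, d$end[i])
    }
  }
  encode_blocks(out_s, out_e)
}

#' Overlap length between an exon chain and an interval
#'
#' @param blocks a block string.
#' @param start,end 0-based half-open interval.
#' @return total bp of the chain lying inside `[start, end)`.
#' @export
blocks_overlap_interval <- function(blocks, start, end) {
  d <- decode_blocks(blocks)
  sum(pmax(0, pmin(d$end, end) - pmax(d$start, start)))
}

#' Overlap length between two exon chains
#' @param a,b block strings.
#' @return total shared bp between the two chains.
#' @export
blocks_overlap_blocks <- function(a, b) {
  db <- decode_blocks(b)
  sum(vapply(seq_len(nrow(db)), function(i)
    blocks_overlap_interval(a, db$start[i], db$end[i]), numeric(1)))
}

#' Is exon chain `a` contained in exon chain `b`?
#'
#' TRUE iff every exon of `a` lies entirely within some exon of `b`.
#' @param a,b block strings.
#' @return logical scalar.
#' @export
blocks_contained_in <- function(a, b) {
  da <- decode_blocks(a); db <- decode_blocks(b)
  all(vapply(seq_len(nrow(da)), function(i)
    any(db$start <= da$start[i] & da$end[i] <= db$end), logical(1)))
}
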