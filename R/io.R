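## Readers and writers for the external formats the toolkit touches.
## Internal coordinates are 0-based half-open; GTF and VCF are converted
## at these boundaries and nowhere else.

#' Read a gene or HERV-element annotation
#'
#' Supported formats:
#' * `"GTF"` — Gencode-style; 1-based inclusive coordinates are converted
#'   to internal 0-based half-open.  Returns a `gene_models` object.
#' * `"BED6"` — plain BED; returns a `gene_models` object with one
#'   single-exon transcript per line.
#' * `"HERVd-BED"` — BED6 dialect in which column 4 encodes
#'   `ERV_<id>_<family[,family...]>`; an optional column 7 overrides the
#'   LTR/INT component and an optional column 8 carries a provirus
#'   grouping id.  Returns a `data.frame` of HERV elements.
#'
#' Records on chromosomes absent from any reference are retained; no
#' reference check is performed.
#'
#' @param path file path.
#' @param format one of `"GTF"`, `"BED6"`, `"HERVd-BED"`.
#' @return see above.
#' @export
read_annotation <- function(path, format = c("GTF", "BED6", "HERVd-BED")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  switch(format,
         "GTF" = parse_gtf(lines, keep),
         "BED6" = parse_bed6(lines, keep),
         "HERVd-BED" = parse_hervd_bed(lines, keep))
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

parse_gtf <- function(lines, keep) {
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9)
  if (length(bad))
    stop("malformed GTF line ", idx[bad[1]], ": expected 9 tab-separated fields")
  m <- do.call(rbind, lapply(fields, function(f) f[1:9]))
  start1 <- suppressWarnings(as.numeric(m[, 4]))
  end1 <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad))
    stop("malformed GTF line ", idx[bad[1]], ": non-numeric coordinates")
  bad <- which(start1 > end1)
  if (length(bad))
    stop("malformed GTF line ", idx[bad[1]], ": start > end")
  df <- data.frame(chrom = m[, 1], feature = m[, 3],
                   start = start1 - 1, end = end1,  # to 0-based half-open
                   strand = m[, 7], attrs = m[, 9],
                   stringsAsFactors = FALSE)
  df$gene_id <- gtf_attr(df$attrs, "gene_id")
  df$transcript_id <- gtf_attr(df$attrs, "transcript_id")
  exons <- df[df$feature == "exon", ]
  gene_rows <- df[df$feature == "gene", ]
  if (nrow(gene_rows) == 0 && nrow(exons) > 0) {
    # derive gene spans from exons when explicit gene rows are absent
    sp <- stats::aggregate(cbind(start, end) ~ gene_id + chrom + strand,
                           data = exons,
                           FUN = function(x) x[1])
    agg_s <- tapply(exons$start, exons$gene_id, min)
    agg_e <- tapply(exons$end, exons$gene_id, max)
    sp$start <- as.numeric(agg_s[sp$gene_id])
    sp$end <- as.numeric(agg_e[sp$gene_id])
    gene_rows <- sp
    gene_rows$attrs <- ""
  }
  genes <- data.frame(gene_id = gene_rows$gene_id,
                      chrom = gene_rows$chrom,
                      start = gene_rows$start, end = gene_rows$end,
                      strand = gene_rows$strand,
                      biotype = gtf_attr(gene_rows$attrs, "gene_type"),
                      stringsAsFactors = FALSE)
  # extra attributes some producers attach to exon rows
  for (key in c("support_count", "identity", "n_hits",
                "location", "origin", "fl_subtype")) {
    v <- gtf_attr(df$attrs, key)
    if (any(!is.na(v))) genes[[key]] <- gtf_attr(gene_rows$attrs, key)
  }
  ex <- exons[order(exons$gene_id, exons$transcript_id, exons$start),
              c("gene_id", "transcript_id", "chrom", "start", "end", "strand")]
  rownames(ex) <- NULL
  structure(list(genes = genes, exons = ex), class = "gene_models")
}

parse_bed_common <- function(lines, keep, min_cols) {
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  # tolerate space-separated BED
  one <- lengths(fields) == 1
  fields[one] <- strsplit(lines[idx][one], "[ \t]+")
  bad <- which(lengths(fields) < min_cols)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": fewer than ", min_cols,
         " columns")
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": bad coordinates")
  list(fields = fields, start = start, end = end)
}

parse_bed6 <- function(lines, keep) {
  p <- parse_bed_common(lines, keep, 3)
  n <- length(p$fields)
  getcol <- function(i, default)
    vapply(p$fields, function(f) if (length(f) >= i) f[i] else default, "")
  name <- getcol(4, "")
  strand <- getcol(6, ".")
  name[!nzchar(name)] <- paste0("feature_", which(!nzchar(name)))
  genes <- data.frame(gene_id = name,
                      chrom = vapply(p$fields, `[`, "", 1),
                      start = p$start, end = p$end, strand = strand,
                      biotype = NA_character_, stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = name, transcript_id = paste0(name, ".t1"),
                      chrom = genes$chrom, start = p$start, end = p$end,
                      strand = strand, stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

parse_hervd_bed <- function(lines, keep) {
  p <- parse_bed_common(lines, keep, 6)
  chrom <- vapply(p$fields, `[`, "", 1)
  name <- vapply(p$fields, `[`, "", 4)
  strand <- vapply(p$fields, `[`, "", 6)
  m <- regmatches(name, regexec("^(ERV_[0-9A-Za-z]+)_(.+)$", name))
  bad <- which(lengths(m) != 3)
  if (length(bad))
    stop("malformed HERVd name at line ", which(keep)[bad[1]], ": ", name[bad[1]])
  element_id <- vapply(m, `[`, "", 2)
  family <- vapply(m, `[`, "", 3)
  getcol <- function(i)
    vapply(p$fields, function(f)
      if (length(f) >= i && nzchar(f[i])) f[i] else NA_character_, "")
  component <- getcol(7)
  infer <- ifelse(grepl("-int(,|$)", family), "INT", "LTR")
  component[is.na(component)] <- infer[is.na(component)]
  data.frame(element_id = element_id, chrom = chrom,
             start = p$start, end = p$end, strand = strand,
             family = family, component = component,
             provirus_id = getcol(8), stringsAsFactors = FALSE)
}

#' Read genotypes from a VCF
#'
#' Keeps biallelic SNVs only; multi-allelic or non-SNV records are skipped
#' and counted.  GT is taken from the first colon-separated subfield;
#' dosage is the number of alternate alleles (0/1/2) or `NA` when any
#' allele is missing.
#'
#' @param vcf_path path to an uncompressed VCF v4.x file.
#' @return a `genotype_study`: list with `dosage` (variants x individuals
#'   integer matrix, `NA` = missing), `variants` (metadata with 0-based
#'   `pos`, `maf`), `individuals`, and `n_skipped`.
#' @export
read_genotypes <- function(vcf_path) {
  lines <- readLines(vcf_path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("VCF header line (#CHROM) not found")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  individuals <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body) & !grepl("^#", body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ref <- vapply(fields, `[`, "", 4)
  alt <- vapply(fields, `[`, "", 5)
  ok <- !grepl(",", alt, fixed = TRUE) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!ok)
  fields <- fields[ok]
  if (length(fields) == 0)
    stop("no biallelic SNV records in ", vcf_path)
  gt_dosage <- function(gt) {
    gt <- sub(":.*", "", gt)
    a <- strsplit(gt, "[|/]")
    vapply(a, function(x) {
      if (any(x == ".") || length(x) == 0) return(NA_integer_)
      sum(as.integer(x))
    }, integer(1))
  }
  dosage <- t(vapply(fields, function(f) gt_dosage(f[-(1:9)]),
                     integer(length(individuals))))
  ids <- vapply(fields, `[`, "", 3)
  noid <- ids == "." | !nzchar(ids)
  chrom <- vapply(fields, `[`, "", 1)
  pos1 <- as.numeric(vapply(fields, `[`, "", 2))
  ids[noid] <- paste0(chrom[noid], ":", pos1[noid])
  dimnames(dosage) <- list(ids, individuals)
  variants <- data.frame(variant_id = ids, chrom = chrom,
                         pos = pos1 - 1,   # to 0-based
                         ref = ref[ok], alt = alt[ok],
                         stringsAsFactors = FALSE)
  variants$maf <- apply(dosage, 1, dosage_maf)
  structure(list(dosage = dosage, variants = variants,
                 individuals = individuals, n_skipped = n_skipped),
            class = "genotype_study")
}

dosage_maf <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) == 0) return(NA_real_)
  af <- sum(d) / (2 * length(d))
  min(af, 1 - af)
}

#' Write a set of HERV loci as GTF
#'
#' Emits one `gene`, one `transcript`, and one `exon` row per exon for
#' each locus, converting internal 0-based half-open coordinates to GTF's
#' 1-based inclusive convention.  Classification labels, when present,
#' travel as attributes and survive a round trip through
#' [read_annotation()].
#'
#' @param loci a `herv_loci` object (see [merge_candidates()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_gtf <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## hervtools locus annotation", con)
  df <- loci$loci
  for (i in seq_len(nrow(df))) {
    lid <- df$locus_id[i]
    ex <- decode_blocks(df$blocks[i])
    extra <- ""
    for (key in c("location", "origin", "fl_subtype")) {
      if (!is.null(df[[key]]) && !is.na(df[[key]][i]))
        extra <- paste0(extra, sprintf(' %s "%s";', key, df[[key]][i]))
    }
    at <- sprintf('gene_id "%s"; transcript_id "%s.t1";%s', lid, lid, extra)
    span <- c(min(ex$start), max(ex$end))
    row <- function(feat, s, e)
      sprintf("%s\thervtools\t%s\t%d\t%d\t.\t%s\t.\t%s",
              df$chrom[i], feat, as.integer(s) + 1L, as.integer(e),
              df$strand[i], at)
    writeLines(row("gene", span[1], span[2]), con)
    writeLines(row("transcript", span[1], span[2]), con)
    for (j in seq_len(nrow(ex)))
      writeLines(row("exon", ex$start[j], ex$end[j]), con)
  }
  invisible(path)
}

#' Read a per-sample assembled-transcript GTF
#'
#' Inverse of [write_transcript_gtf()]: exon rows carrying `sample_id`,
#' `support_count`, `identity` attributes are regrouped into one row
#' per transcript hit with an encoded exon chain.
#'
#' @param path GTF path.
#' @return transcript-hit `data.frame` for [filter_candidates()].
#' @export
read_transcript_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9)
  if (length(bad))
    stop("malformed GTF line ", idx[bad[1]])
  m <- do.call(rbind, lapply(fields, function(f) f[1:9]))
  ex <- data.frame(chrom = m[, 1], start = as.numeric(m[, 4]) - 1,
                   end = as.numeric(m[, 5]), score = m[, 6],
                   strand = m[, 7], attrs = m[, 9],
                   stringsAsFactors = FALSE)
  ex <- ex[m[, 3] == "exon", , drop = FALSE]
  ex$transcript_id <- gtf_attr(ex$attrs, "transcript_id")
  ex$sample_id <- gtf_attr(ex$attrs, "sample_id")
  ex$support_count <- as.numeric(gtf_attr(ex$attrs, "support_count"))
  ex$identity <- as.numeric(gtf_attr(ex$attrs, "identity"))
  rows <- lapply(split(seq_len(nrow(ex)), ex$transcript_id), function(ii) {
    e <- ex[ii, , drop = FALSE]
    data.frame(transcript_id = e$transcript_id[1],
               sample_id = e$sample_id[1],
               support_count = e$support_count[1],
               chrom = e$chrom[1], strand = e$strand[1],
               blocks = encode_blocks(e$start, e$end),
               identity = e$identity[1],
               score = suppressWarnings(as.numeric(e$score[1])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a locus GTF back into a `herv_loci` object
#'
#' Inverse of [write_locus_gtf()]; classification attributes, when
#' present, are restored as columns.
#'
#' @param path GTF path.
#' @return a `herv_loci` object.
#' @export
read_locus_gtf <- function(path) {
  gm <- read_annotation(path, "GTF")
  out <- empty_loci()
  if (nrow(gm$genes) == 0) return(out)
  g <- gm$genes
  blocks <- vapply(g$gene_id, function(gid) {
    e <- gm$exons[gm$exons$gene_id == gid, , drop = FALSE]
    encode_blocks(e$start, e$end)
  }, character(1))
  df <- data.frame(locus_id = g$gene_id, chrom = g$chrom,
                   strand = g$strand, blocks = unname(blocks),
                   length = blocks_length(unname(blocks)),
                   n_supporting = NA_integer_, stringsAsFactors = FALSE)
  for (key in c("location", "origin", "fl_subtype"))
    if (!is.null(g[[key]])) df[[key]] <- g[[key]]
  out$loci <- df
  out
}

#' Read an expression-style matrix TSV
#'
#' Header row = sample ids, first column = feature ids.
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write a matrix as TSV (features x samples)
#' @param m matrix with dimnames.
#' @param path file path.
#' @param id_col name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `individual_id`, `body_site`, `sex`,
#' `ethnicity`, `age`.
#' @param path file path.
#' @return `data.frame` of sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("sample_id", "individual_id", "body_site", "sex",
            "ethnicity", "age")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (any(df$age < 0)) stop("negative age in metadata")
  df
}

#' Read a peak file (BED3+ / narrowPeak)
#'
#' @param path file path.
#' @param mark histone mark label attached to every record.
#' @param body_site,individual optional labels attached to every record.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `mark`,
#'   `body_site`, `individual`.
#' @export
read_peaks <- function(path, mark, body_site = NA, individual = NA) {
  lines <- readLines(path)
  keep <- !grepl("^#|^track", lines) & nzchar(lines)
  p <- parse_bed_common(lines, keep, 3)
  data.frame(chrom = vapply(p$fields, `[`, "", 1),
             start = p$start, end = p$end,
             mark = mark, body_site = body_site, individual = individual,
             stringsAsFactors = FALSE)
}

#' Read a bedMethyl-style methylation table
#'
#' TSV with columns `chrom`, `pos` (0-based), `coverage`, `percent`
#' (0-100).
#' @param path file path.
#' @return `data.frame` with columns `chrom`, `pos`, `coverage`, `beta`.
#' @export
read_methylation <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("chrom", "pos", "coverage", "percent")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("methylation table missing columns: ",
                         paste(miss, collapse = ", "))
  df$beta <- df$percent / 100
  if (any(df$beta < 0 | df$beta > 1)) stop("percent outside [0, 100]")
  df[, c("chrom", "pos", "coverage", "beta")]
}
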