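#' Read intake: alignments in, locus read bins out
#'
#' Reads reach the profiler either pre-aligned (SAM/BAM) or as FASTQ routed
#' through an external genome aligner (see [align_fastq()]); only primary
#' alignments that fully span a target repeat (plus a small margin) are kept.
#'
#' @name read-intake
NULL

#' Load alignments from SAM or BAM
#'
#' BAM goes through Rsamtools; SAM text is parsed directly so plain-text
#' fixtures work. Alignment categories are decoded from the FLAG field
#' (0x4 unmapped, 0x100 secondary, 0x800 supplementary, otherwise primary);
#' reference spans come from POS and the CIGAR reference width.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return Data frame with one row per record: `qname`, `seq`, `qual`,
#'   `rname`, `start`, `end` (0-based half-open, `NA` if unmapped), `mapq`,
#'   `category`.
#' @export
load_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(load_alignments_bam(path))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) return(empty_alignments())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ", which(nf < 11L)[1], call. = FALSE)
  }
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  rname <- vapply(fields, `[[`, character(1), 3L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4L))
  cigar <- vapply(fields, `[[`, character(1), 6L)
  build_alignments(
    qname = vapply(fields, `[[`, character(1), 1L),
    flag = flag, rname = rname, pos = pos,
    mapq = as.integer(vapply(fields, `[[`, character(1), 5L)),
    cigar = cigar,
    seq = vapply(fields, `[[`, character(1), 10L),
    qual = vapply(fields, `[[`, character(1), 11L))
}

load_alignments_bam <- function(path) {
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  build_alignments(qname = b$qname, flag = b$flag,
                   rname = as.character(b$rname), pos = b$pos, mapq = b$mapq,
                   cigar = b$cigar, seq = as.character(b$seq),
                   qual = as.character(b$qual))
}

build_alignments <- function(qname, flag, rname, pos, mapq, cigar, seq, qual) {
  unmapped <- bitwAnd(flag, 4L) != 0L
  category <- ifelse(unmapped, "unmapped",
              ifelse(bitwAnd(flag, 256L) != 0L, "secondary",
              ifelse(bitwAnd(flag, 2048L) != 0L, "supplementary", "primary")))
  start <- ifelse(unmapped, NA_integer_, pos - 1L)
  width <- rep(NA_integer_, length(flag))
  ok <- !unmapped & !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    width[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  }
  data.frame(qname = qname, seq = seq, qual = qual,
             rname = ifelse(unmapped, NA_character_, rname),
             start = start, end = start + width,
             mapq = ifelse(unmapped, NA_integer_, mapq),  # MAPQ meaningless there

             category = category, stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  data.frame(qname = character(), seq = character(), qual = character(),
             rname = character(), start = integer(), end = integer(),
             mapq = integer(), category = character(), stringsAsFactors = FALSE)
}

#' Align a FASTQ to a reference with an external long-read aligner
#'
#' Shells out through a command template (default: minimap2 with
#' nanopore-friendly settings tuned for short amplicons). The template must
#' contain `{ref}`, `{fastq}`, `{out}` placeholders and write SAM to `{out}`.
#'
#' @param fastq,reference,out File paths.
#' @param command Command template.
#' @return `out`, invisibly.
#' @export
align_fastq <- function(fastq, reference, out,
                        command = paste("minimap2 -ax map-ont --secondary=no",
                                        "-k 10 -w 5 -m 20 {ref} {fastq} -o {out}")) {
  cmd <- gsub("{ref}", shQuote(reference),
         gsub("{fastq}", shQuote(fastq),
         gsub("{out}", shQuote(out), command, fixed = TRUE),
         fixed = TRUE), fixed = TRUE)
  status <- system(paste(cmd, "2>/dev/null"))
  if (status != 0L || !file.exists(out)) {
    stop("external aligner failed (exit ", status, "): ", cmd, call. = FALSE)
  }
  invisible(out)
}

#' Bin primary alignments by the STR locus they span
#'
#' A read is assigned to locus L iff it is a primary alignment on L's
#' chromosome whose interval contains
#' `[max(0, L$start - min_span_flank), L$end + min_span_flank)` — partial
#' overlap is not spanning. Loci must be non-overlapping, so a read lands in
#' at most one bin.
#'
#' @param alignments Data frame from [load_alignments()].
#' @param loci An `str_loci` table.
#' @param min_span_flank Required margin beyond the repeat, in bases.
#' @param min_mapq Optional minimum mapping quality (default 0 = no filter).
#' @return Named list (one element per locus) of `str_locus_reads`: list with
#'   `locus` (the definition row) and `reads` (alignment rows).
#' @export
extract_locus_reads <- function(alignments, loci, min_span_flank = 10L,
                                min_mapq = 0L) {
  check_loci_disjoint(loci)
  prim <- alignments[alignments$category == "primary" &
                     alignments$mapq >= min_mapq, , drop = FALSE]
  out <- vector("list", nrow(loci))
  names(out) <- loci$name
  for (i in seq_len(nrow(loci))) {
    lo <- max(0L, loci$start[i] - min_span_flank)
    hi <- loci$end[i] + min_span_flank
    hit <- prim$rname == loci$chrom[i] & prim$start <= lo & prim$end >= hi
    out[[i]] <- structure(
      list(locus = loci[i, , drop = FALSE],
           reads = prim[hit, , drop = FALSE]),
      class = "str_locus_reads")
  }
  out
}

check_loci_disjoint <- function(loci) {
  for (ch in unique(loci$chrom)) {
    sub <- loci[loci$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping locus definitions on ", ch, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' On-target / off-target / unmapped read accounting
#'
#' On-target = primary alignments spanning any target locus; off-target =
#' mapped but not on-target (secondary/supplementary placements count here);
#' unmapped = unmapped records.
#'
#' @param alignments Data frame from [load_alignments()].
#' @param loci An `str_loci` table.
#' @param min_span_flank Margin used for the spanning rule.
#' @return List with `counts` (named integer vector on_target/off_target/
#'   unmapped/total) and `proportions` (NA-filled and `empty = TRUE` when
#'   there are no reads).
#' @export
compute_mapping_stats <- function(alignments, loci, min_span_flank = 10L) {
  total <- nrow(alignments)
  unmapped <- sum(alignments$category == "unmapped")
  bins <- extract_locus_reads(alignments, loci, min_span_flank)
  on_target_ids <- unique(unlist(lapply(bins, function(b) rownames(b$reads))))
  on_target <- length(on_target_ids)
  off_target <- total - unmapped - on_target
  counts <- c(on_target = on_target, off_target = off_target,
              unmapped = unmapped, total = total)
  props <- if (total > 0L) counts[1:3] / total else
    c(on_target = NA_real_, off_target = NA_real_, unmapped = NA_real_)
  list(counts = counts, proportions = props, empty = total == 0L)
}
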