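#' GenBank-style STR allele records
#'
#' The catalog builder consumes STRSeq-style GenBank flat files. The dialect
#' it understands (and that [write_genbank_records()] emits) is:
#'
#' * `ACCESSION` — the allele identifier.
#' * a `source` feature carrying `/chromosome="chr5"` (or `"5"`).
#' * a `repeat_region` feature whose location `a..b` is the 1-based inclusive
#'   position of the *reference* repeat region on that chromosome, with
#'   qualifiers `/standard_name` (locus name), `/note="bracketed_motif=..."`
#'   (the bracketed repeat motif), and zero or more
#'   `/flank_variant="offset:REF>ALT"` entries (see below).
#' * `ORIGIN` — the allele's repeat-region sequence (which may differ in
#'   length from the reference location span).
#'
#' Flank-variant offsets: negative offsets count back from the repeat start
#' (`-1` is the base immediately upstream); non-negative offsets count
#' forward from the repeat end (`0` is the first downstream base). `REF`/`ALT`
#' of unequal length describe indels.
#'
#' Coordinates are converted at this boundary from GenBank's 1-based
#' inclusive convention to the package-internal 0-based half-open one.
#'
#' @name genbank-dialect
NULL

#' Parse GenBank flat-file allele records
#'
#' Records lacking a repeat_region feature or a locus name are skipped, not
#' fatal: they are collected and attached to the result as attribute
#' `"skipped"` (a character vector of messages), and a warning summarises
#' them.
#'
#' @param path Path to a GenBank flat file (possibly multi-record), or a
#'   character vector of its lines.
#' @param locus_qualifier Feature qualifier holding the locus name.
#' @param motif_note_key Key inside the `/note` qualifier holding the motif.
#' @return List of `str_allele_record` objects (see [allele_record()]).
#' @export
parse_genbank_records <- function(path, locus_qualifier = "standard_name",
                                  motif_note_key = "bracketed_motif") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  if (length(lines) == 0L) stop("empty GenBank input", call. = FALSE)
  # split on record terminator "//"
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- list()
  skipped <- character()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    if (!any(grepl("^LOCUS", chunk))) next
    rec <- tryCatch(parse_one_genbank(chunk, locus_qualifier, motif_note_key),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      skipped <- c(skipped, sprintf("record %d: %s", k, rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (length(skipped)) {
    warning(length(skipped), " record(s) skipped: ",
            paste(skipped, collapse = "; "), call. = FALSE)
  }
  attr(records, "skipped") <- skipped
  records
}

parse_one_genbank <- function(chunk, locus_qualifier, motif_note_key) {
  acc_line <- grep("^ACCESSION", chunk, value = TRUE)
  accession <- if (length(acc_line)) trimws(sub("^ACCESSION", "", acc_line[1])) else
    trimws(strsplit(sub("^LOCUS\\s+", "", grep("^LOCUS", chunk, value = TRUE)[1]),
                    "\\s+")[[1]][1])
  quals <- genbank_qualifiers(chunk)
  chrom <- quals$chromosome
  if (is.null(chrom)) stop("no /chromosome qualifier")
  loc <- genbank_feature_location(chunk, "repeat_region")
  if (is.null(loc)) stop("no repeat_region feature")
  locus <- quals[[locus_qualifier]]
  if (is.null(locus)) stop("no /", locus_qualifier, " (locus name) qualifier")
  note <- quals$note
  motif_txt <- NULL
  if (!is.null(note)) {
    hit <- grepl(paste0("^", motif_note_key, "="), note)
    if (any(hit)) motif_txt <- sub(paste0("^", motif_note_key, "="), "", note[hit][1])
  }
  if (is.null(motif_txt)) stop("no ", motif_note_key, " note qualifier")
  motif <- parse_bracketed_motif(motif_txt)
  seq <- genbank_origin(chunk)
  if (!nzchar(seq)) stop("no ORIGIN sequence")
  variants <- parse_flank_variants(quals$flank_variant)
  unit_length <- modal_unit_length(motif)
  allele_record(
    accession = accession, locus = locus, chromosome = chrom,
    repeat_start = loc[1] - 1L, repeat_end = loc[2],  # to 0-based half-open
    repeat_sequence = seq, flanking_variants = variants,
    motif = motif, designation = designation_from_motif(motif, unit_length)
  )
}

# all qualifiers in the FEATURES block, values possibly repeated;
# handles multi-line quoted values
genbank_qualifiers <- function(chunk) {
  fstart <- grep("^FEATURES", chunk)
  fend <- grep("^ORIGIN", chunk)
  if (!length(fstart)) return(list())
  block <- chunk[(fstart[1] + 1L):(if (length(fend)) fend[1] - 1L else length(chunk))]
  # join continuation lines: a qualifier starts with /; others continue previous
  joined <- character()
  for (ln in block) {
    t <- trimws(ln)
    if (grepl("^/", t) || grepl("^[a-zA-Z_']+\\s+[0-9<]", t)) {
      joined <- c(joined, t)
    } else if (length(joined)) {
      joined[length(joined)] <- paste(joined[length(joined)], t)
    }
  }
  qlines <- grep("^/", joined, value = TRUE)
  quals <- list()
  for (q in qlines) {
    key <- sub("^/([a-zA-Z_]+).*$", "\\1", q)
    val <- sub("^/[a-zA-Z_]+=?", "", q)
    val <- gsub('^"|"$', "", val)
    quals[[key]] <- c(quals[[key]], val)
  }
  quals
}

genbank_feature_location <- function(chunk, feature) {
  pat <- paste0("^\\s{2,}", feature, "\\s+([0-9]+)\\.\\.([0-9]+)")
  hit <- grep(pat, chunk, value = TRUE)
  if (!length(hit)) return(NULL)
  c(as.integer(sub(pat, "\\1", hit[1])), as.integer(sub(pat, "\\2", hit[1])))
}

genbank_origin <- function(chunk) {
  o <- grep("^ORIGIN", chunk)
  if (!length(o) || o[1] == length(chunk)) return("")
  seq_lines <- chunk[(o[1] + 1L):length(chunk)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
}

modal_unit_length <- function(motif) {
  lens <- rep(nchar(motif$unit[!motif$spacer]), motif$count[!motif$spacer])
  lens <- lens[lens >= 2L]
  if (!length(lens)) stop("cannot infer unit length from motif", call. = FALSE)
  as.integer(names(sort(table(lens), decreasing = TRUE))[1])
}

#' Construct an STR allele record
#'
#' @param accession Identifier string.
#' @param locus Locus name.
#' @param chromosome Reference sequence name (`"chr5"` and `"5"` styles both
#'   accepted downstream).
#' @param repeat_start,repeat_end 0-based half-open reference interval of the
#'   repeat region.
#' @param repeat_sequence Nucleotide string of this allele's repeat region.
#' @param flanking_variants Data frame with columns `offset`, `ref`, `alt`
#'   (see the package's flank-variant offset convention), or `NULL`.
#' @param motif An `str_motif`.
#' @param designation An `str_designation`.
#' @return An `str_allele_record`.
#' @export
allele_record <- function(accession, locus, chromosome, repeat_start,
                          repeat_end, repeat_sequence,
                          flanking_variants = NULL, motif, designation) {
  stopifnot(repeat_end > repeat_start, nzchar(repeat_sequence))
  if (is.null(flanking_variants)) {
    flanking_variants <- data.frame(offset = integer(), ref = character(),
                                    alt = character(), stringsAsFactors = FALSE)
  }
  structure(list(
    accession = accession, locus = locus, chromosome = chromosome,
    repeat_start = as.integer(repeat_start), repeat_end = as.integer(repeat_end),
    repeat_sequence = toupper(repeat_sequence),
    flanking_variants = flanking_variants,
    motif = motif, designation = designation
  ), class = "str_allele_record")
}

#' @export
print.str_allele_record <- function(x, ...) {
  cat(sprintf("<allele %s> %s %s:%d-%d allele %s motif %s (%d variant(s))\n",
              x$accession, x$locus, x$chromosome, x$repeat_start, x$repeat_end,
              format(x$designation), format(x$motif), nrow(x$flanking_variants)))
  invisible(x)
}

parse_flank_variants <- function(strings) {
  if (is.null(strings) || !length(strings)) {
    return(data.frame(offset = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  pat <- "^(-?[0-9]+):([ACGT]+)>([ACGT]*)$"
  bad <- !grepl(pat, strings)
  if (any(bad)) stop("malformed flank_variant '", strings[bad][1], "'", call. = FALSE)
  data.frame(offset = as.integer(sub(pat, "\\1", strings)),
             ref = sub(pat, "\\2", strings),
             alt = sub(pat, "\\3", strings), stringsAsFactors = FALSE)
}

format_flank_variants <- function(v) {
  if (!nrow(v)) return("")
  paste(sprintf("%d:%s>%s", v$offset, v$ref, v$alt), collapse = ",")
}
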