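#' STR allele catalog construction
#'
#' The catalog attaches reference-genome flanks (default 500 bp up- and
#' downstream) to each allele's repeat sequence so short nanopore amplicon
#' reads align well, applies any flanking variants the record carries, and
#' serializes everything to an allele-reference FASTA whose headers carry the
#' forensic nomenclature.
#'
#' @name catalog
NULL

#' Collapse redundant allele records
#'
#' Two records of the same locus are duplicates iff their repeat sequences
#' AND flanking variants are both identical; duplicates are reduced to one,
#' keeping the lexicographically smallest accession. Records differing only
#' in a flanking variant are both kept. Order-stable and idempotent.
#'
#' @param records List of `str_allele_record`.
#' @return Possibly shorter list of records.
#' @export
collapse_redundant <- function(records) {
  if (!length(records)) return(records)
  keys <- vapply(records, function(r) {
    paste(r$locus, r$repeat_sequence, format_flank_variants(r$flanking_variants),
          sep = "\r")
  }, character(1))
  keep <- list()
  pos <- integer()
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(records)) {
    k <- keys[i]
    if (is.null(seen[[k]])) {
      seen[[k]] <- length(keep) + 1L
      keep[[length(keep) + 1L]] <- records[[i]]
    } else {
      j <- seen[[k]]
      if (records[[i]]$accession < keep[[j]]$accession) keep[[j]] <- records[[i]]
    }
  }
  keep
}

#' Build the allele catalog from records and a reference genome
#'
#' For each record, the repeat sequence is framed by `flank_length` bases
#' taken verbatim from the reference genome at the record's repeat interval,
#' the record's flanking variants are applied (upstream variants
#' right-to-left, downstream left-to-right, so indel shifts never invalidate
#' remaining offsets), and the result becomes the entry's reference
#' sequence. Repeats closer than `flank_length` to a contig end get a
#' truncated flank and a `truncated` flag.
#'
#' @param records List of `str_allele_record` (typically after
#'   [collapse_redundant()]).
#' @param reference A `Biostrings::DNAStringSet` or path to a FASTA file.
#'   Both `"chr1"` and `"1"` naming styles are accepted.
#' @param flank_length Flank size in bases (default 500).
#' @return An `str_catalog`: list with `entries` (list of `str_catalog_entry`)
#'   and `flank_length`.
#' @export
build_catalog <- function(records, reference, flank_length = 500L) {
  stopifnot(flank_length > 0L)
  ref <- load_reference(reference)
  entries <- lapply(records, function(r) {
    chrom <- resolve_chrom(r$chromosome, names(ref))
    if (is.na(chrom)) {
      stop("chromosome '", r$chromosome, "' absent from reference", call. = FALSE)
    }
    chrom_seq <- ref[[chrom]]
    clen <- length(chrom_seq)
    up_start <- max(0L, r$repeat_start - flank_length)
    down_end <- min(clen, r$repeat_end + flank_length)
    up <- as.character(Biostrings::subseq(chrom_seq, up_start + 1L, r$repeat_start))
    down <- as.character(Biostrings::subseq(chrom_seq, r$repeat_end + 1L, down_end))
    truncated <- nchar(up) < flank_length || nchar(down) < flank_length
    fl <- apply_flank_variants(up, down, r$flanking_variants)
    structure(list(
      allele = r,
      reference_sequence = paste0(fl$up, r$repeat_sequence, fl$down),
      flank_length = as.integer(flank_length),
      upstream_used = nchar(fl$up), downstream_used = nchar(fl$down),
      repeat_offset = nchar(fl$up),  # 0-based start of repeat within entry
      truncated = truncated
    ), class = "str_catalog_entry")
  })
  structure(list(entries = entries, flank_length = as.integer(flank_length)),
            class = "str_catalog")
}

load_reference <- function(reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  stopifnot(methods::is(reference, "DNAStringSet"))
  names(reference) <- sub("\\s.*$", "", names(reference))
  reference
}

# accept "chr5" vs "5" interchangeably
resolve_chrom <- function(chrom, ref_names) {
  if (chrom %in% ref_names) return(chrom)
  alt <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom) else paste0("chr", chrom)
  if (alt %in% ref_names) return(alt)
  NA_character_
}

# offsets: negative = count back from repeat start (-1 = last upstream base);
# non-negative = count forward from repeat end (0 = first downstream base)
apply_flank_variants <- function(up, down, variants) {
  if (nrow(variants)) {
    upv <- variants[variants$offset < 0L, , drop = FALSE]
    upv <- upv[order(upv$offset, decreasing = TRUE), , drop = FALSE]  # right-to-left
    for (i in seq_len(nrow(upv))) {
      pos <- nchar(up) + upv$offset[i] + 1L  # 1-based within up
      up <- apply_one_variant(up, pos, upv$ref[i], upv$alt[i], "upstream")
    }
    dnv <- variants[variants$offset >= 0L, , drop = FALSE]
    dnv <- dnv[order(dnv$offset, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(dnv))) {
      pos <- dnv$offset[i] + 1L
      down <- apply_one_variant(down, pos, dnv$ref[i], dnv$alt[i], "downstream")
    }
  }
  list(up = up, down = down)
}

apply_one_variant <- function(seq, pos, ref, alt, side) {
  if (pos < 1L || pos + nchar(ref) - 1L > nchar(seq)) {
    stop("flank variant outside ", side, " flank", call. = FALSE)
  }
  have <- substr(seq, pos, pos + nchar(ref) - 1L)
  if (have != ref) {
    stop(side, " flank variant REF mismatch: expected ", ref, ", found ", have,
         call. = FALSE)
  }
  paste0(substr(seq, 1L, pos - 1L), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}

#' @export
print.str_catalog <- function(x, ...) {
  loci <- unique(vapply(x$entries, function(e) e$allele$locus, character(1)))
  cat(sprintf("<str_catalog> %d allele(s) across %d locus/loci, flank %d bp\n",
              length(x$entries), length(loci), x$flank_length))
  invisible(x)
}

#' Subset a catalog to one locus
#' @param catalog An `str_catalog`.
#' @param locus Locus name.
#' @return List of `str_catalog_entry` for that locus.
#' @export
catalog_locus_entries <- function(catalog, locus) {
  Filter(function(e) e$allele$locus %in% locus, catalog$entries)
}

# ---- FASTA header dialect ---------------------------------------------------
# ">{accession}|locus={locus}|motif={motif, ' '->'_'}|designation={des}"
# underscore substitutes the motif's spaces so headers stay single-token-safe.

catalog_header <- function(entry) {
  a <- entry$allele
  sprintf("%s|locus=%s|motif=%s|designation=%s",
          a$accession, a$locus, gsub(" ", "_", format(a$motif)),
          format(a$designation))
}

#' Parse an allele-reference FASTA header
#' @param header Header string (without the leading `>`).
#' @return List with `accession`, `locus`, `motif` (`str_motif`),
#'   `designation` (`str_designation`).
#' @export
parse_catalog_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  kv <- parts[-1]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]+=", "", kv)
  named <- stats::setNames(as.list(vals), keys)
  if (is.null(named$locus) || is.null(named$motif) || is.null(named$designation)) {
    stop("malformed catalog FASTA header: ", header, call. = FALSE)
  }
  list(accession = parts[1], locus = named$locus,
       motif = parse_bracketed_motif(gsub("_", " ", named$motif)),
       designation = parse_designation(named$designation))
}

#' Write the allele-reference FASTA
#'
#' Deterministic: same catalog gives byte-identical output.
#'
#' @param catalog An `str_catalog`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  seqs <- Biostrings::DNAStringSet(vapply(catalog$entries, function(e)
    e$reference_sequence, character(1)))
  names(seqs) <- vapply(catalog$entries, catalog_header, character(1))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Write the catalog table (TSV)
#' @param catalog An `str_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_catalog_table <- function(catalog, path) {
  rows <- lapply(catalog$entries, function(e) {
    a <- e$allele
    data.frame(accession = a$accession, locus = a$locus, chrom = a$chromosome,
               start = a$repeat_start, end = a$repeat_end,
               repeat_seq = a$repeat_sequence,
               variants = format_flank_variants(a$flanking_variants),
               motif = format(a$motif), designation = format(a$designation),
               truncated = e$truncated, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- locus definitions ------------------------------------------------------

#' Construct a table of target STR locus definitions
#'
#' @param name Locus names.
#' @param chrom Reference sequence names.
#' @param start,end 0-based half-open reference intervals.
#' @param locus_class `"autosomal"`, `"Y"`, or `"Y-merged"` (the DYS385ab
#'   duplication).
#' @param unit_length Repeat-unit lengths in bases (>= 2).
#' @param merge_group Optional group label: loci sharing a label are pooled
#'   into one merged locus of that name before counting (the DYS385a/b rule).
#' @return Data frame of class `str_loci`.
#' @export
locus_definitions <- function(name, chrom, start, end, locus_class,
                              unit_length, merge_group = NA_character_) {
  stopifnot(all(unit_length >= 2L), all(end > start),
            all(locus_class %in% c("autosomal", "Y", "Y-merged")))
  df <- data.frame(name = name, chrom = chrom, start = as.integer(start),
                   end = as.integer(end), locus_class = locus_class,
                   unit_length = as.integer(unit_length),
                   merge_group = merge_group, stringsAsFactors = FALSE)
  class(df) <- c("str_loci", "data.frame")
  df
}

#' Write locus definitions as BED (0-based half-open)
#'
#' Columns: chrom, start, end, name, unit_length, locus_class, merge_group.
#' Columns 5-7 are non-standard BED extensions.
#'
#' @param loci An `str_loci` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  utils::write.table(
    loci[, c("chrom", "start", "end", "name", "unit_length", "locus_class",
             "merge_group")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read locus definitions from BED
#' @param path BED path as written by [write_loci_bed()] (plain BED4 also
#'   accepted; missing class defaults to autosomal, unit length to 4).
#' @return An `str_loci` table.
#' @export
read_loci_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (ncol(df) < 4L) stop("BED needs at least 4 columns", call. = FALSE)
  locus_definitions(
    name = df[[4]], chrom = df[[1]], start = df[[2]], end = df[[3]],
    locus_class = if (ncol(df) >= 6L) df[[6]] else "autosomal",
    unit_length = if (ncol(df) >= 5L) df[[5]] else 4L,
    merge_group = if (ncol(df) >= 7L) as.character(df[[7]]) else NA_character_)
}
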