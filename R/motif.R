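#' Bracketed repeat motifs and length-based allele designations
#'
#' Forensic sequence-based STR nomenclature writes an allele as an ordered
#' series of repeat blocks, e.g. `"[TAGA]9 [CAGA]3 N48 [TAGA]13 [CAGA]6"`:
#' `[UNIT]count` is a run of `count` copies of `UNIT`, a bare `UNIT` token is a
#' singleton (count 1, printed without brackets), and `Nk` is a k-base
#' non-repeat spacer that contributes sequence length but no repeat units.
#' The CE-compatible length-based designation is the total whole repeat-unit
#' count, with microvariants written `N.b` where `b` is the leftover base
#' count (e.g. `15.1`, `2.2`).
#'
#' @name motif-nomenclature
NULL

#' Parse a bracketed repeat motif string
#'
#' @param text Motif string: whitespace-separated tokens of the form
#'   `[UNIT]count`, bare `UNIT` (a singleton), or `Nk` (a k-base spacer).
#' @return An object of class `str_motif`: a data frame of blocks with
#'   columns `unit`, `count`, `bracketed`, `spacer`, `spacer_length`,
#'   preserving input order.
#' @examples
#' m <- parse_bracketed_motif("[TAGA]9 [CAGA]3 N48 [TAGA]13 [CAGA]6")
#' format(m)
#' @export
parse_bracketed_motif <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("empty or invalid motif string", call. = FALSE)
  }
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  blocks <- lapply(tokens, parse_motif_token)
  motif <- do.call(rbind, blocks)
  if (!any(!motif$spacer)) {
    stop("motif must contain at least one non-spacer block", call. = FALSE)
  }
  class(motif) <- c("str_motif", "data.frame")
  motif
}

parse_motif_token <- function(token) {
  if (grepl("^\\[[ACGT]+\\][0-9]+$", token)) {
    unit <- sub("^\\[([ACGT]+)\\].*$", "\\1", token)
    count <- as.integer(sub("^\\[[ACGT]+\\]([0-9]+)$", "\\1", token))
    if (count < 1L) stop("zero repeat count in token '", token, "'", call. = FALSE)
    return(motif_block(unit, count, bracketed = TRUE))
  }
  if (grepl("^N[0-9]+$", token)) {
    len <- as.integer(sub("^N", "", token))
    if (len < 1L) stop("zero-length spacer token '", token, "'", call. = FALSE)
    return(motif_block("", 1L, spacer = TRUE, spacer_length = len))
  }
  if (grepl("^[ACGT]+$", token)) {
    return(motif_block(token, 1L, bracketed = FALSE))
  }
  stop("malformed motif token '", token, "'", call. = FALSE)
}

motif_block <- function(unit, count, bracketed = FALSE, spacer = FALSE,
                        spacer_length = 0L) {
  data.frame(unit = unit, count = as.integer(count), bracketed = bracketed,
             spacer = spacer, spacer_length = as.integer(spacer_length),
             stringsAsFactors = FALSE)
}

#' @export
format.str_motif <- function(x, ...) {
  tok <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    tok[i] <- if (x$spacer[i]) {
      paste0("N", x$spacer_length[i])
    } else if (x$bracketed[i]) {
      paste0("[", x$unit[i], "]", x$count[i])
    } else {
      x$unit[i]
    }
  }
  paste(tok, collapse = " ")
}

#' @export
print.str_motif <- function(x, ...) {
  cat("<str_motif> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Expand a motif to its nucleotide sequence
#'
#' Spacers carry no explicit sequence, so any motif containing one cannot be
#' expanded and raises an error.
#'
#' @param motif An `str_motif`.
#' @return Nucleotide string: each unit repeated `count` times, concatenated.
#' @export
expand_motif <- function(motif) {
  stopifnot(inherits(motif, "str_motif"))
  if (any(motif$spacer)) {
    stop("motif contains a spacer without explicit sequence; cannot expand",
         call. = FALSE)
  }
  paste(vapply(seq_len(nrow(motif)), function(i) {
    strrep(motif$unit[i], motif$count[i])
  }, character(1)), collapse = "")
}

#' Length-based allele designation from a motif
#'
#' Sums whole repeat-unit counts over non-spacer blocks whose unit length
#' equals the locus repeat-unit length; bases from off-length blocks are
#' pooled, contributing `floor(b / unit_length)` further whole units and
#' `b %% unit_length` leftover (microvariant) bases. Spacers contribute
#' nothing. For the DYS389II motif `[TAGA]9 [CAGA]3 N48 [TAGA]13 [CAGA]6`
#' this gives 9 + 3 + 13 + 6 = 31.
#'
#' @param motif An `str_motif`.
#' @param unit_length Repeat-unit length of the locus, in bases (>= 2).
#' @return An `str_designation` with fields `whole` and `partial`; formats as
#'   `"31"` or `"2.2"` (microvariant).
#' @export
designation_from_motif <- function(motif, unit_length) {
  stopifnot(inherits(motif, "str_motif"))
  unit_length <- as.integer(unit_length)
  if (is.na(unit_length) || unit_length < 2L) {
    stop("unit_length must be an integer >= 2", call. = FALSE)
  }
  on_length <- !motif$spacer & nchar(motif$unit) == unit_length
  off_length <- !motif$spacer & !on_length
  whole <- sum(motif$count[on_length])
  off_bases <- sum(nchar(motif$unit[off_length]) * motif$count[off_length])
  whole <- whole + off_bases %/% unit_length
  partial <- off_bases %% unit_length
  allele_designation(whole, partial)
}

#' Construct a length-based allele designation
#'
#' @param whole Non-negative whole repeat-unit count.
#' @param partial Leftover bases (0 for whole-repeat alleles); must be less
#'   than the locus unit length, which this constructor cannot check.
#' @return An `str_designation`.
#' @export
allele_designation <- function(whole, partial = 0L) {
  whole <- as.integer(whole); partial <- as.integer(partial)
  stopifnot(whole >= 0L, partial >= 0L)
  structure(list(whole = whole, partial = partial),
            class = "str_designation")
}

#' @export
format.str_designation <- function(x, ...) {
  if (x$partial == 0L) as.character(x$whole) else
    paste0(x$whole, ".", x$partial)
}

#' @export
print.str_designation <- function(x, ...) {
  cat("<allele designation> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a designation string such as "13" or "15.1"
#' @param text Designation string.
#' @return An `str_designation`.
#' @export
parse_designation <- function(text) {
  if (!grepl("^[0-9]+(\\.[0-9]+)?$", text)) {
    stop("malformed allele designation '", text, "'", call. = FALSE)
  }
  parts <- strsplit(text, ".", fixed = TRUE)[[1]]
  allele_designation(as.integer(parts[1]),
                     if (length(parts) > 1L) as.integer(parts[2]) else 0L)
}
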