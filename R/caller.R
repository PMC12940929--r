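#' Genotype and haplotype calling from normalized read counts
#'
#' Per-locus raw allele counts are normalized to the best-covered allele
#' (top allele = 1.0 by construction). Autosomal loci report the top allele
#' always and the second-ranked allele iff its normalized value exceeds the
#' heterozygote threshold (default 0.4, strict inequality on full precision);
#' Y loci report only the top allele, except the DYS385a/b duplication whose
#' pooled reads yield the top two alleles exceeding the threshold.
#'
#' @name genotype-calling
NULL

#' Caller configuration
#'
#' @param threshold Heterozygote normalization threshold in (0,1);
#'   default 0.4. Laboratories should tune this against internal validation
#'   data.
#' @param min_coverage Minimum reads at a locus to attempt a call
#'   (default 10); below it the locus is flagged as low-coverage dropout,
#'   which keeps dropout distinguishable from homozygosity.
#' @param inclusive Use `>=` instead of strict `>` at the threshold.
#' @param display_digits Significant figures for normalized values in
#'   human-readable reports (machine output keeps full precision).
#' @return List of class `str_caller_config`.
#' @export
caller_config <- function(threshold = 0.4, min_coverage = 10L,
                          inclusive = FALSE, display_digits = 2L) {
  stopifnot(threshold > 0, threshold < 1, min_coverage >= 0L)
  structure(list(threshold = threshold, min_coverage = as.integer(min_coverage),
                 inclusive = inclusive, display_digits = as.integer(display_digits)),
            class = "str_caller_config")
}

#' Normalize raw allele counts to the top allele
#'
#' @param counts Named numeric vector of raw per-allele read counts.
#' @return Data frame (class `str_norm_counts`) with columns `accession`,
#'   `raw`, `norm` (= raw / max raw, full precision), sorted by descending
#'   raw count (ties by accession); or `NULL` with attribute
#'   `"dropout" = TRUE` when all counts are zero.
#' @export
normalize_counts <- function(counts) {
  stopifnot(length(counts) >= 1L, !is.null(names(counts)), all(counts >= 0))
  if (max(counts) == 0) {
    return(structure(list(), dropout = TRUE, class = "str_norm_counts_dropout"))
  }
  o <- order(-counts, names(counts))
  df <- data.frame(accession = names(counts)[o], raw = as.numeric(counts[o]),
                   norm = as.numeric(counts[o]) / max(counts),
                   stringsAsFactors = FALSE)
  class(df) <- c("str_norm_counts", "data.frame")
  df
}

is_dropout <- function(norm) inherits(norm, "str_norm_counts_dropout")

exceeds <- function(x, config) {
  if (config$inclusive) x >= config$threshold else x > config$threshold
}

#' Call an autosomal genotype from normalized counts
#'
#' @param norm An `str_norm_counts` (see [normalize_counts()]).
#' @param config An `str_caller_config`.
#' @param locus Locus name (carried into the call).
#' @return An `str_locus_call`: top allele always; second allele iff its
#'   normalized value exceeds the threshold; rank-1 ties report both with a
#'   `tie` flag. Homozygotes carry one allele row but `zygosity =
#'   "homozygous"` (expanded to two allele calls by the concordance scorer).
#' @export
call_autosomal <- function(norm, config = caller_config(), locus = NA_character_) {
  if (is_dropout(norm)) return(dropout_call(locus, "autosomal"))
  top <- norm[norm$norm == 1.0, , drop = FALSE]
  flags <- character()
  if (nrow(top) > 1L) {
    picked <- top[1:2, , drop = FALSE]
    flags <- "tie"
    zyg <- "heterozygous"
  } else if (nrow(norm) >= 2L && exceeds(norm$norm[2L], config)) {
    picked <- norm[1:2, , drop = FALSE]
    zyg <- "heterozygous"
  } else {
    picked <- norm[1L, , drop = FALSE]
    zyg <- "homozygous"
  }
  locus_call(locus, "autosomal", picked, zyg, flags)
}

#' Call a Y haplotype from normalized counts
#'
#' @param norm An `str_norm_counts`.
#' @param config An `str_caller_config`.
#' @param locus Locus name.
#' @param merged Is this the pooled DYS385ab-style locus? If so the top two
#'   alleles exceeding the threshold are reported (possibly just one);
#'   otherwise exactly the top allele. A rank-1 tie at a non-merged Y locus
#'   yields no call plus a `tie` flag.
#' @return An `str_locus_call`.
#' @export
call_y <- function(norm, config = caller_config(), locus = NA_character_,
                   merged = FALSE) {
  cls <- if (merged) "Y-merged" else "Y"
  if (is_dropout(norm)) return(dropout_call(locus, cls))
  top <- norm[norm$norm == 1.0, , drop = FALSE]
  if (merged) {
    keep <- norm[seq_len(min(2L, nrow(norm))), , drop = FALSE]
    keep <- keep[keep$norm == 1.0 | exceeds(keep$norm, config), , drop = FALSE]
    return(locus_call(locus, cls, keep, "haplotype",
                      if (nrow(top) > 2L) "tie" else character()))
  }
  if (nrow(top) > 1L) {
    return(locus_call(locus, cls, norm[0L, , drop = FALSE], "haplotype", "tie"))
  }
  locus_call(locus, cls, norm[1L, , drop = FALSE], "haplotype", character())
}

dropout_call <- function(locus, locus_class) {
  empty <- data.frame(accession = character(), raw = numeric(),
                      norm = numeric(), stringsAsFactors = FALSE)
  locus_call(locus, locus_class, empty, "dropout", "dropout")
}

locus_call <- function(locus, locus_class, alleles, zygosity, flags) {
  structure(list(locus = locus, locus_class = locus_class,
                 alleles = as.data.frame(alleles), zygosity = zygosity,
                 flags = flags),
            class = "str_locus_call")
}

#' @export
print.str_locus_call <- function(x, ...) {
  al <- if (nrow(x$alleles)) {
    paste(sprintf("%s (%g/%s)", x$alleles$accession, x$alleles$raw,
                  signif(x$alleles$norm, 2)), collapse = " ")
  } else "-"
  fl <- if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""
  cat(sprintf("%s\t%s\t%s%s\n", x$locus, x$zygosity, al, fl))
  invisible(x)
}

#' Pool the two read sets of a duplicated locus (DYS385a/b rule)
#'
#' @param a,b `str_locus_reads` for the two copies.
#' @param name Name of the merged locus (e.g. `"DYS385ab"`).
#' @return One `str_locus_reads` whose reads are the multiset union and
#'   whose locus definition takes class `"Y-merged"`.
#' @export
merge_dys385 <- function(a, b, name = "DYS385ab") {
  locus <- a$locus
  locus$name <- name
  locus$locus_class <- "Y-merged"
  structure(list(locus = locus, reads = rbind(a$reads, b$reads)),
            class = "str_locus_reads")
}

#' Call one locus from a raw count row
#'
#' Dispatches on locus class; applies the minimum-coverage rule first
#' (total assigned + unassigned reads below `min_coverage` -> low-coverage
#' dropout).
#'
#' @param count_row An `str_count_row` from [count_alleles()].
#' @param locus_def One-row `str_loci` slice.
#' @param config An `str_caller_config`.
#' @param designations Optional named character vector accession ->
#'   designation string, attached to the call's allele table.
#' @param motifs Optional named character vector accession -> motif string.
#' @return An `str_locus_call` with a `counts` attribute carrying the raw row.
#' @export
call_locus <- function(count_row, locus_def, config = caller_config(),
                       designations = NULL, motifs = NULL) {
  total <- sum(count_row$counts) + count_row$unassigned
  cls <- locus_def$locus_class
  if (total < config$min_coverage) {
    call <- dropout_call(locus_def$name, cls)
    call$flags <- unique(c(call$flags, "low_coverage"))
  } else {
    norm <- normalize_counts(count_row$counts)
    call <- if (cls == "autosomal") {
      call_autosomal(norm, config, locus_def$name)
    } else {
      call_y(norm, config, locus_def$name, merged = cls == "Y-merged")
    }
  }
  call$alleles$designation <- if (is.null(designations)) {
    rep(NA_character_, nrow(call$alleles))
  } else unname(designations[call$alleles$accession])
  call$alleles$motif <- if (is.null(motifs)) {
    rep(NA_character_, nrow(call$alleles))
  } else unname(motifs[call$alleles$accession])
  attr(call, "counts") <- count_row
  call
}

#' A sample's full STR profile
#'
#' @param sample_id Sample identifier.
#' @param calls Named list of `str_locus_call` (at most one per locus).
#' @return An `str_profile`.
#' @export
str_profile <- function(sample_id, calls) {
  stopifnot(!anyDuplicated(names(calls)))
  structure(list(sample_id = sample_id, calls = calls), class = "str_profile")
}

#' @export
print.str_profile <- function(x, ...) {
  cat(sprintf("<str_profile> sample %s, %d locus call(s)\n",
              x$sample_id, length(x$calls)))
  for (cl in x$calls) print(cl)
  invisible(x)
}
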