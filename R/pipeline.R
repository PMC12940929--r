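#' End-to-end profiling pipeline
#'
#' Ties the modules together: load alignments (or align a FASTQ through the
#' external-aligner contract), bin primary spanning reads per target locus,
#' pool duplicated-locus groups (DYS385a/b), score reads against the locus's
#' catalog alleles, and call the profile.
#'
#' @name pipeline
NULL

#' Profile one sample
#'
#' @param input Path to SAM/BAM, or an alignment data frame from
#'   [load_alignments()].
#' @param catalog An `str_catalog`.
#' @param loci An `str_loci` table (the panel).
#' @param config An `str_caller_config`.
#' @param sample_id Sample identifier for the report.
#' @param min_span_flank Spanning margin in bases (see
#'   [extract_locus_reads()]).
#' @param max_divergence Identity floor for read assignment.
#' @param window Scoring window around the repeat (see [count_alleles()]).
#' @return List of class `str_profile_result`: `profile` (`str_profile`),
#'   `table` (report rows, see [profile_table()]), `count_rows`,
#'   `stats` (mapping statistics).
#' @export
profile_sample <- function(input, catalog, loci, config = caller_config(),
                           sample_id = "sample", min_span_flank = 10L,
                           max_divergence = 0.30, window = 200L) {
  alignments <- if (is.character(input)) load_alignments(input) else input
  bins <- extract_locus_reads(alignments, loci, min_span_flank)
  stats <- compute_mapping_stats(alignments, loci, min_span_flank)

  merged <- merge_locus_groups(bins, loci)
  designations <- catalog_designation_map(catalog)
  motifs <- catalog_motif_map(catalog)

  calls <- list()
  for (nm in names(merged$bins)) {
    entries <- catalog_locus_entries(catalog, merged$members[[nm]])
    cr <- count_alleles(merged$bins[[nm]], entries,
                        max_divergence = max_divergence, window = window)
    calls[[nm]] <- call_locus(cr, merged$bins[[nm]]$locus, config,
                              designations = designations, motifs = motifs)
  }
  profile <- str_profile(sample_id, calls)
  structure(list(profile = profile,
                 table = profile_table(profile, designations, motifs),
                 count_rows = lapply(calls, attr, "counts"),
                 stats = stats),
            class = "str_profile_result")
}

# pool bins of loci sharing a merge_group into one merged locus; returns
# bins plus, per output locus, the member locus names (for catalog lookup)
merge_locus_groups <- function(bins, loci) {
  groups <- unique(stats::na.omit(loci$merge_group))
  members <- as.list(stats::setNames(names(bins), names(bins)))
  for (g in groups) {
    nms <- loci$name[!is.na(loci$merge_group) & loci$merge_group == g]
    if (length(nms) < 2L) next
    pooled <- Reduce(function(a, b) merge_dys385(a, b, name = g),
                     bins[nms])
    bins[nms] <- NULL
    members[nms] <- NULL
    bins[[g]] <- pooled
    members[[g]] <- nms
  }
  list(bins = bins, members = members)
}

catalog_designation_map <- function(catalog) {
  stats::setNames(
    vapply(catalog$entries, function(e) format(e$allele$designation),
           character(1)),
    vapply(catalog$entries, function(e) e$allele$accession, character(1)))
}

catalog_motif_map <- function(catalog) {
  stats::setNames(
    vapply(catalog$entries, function(e) format(e$allele$motif), character(1)),
    vapply(catalog$entries, function(e) e$allele$accession, character(1)))
}

#' @export
print.str_profile_result <- function(x, ...) {
  print(x$profile)
  if (!x$stats$empty) {
    p <- x$stats$proportions
    cat(sprintf("reads: %d total; %.1f%% on-target, %.1f%% off-target, %.1f%% unmapped\n",
                x$stats$counts[["total"]], 100 * p[["on_target"]],
                100 * p[["off_target"]], 100 * p[["unmapped"]]))
  }
  invisible(x)
}

#' Finalize a simulated ground-truth table against a locus panel
#'
#' Fills `locus_class` from the panel and collapses rows of loci sharing a
#' merge group (DYS385a/b) into a single merged-locus row carrying both
#' alleles.
#'
#' @param truth Truth rows from [simulate_reads()].
#' @param loci An `str_loci` table.
#' @return Truth data frame in the [read_truth_profiles()] dialect.
#' @export
finalize_truth <- function(truth, loci) {
  cls <- stats::setNames(loci$locus_class, loci$name)
  grp <- stats::setNames(loci$merge_group, loci$name)
  truth$locus_class <- unname(cls[truth$locus])
  out <- truth[is.na(grp[truth$locus]), , drop = FALSE]
  groups <- unique(stats::na.omit(grp[truth$locus]))
  for (g in groups) {
    sub <- truth[!is.na(grp[truth$locus]) & grp[truth$locus] == g, , drop = FALSE]
    for (s in unique(sub$sample)) {
      ss <- sub[sub$sample == s, , drop = FALSE]
      alleles <- unique(stats::na.omit(c(rbind(ss$allele1, ss$allele2))))
      mots <- unique(stats::na.omit(c(rbind(ss$motif1, ss$motif2))))
      out <- rbind(out, data.frame(
        sample = s, locus = g, locus_class = "Y-merged",
        allele1 = alleles[1],
        allele2 = if (length(alleles) > 1L) alleles[2] else NA_character_,
        motif1 = mots[1],
        motif2 = if (length(mots) > 1L) mots[2] else NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
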