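#' Read-to-allele assignment
#'
#' Each binned read is scored against every catalog allele of its locus by
#' unit-cost semi-global edit distance (free end gaps for the longer
#' sequence), in both orientations; the unique lowest-cost allele wins
#' provided its identity clears `1 - max_divergence`. Ties and
#' below-floor reads are left unassigned — inflating either allele of a tie
#' would bias the downstream count normalization.
#'
#' @name allele-matching
NULL

#' Score one read against one allele reference sequence
#'
#' @param read,reference Non-empty ACGTN nucleotide strings (`N` matches
#'   nothing).
#' @return List with `cost` (edit operations of the best semi-global
#'   placement, minimum over the read's two orientations) and `identity`
#'   (`1 - cost / alignment length`, the alignment length being the
#'   contained, i.e. shorter, sequence's length).
#' @export
score_read <- function(read, reference) {
  if (!nzchar(read) || !nzchar(reference)) {
    stop("empty sequence", call. = FALSE)
  }
  cost <- min(.sg_cost(toupper(read), toupper(reference)),
              .sg_cost(revcomp(toupper(read)), toupper(reference)))
  alen <- min(nchar(read), nchar(reference))
  list(cost = cost, identity = 1 - cost / alen)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# orientation-aware cost matrix reads x refs
sg_cost_both <- function(reads, refs) {
  reads <- toupper(reads); refs <- toupper(refs)
  pmin(.sg_cost_matrix(reads, refs), .sg_cost_matrix(revcomp(reads), refs))
}

#' Assign a read to one of its locus's candidate alleles
#'
#' @param read Read sequence.
#' @param candidates Named character vector of allele reference sequences
#'   (names = accessions).
#' @param max_divergence Maximum tolerated divergence; reads whose best
#'   identity falls below `1 - max_divergence` stay unassigned (default 0.30,
#'   tolerant of nanopore error while rejecting wrong-locus reads).
#' @return Accession of the unique lowest-cost allele, or `NA_character_`
#'   (tie for lowest cost, or identity below the floor).
#' @export
assign_read <- function(read, candidates, max_divergence = 0.30) {
  stopifnot(length(candidates) >= 1L)
  costs <- sg_cost_both(read, unname(candidates))[1L, ]
  pick_assignment(costs, names(candidates), nchar(read), nchar(candidates),
                  max_divergence)
}

pick_assignment <- function(costs, accessions, read_len, ref_lens,
                            max_divergence) {
  best <- min(costs)
  hits <- which(costs == best)
  if (length(hits) != 1L) return(NA_character_)
  identity <- 1 - best / min(read_len, ref_lens[hits])
  if (identity < 1 - max_divergence) return(NA_character_)
  accessions[hits]
}

#' Count assigned reads per allele at one locus
#'
#' Alleles can optionally be trimmed to a window around the repeat before
#' scoring (`window` bases of flank on each side): the catalog's long flanks
#' exist for genome-stage mapping, and amplicon reads only ever overlap the
#' repeat-proximal flank, so the trimmed alignment assigns identically at a
#' fraction of the cost. `window = NULL` scores full entries.
#'
#' @param locus_reads An `str_locus_reads` (from [extract_locus_reads()]),
#'   or any list with a `reads` data frame carrying a `seq` column.
#' @param entries Catalog entries for this locus
#'   (see [catalog_locus_entries()]); must be non-empty.
#' @param max_divergence Identity floor, as in [assign_read()].
#' @param window Flank bases retained around the repeat when scoring
#'   (default 200), or `NULL` for no trimming.
#' @return List of class `str_count_row`: `counts` (named integer vector,
#'   accession -> raw read count, every candidate present), `unassigned`,
#'   `assignments` (per-read accession or NA).
#' @export
count_alleles <- function(locus_reads, entries, max_divergence = 0.30,
                          window = 200L) {
  if (!length(entries)) {
    stop("locus has no catalog entries; configuration error", call. = FALSE)
  }
  accs <- vapply(entries, function(e) e$allele$accession, character(1))
  refs <- vapply(entries, trim_entry_sequence, character(1), window = window)
  reads <- locus_reads$reads$seq
  counts <- stats::setNames(integer(length(accs)), accs)
  if (!length(reads)) {
    return(structure(list(counts = counts, unassigned = 0L,
                          assignments = character(0)), class = "str_count_row"))
  }
  costs <- sg_cost_both(reads, unname(refs))
  assignments <- vapply(seq_along(reads), function(i) {
    pick_assignment(costs[i, ], accs, nchar(reads[i]), nchar(refs),
                    max_divergence)
  }, character(1))
  tab <- table(factor(assignments, levels = accs))
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, unassigned = sum(is.na(assignments)),
                 assignments = assignments), class = "str_count_row")
}

trim_entry_sequence <- function(entry, window) {
  s <- entry$reference_sequence
  if (is.null(window)) return(s)
  rep_len <- nchar(entry$allele$repeat_sequence)
  from <- max(1L, entry$repeat_offset - window + 1L)
  to <- min(nchar(s), entry$repeat_offset + rep_len + window)
  substr(s, from, to)
}
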