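#' Seeded fixtures and nanopore-like amplicon read simulation
#'
#' The generator fabricates a toy world — GenBank-style allele records, a
#' mini reference genome embedding each locus's reference allele, locus
#' definitions, and a truth table — then simulates full-length amplicon reads
#' (repeat plus a primer-flank on each side) from a stated diploid/haploid
#' truth profile, with configurable substitution/insertion/deletion error
#' rates, a homopolymer deletion multiplier, and optional minus-one-repeat
#' PCR stutter. Everything is deterministic under a fixed seed.
#'
#' @name read-simulator
NULL

BASES <- c("A", "C", "G", "T")

#' Per-base sequencing error model
#'
#' @param sub,ins,del Substitution / insertion / deletion rates per base,
#'   each in `[0, 0.2]`.
#' @param homopolymer_mult Multiplier (>= 1) applied to the deletion rate
#'   inside homopolymer runs of length >= 4, where nanopore deletions
#'   concentrate.
#' @return List of class `str_error_model`.
#' @export
error_model <- function(sub = 0.05, ins = 0.02, del = 0.03,
                        homopolymer_mult = 2) {
  stopifnot(all(c(sub, ins, del) >= 0), all(c(sub, ins, del) <= 0.2),
            homopolymer_mult >= 1)
  structure(list(sub = sub, ins = ins, del = del,
                 homopolymer_mult = homopolymer_mult),
            class = "str_error_model")
}

#' Minus-one-repeat PCR stutter model
#'
#' @param minus_one Proportion of reads drawn from the minus-one-repeat
#'   artifact template, in `[0, 0.5)`. Stutter reads carry exactly one fewer
#'   whole repeat unit than the template allele.
#' @return List of class `str_stutter_model`.
#' @export
stutter_model <- function(minus_one = 0) {
  stopifnot(minus_one >= 0, minus_one < 0.5)
  structure(list(minus_one = minus_one), class = "str_stutter_model")
}

#' Truth specification for one simulated sample
#'
#' @param sample_id Sample identifier.
#' @param sex `"male"` or `"female"`; female specs must list no Y alleles.
#' @param truth Named list locus -> character vector of allele accessions
#'   (1-2 autosomal, 1 per Y locus, 1-2 across a DYS385ab-style pair).
#' @param depth Reads per locus.
#' @return List of class `str_sim_spec`.
#' @export
sim_sample_spec <- function(sample_id, sex = c("male", "female"), truth,
                            depth = 200L) {
  sex <- match.arg(sex)
  stopifnot(length(truth) >= 1L, !is.null(names(truth)), depth >= 1L)
  structure(list(sample_id = sample_id, sex = sex, truth = truth,
                 depth = as.integer(depth)), class = "str_sim_spec")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# real STR units are primitive: not a power of a shorter word (else the
# locus has a shorter true period and mapping/designation both degrade)
is_primitive_unit <- function(unit) {
  n <- nchar(unit)
  if (length(unique(strsplit(unit, "")[[1]])) < 2L) return(FALSE)
  for (d in seq_len(n %/% 2)) {
    if (n %% d == 0L && strrep(substr(unit, 1L, d), n %/% d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

random_repeat_unit <- function(ulen) {
  repeat {
    unit <- random_dna(ulen)
    if (is_primitive_unit(unit)) return(unit)
  }
}

# a unit one substitution away from `unit`
mutate_unit <- function(unit) {
  pos <- sample(nchar(unit), 1L)
  old <- substr(unit, pos, pos)
  substr(unit, pos, pos) <- sample(setdiff(BASES, old), 1L)
  unit
}

#' Generate a toy allele catalog world
#'
#' Produces parseable GenBank-style records, a mini reference genome with
#' each locus's reference allele embedded at recorded coordinates, locus
#' definitions, and a truth table. The world always contains at least one
#' isoallele pair (equal length, unequal sequence), one microvariant allele,
#' one allele with a flanking SNP, and — when `n_loci >= 4` — a DYS385-like
#' duplicated Y locus pair sharing a merge group. Deterministic under
#' `seed`.
#'
#' Unit lengths mirror the commercial forensic multiplex the pipeline
#' emulates: autosomal STR panels there are exclusively tetra- and
#' pentanucleotide (e.g. Penta D/E), while the Y side adds a trinucleotide
#' locus (DYS392-like) and a pentanucleotide one (DYS438-like); the
#' duplicated DYS385-like pair is tetranucleotide.
#'
#' @param n_loci Number of locus definitions (>= 1).
#' @param alleles_per_locus Alleles per locus (>= 2 for the special cases).
#' @param autosomal_units Repeat-unit lengths cycled across autosomal loci.
#' @param y_units Repeat-unit lengths cycled across non-duplicated Y loci.
#' @param seed Integer seed.
#' @param contig_pad Reference bases flanking each embedded repeat
#'   (default 700, comfortably above the catalog's 500 bp flank).
#' @return List with `records`, `reference` (`DNAStringSet`), `loci`
#'   (`str_loci`), `truth` (data frame: accession, locus, designation,
#'   motif, repeat length).
#' @export
make_fixture_catalog <- function(n_loci = 10L, alleles_per_locus = 4L,
                                 autosomal_units = c(4L, 4L, 4L, 5L),
                                 y_units = c(3L, 4L, 5L), seed = 1L,
                                 contig_pad = 700L) {
  stopifnot(n_loci >= 1L, alleles_per_locus >= 1L)
  set.seed(seed)
  n_y <- if (n_loci >= 4L) 3L else 0L   # one plain Y + the duplicated pair
  n_auto <- n_loci - n_y
  records <- list()
  truth <- list()
  ref_seqs <- character()
  loci_rows <- list()
  for (i in seq_len(n_loci)) {
    is_pair <- n_y > 0L && i > n_loci - 2L        # last two = duplicated pair
    is_y <- n_y > 0L && i > n_auto
    name <- if (is_pair) paste0("DYS385", c("a", "b")[i - (n_loci - 2L)]) else
      if (is_y) sprintf("YSTR%02d", i) else sprintf("STR%02d", i)
    ulen <- if (is_pair) {
      4L
    } else if (is_y) {
      y_units[(i - n_auto - 1L) %% length(y_units) + 1L]
    } else {
      autosomal_units[(i - 1L) %% length(autosomal_units) + 1L]
    }
    unit <- random_repeat_unit(ulen)
    base_count <- sample(8:14, 1L)
    counts <- base_count + seq_len(alleles_per_locus) - 1L
    motifs <- lapply(counts, function(k) {
      parse_bracketed_motif(sprintf("[%s]%d", unit, k))
    })
    # locus 1: replace allele 2 by an isoallele of allele 3 (same length,
    # different sequence); locus 2: make the last allele a microvariant
    if (i == 1L && alleles_per_locus >= 3L) {
      k <- counts[3L]
      motifs[[2L]] <- parse_bracketed_motif(
        sprintf("[%s]%d %s %s", unit, k - 2L, mutate_unit(unit), unit))
    }
    if (i == 2L && alleles_per_locus >= 2L) {
      k <- counts[alleles_per_locus]
      part <- substr(unit, 1L, max(1L, ulen - 2L))
      motifs[[alleles_per_locus]] <- parse_bracketed_motif(
        sprintf("[%s]%d %s", unit, k, part))
    }
    chrom <- if (is_y || is_pair) "chrY" else sprintf("chr%d", i)
    ref_repeat <- expand_motif(motifs[[1L]])
    if (is_pair && i == n_loci) {
      # second copy appended to the existing chrY contig
      offset <- nchar(ref_seqs[["chrY"]]) + contig_pad
      ref_seqs[["chrY"]] <- paste0(ref_seqs[["chrY"]], random_dna(contig_pad),
                                   ref_repeat, random_dna(contig_pad))
    } else if (chrom %in% names(ref_seqs)) {
      offset <- nchar(ref_seqs[[chrom]]) + contig_pad
      ref_seqs[[chrom]] <- paste0(ref_seqs[[chrom]], random_dna(contig_pad),
                                  ref_repeat, random_dna(contig_pad))
    } else {
      offset <- contig_pad
      ref_seqs[[chrom]] <- paste0(random_dna(contig_pad), ref_repeat,
                                  random_dna(contig_pad))
    }
    rep_start <- offset
    rep_end <- offset + nchar(ref_repeat)
    loci_rows[[i]] <- locus_definitions(
      name = name, chrom = chrom, start = rep_start, end = rep_end,
      locus_class = if (is_pair) "Y-merged" else if (is_y) "Y" else "autosomal",
      unit_length = ulen,
      merge_group = if (is_pair) "DYS385ab" else NA_character_)
    for (j in seq_len(alleles_per_locus)) {
      variants <- NULL
      if (i == 1L && j == alleles_per_locus) {
        # exercise flank-variant application: SNP 12 bases upstream
        refbase <- substr(ref_seqs[[chrom]], rep_start - 12L + 1L,
                          rep_start - 12L + 1L)
        variants <- data.frame(offset = -12L, ref = refbase,
                               alt = sample(setdiff(BASES, refbase), 1L),
                               stringsAsFactors = FALSE)
      }
      m <- motifs[[j]]
      rec <- allele_record(
        accession = sprintf("SIM%02d_%02d", i, j), locus = name,
        chromosome = chrom, repeat_start = rep_start, repeat_end = rep_end,
        repeat_sequence = expand_motif(m), flanking_variants = variants,
        motif = m, designation = designation_from_motif(m, ulen))
      records[[length(records) + 1L]] <- rec
      truth[[length(truth) + 1L]] <- data.frame(
        accession = rec$accession, locus = name,
        designation = format(rec$designation), motif = format(m),
        repeat_length = nchar(rec$repeat_sequence), stringsAsFactors = FALSE)
    }
  }
  reference <- Biostrings::DNAStringSet(ref_seqs)
  names(reference) <- names(ref_seqs)
  list(records = records, reference = reference,
       loci = do.call(rbind, loci_rows), truth = do.call(rbind, truth))
}

#' Write allele records as a GenBank flat file
#'
#' Emits the dialect documented in [genbank-dialect]; the fixture
#' round-trip (write then [parse_genbank_records()]) is the identity on the
#' fields the catalog uses.
#'
#' @param records List of `str_allele_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    seq <- tolower(r$repeat_sequence)
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   PRI 01-JAN-2025",
                       r$accession, nchar(seq)), con)
    writeLines(sprintf("DEFINITION  Homo sapiens microsatellite %s allele %s.",
                       r$locus, format(r$designation)), con)
    writeLines(sprintf("ACCESSION   %s", r$accession), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    writeLines("                     /organism=\"Homo sapiens\"", con)
    writeLines(sprintf("                     /chromosome=\"%s\"", r$chromosome), con)
    writeLines(sprintf("     repeat_region   %d..%d",
                       r$repeat_start + 1L, r$repeat_end), con)
    writeLines(sprintf("                     /standard_name=\"%s\"", r$locus), con)
    writeLines("                     /rpt_type=tandem", con)
    writeLines(sprintf("                     /note=\"bracketed_motif=%s\"",
                       format(r$motif)), con)
    writeLines(sprintf("                     /allele=\"%s\"",
                       format(r$designation)), con)
    if (nrow(r$flanking_variants)) {
      for (k in seq_len(nrow(r$flanking_variants))) {
        v <- r$flanking_variants[k, ]
        writeLines(sprintf("                     /flank_variant=\"%d:%s>%s\"",
                           v$offset, v$ref, v$alt), con)
      }
    }
    writeLines("ORIGIN", con)
    starts <- seq(1L, nchar(seq), by = 60L)
    for (s in starts) {
      line <- substr(seq, s, min(s + 59L, nchar(seq)))
      groups <- substring(line, seq(1L, nchar(line), 10L),
                          pmin(seq(10L, nchar(line) + 9L, 10L), nchar(line)))
      writeLines(sprintf("%9d %s", s, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# homopolymer run length at each position
run_lengths_at <- function(bases) {
  r <- rle(bases)
  rep(r$lengths, r$lengths)
}

apply_errors <- function(seq, model) {
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  del_rate <- rep(model$del, n)
  del_rate[run_lengths_at(bases) >= 4L] <-
    pmin(0.5, model$del * model$homopolymer_mult)
  u <- stats::runif(n)
  drop <- u < del_rate
  sub <- !drop & (u < del_rate + model$sub)
  ins <- stats::runif(n) < model$ins
  out <- bases
  if (any(sub)) {
    out[sub] <- vapply(out[sub], function(b) sample(setdiff(BASES, b), 1L),
                       character(1))
  }
  out[drop] <- ""
  if (any(ins)) {
    idx <- which(ins)
    out[idx] <- paste0(out[idx], sample(BASES, length(idx), replace = TRUE))
  }
  paste(out, collapse = "")
}

# amplicon template for an entry: repeat plus primer flanks
entry_amplicon <- function(entry, amplicon_flank) {
  s <- entry$reference_sequence
  rep_len <- nchar(entry$allele$repeat_sequence)
  from <- max(1L, entry$repeat_offset - amplicon_flank + 1L)
  to <- min(nchar(s), entry$repeat_offset + rep_len + amplicon_flank)
  substr(s, from, to)
}

# minus-one-repeat artifact template (NULL when no block can lose a unit)
entry_stutter_amplicon <- function(entry, amplicon_flank) {
  m <- entry$allele$motif
  if (any(m$spacer)) return(NULL)
  candidates <- which(!m$spacer & m$count >= 2L)
  if (!length(candidates)) return(NULL)
  pick <- candidates[which.max(m$count[candidates])]
  m$count[pick] <- m$count[pick] - 1L
  s <- entry$reference_sequence
  up <- substr(s, max(1L, entry$repeat_offset - amplicon_flank + 1L),
               entry$repeat_offset)
  rep_len <- nchar(entry$allele$repeat_sequence)
  down <- substr(s, entry$repeat_offset + rep_len + 1L,
                 min(nchar(s), entry$repeat_offset + rep_len + amplicon_flank))
  paste0(up, expand_motif(m), down)
}

#' Simulate amplicon reads for one sample
#'
#' Per locus, `depth` reads are drawn from the truth alleles (binomial 0.5
#' for heterozygotes unless `imbalance` shifts it), each read being the full
#' amplicon (repeat + `amplicon_flank` primer flank each side) with stutter
#' applied first (whole-template swap) and then positional errors; half the
#' reads, in expectation, are reverse-complemented. Deterministic under
#' `seed`.
#'
#' @param spec An `str_sim_spec`.
#' @param catalog An `str_catalog` covering the spec's accessions.
#' @param error An `str_error_model`.
#' @param stutter An `str_stutter_model`.
#' @param seed Integer seed.
#' @param amplicon_flank Primer-flank bases on each side of the repeat
#'   (default 30).
#' @param imbalance Probability of drawing the first truth allele at a
#'   two-allele locus (default 0.5; other values probe threshold behavior).
#' @param loci Optional `str_loci` table; when given, a female spec naming a
#'   Y locus is rejected.
#' @return List with `reads` (data frame: `read_id`, `seq`, `qual`, `locus`,
#'   `accession`, `stutter`) and `truth` (ground-truth rows in the
#'   [read_truth_profiles()] dialect).
#' @export
simulate_reads <- function(spec, catalog, error = error_model(),
                           stutter = stutter_model(), seed = 1L,
                           amplicon_flank = 30L, imbalance = 0.5,
                           loci = NULL) {
  stopifnot(inherits(spec, "str_sim_spec"))
  if (spec$sex == "female" && !is.null(loci)) {
    ycls <- loci$name[loci$locus_class != "autosomal"]
    bad <- intersect(names(spec$truth), ycls)
    if (length(bad)) {
      stop("female spec lists Y locus/loci: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  set.seed(seed)
  by_acc <- stats::setNames(catalog$entries,
                            vapply(catalog$entries,
                                   function(e) e$allele$accession, character(1)))
  rows <- list()
  truth_rows <- list()
  for (loc in names(spec$truth)) {
    accs <- spec$truth[[loc]]
    if (!all(accs %in% names(by_acc))) {
      stop("allele accession(s) missing from catalog: ",
           paste(setdiff(accs, names(by_acc)), collapse = ", "), call. = FALSE)
    }
    entries <- by_acc[accs]
    cls <- entries[[1]]$allele  # locus class known to caller; not needed here
    amps <- vapply(entries, entry_amplicon, character(1),
                   amplicon_flank = amplicon_flank)
    stamps <- lapply(entries, entry_stutter_amplicon,
                     amplicon_flank = amplicon_flank)
    pick <- if (length(accs) == 2L) {
      ifelse(stats::runif(spec$depth) < imbalance, 1L, 2L)
    } else rep(1L, spec$depth)
    is_stutter <- stats::runif(spec$depth) < stutter$minus_one &
      !vapply(stamps[pick], is.null, logical(1))
    seqs <- character(spec$depth)
    for (k in seq_len(spec$depth)) {
      template <- if (is_stutter[k]) stamps[[pick[k]]] else amps[[pick[k]]]
      seqs[k] <- apply_errors(template, error)
    }
    flip <- stats::runif(spec$depth) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    rows[[loc]] <- data.frame(
      read_id = sprintf("%s_%s_%04d", spec$sample_id, loc, seq_len(spec$depth)),
      seq = seqs, qual = strrep("I", nchar(seqs)), locus = loc,
      accession = accs[pick], stutter = is_stutter, stringsAsFactors = FALSE)
    des <- vapply(entries, function(e) format(e$allele$designation), character(1))
    mot <- vapply(entries, function(e) format(e$allele$motif), character(1))
    truth_rows[[loc]] <- data.frame(
      sample = spec$sample_id, locus = loc,
      locus_class = NA_character_,  # filled by caller from the loci table
      allele1 = des[1], allele2 = if (length(des) > 1L) des[2] else NA_character_,
      motif1 = mot[1], motif2 = if (length(mot) > 1L) mot[2] else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, rows), truth = do.call(rbind, truth_rows))
}

#' Write simulated reads as FASTQ
#' @param reads Data frame from [simulate_reads()] (`$reads`).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1L, length(lines), 4L)] <- paste0("@", reads$read_id)
  lines[seq(2L, length(lines), 4L)] <- reads$seq
  lines[seq(3L, length(lines), 4L)] <- "+"
  lines[seq(4L, length(lines), 4L)] <- reads$qual
  writeLines(lines, path)
  invisible(path)
}
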