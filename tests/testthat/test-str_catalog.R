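# Nomenclature parsing, designation arithmetic, GenBank intake,
# redundancy collapse, and catalog assembly.

test_that("bracketed motif parsing handles brackets, singletons and spacers", {
  m <- parse_bracketed_motif("[TAGA]9 [CAGA]3 N48 [TAGA]13 [CAGA]6")
  expect_equal(nrow(m), 5L)
  expect_equal(m$count[!m$spacer], c(9L, 3L, 13L, 6L))
  expect_true(all(m$bracketed[!m$spacer]))
  expect_equal(which(m$spacer), 3L)
  expect_equal(m$spacer_length[3], 48L)

  m2 <- parse_bracketed_motif("[TCTA]9 TCTG TCTA")
  expect_equal(m2$count, c(9L, 1L, 1L))
  expect_equal(m2$bracketed, c(TRUE, FALSE, FALSE))
})

test_that("malformed motifs raise errors naming the offending token", {
  expect_error(parse_bracketed_motif(""), "empty")
  expect_error(parse_bracketed_motif("[TAGA]0"), "\\[TAGA\\]0")
  expect_error(parse_bracketed_motif("[TAXA]4"), "\\[TAXA\\]4")
  expect_error(parse_bracketed_motif("[TAGA"), "\\[TAGA")
  expect_error(parse_bracketed_motif("N12"), "non-spacer")
})

test_that("motif serialization round-trips (whitespace-normalized)", {
  fixtures <- c("[TAGA]9 [CAGA]3 N48 [TAGA]13 [CAGA]6",
                "[TCTA]9 TCTG TCTA",
                "[AGAT]13",
                "[AAAGA]2 GT",
                "  [AGAT]5   N10  [AGAT]2 ")
  for (f in fixtures) {
    norm <- gsub("\\s+", " ", trimws(f))
    expect_identical(format(parse_bracketed_motif(f)), norm)
    expect_identical(format(parse_bracketed_motif(format(parse_bracketed_motif(f)))),
                     norm)
  }
})

test_that("length-based designations sum repeat units and pool leftovers", {
  # spacer contributes length but no units: 9 + 3 + 13 + 6 = 31
  m <- parse_bracketed_motif("[TAGA]9 [CAGA]3 N48 [TAGA]13 [CAGA]6")
  expect_identical(format(designation_from_motif(m, 4L)), "31")
  expect_identical(format(designation_from_motif(parse_bracketed_motif("[AGAT]13"), 4L)),
                   "13")
  # microvariant: 2 whole penta units + 2 leftover bases -> 2.2
  expect_identical(format(designation_from_motif(parse_bracketed_motif("[AAAGA]2 GT"), 5L)),
                   "2.2")
  # isoalleles of equal length share the designation
  a <- parse_bracketed_motif("[TCTA]11")
  b <- parse_bracketed_motif("[TCTA]9 TCTG TCTA")
  expect_identical(format(designation_from_motif(a, 4L)), "11")
  expect_identical(format(designation_from_motif(b, 4L)), "11")
})

test_that("designation equals expanded length / unit length for spacer-free motifs", {
  set.seed(11)
  for (k in 1:25) {
    ulen <- sample(3:5, 1)
    unit <- random_seq(ulen)
    n <- sample(2:20, 1)
    extra <- sample(0:2, 1)
    txt <- sprintf("[%s]%d", unit, n)
    if (extra > 0) txt <- paste(txt, substr(unit, 1, extra))
    m <- parse_bracketed_motif(txt)
    d <- designation_from_motif(m, ulen)
    len <- nchar(expand_motif(m))
    expect_equal(d$whole, len %/% ulen)
    expect_equal(d$partial, len %% ulen)
  }
})

test_that("expand_motif concatenates units and refuses spacers", {
  expect_identical(expand_motif(parse_bracketed_motif("[AGAT]2")), "AGATAGAT")
  expect_equal(nchar(expand_motif(parse_bracketed_motif("[AGAT]13"))), 52L)
  expect_error(expand_motif(parse_bracketed_motif("[TAGA]9 N48 [TAGA]13")),
               "spacer")
})

test_that("GenBank records round-trip through the writer and parser", {
  fx <- make_fixture_catalog(n_loci = 3L, alleles_per_locus = 3L, seed = 5L)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank_records(fx$records, path)
  parsed <- parse_genbank_records(path)
  expect_length(parsed, length(fx$records))
  for (i in seq_along(parsed)) {
    orig <- fx$records[[i]]; got <- parsed[[i]]
    expect_identical(got$accession, orig$accession)
    expect_identical(got$locus, orig$locus)
    expect_identical(got$chromosome, orig$chromosome)
    expect_identical(got$repeat_start, orig$repeat_start)
    expect_identical(got$repeat_end, orig$repeat_end)
    expect_identical(got$repeat_sequence, orig$repeat_sequence)
    expect_identical(format(got$motif), format(orig$motif))
    expect_identical(format(got$designation), format(orig$designation))
    expect_equal(got$flanking_variants, orig$flanking_variants)
    # motif expansion reproduces the record's repeat sequence
    expect_identical(expand_motif(got$motif), got$repeat_sequence)
  }
})

test_that("1-based inclusive GenBank coordinates become 0-based half-open", {
  fx <- make_fixture_catalog(n_loci = 1L, alleles_per_locus = 1L, seed = 2L)
  rec <- fx$records[[1]]
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank_records(list(rec), path)
  gb <- readLines(path)
  loc_line <- grep("repeat_region", gb, value = TRUE)
  pos <- as.integer(strsplit(sub(".*repeat_region\\s+", "", loc_line), "\\.\\.")[[1]])
  expect_identical(rec$repeat_start, pos[1] - 1L)
  expect_identical(rec$repeat_end, pos[2])
})

test_that("records lacking annotation are skipped, not fatal", {
  fx <- make_fixture_catalog(n_loci = 3L, alleles_per_locus = 1L, seed = 5L)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank_records(fx$records, path)
  lines <- readLines(path)
  # strip the locus-name qualifier from the second record
  recs <- split(seq_along(lines), cumsum(c(1, head(grepl("^//", lines), -1))))
  bad <- recs[[2]]
  lines <- lines[-bad[grepl("standard_name", lines[bad])]]
  expect_warning(parsed <- parse_genbank_records(lines), "skipped")
  expect_length(parsed, 2L)
  expect_length(attr(parsed, "skipped"), 1L)
})

test_that("collapse_redundant keeps distinct records and drops true duplicates", {
  fx <- make_fixture_catalog(n_loci = 2L, alleles_per_locus = 3L, seed = 3L)
  recs <- fx$records
  # all-distinct input unchanged, order-stable
  out <- collapse_redundant(recs)
  expect_identical(vapply(out, `[[`, character(1), "accession"),
                   vapply(recs, `[[`, character(1), "accession"))
  # exact duplicate (different accession) collapses, smallest accession wins
  dup <- recs[[1]]; dup$accession <- "ZZZ_99"
  out2 <- collapse_redundant(c(recs, list(dup)))
  expect_length(out2, length(recs))
  expect_identical(out2[[1]]$accession, recs[[1]]$accession)
  dup2 <- recs[[1]]; dup2$accession <- "AAA_00"
  out3 <- collapse_redundant(c(recs, list(dup2)))
  expect_identical(out3[[1]]$accession, "AAA_00")
  # same repeat, different flanking variant: both kept
  var <- recs[[1]]
  var$accession <- "VAR_01"
  var$flanking_variants <- data.frame(offset = -3L, ref = "A", alt = "G",
                                      stringsAsFactors = FALSE)
  expect_length(collapse_redundant(c(recs, list(var))), length(recs) + 1L)
  # idempotent
  expect_identical(collapse_redundant(out2), out2)
})

test_that("build_catalog frames repeats with reference flanks", {
  fx <- make_fixture_catalog(n_loci = 2L, alleles_per_locus = 2L, seed = 4L)
  cat0 <- build_catalog(fx$records, fx$reference, flank_length = 500L)
  for (e in cat0$entries) {
    expect_equal(nchar(e$reference_sequence),
                 nchar(e$allele$repeat_sequence) + e$upstream_used +
                   e$downstream_used)
    expect_false(e$truncated)
    expect_equal(e$upstream_used, 500L)
    # repeat sits verbatim at its offset
    expect_identical(substr(e$reference_sequence, e$repeat_offset + 1L,
                            e$repeat_offset + nchar(e$allele$repeat_sequence)),
                     e$allele$repeat_sequence)
  }
})

test_that("build_catalog applies flank variants and flags truncation", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("T", 100),
                                                  "AGATAGATAGAT",
                                                  strrep("C", 600))))
  m <- parse_bracketed_motif("[AGAT]3")
  rec <- allele_record("ACC1", "LOC1", "chr1", 100L, 112L, "AGATAGATAGAT",
                       data.frame(offset = -2L, ref = "T", alt = "G"),
                       m, designation_from_motif(m, 4L))
  cat0 <- build_catalog(list(rec), ref, flank_length = 500L)
  e <- cat0$entries[[1]]
  expect_true(e$truncated)             # only 100 bp upstream available
  expect_equal(e$upstream_used, 100L)
  expect_equal(e$downstream_used, 500L)
  up <- substr(e$reference_sequence, 1, 100)
  expect_identical(substr(up, 99, 99), "G")   # offset -2 applied
  expect_identical(substr(up, 100, 100), "T")
  # REF mismatch is fatal
  rec_bad <- rec
  rec_bad$flanking_variants$ref <- "A"
  expect_error(build_catalog(list(rec_bad), ref), "mismatch")
  # absent chromosome is fatal; chr-less alias is accepted
  rec_alias <- rec; rec_alias$chromosome <- "1"
  expect_silent(build_catalog(list(rec_alias), ref))
  rec_miss <- rec; rec_miss$chromosome <- "chr9"
  expect_error(build_catalog(list(rec_miss), ref), "absent")
})

test_that("catalog FASTA headers round-trip and output is deterministic", {
  fx <- make_fixture_catalog(n_loci = 2L, alleles_per_locus = 2L, seed = 6L)
  cat0 <- build_catalog(fx$records, fx$reference)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_catalog_fasta(cat0, f1)
  write_catalog_fasta(cat0, f2)
  expect_identical(readLines(f1), readLines(f2))
  headers <- sub("^>", "", grep("^>", readLines(f1), value = TRUE))
  for (i in seq_along(headers)) {
    h <- parse_catalog_header(headers[i])
    a <- cat0$entries[[i]]$allele
    expect_identical(h$accession, a$accession)
    expect_identical(h$locus, a$locus)
    expect_identical(format(h$motif), format(a$motif))
    expect_identical(format(h$designation), format(a$designation))
  }
})

test_that("loci BED round-trips through writer and reader", {
  fx <- make_fixture_catalog(n_loci = 5L, seed = 7L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_loci_bed(fx$loci, path)
  back <- read_loci_bed(path)
  expect_equal(as.data.frame(back), as.data.frame(fx$loci))
})
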