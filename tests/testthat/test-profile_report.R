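# Concordance scoring dialects, metric arithmetic, and report round-trips.

mk_truth <- function(locus, cls, a1, a2 = NA_character_) {
  data.frame(sample = "s", locus = locus, locus_class = cls,
             allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
}

mk_pred <- function(locus, cls, designations, zygosity) {
  alleles <- data.frame(accession = paste0("ACC", seq_along(designations)),
                        raw = 100, norm = 1,
                        designation = designations,
                        motif = NA_character_, stringsAsFactors = FALSE)
  call <- longstr:::locus_call(locus, cls, alleles, zygosity, character())
  str_profile("s", stats::setNames(list(call), locus))
}

test_that("exact matches score TP with homozygote expansion", {
  cc <- compare_profiles(mk_pred("L", "autosomal", c("16", "17"), "heterozygous"),
                         mk_truth("L", "autosomal", "16", "17"))
  expect_equal(unlist(cc["autosomal", ]), c(TP = 2L, FP = 0L, FN = 0L))
  # homozygote written once on both sides still counts two allele calls
  cc2 <- compare_profiles(mk_pred("L", "autosomal", "16", "homozygous"),
                          mk_truth("L", "autosomal", "16"))
  expect_equal(unlist(cc2["autosomal", ]), c(TP = 2L, FP = 0L, FN = 0L))
})

test_that("substituted and missing alleles follow the published-table dialect", {
  # false positive beside a homozygous truth: FP only, no FN
  cc <- compare_profiles(mk_pred("D18S51", "autosomal", c("16", "15"),
                                 "heterozygous"),
                         mk_truth("D18S51", "autosomal", "16"))
  expect_equal(unlist(cc["autosomal", ]), c(TP = 1L, FP = 1L, FN = 0L))
  # missing second allele: FN
  cc2 <- compare_profiles(mk_pred("PentaD", "autosomal", "5", "homozygous"),
                          mk_truth("PentaD", "autosomal", "5", "2.2"))
  expect_equal(unlist(cc2["autosomal", ]), c(TP = 1L, FP = 0L, FN = 1L))
  # substituted Y allele: FP only (truth allele neither TP nor FN)
  cc3 <- compare_profiles(mk_pred("DYS390", "Y", "22", "haplotype"),
                          mk_truth("DYS390", "Y", "23"))
  expect_equal(unlist(cc3["Y", ]), c(TP = 0L, FP = 1L, FN = 0L))
  # merged-locus pair called against a single-allele truth: two FPs
  cc4 <- compare_profiles(mk_pred("DYS385ab", "Y-merged", c("12", "13"),
                                  "haplotype"),
                          mk_truth("DYS385ab", "Y-merged", "11"))
  expect_equal(unlist(cc4["Y", ]), c(TP = 0L, FP = 2L, FN = 0L))
})

test_that("conventional mode scores substitutions as FP + FN", {
  cc <- compare_profiles(mk_pred("D18S51", "autosomal", c("16", "15"),
                                 "heterozygous"),
                         mk_truth("D18S51", "autosomal", "16"),
                         mode = "conventional")
  expect_equal(unlist(cc["autosomal", ]), c(TP = 1L, FP = 1L, FN = 1L))
  cc2 <- compare_profiles(mk_pred("DYS390", "Y", "22", "haplotype"),
                          mk_truth("DYS390", "Y", "23"), mode = "conventional")
  expect_equal(unlist(cc2["Y", ]), c(TP = 0L, FP = 1L, FN = 1L))
})

test_that("predicted loci absent from truth are skipped with a warning", {
  pred <- mk_pred("LX", "autosomal", "10", "homozygous")
  expect_warning(cc <- compare_profiles(pred, mk_truth("L", "autosomal", "9")),
                 "absent from ground truth")
  # the truth locus with no prediction is all-FN
  expect_equal(unlist(cc["autosomal", ]), c(TP = 0L, FP = 0L, FN = 1L))
})

test_that("sequence-level matching is at least as strict as length-level", {
  truth <- mk_truth("L", "autosomal", "13", "13")
  truth$motif1 <- "[AGAT]13"; truth$motif2 <- "[AGAT]13"
  pred <- mk_pred("L", "autosomal", c("13", "13"), "heterozygous")
  pred$calls$L$alleles$motif <- c("[AGAT]13", "CGAT [AGAT]12")
  len <- compare_profiles(pred, truth, level = "length")
  seqv <- compare_profiles(pred, truth, level = "sequence")
  expect_equal(len["autosomal", "TP"], 2L)
  expect_equal(seqv["autosomal", "TP"], 1L)  # isoallele mismatch caught
  expect_lte(seqv["autosomal", "TP"], len["autosomal", "TP"])
})

test_that("compute_metrics reproduces the published tally arithmetic", {
  m <- compute_metrics(c(TP = 154, FP = 4, FN = 0))
  expect_equal(m$recall, 1)
  expect_equal(round(100 * m$precision, 1), 97.5)
  expect_equal(round(100 * m$f1, 1), 98.7)

  m2 <- compute_metrics(c(TP = 798, FP = 0, FN = 1))
  expect_equal(round(100 * m2$recall, 1), 99.9)
  expect_equal(m2$precision, 1)
  expect_equal(round(100 * m2$f1, 1), 99.9)

  perfect <- compute_metrics(c(TP = 37, FP = 0, FN = 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  # undefined-safe, never a division failure
  none <- compute_metrics(c(TP = 0, FP = 0, FN = 0))
  expect_true(is.na(none$precision) && is.na(none$recall) && is.na(none$f1))
  # scale-free
  m3 <- compute_metrics(c(TP = 154 * 7, FP = 4 * 7, FN = 0))
  expect_equal(m3$f1, m$f1)
})

test_that("benchmark tallies are additive across samples", {
  p1 <- mk_pred("L", "autosomal", c("16", "15"), "heterozygous")
  p2 <- mk_pred("L", "autosomal", "16", "homozygous")
  truth <- rbind(mk_truth("L", "autosomal", "16"),
                 mk_truth("L", "autosomal", "16"))
  truth$sample <- c("a", "b")
  bm <- benchmark_profiles(list(a = p1, b = p2), truth)
  cc <- attr(bm, "concordance")
  expect_equal(cc$total["autosomal", "TP"],
               cc$a["autosomal", "TP"] + cc$b["autosomal", "TP"])
  expect_equal(cc$total["autosomal", "FP"], 1L)
  expect_equal(bm$autosomal_TP[bm$sample == "total"], 3L)
})

test_that("profile reports round-trip through TSV", {
  fx <- make_fixture_catalog(n_loci = 3L, alleles_per_locus = 3L, seed = 12L)
  cat0 <- build_catalog(fx$records, fx$reference)
  des <- longstr:::catalog_designation_map(cat0)
  mot <- longstr:::catalog_motif_map(cat0)
  calls <- list()
  for (i in 1:2) {
    loc <- fx$loci[i, , drop = FALSE]
    accs <- vapply(catalog_locus_entries(cat0, loc$name),
                   function(e) e$allele$accession, character(1))
    cr <- structure(list(counts = stats::setNames(c(800L, 500L, 30L), accs),
                         unassigned = 3L, assignments = character()),
                    class = "str_count_row")
    calls[[loc$name]] <- call_locus(cr, loc, caller_config(),
                                    designations = des, motifs = mot)
  }
  prof <- str_profile("blood07", calls)
  tbl <- profile_table(prof, des, mot)
  expect_equal(unique(tbl$sample), "blood07")
  expect_true(all(tbl$called[tbl$norm == 1.0]))
  # uncalled detected alleles appear with called = FALSE
  expect_true(any(!tbl$called))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(tbl, path)
  back <- read_profile(path)
  expect_identical(back$sample_id, "blood07")
  expect_identical(names(back$calls), names(prof$calls))
  for (nm in names(prof$calls)) {
    expect_identical(back$calls[[nm]]$alleles$accession,
                     prof$calls[[nm]]$alleles$accession)
    expect_identical(back$calls[[nm]]$alleles$designation,
                     prof$calls[[nm]]$alleles$designation)
    expect_identical(back$calls[[nm]]$zygosity, prof$calls[[nm]]$zygosity)
    expect_equal(back$calls[[nm]]$alleles$norm, prof$calls[[nm]]$alleles$norm)
  }
  # writing the re-read profile reproduces the same table rows
  tbl2 <- profile_table(back, des, mot)
  expect_equal(tbl2[, c("locus", "accession", "raw", "called")],
               tbl[, c("locus", "accession", "raw", "called")])
  # empty profile -> header-only file
  p0 <- withr::local_tempfile(fileext = ".tsv")
  write_profile(profile_table(str_profile("empty", list())), p0)
  expect_length(readLines(p0), 1L)
})

test_that("truth profiles round-trip through TSV", {
  truth <- rbind(mk_truth("L1", "autosomal", "16", "17"),
                 mk_truth("DYS19", "Y", "14"))
  truth$motif1 <- c("[AGAT]16", "[TAGA]14"); truth$motif2 <- c("[AGAT]17", NA)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_profiles(truth, path)
  back <- read_truth_profiles(path)
  expect_equal(back, truth)
})
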