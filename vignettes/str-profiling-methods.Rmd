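---
title: "Sequence-based STR profiling from long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based STR profiling from long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longstr)
```

## The problem

Forensic human identification types short tandem repeats (STRs): loci where
a 2–6 bp unit repeats a variable number of times. Capillary electrophoresis
(CE) resolves only fragment *length*, so alleles are named by repeat-unit
count (the length-based designation, e.g. `13`, with microvariants like
`15.1` for leftover bases). Sequencing additionally resolves *isoalleles* —
same length, different sequence, e.g. `[TCTA]11` versus
`[TCTA]9 TCTG TCTA` — and flanking-region variants. Long-read (nanopore)
sequencing makes this portable and cheap, but reads are noisy, so genotypes
must be called from evidence aggregated over many reads.

`longstr` implements the full workflow: build a sequence-resolved allele
catalog from GenBank-style records; map reads to a reference genome (via an
external aligner) and keep primary alignments spanning each target locus;
re-score each binned read against the locus's catalog alleles; normalize
per-allele read counts to the best-covered allele; and call autosomal
genotypes and Y haplotypes, reporting both nomenclature levels. A
concordance module scores called profiles against ground truth, and a
seeded simulator makes the whole pipeline testable offline.

## The allele catalog

Each catalog record carries the accession, locus, reference repeat interval
(internally 0-based half-open; GenBank's 1-based inclusive coordinates are
converted at the boundary), the allele's repeat sequence, its bracketed
motif, and any flanking variants. Records identical in repeat sequence
*and* flanking variants (same locus) are redundant and collapse to one,
keeping the lexicographically smallest accession for determinism. Each
entry is then framed with reference-genome flanks (default 500 bp per
side) so that reads which mostly cover flank still align; flanks shorter
than requested (repeat near a contig end) are used as-is and flagged.

Flanking-variant coordinates are not standardized in source records, so the
package fixes a frame: negative offsets count back from the repeat start
(−1 = last upstream base), non-negative offsets count forward from the
repeat end (0 = first downstream base). `REF`/`ALT` strings of unequal
length express indels; variants are applied right-to-left within each flank
so indel shifts cannot invalidate remaining offsets, and a `REF` mismatch
against the reference genome is a hard error.

The bracketed-motif grammar is `[UNIT]count` for a run, a bare `UNIT` for a
singleton, and `Nk` for a k-base spacer. A spacer contributes sequence
length but zero repeat units — forced by the DYS389II convention, where
`[TAGA]9 [CAGA]3 N48 [TAGA]13 [CAGA]6` is allele 31 (9+3+13+6). Off-length
blocks are pooled: whole units are `floor(bases/unit_length)` and the
remainder becomes the microvariant suffix (`2.2` = 2 units + 2 bases). The
designation is always computed from the motif, never parsed from free text.

## Read intake and assignment

Only primary alignments count; secondary and supplementary placements are
excluded. A read belongs to a locus only if its aligned interval fully
contains the repeat ± `min_span_flank` (default 10 bp — "spanning" with a
small guard against aligner end-trimming). Loci must be non-overlapping, so
a read lands in at most one bin. No mapping-quality filter is applied by
default (a flag exists).

Binned reads are re-scored against the locus's alleles by unit-cost
semi-global edit distance (free end gaps for the longer sequence, `N`
matches nothing), computed in C++ and checked in the test suite against an
independent R dynamic-programming oracle. Both read orientations are
scored and the better taken, so assignment is strand-invariant. A read is
assigned to the unique lowest-cost allele provided its identity
(1 − cost/length of the contained sequence) is at least
1 − `max_divergence` (default 0.30: tolerant of nanopore error, rejects
wrong-locus junk); ties are discarded rather than split, because crediting
either allele would bias the normalization that follows.

Two performance notes. First, alleles are scored after trimming to the
repeat ± `window` bp (default 200): the 500 bp catalog flanks exist for the
genome-mapping stage, while amplicon reads only ever overlap the
repeat-proximal flank, so the trimmed alignment assigns identically at a
fraction of the cost (`window = NULL` restores full-length scoring).
Second, because all alleles of a locus share their flanks, flank-sequence
errors cost every candidate equally — discrimination comes from the repeat
region, which is why containment of the full repeat is required at intake.

## Calling

Raw per-allele counts are normalized to the best-covered allele, so the top
allele is exactly 1.0. Autosomal loci always report the top allele and
report the second-ranked allele iff its normalized value *exceeds* the
heterozygote threshold (default 0.4, strict `>` on full precision; an
inclusive mode exists). The published worked examples behave accordingly:
2112/2865 → 0.74 displays as 0.7; 550/937 → 0.6 is called at DYS385ab
while 90/937 → 0.1 is not. Y loci report only the top allele — except the
DYS385a/b duplication, which one primer pair amplifies at two Y sites:
reads from both bins are pooled under one merged locus and the top two
alleles exceeding the threshold are reported.

A locus with fewer than `min_coverage` reads (default 10; the method's
source material states no minimum, but dropout must be distinguishable
from homozygosity) is flagged as dropout and yields no allele call; a
zero-coverage Y locus in a female sample is therefore a dropout, not an
error. Rank-1 ties report both alleles with a `tie` flag at autosomal loci
and abstain (flagged) at non-merged Y loci.

Homozygotes are reported once in human-readable output but count as two
allele calls in concordance scoring — required to reproduce published
control-panel bookkeeping (54 samples × 22 autosomal loci × 2 alleles =
2376 scored calls).

## Concordance scoring

Each reported allele is a true positive (matches truth), false positive
(not in truth), or false negative (truth allele missing from the
prediction); precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic
mean, all undefined-safe. Matching is at length level (designations) or
sequence level (whitespace-normalized motifs; strictly harder).

Two dialects are provided because published benchmark arithmetic requires
a specific one. In the default `"published"` mode, a *substituted* allele (a
wrong allele reported in place of a right one) counts as FP only — the
displaced truth allele is neither TP nor FN — and FN arises only when the
prediction reports fewer alleles than truth holds. This reproduces
benchmark rows such as a Y haplotype miscall contributing FP 1/FN 0 and a
spurious second autosomal allele beside a homozygous truth contributing
TP 1/FP 1/FN 0. The `"conventional"` mode is plain multiset difference
after homozygote expansion (a substitution costs FP 1 + FN 1).

Displayed percentages round half away from zero. One published cell
(casework-overall autosomal F1) can only be reproduced by computing the
displayed F1 from the already-rounded precision and recall columns
(99.9 and 99.82 → 99.86 → 99.9, whereas the exact value is 99.85 → 99.8);
`metrics_display()` implements exactly that table convention, while
`compute_metrics()` always returns full precision.

## The simulator and what a green test establishes

`make_fixture_catalog()` fabricates a miniature world: GenBank-style
records, a reference genome with each locus's reference allele embedded
700 bp deep in random sequence, locus definitions, and a truth table. It
always contains an isoallele pair, a microvariant allele, a flank-SNP
allele, and a DYS385-like duplicated Y pair. Unit lengths mirror the
commercial 46-locus multiplex this pipeline emulates: autosomal loci are
tetra- or pentanucleotide only, while the Y side carries the panel's
trinucleotide locus (DYS392-like) and pentanucleotide locus
(DYS438-like). This composition matters: in a periodic repeat, base
deletions collapse toward the minus-one-unit allele, and with a ~3%
deletion rate a trinucleotide *heterozygote* ratio is pushed toward the
0.4 threshold. Real multiplexes avoid that regime by design (no autosomal
trinucleotide loci), and so does the fixture panel; the phenomenon itself
remains observable at the haploid Y trinucleotide locus, where it mimics
the minus/plus-one-unit miscalls reported for real casework.

`simulate_reads()` draws `depth` full amplicons per locus (short commercial
amplicons are spanned entirely by nanopore reads, so no fragmentation
model) from the truth alleles — binomial 0.5 for heterozygotes, with an
`imbalance` knob for probing the threshold — applies stutter first (whole
template swapped for the minus-one-repeat artifact, proportion
`minus_one`), then per-base substitutions/insertions/deletions at the
configured rates, with deletions multiplied (default ×2) inside
homopolymer runs ≥ 4 where nanopore deletions concentrate. Half the reads
are reverse-complemented. Default rates (5%/2%/3%, stutter 10%) represent
a conservative nanopore amplicon dataset. Quality strings are constant:
the matcher is deliberately quality-blind. Everything is deterministic
under a fixed seed, byte for byte.

The simulator does *not* model: multi-contributor mixtures, allelic
dropout from degraded input, plus-one stutter, signal-level artifacts,
barcode chemistry, or context-dependent substitution spectra. A green
end-to-end test therefore establishes that the catalog/binning/assignment/
normalization/calling chain is internally correct and robust to idealized
uniform noise at stated rates — not that the method is validated for
casework.

## Defaults at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `flank_length` | 500 | bp | reference flank added per side of each catalog allele |
| `min_span_flank` | 10 | bp | spanning margin; guards against aligner end-trimming |
| `max_divergence` | 0.30 | fraction | identity floor for assignment; tolerates nanopore error |
| `window` | 200 | bp | allele trimming for scoring; flanks beyond it cannot change assignments |
| `threshold` | 0.4 | fraction of top count | heterozygote cutoff, strict `>`; tune per laboratory validation |
| `min_coverage` | 10 | reads | dropout vs homozygote distinction |
| `sub/ins/del` | 0.05/0.02/0.03 | per base | conservative nanopore amplicon error profile |
| `homopolymer_mult` | 2 | — | deletion enrichment in runs ≥ 4 |
| `minus_one` | 0 (sims use 0.1) | fraction of reads | PCR stutter proportion |
| `amplicon_flank` | 30 | bp | primer-flank per side of simulated amplicons (scaled-down toy amplicons) |

## Known limitations

* Assignment is winner-takes-all per read; no probabilistic weighting of
  near-ties, no stutter-aware genotype likelihoods.
* The DYS385a/b merge reports accessions from either physical copy; if both
  copies carry same-designation alleles the merged call can list one
  designation twice.
* Sequence-level concordance compares motif strings verbatim (after
  whitespace normalization); semantically equal but differently bracketed
  motifs would not match.
* The GenBank parser targets the documented STRSeq-style dialect; records
  lacking the expected qualifiers are skipped with a warning rather than
  guessed at.
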