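---
title: "Duplex-UMI sequencing for low-frequency edit detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex-UMI sequencing for low-frequency edit detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexr)
```

## The measurement problem

Genome-edited crops typically differ from their wild-type background by a
single nucleotide variant (SNV) or a short insertion/deletion (InDel).
Quantifying such an allele at a mass fraction of 0.1 % in a food or feed
matrix is far below the raw error rate of short-read sequencing (~1e-3
per base) and below the PCR error floor of amplicon assays.  Duplex UMI
sequencing solves this with two nested consensus layers:

1. **Single-strand consensus (SSC).** Every original DNA fragment is
   ligated to an adapter carrying a 12-nt random unique molecular
   identifier (UMI) and a 2-nt strand tag (TT on one strand, GG on the
   other).  All reads sharing (locus, UMI, strand tag) are PCR copies of
   one strand of one molecule; a per-column plurality consensus removes
   independent sequencing errors.
2. **Duplex consensus (DCS).** The two opposite-strand SSCs of one
   molecule are merged; any column where the strands disagree is masked
   with `N`.  A PCR error arises on one strand and is eliminated here.
   Only damage already present on *both* strands of the original
   molecule — in practice oxidative/deamination damage copied across
   during end repair — survives.

A mutation's frequency is then a *molecule count ratio*: mutant duplex
consensus sequences carrying the exact same normalised mutation, divided
by the total number of duplex consensus sequences covering the site with
a non-`N` state.  The package implements this pipeline
(`tag_reads()` → `group_families()` → `consensus_sample()` →
`call_dcs_variants()` → `aggregate_counts()` → `replicate_filter()`),
a synthetic duplex-library simulator used as ground truth, and the
evaluation statistics.

## The simulator and what it emulates

`ngt_design()` builds a synthetic four-window reference in which each
window carries one 24-nt single-primer-extension (SPE) site and one
edited line: a homozygous 1-bp deletion (−C), a homozygous 5-bp deletion
(−CAGTT), a homozygous 1-bp insertion (+A), and a heterozygous line with
a 1-bp deletion (−A) and a 1-bp insertion (+C) on its two alleles — five
distinct mutations.  In the tomato study this emulates, the two
phytoene-synthase lines share one target region; here each line gets its
own window so that truth accounting stays per-line.  The deleted motifs
are planted with non-repeating flanks so left-normalisation keeps their
coordinates fixed.

`design_mixture()` converts nominal per-allele copy ratios into DNA mass
fractions: for homozygous diploid leaf material, mass fraction and copy
ratio coincide; a heterozygous line carries each edited allele on half
its genome copies, so its DNA enters at double the mass.

`simulate_molecules()` / `emit_fastq()` generate the library
(defaults in `sim_params()`):

* fragments of mean 550 nt (SD 40, clipped 400–700) from sonication;
* one amplifiable end per molecule: the amplicon runs from the SPE
  primer 5' end to the adapter-bearing fragment end, with a uniform
  breakpoint giving insert sizes of 150–200 nt — reproducing the short,
  variable inserts of SPE libraries without modelling size selection
  explicitly;
* read 1 = `[12-nt UMI][TT/GG tag][genomic bases from the adapter end
  inward]`, read 2 = `[SPE primer oligo][genomic bases]`, 2 × 150 nt,
  constant Q30 qualities (error injection is independent of the written
  qualities);
* reads per captured strand `1 + Poisson(4.5)` and bottom-strand capture
  probability 0.85, which together give ≈ 10 reads per UMI, the
  empirically healthy regime in which molecules are sequenced on both
  strands without over-sequencing;
* per-base sequencing error 1e-3, i.i.d. over all read bases including
  UMI, tag and primer bases.

Three artefact classes are injected and recorded in a per-molecule
truth ledger:

| class | rate (default) | placement | duplex fate |
|---|---|---|---|
| `single_strand` | 1e-3 / molecule | uniform in the amplicon | masked (N) |
| `end_repair` | 3e-4 / molecule | ≤ 30 nt from the adapter-proximal end, G→T or C→T on the damaged strand, copied complementarily | **survives** |
| `pcr_jackpot` | 5e-5 / base opportunity | random position, a random fraction of one strand family's reads | masked (N) |

The ledger lets tests assert the duplex error model mechanistically:
single-strand damage never reaches a DCS base, end-repair damage always
does when both strands are captured, and end-repair calls cluster at
short distance from the UMI (`distance_to_umi_trend()` fits a Poisson
regression of bin counts on bin midpoints, bin 1–20 → midpoint 10, and
recovers a negative distance coefficient).

What the simulator does **not** emulate: ligation efficiency, adapter
dimers, index hopping, instrument quality profiles, off-target priming,
size selection, and the merging of two overlapping fragment ends into
one duplex.  Passing tests therefore demonstrate the correctness of the
*algorithmic* chain under a faithful error taxonomy, not performance on
any particular instrument run.

## Parameters that matter

* **Strand-tag matching is exact.** The tag is 2 nt; tolerating one
  mismatch would merge the two strands of a molecule, which is the one
  error duplex logic cannot recover from.  UMIs containing `N` are
  rejected rather than repaired for the same reason.
* **Primer matching allows 1 mismatch, anchored at read-2 position 0**;
  SPE amplicons are primer-anchored by construction, so a shifted match
  is off-target.  Two equally good primers → ambiguity rejection.
* **Directional UMI merge.** A family whose UMI is within Hamming
  distance 1 of a ≥ 3× larger family (same locus and strand) is absorbed
  into it.  With a 12-nt UMI and 1e-3 error, ~1.2 % of reads otherwise
  found spurious singleton families.
* **SSC plurality 0.6.** A column keeps its plurality base when its
  fraction is ≥ 0.6 (boundary kept: 3 of 5 reads suffice), else `N`.
  Indel states compete like bases, including the "absent" state of an
  insertion slot.
* **`min_reads_per_strand = 1`.** A duplex needs both strands, but each
  strand may be a single read: a large share of UMIs carry few reads,
  and the error control is duplex masking, not per-strand depth.
  Raising the minimum only removes duplexes (tested monotone).
* **Alignment scoring** match +1, mismatch −2, gap open −4 (first gapped
  base), gap extend −1; global in the read, free end positioning in the
  window; ties prefer the leftmost start and deletions before
  insertions; score floor 0.4 × insert length.  Verified against a
  brute-force substring-enumeration oracle on short sequences.
* **Edge guard 2 columns.** Observations within two columns of a DCS
  span edge are discarded; gapped alignment ends are not trustworthy.
* **Region of interest (ROI).** Variants are called in the segment every
  amplicon covers — from the primer anchor through the read-2 footprint
  (`default_roi()`).  Beyond it, duplex depth decays with the fragment
  breakpoint lottery, and a single molecule can masquerade as a high
  frequency over a denominator of a handful.  Disable with `roi = NULL`.
* **Replicate filter**: accept a variant with ≥ 2 duplex counts in all
  3 replicates, or ≥ 5 counts in ≥ 2 replicates; 4 counts in 2
  replicates is rejected (the observed separation point between real
  edits and end-repair artefacts).

## Statistics

`precision_trueness()` reports, per mutation × level, the CV %
(sample SD over mean of replicate frequencies) and bias %
(mean vs nominal level), flagged against the acceptance thresholds used
in GMO analysis: CV ≤ 25 % (relaxed to < 50 % below the 0.2 % level) and
|bias| ≤ 25 %.

`fit_quasibinomial()` regresses mutant/total duplex count pairs on the
nominal level with a binomial-family IRLS fit and a Pearson-moment
dispersion.  The logit link is the default (frequencies near 0 are far
from the identity-link boundary); an identity link is available as a
sensitivity check and is the natural choice when frequencies are exactly
proportional to level.  Counts, not precomputed ratios, enter the fit so
the dispersion estimate is well-defined.

`fit_poisson_offset()` models mutant duplex counts with log-link Poisson
regression and `log(total)` as a fixed offset; factor significance uses
likelihood-ratio chi-square tests (invariant to parameterisation, unlike
Wald).  Designs in which a factor level has all-zero counts are flagged
degenerate instead of silently reported.  On balanced simulated
titrations, the down-sampling level factor is non-significant in ≥ 90 %
of seeded runs while the mutation factor stays significant — the
expected behaviour when counts scale with their offsets.

At the 0.1 % level the mutant duplex count is a small Poisson variable
(mean ≈ 8 at duplex depth 8,000), so replicate CV is dominated by
counting statistics: CV ≈ 100/√(p·D) %.  The test suite checks this law
at p = 0.001, D = 3,000 over 50 seeds.

## Numerical and design choices

* Consensus within a family is computed per mate in read coordinates and
  the consensus string is then aligned once.  For SPE-anchored amplicon
  families — all members are full-length PCR copies of one template and
  read errors are substitutions — this is exactly equivalent to aligning
  every read and taking per-column consensus, at a fraction of the cost.
  The column-map operations (`build_ssc()`, `build_dcs()`) implement the
  general contract and are cross-checked against an exhaustive
  per-column majority oracle.
* Mate overlap disagreements inside one SSC become `N` (conservative);
  the two mates of a pair derive from the same strand, so a disagreement
  is a sequencing error with no majority.
* Duplex merging is symmetric; an insertion present on one strand only
  is dropped, differing inserted strings are dropped, equal ones kept.
* InDels are left-normalised only at variant-calling time, so consensus
  columns stay in aligner coordinates; "the same exact mutation" is
  identity of the normalised (pos, ref, alt) tuple.
* Depth counts only non-`N` covering duplexes: an `N` supports neither
  allele.  This shrinks denominators slightly relative to raw coverage.
* Problem sizes used by the tests and the acceptance script: 4 loci ×
  ~8,000 duplex molecules per locus (≈ 9,400 template molecules at 0.85
  bottom-strand capture) × 4 levels × 3 replicates, ≈ 380k read pairs
  per library; parameter-recovery suites use one locus at duplex depth
  2,000–3,000 over 50 seeds.  These reproduce the study's depth regime
  at the level of the target windows themselves.

## Known limitations

* One amplifiable end per molecule; the real protocol can read both
  ends of a fragment and merge their consensus sequences.  Duplex depth
  per input molecule is therefore conservative.
* No germline/background SNP subtraction beyond the replicate filter,
  no structural variants, and no attribution of a detected mutation to
  editing versus natural origin (the PAM-proximity flag
  `pam_proximity()` is an annotation, not a verdict).
* Quality strings are constant; quality-aware consensus would add
  nothing under this error model but matters on real data.
* The identity of an edit under the primer footprint is invisible by
  construction: PCR replaces those bases with the primer oligo.
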