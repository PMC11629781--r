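---
title: "Degenerate-primer mismatch analysis for the miniCOI marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate-primer mismatch analysis for the miniCOI marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicoiscan)
```

## The problem

DNA metabarcoding of marine zooplankton mostly relies on a ~313-bp internal
fragment of the mitochondrial cytochrome oxidase I gene ("miniCOI"), amplified
with degenerate primers. The forward primer region of this fragment is poorly
conserved across zooplankton, and primer–template mismatches — especially near
the primer's 3′ end — suppress or abolish amplification. Two taxa illustrate
the consequences at global scale: the cyclopoid copepod *Oithona similis*,
whose geographically structured haplotype lineages differ in how well they
match the common forward primers, and the Class Appendicularia, where heavy
forward-primer mismatch loads combine with homopolymeric poly-T inserts in the
mitochondrial COI region to make amplification fail outright.

`minicoiscan` implements the full in-silico side of this analysis: IUPAC- and
inosine-aware primer/template matching, binding-site location, per-position
mismatch profiling with amplification-risk classification, haplotype-lineage
grouping with n-weighted summaries, poly-T run detection, and a transcribed
study-outcome dataset summarising reported metabarcoding misperformance across
30 reviewed field studies.

## Matching model

A degenerate primer is a string over the 15 IUPAC codes plus inosine (I). A
primer symbol matches a template symbol iff their sets of concrete bases
intersect:

```{r}
bases_compatible("W", "A")  # W = {A,T}
bases_compatible("Y", "A")  # Y = {C,T}
bases_compatible("R", "G")  # R = {A,G}
```

Two conventions deserve a note:

* **Inosine is universal.** Inosine pairs with all four bases, though with
  unequal duplex stability (I-C > I-A > I-T ≈ I-G). We adopt the conservative
  convention that inosine matches everything; `inosine_policy("ranked")`
  carries the stability ordering as report metadata but never changes a
  verdict. This errs on the side of under-counting mismatches for
  inosine-bearing primers (jgHCO2198, mlCOIintF-XT).
* **Ambiguous templates match anything.** Real reference sequences can carry
  `N` (or other ambiguity codes). Under intersection semantics these match
  every primer symbol; profiles flag such positions `"ambiguous-template"` so
  downstream reports can exclude them. The packaged fixtures contain only
  concrete bases, so this rule affects user-supplied FASTA only. Template
  input is case-folded and `U` is mapped to `T`, since some reference
  sequences derive from cDNA.

The registry ships the five standard miniCOI primers bit-exactly and their
four pairings (Leray-Folmer, Leray-Meyer, Leray-Geller, Leray XT):

```{r}
get_primer("mlCOIintF")
get_primer("mlCOIintF-XT")
```

The Leray XT forward primer allows, at every one of its 26 positions, a
superset of the bases allowed by mlCOIintF — so its mismatch total can never
exceed mlCOIintF's on any template, a monotonicity the test suite checks
against all 283 fixture regions.

## Mismatch profiles and risk classification

`profile_mismatches()` compares a primer (5′→3′, 1-based positions) against a
concrete binding region and records every incompatible position. Position
L−2..L — for the 26-nt forward primers, positions 24–26 — form the 3′-terminal
window; "internal" means everything outside it. The window size defaults to 3
because the empirical literature anchors the elevated risk on the last three
nucleotides, but it is a configurable knob since published studies differ.

`classify_risk()` maps a profile to one of four ordered levels, interpolating
thresholds that mock-community and simulation studies report:

* `failure_likely` — ≥ 4 internal mismatches (simulations find amplification
  prevented in most cases), or ≥ 3 total with a 3′-terminal hit (misdetection
  odds beyond 1/1000);
* `severe` — ≥ 3 mismatches without a terminal hit (13- to >100-fold fewer
  amplifications reported for five to six internal mismatches), or any
  mismatch count with a terminal hit;
* `reduced` — 1–2 internal mismatches (about a 1/10 misdetection);
* `negligible` — none.

The sources these boundaries come from were calibrated on different systems
and do not form a single coherent model; the `rationale` string therefore
always names the rule applied, so users can audit every call. Risk is monotone
in the profile: adding a mismatch never lowers the level (a property test).

`locate_binding_site()` finds the binding window by exhaustive sliding-window
minimisation of the mismatch count; ties break to the leftmost window for
reproducibility. Windows scoring above `max_scan_mismatches` (default 10 for a
26-nt primer) are reported as not found rather than guessed. Reverse primers
are scanned through the reverse complement of the template, so profile
coordinates are always primer coordinates; the complement of inosine is taken
as inosine.

## Lineage analysis

Given a set of full-length binding regions, `find_variable_positions()`
reports the columns with more than one concrete base, and
`group_by_haplotype()` partitions the regions by their tuple of bases at those
positions. Labels are Roman numerals in first-seen input order: the packaged
*O. similis* fixture rows are stored in their documented order, so labels are
stable; for arbitrary input, reordering permutes labels but never counts.
Percent summaries round half-up to the nearest integer (the convention of the
printed tables this package reproduces, e.g. 43/247 → 17%).

```{r}
regs <- fixture_regions("oithona_similis", with_multiplicity = TRUE)
rep <- lineage_report(regs)
rep$variable_positions
rep$summary$per_primer
```

## Poly-T inserts

Appendicularian mitochondrial genomes can carry intron-like homopolymeric
poly-T inserts (coding strand; poly-A on the non-coding strand) that are
excised at the mRNA level. Reported inserts run from tens of nucleotides to
~500 nt (up to ~1500 nt in some species), averaging about 140 nt.
`find_runs()`/`scan_polyT()` detect maximal T-runs above a length floor,
`min_len = 10` by default. The floor is our stated convention, not an
empirically fitted threshold: no published cutoff separates a biological
insert from ordinary AT-rich COI sequence, but reported inserts start at
"tens" of Ts while ordinary COI rarely reaches ten consecutive Ts. The floor
is exposed as a parameter, and raising it can only remove reported runs
(tested monotonicity). An option also scans for poly-A runs when the supplied
strand orientation is unknown.

## Fixtures and the synthetic-data generator

The three packaged fixture tables transcribe published variable-position
states for the miniCOI forward-primer region: 14 *O. similis* lineages with
multiplicities summing to 247 sequences, 21 appendicularian sequences (14
species, with per-sequence poly-T flags), and 15 thaliacean sequences (12
species). Conserved (unlisted) positions are filled with the lexicographically
smallest base in the intersection of both forward primers' allowed sets — an
arbitrary but deterministic choice that provably cannot create a mismatch for
either primer, and the test suite verifies profiles are invariant to any
other valid fill. The printed per-primer mismatch totals travel with the
tables as reference columns; they are used only as an oracle (all 100
row×primer totals are recomputed and compared exactly), never as an input.
Two dataset names (*O. nana* haplotypes, *Microsetella norvegica*) are
reserved but ship no rows: their haplotype bases were never published in
transcribable form.

`synthesize_fasta()` embeds fixture regions in realistic template context:
random flanks, the 26-nt forward region, a 261-nt interior (giving the 313-bp
amplicon), an optional poly-T insert, and an exact complement target of the
chosen reverse primer. Insert lengths are 10 + geometric with mean 140,
truncated at 500 nt — matching the reported size distribution, with the floor
guaranteeing a planted insert is always a detectable run. Random segments are
generated with homopolymer runs capped at 7 nt, so a synthetic record contains
a qualifying poly-T run iff one was planted; this makes the species-flag
reproduction exact for every seed. Everything is deterministic given the
config seed.

What the generator does *not* emulate: sequencing error, indels, within-lineage
variation outside the variable positions, partial primer-region coverage, and
the base composition of real COI flanks. Passing tests on synthetic data
therefore demonstrate the correctness of the algorithms on their intended
inputs, not robustness to noisy real-world FASTA — for real data the locator's
`max_scan_mismatches` guard and the ambiguous-template flags are the relevant
safety rails.

## Metasynthesis dataset

The packaged `study_outcomes.tsv` is a curated transcription of a 30-study
review of miniCOI metabarcoding performance: one record per
study × taxon × basin, with the primer combination used and the outcome
(`fail` = no detection; `bias` = pronounced under-representation; `NA` = not
assessable; `OK` = fair-to-good correspondence). Both focal taxa
(Appendicularians, *O. similis*) are recorded for all 30 studies; other taxa
carry records where misperformance was reported. A study sampling two ocean
basins holds one record per basin, so the loader enforces uniqueness on the
(study, taxon, basin) triple; per-basin tallies count each basin, totals count
distinct studies. Where the review's summary views disagreed internally, the
transcription follows the per-study listing (the packaged table is the
authoritative dataset for this package, and every tally is reproducible from
it by re-filtering).

```{r}
meta_report()$headline
```

## Problem sizes and runtime

All quantitative checks run at desk scale: the 247-sequence lineage fixture,
the 21 + 15 tunicate regions, 500 Monte-Carlo records for the insert-length
distribution, and brute-force expansion oracles restricted to primers with at
most 2^12 concrete expansions. The full suite runs in well under a minute on
one CPU.

## Known limitations

* Risk levels are categorical interpolations of heterogeneous published
  evidence, not a thermodynamic model; no melting-temperature or duplex
  stability computation is attempted.
* The reverse-primer machinery is property-tested (planted sites, coordinate
  mapping) but has no curated fixture: public reference alignments rarely
  cover the reverse-binding region, so no published per-sequence reverse
  totals exist to transcribe.
* p-distances are computed on caller-aligned sequences; the package does not
  align.
* The lineage fixture realises one region per lineage replicated n times;
  statistics that depend only on the variable positions are exact, but the
  fixture is not a substitute for the underlying alignment.
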