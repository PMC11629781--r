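# minicoiscan

In-silico mismatch evaluation of degenerate PCR primers against cytochrome
oxidase I (COI) primer-binding regions, aimed at the ~313-bp "miniCOI"
fragment used in marine zooplankton DNA metabarcoding.

## The problem

MiniCOI metabarcoding depends on degenerate primers — most commonly the
forward primer mlCOIintF (`GGWACWGGWTGAACWGTWTAYCCYCC`) or its
inosine-bearing "Leray XT" variant, paired with one of the HCO2198-family
reverse primers. The forward primer region of COI is poorly conserved across
zooplankton, and primer–template mismatches (especially within the last three
nucleotides of the primer's 3′ end) sharply reduce or abolish amplification.
The practical result is systematic false negatives for globally abundant taxa
such as the copepod *Oithona similis* (whose geographic haplotype lineages
differ in mismatch load) and the Class Appendicularia (heavy mismatch loads
plus homopolymeric poly-T inserts in mitochondrial COI).

`minicoiscan` provides:

* **IUPAC + inosine matching semantics** — a primer symbol matches a template
  symbol iff their base sets intersect; inosine is treated as universal
  (`I → {A,C,G,T}`), with the stability ordering I-C > I-A > I-T ≈ I-G kept
  as metadata only.
* **A bit-exact primer registry** — mlCOIintF, mlCOIintF-XT, HCO2198,
  dgHCO2198, jgHCO2198 and the four standard pairings (Leray-Folmer,
  Leray-Meyer, Leray-Geller, Leray XT).
* **Binding-site location and mismatch profiling** — sliding-window minimum
  mismatch search, per-position profiles in primer coordinates, 3′-terminal
  annotation, and a four-level amplification-risk classification
  (`negligible` / `reduced` / `severe` / `failure_likely`) with an auditable
  rationale per call.
* **Haplotype-lineage analysis** — variable-position detection, grouping by
  the base tuple at those positions, and n-weighted summaries (mismatch
  ranges, terminal-mismatch fractions, per-position counts).
* **Poly-T insert detection** — maximal homopolymer runs above a configurable
  floor (default 10 nt; reported inserts average ~140 nt).
* **A metasynthesis dataset** — a curated transcription of 30 reviewed field
  studies (study × taxon × basin × primer combination × outcome) with the
  tally machinery to reproduce the review's headline counts.
* **Packaged fixtures and a seedable synthetic-FASTA generator** for
  end-to-end and property testing without any downloads.

## Worked example

Profile the worst *O. similis* lineage against the Leray forward primer:

```r
library(minicoiscan)

get_primer("mlCOIintF")
#> forward primer mlCOIintF (26 nt, 7 ambiguities)
#>   5'-GGWACWGGWTGAACWGTWTAYCCYCC-3'

r <- fixture_regions("oithona_similis")[[11]]   # lineage #XI (NE Pacific)
prof <- profile_mismatches(get_primer("mlCOIintF"), r)
prof
#> mlCOIintF vs #XI: 6 mismatch(es) at 3,6,9,12,18,24 [internal 5, 3'-terminal window hit: TRUE]

classify_risk(prof)
#> risk: failure_likely (5 internal mismatches: four or more internal mismatches prevent amplification in most cases)
```

Six mismatches, five of them internal and one at position 24 (the third
nucleotide from the 3′ end): amplification of this lineage with mlCOIintF is
expected to fail — matching the detection failures reported where this
lineage occurs.

The full lineage analysis over the 247-sequence fixture:

```r
rep <- lineage_report(fixture_regions("oithona_similis", with_multiplicity = TRUE))
rep$summary$per_primer
#>         primer min_total max_total lineages_terminal3 sequences_terminal3 pct_sequences_terminal3
#> 1    mlCOIintF         1         6                  5                  43                      17
#> 2 mlCOIintF-XT         0         4                  5                  43                      17
```

Fourteen lineages; mismatch totals range 1–6 for mlCOIintF but 0–4 for the
more degenerate Leray XT primer; five lineages (17% of sequences) carry a
3′-terminal mismatch that affects both primers equally.

A command-line wrapper over the same functions ships at
`inst/cli/minicoi.R`, with subcommands `scan`, `lineages`, `polyt`, `meta`
and `fixtures`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/minicoi.R", package="minicoiscan"))')" \
    scan --fasta input.fasta --out scan.tsv
```

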