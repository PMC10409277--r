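---
title: "Methods: separating heteroplasmy from numt artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating heteroplasmy from numt artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtsieve)
```

## The problem

Heteroplasmy — the coexistence of more than one mitochondrial DNA sequence
within a single plant — should show up as *intra-individual polymorphism*:
reference positions where reads from one individual carry two alleles. The
converse does not hold. Plant mitochondrial genomes (typically 200–500 kbp)
share sequence with the plastid genome and, extensively, with the nuclear
genome. Nuclear insertions of mitochondrial DNA (**numts**) are the nastiest
confounder: a single-copy numt that diverged slightly from its cognate mtDNA
produces low-frequency "variant" reads at exactly the frequencies expected
of real heteroplasmy.

The arithmetic is fixed by the per-cell copy number ratio. In green leaves
the mtDNA:nuDNA ratio *r* is roughly 40:1 to 60:1, so reads from a
single-copy cognate numt make up about

$$\frac{1}{r+1} \approx 1.6\%\text{–}2.4\%$$

of the coverage over the shared interval — squarely inside the 1–10% band
where heteroplasmy screens operate. Worse, numts show strong
presence/absence (P/A) polymorphism between lines of one species, so
masking them against a *single* nuclear reference assembly silently fails
for any numt that assembly happens to lack. This package implements the
whole decision pipeline as testable code and ships a simulator that
reproduces these statistics exactly, so every claim can be exercised
end-to-end without external data.

## Pipeline overview

1. **Homology partition** (`find_local_homologies()`,
   `classify_categories()`, `summarize_partition()`): every mtDNA position
   is scored for three booleans — homology to another mtDNA region, to
   nuclear DNA, to plastid DNA — and encoded as categories 1–8. Category 2
   (no homology anywhere, single copy) is the only safe ground for
   heteroplasmy calling.
2. **Tiling scan** (`tile_reference()`, `scan_tiles()`,
   `merge_positive_tiles()`): 50-bp tiles of the mtDNA reference are tested
   against several nuclear assemblies; the presence/absence matrix across
   columns exposes the reference-dependency of numt detection.
3. **Pileup calling** (`map_reads_lightweight()`, `base_composition()`,
   `call_intraindividual_sites()`, `restrict_to_category()`): per-site base
   compositions are filtered with the two classical thresholds — a variant
   fraction of at least 1% of total coverage *and* at least ~10 supporting
   reads.
4. **Phase analysis** (`extract_window_haplotypes()`, `phase_verdict()`,
   `match_haplotype_to_numt()`): linked variant alleles in the coupling
   phase (all-or-none on each molecule) are what a numt produces; a perfect
   residue match between the variant haplotype and a candidate numt labels
   the sites numt-consistent.
5. **Marker assay** (`extract_amplicon()`, `digest()`,
   `genotype_individual()`, `segregation_test()`): an in-silico PCR–RFLP
   marker genotyped across an F2 settles the question genetically — a
   nuclear (numt) locus segregates 1:2:1, a mitochondrial one does not
   segregate at all.

## The simulator and what it does (not) model

`build_genome_system()` plants three feature kinds into seeded random
genomes: internal mtDNA repeats, plastid blocks copied into the mtDNA, and
numts — cognate mtDNA substrings with explicit substitution edits and
optional internal tandem duplications, written over a nuclear background
shared by all simulated lines. Because lines share one background, two
lines differ only in numt presence/absence and numt alleles, which is the
P/A polymorphism under study. `inject_heteroplasmy()` adds true
heteroplasmic sites, either independent or coupled into one variant
molecule class.

`simulate_reads()` draws paired-end fragments with per-host weights
proportional to *copies × length*; mt:nu and pt:nu copy ratios come from
`sim_config()`. Defaults are 150-bp paired reads, 350 ± 35 bp inserts,
per-base substitution error 0.001, mt:nu = 50:1. Under this model the
nuclear-origin read fraction over a cognate numt interval is exactly
1/(r+1) in expectation, which the test suite verifies at r ∈ {40, 50, 60}
within three binomial standard errors.

Deliberately **not** modelled: realistic Illumina error profiles, GC bias,
PCR duplicates, indel sequencing errors, mapping-quality effects, and
quality-score variation (all bases carry a constant Q37 placeholder;
quality trimming is upstream preprocessing). Passing tests therefore
demonstrate the logic of the pipeline under clean sampling statistics, not
robustness to every artifact of real instruments. Reads wrap the circular
mtDNA origin only when `circular_mt = TRUE` (default off, keeping reported
positions linear).

## Numerical and design choices

* **Homology engine.** k-mer seeding (k = 15, both strands) with ungapped
  extension along each seeded diagonal, trimmed to the maximal-scoring span
  (match +1, mismatch −2). Boundaries are therefore deterministic
  score-maximising ends — reproducible where a human would otherwise judge
  an alignment by eye. Defaults: aligned length ≥ 100 bp, identity ≥ 0.80.
  Gapped homologs appear as hits on neighbouring diagonals; per-position
  classification unions them, so the partition is insensitive to this.
  On self-comparison the trivial identity diagonal is excluded.
* **Tiling scan.** "Every 50-bp query" is read as consecutive
  non-overlapping tiles (step = 50, configurable down to 1). A terminal
  remainder under 20 bp merges into the previous tile; tiny queries would
  otherwise match spuriously. A cell is positive when the best ungapped
  placement covers ≥ 90% of the tile at ≥ 90% identity — both recorded in
  the output attributes, and positivity is monotone in the identity
  threshold by construction.
* **Pileup thresholds.** `min_fraction = 0.01` of *total* coverage
  (including indel evidence) and `min_reads = 10`, applied per allele; a
  site counts once with all qualifying alleles listed. Insertions are
  counted at the anchor position left of the event, deletions at each
  deleted position.
* **Phase rule.** The clone-sequencing evidence behind "coupling" is
  qualitative; here the verdict is quantitative: coupling when ≥ 95% of
  informative sources (spanning ≥ 2 variant positions) are pure all-ref or
  all-variant, repulsion when ≥ 95% are mixed strings, `mixed` otherwise.
  The threshold is configurable.
* **Median rule for numt sizes.** With an even number of intervals the
  default median is the lower middle value, so the statistic is always an
  observed length; `median_rule = "midpoint"` restores the conventional
  average.
* **Exact segregation test.** The goodness-of-fit test is an exact
  multinomial test by full enumeration: the p-value sums the probabilities
  of all outcomes at most as probable as the observed one (relative
  tolerance 1e-7 for floating-point ties), giving p = 1 exactly at the
  modal outcome and a conservative rejection rate under the null (verified
  at ≤ 6% for α = 0.05, n = 16, 10,000 replicates). For the classic F2
  counts (1, 10, 5) against 1:2:1 this construction gives p = 0.221 and
  the chi-square approximation 0.223; a published analysis of the same
  counts reported p = 0.49 from "Fisher's exact test" without stating the
  contingency construction, so that value is recorded here as a comparison
  point and not asserted by any test.
* **Gel-level co-migration.** Fragments within 5% relative length are
  treated as one band when comparing digestion patterns, which is about
  the resolution of a 2% agarose gel.
* **Depth-based plastid flag.** Positions with depth strictly above 10,000
  are flagged; this is reported separately from the alignment-based
  plastid flag and OR-ed only on request, since the two kinds of evidence
  have different failure modes.

## Known reference points

Feeding the published eight-category totals of the sugar beet mtDNA
reference (368,801 bp; `beet_category_totals()`) to
`summarize_partition()` reproduces the survey arithmetic: 76,749 bp
repeated, 292,052 bp single-copy, 256,797 bp (70%) nuclear-homologous,
8,753 bp plastid-homologous, of which 97% also have a nuclear counterpart.
The published prose rounds the unique total to 111,759 bp while the
category totals sum to 111,756 bp; this package always reports the sum of
its own categories, so the 3-bp difference is visible and documented
rather than reproduced. The published 309-bp window allele table
(`beet_window_alleles()`) yields 12 polymorphic positions in
35,559–35,670, 6 of them polymorphic in both lines — both counts are
recomputed from the table, never hard-coded downstream.

## Problem sizes

The test suite and `scripts/acceptance.R` run on desk-scale systems chosen
to make every statistical check well-powered while finishing in seconds:
mitochondrial references of 8–15 kbp, nuclear backgrounds of 16–30 kbp,
mt depths of 500–1500×, and a 1,007-bp planted numt whose 12 edited sites
sit ≥ 160 bp inside the block (reads straddling a numt edge carry nuclear
flanks, fail to map to the mtDNA, and would otherwise starve edge sites of
variant coverage — real polymorphic windows likewise sit inside larger
homologous segments). At 1500× depth a 2% variant allele expects ~30
supporting reads, comfortably above the 10-read floor.

## Limitations

* The mapper is ungapped and single-reference; it is intended for the
  simulator's substitution-only reads. External BAMs from gapped mappers
  are supported through the `file` argument of `base_composition()`.
* The homology engine reports ungapped segments; a numt with a large
  internal rearrangement is seen as several intervals, not one alignment.
* Heteroplasmy inside repeat-, plastid- or nuclear-homologous mtDNA is out
  of scope by design: the pipeline restricts to category 2, exactly
  because nothing reliable can be said elsewhere without line-specific
  assemblies.
* The exact multinomial test enumerates O(n²) outcomes — fine for any F2
  population a human would genotype, not for n in the tens of thousands.
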