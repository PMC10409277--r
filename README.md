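# numtsieve

Tools for a question that sounds easy and is not: when reads from a single
plant show a low-frequency second allele on the mitochondrial genome, is
that **heteroplasmy** (two mtDNA sequences coexisting in the cell) or a
**numt** — a nuclear insertion of mitochondrial DNA whose slightly diverged
copy cross-maps onto the mtDNA reference?

The two explanations are quantitatively confusable. With a per-cell
mtDNA:nuDNA copy ratio of *r*:1 (about 40–60:1 in green leaves), a
single-copy numt identical to its cognate mtDNA interval contributes a
fraction

```
1 / (r + 1)  ≈  2%
```

of the reads over that interval — right in the window where heteroplasmy
screens look. And because numts show strong presence/absence polymorphism
between lines of one species, masking them against a single nuclear
assembly fails silently for every numt that assembly lacks.

`numtsieve` implements the full decision pipeline:

* **Homology partition** — classify every mtDNA position by three booleans
  (self-repeat / nuclear-homologous / plastid-homologous) into categories
  1–8; category 2 (unique, single-copy) is the only safe ground for
  heteroplasmy calling (`find_local_homologies`, `classify_categories`,
  `summarize_partition`, `depth_flag_pt_homology`).
* **50-bp tiling scan** — test every tile of the mtDNA against several
  nuclear assemblies and build the presence/absence matrix that exposes
  reference-dependency of numt detection (`tile_reference`, `scan_tiles`,
  `merge_positive_tiles`, `numt_size_stats`, `classify_solitary_clustered`).
* **Pileup variant extraction** — per-site base composition and the
  two-threshold rule (variant fraction ≥ 1% of total coverage *and* ≥ 10
  supporting reads), restricted to chosen categories
  (`map_reads_lightweight`, `base_composition`,
  `call_intraindividual_sites`, `restrict_to_category`, `shared_sites`).
* **Haplotype phase and numt matching** — coupling/repulsion verdicts from
  reads or clone sequences spanning several variant sites, and residue
  matching of a variant haplotype against a candidate numt
  (`extract_window_haplotypes`, `phase_verdict`, `build_allele_table`,
  `match_haplotype_to_numt`).
* **In-silico PCR–RFLP and F2 segregation** — amplicon extraction,
  restriction digestion, gel-level genotyping, and an exact multinomial
  goodness-of-fit test against 1:2:1 (`extract_amplicon`, `digest`,
  `genotype_individual`, `segregation_test`).
* **A seeded simulator** — genomes with planted repeats, plastid blocks,
  numts and true heteroplasmy, plus copy-ratio-weighted paired-end reads
  with per-read ground truth, so the whole pipeline is testable offline
  (`sim_config`, `feature_plan`, `build_genome_system`,
  `inject_heteroplasmy`, `simulate_reads`).

## Worked example: the reference-dependency trap

Line A carries a 1 kbp numt with ten substitutions relative to its cognate
mtDNA interval; line B does not. Reads come from line A at 1200× mtDNA
depth with mt:nu = 50:1.

```r
library(numtsieve)

cfg <- sim_config(seed = 42, mt_depth = 1200, copy_ratio_mt_nu = 50)
set.seed(42); mt_preview <- random_dna(10000)
edit_pos <- seq(3151, by = 60, length.out = 10)
nxt <- c(A = "C", C = "G", G = "T", T = "A")
edits <- tibble::tibble(
  offset = edit_pos - 3000L,
  alt = unname(nxt[substring(mt_preview, edit_pos, edit_pos)]))

plan <- feature_plan(
  mt_length = 10000, nuclear_length = 20000, lines = c("A", "B"),
  features = list(numt_feature("A", at = 6000, cognate = c(3001, 4000),
                               edits = edits, name = "numt1")))
sys   <- build_genome_system(cfg, plan)
reads <- simulate_reads(sys, "A", cfg)
aln   <- map_reads_lightweight(reads, sys$mt_seq)
sites <- call_intraindividual_sites(base_composition(aln, sys$mt_seq))
sites
#> # A tibble: 10 × 8
#>     pos ref   variant variants count depth fraction class
#>   <int> <chr> <chr>   <chr>    <int> <int>    <dbl> <chr>
#> 1  3151 T     A       A           25  1253   0.0200 SNP
#> 2  3211 G     T       T           33  1276   0.0259 SNP
#> 3  3271 A     C       C           38  1284   0.0296 SNP
#> # ℹ 7 more rows
```

All ten numt-divergent sites come out as "intra-individual polymorphism"
at ~2% — indistinguishable, site by site, from low-level heteroplasmy.
Whether the category-2 filter removes them depends entirely on which
nuclear reference the partition was computed against:

```r
part_A <- classify_categories(10000,
  nu_hits = find_local_homologies(sys$mt_seq, sys$nuclear_seqs$A))
part_B <- classify_categories(10000,
  nu_hits = find_local_homologies(sys$mt_seq, sys$nuclear_seqs$B))
nrow(restrict_to_category(sites, part_A))
#> [1] 0     # numt-bearing reference: all 10 sites masked
nrow(restrict_to_category(sites, part_B))
#> [1] 10    # numt-lacking reference: every site survives, looking heteroplasmic
```

The genetic tiebreaker: a marker on a nuclear numt segregates 1:2:1 in an
F2, a mitochondrial locus does not segregate. For F2 genotype counts of
(1, 10, 5):

```r
segregation_test(c(1, 10, 5))
#> <segregation_result> counts 1:10:5 vs ratio 1:2:1: p = 0.2209 (exact)
```

consistent with nuclear inheritance — i.e. with the numt explanation.

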