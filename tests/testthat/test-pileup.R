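# Build an alignment_set by hand (reference-oriented sequences).
manual_alignments <- function(seqs, pos, reference) {
  n <- length(seqs)
  structure(tibble::tibble(
    qname = sprintf("r%04d/1", seq_len(n)), mapped = TRUE,
    pos = as.integer(pos), strand = "+",
    nmismatch = 0L, seq = seqs),
    reference_length = nchar(reference),
    class = c("alignment_set", class(tibble::tibble())))
}

test_that("error-free reads map back to their truth coordinates", {
  cfg <- sim_config(seed = 61, mt_depth = 60, error_rate = 0)
  sys <- build_genome_system(cfg, feature_plan(4000, 2000))
  reads <- simulate_reads(sys, "A", cfg)
  mt_reads <- reads[reads$host == "mt", ]
  aln <- map_reads_lightweight(mt_reads, sys$mt_seq)
  expect_true(all(aln$mapped))
  truth <- c(rbind(mt_reads$m1_start, mt_reads$m2_start))
  truth1 <- c(mt_reads$m1_start, mt_reads$m2_start)
  expect_identical(aln$pos, truth1)
  expect_true(all(aln$nmismatch == 0))
})

test_that("reads with 1% substitution error map within 2 bp of truth", {
  cfg <- sim_config(seed = 62, mt_depth = 100, error_rate = 0.01)
  sys <- build_genome_system(cfg, feature_plan(4000, 2000))
  reads <- simulate_reads(sys, "A", cfg)
  mt_reads <- reads[reads$host == "mt", ]
  aln <- map_reads_lightweight(mt_reads, sys$mt_seq)
  truth1 <- c(mt_reads$m1_start, mt_reads$m2_start)
  ok <- aln$mapped & abs(aln$pos - truth1) <= 2
  expect_gte(mean(ok), 0.99)
})

test_that("reads from an unrelated sequence stay unmapped", {
  set.seed(63)
  ref <- random_dna(3000)
  other <- random_dna(400)
  reads <- tibble::tibble(id = "x1", mate1 = substr(other, 1, 150),
                          mate2 = revcomp(substr(other, 251, 400)))
  aln <- map_reads_lightweight(reads, ref)
  expect_true(all(!aln$mapped))
})

test_that("base composition counts a constructed 970/30 pileup correctly", {
  set.seed(64)
  ref <- random_dna(400)
  site <- 200L
  ref_base <- substr(ref, site, site)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  start <- site - 100L
  read_ref <- substr(ref, start, start + 149L)
  read_alt <- read_ref
  substr(read_alt, 101, 101) <- alt
  aln <- manual_alignments(c(rep(read_ref, 970), rep(read_alt, 30)),
                           rep(start, 1000), ref)
  comp <- base_composition(aln, ref)
  expect_identical(comp$depth[site], 1000L)
  expect_identical(comp[[alt]][site], 30L)
  expect_identical(comp[[ref_base]][site], 970L)
  sites <- call_intraindividual_sites(comp)
  expect_identical(sites$pos, site)
  expect_identical(sites$variant, alt)
  expect_equal(sites$fraction, 0.03)
})

test_that("both calling thresholds must pass, per allele", {
  set.seed(65)
  ref <- random_dna(300)
  mk_comp <- function(depth, alt_count, site = 150L) {
    ref_base <- substr(ref, site, site)
    alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
    start <- site - 50L
    read_ref <- substr(ref, start, start + 149L)
    read_alt <- read_ref
    substr(read_alt, 101, 101) <- alt
    aln <- manual_alignments(
      c(rep(read_ref, depth - alt_count), rep(read_alt, alt_count)),
      rep(start, depth), ref)
    base_composition(aln, ref)
  }
  called <- call_intraindividual_sites(mk_comp(1000, 15))
  expect_identical(nrow(called), 1L)                 # 1.5%, 15 reads
  expect_identical(nrow(call_intraindividual_sites(mk_comp(1000, 9))), 0L)
  expect_identical(nrow(call_intraindividual_sites(mk_comp(400, 4))), 0L)
  expect_identical(nrow(call_intraindividual_sites(mk_comp(1000, 10))), 1L)
})

test_that("category restriction equals a per-site lookup oracle", {
  set.seed(66)
  part <- classify_categories(
    1000,
    self_hits = tibble::tibble(q_start = 101, q_end = 300),
    nu_hits = tibble::tibble(q_start = c(201, 601), q_end = c(400, 700)))
  sites <- structure(
    tibble::tibble(pos = sort(sample.int(1000, 40)), ref = "A",
                   variant = "C", variants = "C", count = 20L,
                   depth = 1000L, fraction = 0.02, class = "SNP"),
    class = c("polymorphic_sites", class(tibble::tibble())))
  kept <- restrict_to_category(sites, part, categories = 2L)
  oracle_keep <- sites$pos[part$labels[sites$pos] == 2L]
  expect_identical(kept$pos, oracle_keep)
  all2 <- restrict_to_category(sites, part, categories = 1:8)
  expect_identical(all2$pos, sites$pos)
})

test_that("shared sites behave as set intersection, optionally allele-aware", {
  a <- tibble::tibble(pos = c(10L, 20L), variant = c("A", "C"))
  b <- tibble::tibble(pos = c(30L, 40L), variant = c("A", "C"))
  expect_identical(nrow(shared_sites(a, b)), 0L)

  set.seed(67)
  pa <- sort(sample.int(500, 60))
  pb <- sort(sample.int(500, 60))
  sa <- tibble::tibble(pos = pa, variant = sample(c("A", "C"), 60, TRUE))
  sb <- tibble::tibble(pos = pb, variant = sample(c("A", "C"), 60, TRUE))
  expect_identical(shared_sites(sa, sb)$pos, intersect(pa, pb))
  aware <- shared_sites(sa, sb, by_allele = TRUE)
  oracle <- intersect(paste(sa$pos, sa$variant), paste(sb$pos, sb$variant))
  expect_setequal(paste(aware$pos, aware$variants_a), oracle)
})

test_that("clean homology-free data yields no called sites at default thresholds", {
  cfg <- sim_config(seed = 68, mt_depth = 1000, error_rate = 0.001)
  sys <- build_genome_system(cfg, feature_plan(3000, 3000))
  reads <- simulate_reads(sys, "A", cfg)
  aln <- map_reads_lightweight(reads, sys$mt_seq)
  comp <- base_composition(aln, sys$mt_seq)
  sites <- suppressMessages(call_intraindividual_sites(comp))
  expect_identical(nrow(sites), 0L)
})

test_that("SAM input through the file path matches the internal pileup", {
  skip_if_not_installed("Rsamtools")
  set.seed(69)
  ref <- random_dna(300)
  starts <- c(1L, 51L, 101L)
  seqs <- substring(ref, starts, starts + 149L)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:mt\tLN:%d", nchar(ref)),
    sprintf("r%d\t0\tmt\t%d\t60\t150M\t*\t0\t0\t%s\t%s",
            seq_along(starts), starts, seqs, strrep("F", 150))), sam)
  comp_file <- base_composition(reference = ref, file = sam)
  aln <- manual_alignments(seqs, starts, ref)
  comp_int <- base_composition(aln, ref)
  expect_identical(comp_file$depth, comp_int$depth)
  expect_identical(comp_file$A, comp_int$A)
  expect_identical(comp_file$T, comp_int$T)
  expect_error(base_composition(reference = ref, file = sam, chrom = "chr1"),
               "not found")
})
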