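clone_sources <- function(seqs, start = 1L) {
  tibble::tibble(name = sprintf("clone%d", seq_along(seqs)),
                 start = start, seq = seqs)
}

test_that("identical-to-reference sources form a single all-reference class", {
  set.seed(71)
  ref <- random_dna(300)
  pos <- c(50L, 120L, 200L)
  hw <- extract_window_haplotypes(clone_sources(rep(ref, 5)), pos,
                                  ref_alleles = chars(ref)[pos])
  expect_identical(nrow(hw), 5L)
  expect_identical(unique(hw$alleles),
                   paste(chars(ref)[pos], collapse = ""))
  v <- phase_verdict(hw)
  expect_identical(v$verdict, "coupling")
  expect_identical(v$variant_class_share, 0)
})

test_that("two clone classes, reference and all-variant, give a coupling verdict", {
  set.seed(72)
  ref <- random_dna(309)
  pos <- sort(sample(20:290, 12))
  ref_al <- chars(ref)[pos]
  var_seq <- ref
  for (p in pos) {
    substr(var_seq, p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(ref, p, p))[1]
  }
  hw <- extract_window_haplotypes(
    clone_sources(c(rep(ref, 97), rep(var_seq, 3))), pos,
    ref_alleles = ref_al)
  v <- phase_verdict(hw)
  expect_identical(v$verdict, "coupling")
  expect_identical(length(v$classes), 2L)
  expect_equal(v$variant_class_share, 0.03)
})

test_that("variants on opposite molecules give repulsion; mixtures give mixed", {
  ref <- strrep("A", 100)
  mk <- function(alleles_at_2_sites, n) {
    s <- ref
    if (alleles_at_2_sites[1] != "A") substr(s, 10, 10) <- "C"
    if (alleles_at_2_sites[2] != "A") substr(s, 60, 60) <- "G"
    rep(s, n)
  }
  pos <- c(10L, 60L)
  rep50 <- extract_window_haplotypes(
    clone_sources(c(mk(c("C", "A"), 50), mk(c("A", "G"), 50))), pos,
    ref_alleles = c("A", "A"))
  expect_identical(phase_verdict(rep50)$verdict, "repulsion")

  mixed <- extract_window_haplotypes(
    clone_sources(c(mk(c("A", "A"), 60), mk(c("C", "G"), 20),
                    mk(c("C", "A"), 20))), pos,
    ref_alleles = c("A", "A"))
  expect_identical(phase_verdict(mixed)$verdict, "mixed")
})

test_that("a window with no informative sources is an error, not a verdict", {
  ref <- strrep("A", 100)
  hw <- extract_window_haplotypes(
    tibble::tibble(name = "short", start = 1L, seq = strrep("A", 20)),
    positions = c(10L, 60L), ref_alleles = c("A", "A"))
  expect_error(phase_verdict(hw), "informative")
  expect_error(extract_window_haplotypes(clone_sources("ACGT"), 5L),
               "at least two")
})

test_that("coupling is detected in at least 99% of simulated runs with >= 20 spanning reads", {
  verdicts <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 700 + s, mt_depth = 250)
    sys <- build_genome_system(cfg, feature_plan(2500, 2500))
    pos <- seq(1200L, by = 10L, length.out = 8L)
    ref <- substring(sys$mt_seq, pos, pos)
    alt <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                  character(1), USE.NAMES = FALSE)
    sys <- inject_heteroplasmy(sys, data.frame(pos = pos, alt = alt,
                                               freq = 0.05), linked = TRUE)
    reads <- simulate_reads(sys, "A", cfg)
    aln <- map_reads_lightweight(reads, sys$mt_seq)
    hw <- extract_window_haplotypes(aln, pos, ref_alleles = ref)
    if (sum(hw$informative) < 20) return(NA_character_)
    phase_verdict(hw)$verdict
  }, character(1))
  expect_true(all(verdicts == "coupling", na.rm = TRUE))
  expect_gte(sum(!is.na(verdicts)), 8)
})

test_that("the allele table reproduces published cells and a per-cell oracle", {
  # no polymorphism: every row equals the reference row
  set.seed(73)
  ref <- random_dna(100)
  pos <- c(10L, 40L, 80L)
  tab0 <- build_allele_table(
    list(s1 = data.frame(pos = integer(), variant = character())),
    pos, ref)
  expect_identical(unlist(tab0[1, -1]), unlist(tab0[2, -1]))

  # published 309-bp window cells
  sl <- window_site_lists()
  tbl <- beet_window_alleles()
  tab <- build_allele_table(list(nk195 = sl$nk195, nk291 = sl$nk291),
                            tbl$pos, tbl$mt_ref)
  expect_identical(unname(unlist(tab[tab$sample == "nk195", "35578"])), "G/T")
  expect_identical(unname(unlist(tab[tab$sample == "nk291", "35578"])), "G")
  expect_identical(unname(unlist(tab[tab$sample == "nk195", "35559"])), "A/G")
  # every cell matches the published table
  expect_identical(unname(unlist(tab[tab$sample == "nk195", -1])), tbl$nk195)
  expect_identical(unname(unlist(tab[tab$sample == "nk291", -1])), tbl$nk291)

  # randomised oracle: direct per-cell construction
  set.seed(74)
  rpos <- sort(sample.int(100, 6))
  rref <- chars(ref)[rpos]
  hit <- sample(c(TRUE, FALSE), 6, replace = TRUE)
  alt <- vapply(rref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1), USE.NAMES = FALSE)
  st <- data.frame(pos = rpos[hit], variant = alt[hit])
  got <- build_allele_table(list(x = st), rpos, ref)
  oracle <- ifelse(hit, paste0(rref, "/", alt), rref)
  expect_identical(unname(unlist(got[got$sample == "x", -1])), oracle)
})

test_that("variant haplotypes match their cognate numt residues", {
  # synthetic window carrying the published residues
  nr <- beet_numt_residues()
  set.seed(75)
  window_start <- 286700L
  win_len <- 300L
  win <- random_dna(win_len)
  off <- nr$pos - window_start + 1L
  win_ch <- chars(win)
  win_ch[off] <- nr$mt_ref
  win <- paste(win_ch, collapse = "")
  variant_alleles <- sub("^./", "", nr$nk195)

  numt_ch <- win_ch
  numt_ch[off] <- nr$dh1440_numt
  numt <- paste(numt_ch, collapse = "")
  res <- match_haplotype_to_numt(nr$pos, variant_alleles, numt, win,
                                 window_start)
  expect_identical(res$matched, 11L)
  expect_identical(res$total, 11L)
  expect_identical(res$verdict, "numt-consistent")
  expect_identical(res$private_diffs, 0L)

  # numt identical to the reference window: nothing matches the variants
  res0 <- match_haplotype_to_numt(nr$pos, variant_alleles, win, win,
                                  window_start)
  expect_identical(res0$matched, 0L)
  expect_identical(res0$verdict, "heteroplasmy-consistent")

  # three planted mismatches over 12 sites leave 9 matching, and a
  # numt-private insertion is reported without breaking position mapping
  pos12 <- seq(286710L, by = 20L, length.out = 12L)
  off12 <- pos12 - window_start + 1L
  v12 <- vapply(chars(win)[off12],
                function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                character(1), USE.NAMES = FALSE)
  numt_ch2 <- chars(win)
  numt_ch2[off12] <- v12
  numt_ch2[off12[c(2, 5, 9)]] <- chars(win)[off12[c(2, 5, 9)]]
  numt2 <- paste(numt_ch2, collapse = "")
  numt2_ins <- paste0(substr(numt2, 1, 150), "ACGTA",
                      substr(numt2, 151, win_len))
  res2 <- match_haplotype_to_numt(pos12, v12, numt2_ins, win, window_start)
  expect_identical(res2$matched, 9L)
  expect_identical(res2$total, 12L)
  expect_gte(res2$private_diffs, 5L)
})
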