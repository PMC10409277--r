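test_that("tiling covers the reference with the documented remainder rule", {
  t100 <- tile_reference(paste0(strrep("A", 60), strrep("C", 40)))
  expect_identical(nrow(t100), 2L)
  expect_identical(t100$start, c(1L, 51L))
  expect_identical(t100$end, c(50L, 100L))

  set.seed(51)
  t130 <- tile_reference(random_dna(130))
  expect_identical(t130$start, c(1L, 51L, 101L))
  expect_identical(t130$end, c(50L, 100L, 130L))

  # full-scale reference length: 1-bp remainder merges into the last tile
  tbig <- tile_reference(random_dna(368801))
  expect_identical(nrow(tbig), 7376L)
  expect_identical(tbig$start[7376], 368751L)
  expect_identical(tbig$end[7376], 368801L)
  expect_identical(tbig$end[7376] - tbig$start[7376] + 1L, 51L)
  # joint coverage with no gaps
  expect_true(all(tbig$start[-1] == tbig$end[-7376] + 1L))
})

test_that("a subject containing the reference verbatim is positive everywhere", {
  set.seed(52)
  mt <- random_dna(1000)
  subj <- paste0(random_dna(500), mt, random_dna(500))
  tiles <- tile_reference(mt)
  m <- scan_tiles(tiles, c(carrier = subj))
  expect_true(all(m$carrier))
  expect_true(all(m$carrier_identity == 1))
})

test_that("a line-specific numt gives discordant presence/absence columns", {
  cfg <- sim_config(seed = 53)
  edits <- spread_edits(preview_mt(53, 6000), c(2001, 2309), 12)
  plan <- feature_plan(
    mt_length = 6000, nuclear_length = 12000, lines = c("A", "B"),
    features = list(numt_feature("A", at = 4000, cognate = c(2001, 2309),
                                 edits = edits)))
  sys <- build_genome_system(cfg, plan)
  tiles <- tile_reference(sys$mt_seq)
  m <- scan_tiles(tiles, c(A = sys$nuclear_seqs$A, B = sys$nuclear_seqs$B))
  overl <- tiles$start <= 2309 & tiles$end >= 2001
  inside <- tiles$start >= 2001 & tiles$end <= 2309
  expect_true(all(m$A[inside]))       # fully-cognate tiles positive in A
  expect_true(all(!m$B))              # line B carries nothing
  expect_true(all(!m$A[!overl]))      # nothing outside the cognate region
  # reference-dependency: the two columns disagree exactly over the numt
  expect_true(any(m$A != m$B))
})

test_that("positivity is monotone in the identity threshold", {
  cfg <- sim_config(seed = 54)
  plan <- feature_plan(
    mt_length = 3000, nuclear_length = 6000,
    features = list(numt_feature("A", at = 2000, cognate = c(1001, 1400),
                                 n_sub = 20)))
  sys <- build_genome_system(cfg, plan)
  tiles <- tile_reference(sys$mt_seq)
  counts <- vapply(c(0.80, 0.90, 0.95, 1.00), function(thr) {
    m <- scan_tiles(tiles, c(A = sys$nuclear_seqs$A), min_identity = thr)
    sum(m$A)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the matrix is identical whatever the reference column order", {
  cfg <- sim_config(seed = 55)
  plan <- feature_plan(
    mt_length = 2000, nuclear_length = 4000, lines = c("A", "B"),
    features = list(numt_feature("B", at = 1000, cognate = c(501, 900))))
  sys <- build_genome_system(cfg, plan)
  tiles <- tile_reference(sys$mt_seq)
  m1 <- scan_tiles(tiles, c(A = sys$nuclear_seqs$A, B = sys$nuclear_seqs$B))
  m2 <- scan_tiles(tiles, c(B = sys$nuclear_seqs$B, A = sys$nuclear_seqs$A))
  expect_identical(m1$A, m2$A)
  expect_identical(m1$B, m2$B)
})

test_that("positive tiles merge into intervals with the gap rule", {
  base <- tibble::tibble(index = 1:30,
                         start = seq(1L, by = 50L, length.out = 30),
                         end = seq(50L, by = 50L, length.out = 30))
  mk <- function(pos) {
    m <- base
    m$ref <- base$index %in% pos
    structure(m, class = c("pa_matrix", class(m)))
  }
  one <- merge_positive_tiles(mk(5))$ref
  expect_identical(nrow(one), 1L)
  expect_identical(one$length, 50L)

  gap1 <- merge_positive_tiles(mk(c(10:12, 14)), max_gap_tiles = 1)$ref
  expect_identical(nrow(gap1), 1L)
  expect_identical(gap1$start, base$start[10])
  expect_identical(gap1$end, base$end[14])

  two <- merge_positive_tiles(mk(c(10:12, 20)), max_gap_tiles = 1)$ref
  expect_identical(nrow(two), 2L)

  # oracle: run-merge by scanning indices
  set.seed(56)
  for (rep in 1:5) {
    pos <- sort(sample(1:30, 8))
    got <- merge_positive_tiles(mk(pos), max_gap_tiles = 1)$ref
    runs <- split(pos, cumsum(c(1, diff(pos) > 2)))
    expect_identical(nrow(got), length(runs))
    expect_identical(got$start, vapply(runs, function(r) base$start[min(r)],
                                       integer(1), USE.NAMES = FALSE))
  }
})

test_that("numt size statistics use the documented mean/mode/median rules", {
  expect_identical(numt_size_stats(100), list(mean = 100, mode = 100,
                                              median = 100))
  s <- numt_size_stats(c(59, 59, 94, 280, 908))
  expect_identical(s$mean, 280)
  expect_identical(s$mode, 59)
  expect_identical(s$median, 94)
  tie <- numt_size_stats(c(50, 50, 100, 100))
  expect_identical(tie$mode, 50)       # smallest on ties
  expect_identical(tie$median, 50)     # lower-middle rule
  mid <- numt_size_stats(c(50, 50, 100, 100), median_rule = "midpoint")
  expect_identical(mid$median, 75)
  expect_error(numt_size_stats(numeric(0)), "no numt")
})

test_that("solitary vs clustered classification is single-linkage on the gap", {
  one <- classify_solitary_clustered(tibble::tibble(start = 100, end = 200))
  expect_true(one$solitary)

  close2 <- classify_solitary_clustered(
    tibble::tibble(start = c(1000, 3000), end = c(1500, 3400)),
    cluster_gap = 5000)
  expect_identical(unique(close2$cluster_id), 1L)
  expect_true(all(!close2$solitary))

  far2 <- classify_solitary_clustered(
    tibble::tibble(start = c(1000, 51000), end = c(1500, 51400)),
    cluster_gap = 5000)
  expect_identical(far2$cluster_id, c(1L, 2L))
  expect_true(all(far2$solitary))
})

test_that("merged tile intervals agree with the alignment-based nu-homology flags", {
  fx <- ref_dep_fixture()
  tiles <- tile_reference(fx$system$mt_seq)
  m <- scan_tiles(tiles, c(A = fx$system$nuclear_seqs$A))
  merged <- merge_positive_tiles(m)$A
  L <- nchar(fx$system$mt_seq)
  tile_cover <- rep(FALSE, L)
  for (i in seq_len(nrow(merged))) {
    tile_cover[merged$start[i]:merged$end[i]] <- TRUE
  }
  flag_cover <- fx$part_A$labels %in% c(3L, 4L, 7L, 8L)
  expect_gte(sum(tile_cover & flag_cover) / sum(flag_cover), 0.9)
})
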