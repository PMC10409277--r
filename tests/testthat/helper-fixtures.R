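# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# The mt sequence a given seed will produce (it is the builder's first
# random draw), so explicit edits can be designed against it.
preview_mt <- function(seed, len) {
  set.seed(seed)
  random_dna(len)
}

# n substitution edits at evenly spaced interior offsets of a cognate
# interval (edits sit well inside the block, like the well-separated
# sites of a typical polymorphic window).
spread_edits <- function(mt_seq, cognate, n, margin = 14L) {
  len <- cognate[2] - cognate[1] + 1L
  offs <- as.integer(round(seq(margin + 1L, len - margin, length.out = n)))
  ref <- substring(mt_seq, cognate[1] + offs - 1L, cognate[1] + offs - 1L)
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  tibble::tibble(offset = offs, alt = unname(nxt[ref]))
}

# Reference-dependency system: line A carries a 12-substitution numt
# (cognate mt 3001..4007, 1007 bp — the polymorphic sites sit in the
# interior, mirroring how a real polymorphic window lies inside a larger
# homologous segment) that line B lacks; 12 coupled heteroplasmic sites
# at 5% sit far from the numt (9001..9111). Reads from line A at 1500x
# mt depth, mapped, piled up and called.
ref_dep_fixture <- function() fixture("ref_dep", function() {
  cfg <- sim_config(seed = 101, mt_depth = 1500, copy_ratio_mt_nu = 50)
  edits <- spread_edits(preview_mt(101, 15000), c(3001, 4007), 12,
                        margin = 160L)
  plan <- feature_plan(
    mt_length = 15000, nuclear_length = 30000, lines = c("A", "B"),
    pt_length = 0,
    features = list(numt_feature("A", at = 8000, cognate = c(3001, 4007),
                                 edits = edits, name = "numtA")))
  system <- build_genome_system(cfg, plan)
  het_pos <- seq(9001L, by = 10L, length.out = 12L)
  het_ref <- substring(system$mt_seq, het_pos, het_pos)
  het_alt <- vapply(het_ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1), USE.NAMES = FALSE)
  system <- inject_heteroplasmy(
    system, data.frame(pos = het_pos, alt = het_alt, freq = 0.05),
    linked = TRUE)

  reads <- simulate_reads(system, "A", cfg)
  aln <- map_reads_lightweight(reads, system$mt_seq)
  comp <- base_composition(aln, system$mt_seq)
  sites <- suppressMessages(call_intraindividual_sites(comp))

  numt_row <- system$planted_features[
    system$planted_features$name == "numtA" &
      system$planted_features$host == "A", ]
  numt_sites <- numt_row$cognate_start[1] + numt_row$edits[[1]]$offset - 1L

  part_A <- classify_categories(
    nchar(system$mt_seq),
    nu_hits = find_local_homologies(system$mt_seq, system$nuclear_seqs$A))
  part_B <- classify_categories(
    nchar(system$mt_seq),
    nu_hits = find_local_homologies(system$mt_seq, system$nuclear_seqs$B))

  list(cfg = cfg, system = system, reads = reads, aln = aln, comp = comp,
       sites = sites, numt_sites = sort(numt_sites), het_pos = het_pos,
       het_alt = het_alt, part_A = part_A, part_B = part_B)
})

# Copy-ratio system: numt identical to its cognate interval; fraction of
# nuclear-origin reads over the cognate interior measures 1/(r+1).
copy_ratio_fixture <- function(r, depth = 600, seed = 301 + r) {
  fixture(sprintf("copy_ratio_%d_%d", r, depth), function() {
    cfg <- sim_config(seed = seed, mt_depth = depth, copy_ratio_mt_nu = r)
    plan <- feature_plan(
      mt_length = 8000, nuclear_length = 16000, lines = "A", pt_length = 0,
      features = list(numt_feature("A", at = 5000, cognate = c(2001, 3200))))
    system <- build_genome_system(cfg, plan)
    reads <- simulate_reads(system, "A", cfg)
    aln <- map_reads_lightweight(reads, system$mt_seq)
    frac <- nuclear_read_fraction(aln, reads, window = c(2151, 3050))
    list(system = system, reads = reads, aln = aln, frac = frac)
  })
}

# Deterministic allele-table inputs from the published 309-bp window.
window_site_lists <- function() {
  tbl <- beet_window_alleles()
  per_line <- function(col) {
    poly <- grepl("/", tbl[[col]], fixed = TRUE)
    data.frame(pos = tbl$pos[poly],
               ref = tbl$mt_ref[poly],
               variant = sub("^./", "", tbl[[col]][poly]))
  }
  list(nk195 = per_line("nk195"), nk291 = per_line("nk291"))
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
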