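#' Map reads to a reference with k-mer seeding
#'
#' A desk-scale single-reference mapper: candidate placements come from
#' exact k-mer seeds taken at regular offsets along each read (both
#' orientations), each candidate is verified by ungapped comparison against
#' the reference, and the placement with the fewest mismatches wins (ties
#' break deterministically to the plus strand, then the smallest position).
#' Reads with no candidate below the mismatch ceiling are reported unmapped.
#' Alignments are ungapped, which matches the simulator's substitution-only
#' error model.
#'
#' @param reads A `read_set` from [simulate_reads()], or a tibble with
#'   columns `id`, `mate1`, `mate2`.
#' @param reference Reference nucleotide string (e.g. the mtDNA reference).
#' @param k Seed length.
#' @param seed_step Offset between successive seeds along a read.
#' @param max_mismatch Maximum mismatches for a placement to count as
#'   mapped; default allows 10% of the read length.
#' @return An `alignment_set` tibble: `qname` (`id/1`, `id/2`), `mapped`,
#'   `pos` (1-based leftmost on the reference), `strand`, `nmismatch`, and
#'   `seq` oriented to the reference strand.
#' @export
map_reads_lightweight <- function(reads, reference, k = 13L, seed_step = 17L,
                                  max_mismatch = NULL) {
  reference <- check_iupac(reference, "reference")
  if (nrow(reads) == 0) {
    return(structure(tibble(qname = character(), mapped = logical(),
                            pos = integer(), strand = character(),
                            nmismatch = integer(), seq = character()),
                     reference_length = nchar(reference),
                     class = c("alignment_set", class(tibble()))))
  }
  rl <- nchar(reads$mate1[1])
  if (rl > nchar(reference)) {
    stop("read length exceeds reference length", call. = FALSE)
  }
  if (is.null(max_mismatch)) max_mismatch <- ceiling(0.1 * rl)

  qname <- c(paste0(reads$id, "/1"), paste0(reads$id, "/2"))
  seqs <- c(reads$mate1, reads$mate2)

  L <- nchar(reference)
  ref_kmer <- tibble(kmer = seq_kmers(reference, k), rpos = seq_len(L - k + 1L))
  ref_raw <- charToRaw(reference)

  offsets <- unique(c(seq.int(1L, rl - k + 1L, by = seed_step), rl - k + 1L))
  cand <- collect_candidates(seqs, offsets, k, ref_kmer)
  cand_rc <- collect_candidates(revcomp(seqs), offsets, k, ref_kmer)

  score <- function(cand, oriented) {
    if (nrow(cand) == 0) return(cand)
    ok <- cand$pos >= 1L & cand$pos + rl - 1L <= L
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) return(cand)
    cand$nmismatch <- vapply(seq_len(nrow(cand)), function(i) {
      r <- charToRaw(oriented[cand$read[i]])
      sum(r != ref_raw[cand$pos[i]:(cand$pos[i] + rl - 1L)])
    }, integer(1))
    cand
  }
  cand <- score(cand, seqs)
  cand_rc <- score(cand_rc, revcomp(seqs))
  cand$strand <- rep("+", nrow(cand))
  cand_rc$strand <- rep("-", nrow(cand_rc))
  all_cand <- bind_rows(cand, cand_rc)

  res <- tibble(qname = qname, mapped = FALSE, pos = NA_integer_,
                strand = NA_character_, nmismatch = NA_integer_,
                seq = seqs)
  if (nrow(all_cand)) {
    all_cand <- all_cand[all_cand$nmismatch <= max_mismatch, , drop = FALSE]
    if (nrow(all_cand)) {
      ord <- order(all_cand$read, all_cand$nmismatch,
                   all_cand$strand, all_cand$pos)
      all_cand <- all_cand[ord, , drop = FALSE]
      best <- all_cand[!duplicated(all_cand$read), , drop = FALSE]
      res$mapped[best$read] <- TRUE
      res$pos[best$read] <- best$pos
      res$strand[best$read] <- best$strand
      res$nmismatch[best$read] <- best$nmismatch
      minus <- best$read[best$strand == "-"]
      res$seq[minus] <- revcomp(res$seq[minus])
    }
  }
  structure(res, reference_length = L,
            class = c("alignment_set", class(res)))
}

# Join read seeds against the reference k-mer index; returns unique
# (read, pos) candidate placements.
collect_candidates <- function(seqs, offsets, k, ref_kmer) {
  n <- length(seqs)
  seed_tbl <- tibble(
    read = rep(seq_len(n), times = length(offsets)),
    offset = rep(offsets, each = n),
    kmer = unlist(lapply(offsets, function(o) substring(seqs, o, o + k - 1L)),
                  use.names = FALSE))
  hits <- inner_join(seed_tbl, ref_kmer, by = "kmer",
                     relationship = "many-to-many")
  if (nrow(hits) == 0) {
    return(tibble(read = integer(), pos = integer()))
  }
  hits$pos <- hits$rpos - hits$offset + 1L
  distinct(hits[, c("read", "pos")])
}

#' Fraction of nuclear-origin reads over a reference window
#'
#' Among mapped mates overlapping `window` on the reference, the fraction
#' whose simulated truth origin is not the mitochondrial genome. With a
#' numt identical to its cognate mtDNA interval and a copy ratio of r:1,
#' this fraction is expected to be 1/(r+1) over the cognate window.
#'
#' @param alignments An `alignment_set` from [map_reads_lightweight()]
#'   against the mtDNA reference.
#' @param reads The `read_set` the alignments came from (truth source).
#' @param window Length-2 vector, 1-based inclusive reference interval.
#' @return A list with `fraction`, `n_window_reads`, `n_nuclear`.
#' @export
nuclear_read_fraction <- function(alignments, reads, window) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  rl <- attr(reads, "config")$read_len
  aln <- alignments[alignments$mapped, , drop = FALSE]
  ov <- aln$pos <= window[2] & (aln$pos + rl - 1L) >= window[1]
  aln <- aln[ov, , drop = FALSE]
  truth_host <- stats::setNames(reads$host, reads$id)
  ids <- sub("/[12]$", "", aln$qname)
  nuc <- truth_host[ids] != "mt" & truth_host[ids] != "pt"
  list(fraction = if (nrow(aln)) mean(nuc) else NA_real_,
       n_window_reads = nrow(aln), n_nuclear = sum(nuc))
}
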