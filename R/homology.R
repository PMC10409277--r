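#' Find local homologies between two sequences
#'
#' A k-mer seed-and-extend local homology search, both strands. Exact
#' k-mer seeds shared by query and subject are grouped by diagonal, runs of
#' nearby seeds are extended without gaps along their diagonal, and each
#' extension is trimmed to its maximal-scoring span (match +1, mismatch
#' `mismatch_score`), so boundaries are the deterministic score-maximising
#' ends rather than a subjective call. Hits shorter than `min_len` or below
#' `min_identity` are dropped. On self-comparison (`query` identical to
#' `subject`) the trivial full-length identity diagonal is excluded, so
#' only genuine internal repeats are reported.
#'
#' Alignments are ungapped; a homolog containing an insertion shows up as
#' hits on neighbouring diagonals, which downstream per-position
#' classification unions anyway.
#'
#' @param query,subject Nucleotide strings (IUPAC alphabet).
#' @param min_len Minimum aligned length in bp (the classical "100 bp or
#'   longer" rule for organellar homology surveys).
#' @param min_identity Minimum identity fraction over the aligned span.
#' @param k Seed k-mer length.
#' @param max_seed_gap Seeds on one diagonal farther apart than this start
#'   separate extensions.
#' @param mismatch_score Score of a mismatch during extension (match = +1).
#' @return A tibble of homology intervals: `q_start`, `q_end`, `subject`
#'   (deparsed subject name), `s_start`, `s_end`, `strand`, `identity`,
#'   `aligned_length`. Coordinates are 1-based inclusive; for minus-strand
#'   hits the subject interval refers to the plus strand of the subject.
#' @export
find_local_homologies <- function(query, subject, min_len = 100,
                                  min_identity = 0.80, k = 15L,
                                  max_seed_gap = 120L, mismatch_score = -2) {
  subject_name <- if (!is.null(names(subject))) names(subject)[1] else "subject"
  query <- check_iupac(query[[1]], "query")
  subject <- check_iupac(subject[[1]], "subject")
  if (nchar(query) == 0 || nchar(subject) == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (min_len < k) stop("min_len must be >= the seed size k", call. = FALSE)
  self_mode <- identical(query, subject)

  hits <- bind_rows(
    diagonal_hits(query, subject, k, "+", self_mode),
    diagonal_hits(query, revcomp(subject), k, "-", FALSE))
  if (nrow(hits) == 0) return(empty_homology(subject_name))

  q_raw <- charToRaw(query)
  s_raw_fwd <- charToRaw(subject)
  s_raw_rev <- charToRaw(revcomp(subject))
  S <- nchar(subject)

  out <- list()
  for (str in unique(hits$strand)) {
    s_raw <- if (str == "+") s_raw_fwd else s_raw_rev
    h <- hits[hits$strand == str, , drop = FALSE]
    for (d in unique(h$diag)) {
      qpos <- sort(h$qpos[h$diag == d])
      # split seed runs separated by more than max_seed_gap
      brk <- c(0L, which(diff(qpos) > max_seed_gap), length(qpos))
      for (b in seq_len(length(brk) - 1L)) {
        run <- qpos[(brk[b] + 1L):brk[b + 1L]]
        iv <- extend_diagonal(q_raw, s_raw, d, min(run), max(run) + k - 1L,
                              mismatch_score)
        if (is.null(iv)) next
        if (iv$len >= min_len && iv$identity >= min_identity) {
          out[[length(out) + 1L]] <-
            c(iv, list(strand = str, diag = d))
        }
      }
    }
  }
  if (!length(out)) return(empty_homology(subject_name))

  res <- tibble(
    q_start = vapply(out, `[[`, integer(1), "q_start"),
    q_end = vapply(out, `[[`, integer(1), "q_end"),
    strand = vapply(out, `[[`, character(1), "strand"),
    diag = vapply(out, `[[`, integer(1), "diag"),
    identity = vapply(out, `[[`, numeric(1), "identity"),
    aligned_length = vapply(out, `[[`, integer(1), "len"))
  res$s_start_raw <- res$q_start + res$diag
  res$s_end_raw <- res$q_end + res$diag
  # map minus-strand coordinates back to the subject plus strand
  res$s_start <- ifelse(res$strand == "+", res$s_start_raw,
                        S - res$s_end_raw + 1L)
  res$s_end <- ifelse(res$strand == "+", res$s_end_raw,
                      S - res$s_start_raw + 1L)
  res$subject <- subject_name
  res <- res[, c("q_start", "q_end", "subject", "s_start", "s_end",
                 "strand", "identity", "aligned_length")]
  res <- distinct(res)
  arrange(res, .data$q_start, .data$q_end, .data$s_start)
}

empty_homology <- function(subject_name) {
  tibble(q_start = integer(), q_end = integer(),
         subject = character(), s_start = integer(), s_end = integer(),
         strand = character(), identity = numeric(),
         aligned_length = integer())
}

# Shared exact k-mers as (qpos, diag) pairs. In self mode the trivial
# diagonal 0 (each k-mer matching itself) is excluded.
diagonal_hits <- function(query, subject, k, strand, self_mode) {
  sk <- seq_kmers(subject, k)
  if (!length(sk)) return(tibble(qpos = integer(), diag = integer(),
                                 strand = character()))
  s_tbl <- tibble(kmer = sk, spos = seq_along(sk))
  qk <- seq_kmers(query, k)
  q_tbl <- tibble(kmer = qk, qpos = seq_along(qk))
  hits <- inner_join(q_tbl, s_tbl, by = "kmer",
                     relationship = "many-to-many")
  if (nrow(hits) == 0) return(tibble(qpos = integer(), diag = integer(),
                                     strand = character()))
  hits$diag <- hits$spos - hits$qpos
  if (self_mode) hits <- hits[hits$diag != 0L, , drop = FALSE]
  tibble(qpos = hits$qpos, diag = hits$diag, strand = strand)
}

# Ungapped extension along one diagonal. The seed anchor [a0, a1] is grown
# over the whole in-bounds diagonal stretch and trimmed to the
# maximal-scoring span containing the anchor.
extend_diagonal <- function(q_raw, s_raw, diag, a0, a1, mismatch_score) {
  Lq <- length(q_raw); Ls <- length(s_raw)
  lo <- max(1L, 1L - diag)
  hi <- min(Lq, Ls - diag)
  if (a0 < lo || a1 > hi) return(NULL)
  m <- q_raw[lo:hi] == s_raw[(lo + diag):(hi + diag)]
  inc <- ifelse(m, 1, mismatch_score)
  ai0 <- a0 - lo + 1L; ai1 <- a1 - lo + 1L
  # best right end: argmax of cumulative score from the anchor start
  cs_r <- cumsum(inc[ai0:length(inc)])
  right <- ai0 + which.max(cs_r) - 1L
  # best left start: argmax of cumulative score running leftwards
  cs_l <- cumsum(rev(inc[1:ai1]))
  left <- ai1 - which.max(cs_l) + 1L
  ident <- mean(m[left:right])
  list(q_start = lo + left - 1L, q_end = lo + right - 1L,
       identity = ident, len = right - left + 1L)
}
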