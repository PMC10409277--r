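#' Extract per-source allele strings over a set of variant positions
#'
#' Works identically for sequencing reads and for cloned (Sanger-style)
#' amplicon sequences: both are just sources with a start coordinate on
#' the reference and a sequence oriented to the reference strand. Each
#' source gets one character per variant position (a gap token `-` where
#' it does not cover the position). Sources spanning fewer than two of
#' the positions are kept in the table but flagged uninformative, and are
#' excluded from phase computation.
#'
#' @param sources An `alignment_set` (mapped rows are used), or a tibble
#'   with columns `name`, `start`, `seq` (reference-oriented).
#' @param positions Sorted variant positions (>= 2) on the reference.
#' @param ref_alleles Optional reference bases at `positions`; taken from
#'   nowhere else, so supply them when a verdict is wanted.
#' @param window Optional length-2 interval; positions outside it are an
#'   error.
#' @return A `haplotype_window`: tibble `source`, `alleles` (string),
#'   `n_covered`, `informative`, with `positions` and `ref_alleles`
#'   attributes.
#' @export
extract_window_haplotypes <- function(sources, positions,
                                      ref_alleles = NULL, window = NULL) {
  positions <- sort(as.integer(positions))
  if (length(positions) < 2) {
    stop("need at least two variant positions", call. = FALSE)
  }
  if (!is.null(window)) {
    if (any(positions < window[1] | positions > window[2])) {
      stop("positions outside the window", call. = FALSE)
    }
  }
  if (inherits(sources, "alignment_set")) {
    sources <- sources[sources$mapped, , drop = FALSE]
    src <- tibble(name = sources$qname, start = sources$pos,
                  seq = sources$seq)
  } else {
    src <- as_tibble(sources)[, c("name", "start", "seq")]
  }
  len <- nchar(src$seq)
  allele_at <- function(p) {
    inside <- src$start <= p & (src$start + len - 1L) >= p
    out <- rep("-", nrow(src))
    out[inside] <- substring(src$seq[inside], p - src$start[inside] + 1L,
                             p - src$start[inside] + 1L)
    out
  }
  mat <- vapply(positions, allele_at, character(nrow(src)))
  if (nrow(src) == 1) mat <- matrix(mat, nrow = 1)
  covered <- rowSums(mat != "-")
  hw <- tibble(source = src$name,
               alleles = apply(mat, 1, paste, collapse = ""),
               n_covered = as.integer(covered),
               informative = covered >= 2)
  structure(hw, positions = positions, ref_alleles = ref_alleles,
            class = c("haplotype_window", class(hw)))
}

#' Decide coupling vs repulsion phase
#'
#' Informative sources are classified by their covered positions:
#' *pure* sources carry the reference allele everywhere or the variant
#' (non-reference) allele everywhere; *mixed* sources carry both. The
#' verdict is `coupling` when at least `coupling_threshold` (default 95%)
#' of informative sources are pure — the signature of variant alleles
#' residing together on one molecule class. It is `repulsion` when at
#' least that share of informative sources are mixed strings (variants
#' never co-occurring on a molecule), and `mixed` otherwise.
#'
#' @param window A `haplotype_window` with reference alleles attached.
#' @param coupling_threshold Fraction of informative sources required.
#' @return A `phase_result`: list with `verdict`, `classes` (haplotype
#'   string counts over informative sources), `n_informative`,
#'   `prop_pure`, `variant_class_share`.
#' @export
phase_verdict <- function(window, coupling_threshold = 0.95) {
  stopifnot(inherits(window, "haplotype_window"))
  ref <- attr(window, "ref_alleles")
  if (is.null(ref)) {
    stop("reference alleles are required for a phase verdict", call. = FALSE)
  }
  inf <- window[window$informative, , drop = FALSE]
  if (nrow(inf) == 0) {
    stop("no informative sources span two or more positions", call. = FALSE)
  }
  positions <- attr(window, "positions")
  chars <- strsplit(inf$alleles, "", fixed = TRUE)
  status <- vapply(chars, function(ch) {
    cov <- ch != "-"
    is_ref <- ch[cov] == ref[cov]
    if (all(is_ref)) "all_ref"
    else if (all(!is_ref)) "all_variant"
    else "mixed"
  }, character(1))
  classes <- sort(table(inf$alleles), decreasing = TRUE)
  prop_pure <- mean(status != "mixed")
  prop_mixed <- mean(status == "mixed")
  verdict <- if (prop_pure >= coupling_threshold) "coupling"
  else if (prop_mixed >= coupling_threshold) "repulsion"
  else "mixed"
  structure(list(verdict = verdict,
                 classes = classes,
                 n_informative = nrow(inf),
                 prop_pure = prop_pure,
                 variant_class_share = mean(status == "all_variant")),
            class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("<phase_result> %s (%d informative sources, %.1f%% pure)\n",
              x$verdict, x$n_informative, 100 * x$prop_pure))
  invisible(x)
}

#' Build an allele table across samples
#'
#' One row for the reference and one per sample; a cell shows `X/Y`
#' (reference allele first) where the sample is intra-individually
#' polymorphic at that position and the single allele otherwise.
#'
#' @param samples Named list of per-sample site tibbles with columns
#'   `pos` and `variant` (or `alt`).
#' @param positions Sorted positions for the table columns.
#' @param reference Reference nucleotide string (alleles are read from
#'   it), or a character vector of reference alleles at `positions`.
#' @return Tibble with `sample` plus one column per position.
#' @export
build_allele_table <- function(samples, positions, reference) {
  positions <- as.integer(positions)
  stopifnot(!is.unsorted(positions))
  ref_alleles <- if (length(reference) == 1 &&
                       nchar(reference) >= max(positions)) {
    substring(reference, positions, positions)
  } else {
    stopifnot(length(reference) == length(positions))
    reference
  }
  rows <- list(tibble(sample = "reference",
                      !!!stats::setNames(as.list(ref_alleles),
                                         as.character(positions))))
  for (nm in names(samples)) {
    s <- as_tibble(samples[[nm]])
    alt_col <- if ("variant" %in% names(s)) "variant" else "alt"
    cell <- ref_alleles
    hit <- match(positions, s$pos)
    has <- !is.na(hit)
    cell[has] <- paste0(ref_alleles[has], "/", s[[alt_col]][hit[has]])
    rows[[nm]] <- tibble(sample = nm,
                         !!!stats::setNames(as.list(cell),
                                            as.character(positions)))
  }
  bind_rows(rows)
}

#' Match a variant haplotype against a candidate numt
#'
#' Aligns the candidate numt sequence to the mtDNA window (global
#' alignment via dynamic programming, so numt-private insertions and
#' deletions are handled), reads off the numt residue standing opposite
#' each variant position, and counts matches to the variant alleles. A
#' perfect score labels the sites numt-consistent: the "variants" are
#' exactly what cross-mapped reads from this numt would produce.
#' Numt-private differences outside the variant positions (the numt's own
#' substitutions and indels) are reported as well; a variant position
#' falling into an alignment gap counts as unmatched and is flagged.
#'
#' @param positions Variant positions (reference coordinates).
#' @param variant_alleles Variant (non-reference) alleles at `positions`.
#' @param numt_seq Candidate numt nucleotide string.
#' @param mt_window_seq mtDNA reference sequence of the window the numt is
#'   cognate to.
#' @param window_start Reference coordinate of `mt_window_seq`'s first
#'   base.
#' @return List: `matched`, `total`, `verdict` (`numt-consistent` when
#'   `matched == total`, else `heteroplasmy-consistent`), `per_site`
#'   tibble (`pos`, `variant`, `numt_residue`, `match`, `in_gap`),
#'   `private_diffs` (numt-vs-reference differences off the variant
#'   positions: substitutions plus inserted/deleted bp).
#' @export
match_haplotype_to_numt <- function(positions, variant_alleles, numt_seq,
                                    mt_window_seq, window_start = 1L) {
  stopifnot(length(positions) == length(variant_alleles))
  numt_seq <- check_iupac(numt_seq, "numt_seq")
  mt_window_seq <- check_iupac(mt_window_seq, "mt_window_seq")
  off <- positions - window_start + 1L
  if (any(off < 1 | off > nchar(mt_window_seq))) {
    stop("variant positions must fall inside the mt window", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(numt_seq),
    subject = Biostrings::DNAString(mt_window_seq),
    type = "global")
  al_numt <- str_chars(as.character(Biostrings::alignedPattern(pa)))
  al_ref <- str_chars(as.character(Biostrings::alignedSubject(pa)))
  # map window offsets to alignment columns
  ref_col <- integer(nchar(mt_window_seq))
  rpos <- 0L
  for (i in seq_along(al_ref)) {
    if (al_ref[i] != "-") {
      rpos <- rpos + 1L
      ref_col[rpos] <- i
    }
  }
  numt_res <- al_numt[ref_col[off]]
  in_gap <- numt_res == "-"
  match_ok <- !in_gap & numt_res == toupper(variant_alleles)
  per_site <- tibble(pos = positions, variant = variant_alleles,
                     numt_residue = numt_res, match = match_ok,
                     in_gap = in_gap)
  off_cols <- ref_col[off]
  other <- setdiff(seq_along(al_ref), off_cols)
  private <- sum(al_numt[other] != al_ref[other])
  list(matched = sum(match_ok), total = length(positions),
       verdict = if (all(match_ok)) "numt-consistent"
                 else "heteroplasmy-consistent",
       per_site = per_site, private_diffs = private)
}
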