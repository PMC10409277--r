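#' Extract PCR amplicons in silico
#'
#' Finds every product a primer pair would amplify from a template: a
#' forward-primer match followed by a downstream match of the reverse
#' complement of the reverse primer, taking the shortest product per
#' forward site. Both template strands are searched (a product found on
#' the minus strand is reported in plus-strand coordinates). Primer
#' matching is exact by default; `max_mismatches` relaxes it for
#' degenerate primers. Absence of a binding site is a result, not an
#' error — it models the "no amplification" outcome of a
#' presence/absence assay.
#'
#' @param template Template nucleotide string.
#' @param fwd,rev Primer sequences, 5'->3', at least 15 nt.
#' @param max_mismatches Mismatches tolerated per primer site.
#' @return An `amplicon_set` tibble: `start`, `end` (1-based inclusive on
#'   the plus strand of the template), `strand`, `length`, `sequence`
#'   (amplicon as sequenced, fwd primer first). Zero rows = no
#'   amplification.
#' @export
extract_amplicon <- function(template, fwd, rev, max_mismatches = 0L) {
  template <- check_iupac(template, "template")
  fwd <- check_iupac(fwd, "forward primer")
  rev <- check_iupac(rev, "reverse primer")
  if (nchar(fwd) < 15 || nchar(rev) < 15) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  find_sites <- function(subject, pattern) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                  Biostrings::DNAString(subject),
                                  max.mismatch = max_mismatches,
                                  with.indels = FALSE)
    Biostrings::start(m)
  }
  products <- function(subject, strand) {
    f_starts <- find_sites(subject, fwd)
    r_starts <- find_sites(subject, revcomp(rev))
    if (!length(f_starts) || !length(r_starts)) return(NULL)
    r_ends <- r_starts + nchar(rev) - 1L
    res <- lapply(f_starts, function(fs) {
      ok <- r_ends[r_ends >= fs + nchar(fwd)]
      if (!length(ok)) return(NULL)
      re <- min(ok)  # shortest product from this forward site
      tibble(p_start = fs, p_end = re, strand = strand,
             sequence = substr(subject, fs, re))
    })
    bind_rows(res)
  }
  L <- nchar(template)
  res <- bind_rows(products(template, "+"),
                   products(revcomp(template), "-"))
  if (is.null(res) || nrow(res) == 0) {
    out <- tibble(start = integer(), end = integer(), strand = character(),
                  length = integer(), sequence = character())
    return(structure(out, class = c("amplicon_set", class(out))))
  }
  res$start <- ifelse(res$strand == "+", res$p_start, L - res$p_end + 1L)
  res$end <- ifelse(res$strand == "+", res$p_end, L - res$p_start + 1L)
  res$length <- res$end - res$start + 1L
  out <- res[, c("start", "end", "strand", "length", "sequence")]
  out <- distinct(arrange(out, .data$start, .data$end))
  structure(out, class = c("amplicon_set", class(out)))
}

#' Digest a sequence with a restriction enzyme motif
#'
#' Returns fragment lengths from the positions of exact motif occurrences
#' (IUPAC degeneracy honoured): n sites give n+1 fragments, ordered along
#' the sequence, always summing to the input length. The cut falls
#' `cut_offset` bases into the motif (default half-way; at gel resolution
#' only the site positions matter, not the within-site offset). Palindromic
#' sites such as Cla I `ATCGAT` need only the plus strand.
#'
#' @param seq Nucleotide string to digest.
#' @param motif Recognition sequence (IUPAC string), e.g. `"ATCGAT"` for
#'   Cla I.
#' @param cut_offset Bases between the motif start and the cut (0 to
#'   motif length).
#' @return Integer vector of fragment lengths (a single element equal to
#'   the input length when the motif never occurs).
#' @export
digest <- function(seq, motif, cut_offset = nchar(motif) %/% 2L) {
  seq <- check_iupac(seq, "seq")
  motif <- check_iupac(motif, "motif")
  stopifnot(cut_offset >= 0, cut_offset <= nchar(motif))
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                Biostrings::DNAString(seq),
                                fixed = FALSE)
  sites <- Biostrings::start(m)
  L <- nchar(seq)
  if (!length(sites)) return(L)
  cuts <- sort(unique(sites + cut_offset - 1L))
  cuts <- cuts[cuts >= 1 & cuts < L]
  if (!length(cuts)) return(L)
  diff(c(0L, cuts, L))
}

#' Genotype an individual from its observed fragment pattern
#'
#' Compares the observed restriction fragment lengths with the two
#' parental allele patterns. A heterozygote shows the union of both
#' patterns; a homozygote shows exactly one. Fragments within
#' `comigration_tol` relative length (default 5%) are treated as
#' co-migrating, modelling agarose gel resolution. A pattern matching
#' neither parent is `unscorable`.
#'
#' @param observed Observed fragment lengths.
#' @param pattern_a,pattern_b Parental fragment patterns (e.g. the cut and
#'   uncut allele of a Cla I site).
#' @param comigration_tol Relative length difference below which two
#'   fragments co-migrate.
#' @return One of `"AA"`, `"AB"`, `"BB"`, `"unscorable"` (A = first
#'   pattern).
#' @export
genotype_individual <- function(observed, pattern_a, pattern_b,
                                comigration_tol = 0.05) {
  stopifnot(length(observed) >= 1)
  if (patterns_equal(pattern_a, pattern_b, comigration_tol)) {
    stop("parental allele patterns are indistinguishable", call. = FALSE)
  }
  union_ab <- merge_comigrating(c(pattern_a, pattern_b), comigration_tol)
  if (patterns_equal(observed, union_ab, comigration_tol)) return("AB")
  if (patterns_equal(observed, pattern_a, comigration_tol)) return("AA")
  if (patterns_equal(observed, pattern_b, comigration_tol)) return("BB")
  "unscorable"
}

comigrate <- function(a, b, tol) abs(a - b) <= tol * pmax(a, b)

# Collapse lengths that would run as one band.
merge_comigrating <- function(lengths, tol) {
  s <- sort(unique(lengths))
  keep <- s[c(TRUE, diff(s) > tol * s[-1])]
  keep
}

# Two band patterns are equal when every band in one has a co-migrating
# band in the other, both ways.
patterns_equal <- function(p, q, tol) {
  p <- merge_comigrating(p, tol); q <- merge_comigrating(q, tol)
  all(vapply(p, function(x) any(comigrate(x, q, tol)), logical(1))) &&
    all(vapply(q, function(x) any(comigrate(x, p, tol)), logical(1)))
}

#' Exact multinomial goodness-of-fit test for segregation ratios
#'
#' Tests observed F2 genotype counts against an expected ratio (default
#' the Mendelian 1:2:1 of a codominant nuclear marker). The exact p-value
#' enumerates every outcome `(a, b, c)` with `a + b + c = n` and sums the
#' multinomial probabilities of outcomes at most as probable as the
#' observed one (with a 1e-7 relative tolerance for floating-point ties),
#' so `p = 1` exactly when the observed outcome is modal. A chi-square
#' approximation (df = 2) is available for comparison. Exact tests on
#' discrete data are conservative: under a true 1:2:1 the rejection rate
#' at alpha = 0.05 stays at or below nominal.
#'
#' @param counts Integer vector of three genotype counts (AA, AB, BB).
#' @param ratio Expected ratio, default `c(1, 2, 1)`.
#' @param method `"exact"` (enumeration) or `"chisq"`.
#' @param alpha Significance level for the reported decision.
#' @return A `segregation_result`: list with `counts`, `ratio`, `p_value`,
#'   `method`, `alpha`, `reject`.
#' @export
segregation_test <- function(counts, ratio = c(1, 2, 1),
                             method = c("exact", "chisq"), alpha = 0.05) {
  method <- match.arg(method)
  counts <- as.integer(counts)
  if (length(counts) != 3 || any(counts < 0)) {
    stop("counts must be three non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("need at least one individual", call. = FALSE)
  prob <- ratio / sum(ratio)
  if (method == "chisq") {
    p <- suppressWarnings(chisq.test(counts, p = prob)$p.value)
  } else {
    grid <- enumerate_trinomial(n)
    lp <- lgamma(n + 1) - lgamma(grid$a + 1) - lgamma(grid$b + 1) -
      lgamma(grid$c + 1) +
      grid$a * log(prob[1]) + grid$b * log(prob[2]) + grid$c * log(prob[3])
    obs_lp <- lp[grid$a == counts[1] & grid$b == counts[2]]
    p <- sum(exp(lp[lp <= obs_lp + 1e-7]))
    p <- min(p, 1)
  }
  structure(list(counts = counts, ratio = ratio, p_value = p,
                 method = method, alpha = alpha, reject = p < alpha),
            class = "segregation_result")
}

enumerate_trinomial <- function(n) {
  a <- rep(0:n, times = n + 1 - 0:n)
  b <- unlist(lapply(0:n, function(x) 0:(n - x)))
  tibble(a = a, b = b, c = n - a - b)
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("<segregation_result> counts %s vs ratio %s: p = %.4g (%s)%s\n",
              paste(x$counts, collapse = ":"),
              paste(x$ratio, collapse = ":"),
              x$p_value, x$method,
              if (x$reject) sprintf(" — reject at alpha %.2g", x$alpha)
              else ""))
  invisible(x)
}
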