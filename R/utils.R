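#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr %>% filter mutate arrange group_by ungroup summarise
#'   bind_rows left_join inner_join select distinct n slice_min
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @importFrom stats rnorm runif rbinom dmultinom rmultinom chisq.test median
#' @importFrom utils write.table head tail
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

BASES <- c("A", "C", "G", "T")

#' Generate a random DNA sequence
#'
#' Draws bases uniformly and independently using the current RNG state.
#' Callers wanting reproducibility set the seed beforehand (the simulation
#' entry points do this from their `sim_config()`).
#'
#' @param n Sequence length in bp.
#' @return A single character string of A/C/G/T.
#' @export
random_dna <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  if (n == 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0) return("")
    comp <- chartr("ACGTUacgtuRYSWKMBDHVNryswkmbdhvn",
                   "TGCAAtgcaaYRSWMKVHDBNyrswmkvhdbn", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reject sequences containing characters outside the IUPAC alphabet.
check_iupac <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"), x)
  if (any(bad)) {
    stop(what, " contains non-IUPAC characters", call. = FALSE)
  }
  x
}

# Split a string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# All k-mers of a string as a character vector (positions 1..L-k+1).
seq_kmers <- function(x, k, step = 1L) {
  L <- nchar(x)
  if (L < k) return(character(0))
  starts <- seq.int(1L, L - k + 1L, by = step)
  substring(x, starts, starts + k - 1L)
}

# Maximal runs of TRUE in a logical vector, as a tibble of start/end.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

# Stamp positions covered by 1-based inclusive intervals into a logical vector.
cover_positions <- function(len, starts, ends) {
  v <- logical(len)
  if (length(starts)) {
    for (i in seq_along(starts)) {
      v[starts[i]:ends[i]] <- TRUE
    }
  }
  v
}
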