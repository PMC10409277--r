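#' Tile a reference into fixed-length query windows
#'
#' Cuts the mtDNA reference into consecutive tiles (default 50 bp,
#' non-overlapping). A terminal remainder shorter than 20 bp is merged into
#' the previous tile (tiny queries match spuriously), so the last tile can
#' be up to `tile_len + 19` bp; remainders of 20 bp or more are kept as
#' their own tile.
#'
#' @param mt_seq Reference nucleotide string.
#' @param tile_len Tile length in bp (>= 20).
#' @param step Step between tile starts; the default equals `tile_len`
#'   (non-overlapping), and can be reduced to 1 for boundary-precise scans.
#' @return Tibble of tiles: `index`, `start`, `end`, `sequence`.
#' @export
tile_reference <- function(mt_seq, tile_len = 50L, step = tile_len) {
  mt_seq <- check_iupac(mt_seq, "mt_seq")
  L <- nchar(mt_seq)
  if (L == 0) stop("empty sequence", call. = FALSE)
  stopifnot(tile_len >= 20, step >= 1)
  starts <- seq.int(1L, L, by = step)
  ends <- pmin(starts + tile_len - 1L, L)
  keep <- starts <= L
  starts <- starts[keep]; ends <- ends[keep]
  n <- length(starts)
  if (n > 1 && (ends[n] - starts[n] + 1L) < 20L) {
    ends[n - 1L] <- ends[n]
    starts <- starts[-n]; ends <- ends[-n]
    n <- n - 1L
  }
  tibble(index = seq_len(n), start = starts, end = ends,
         sequence = substring(mt_seq, starts, ends))
}

#' Scan tiles against nuclear references
#'
#' For every tile x reference cell, the tile is k-mer-seeded against the
#' subject (both strands) and each candidate ungapped placement is scored;
#' the cell is positive when the best placement covers at least `min_cov`
#' of the tile at identity `>= min_identity`. Because positivity is "best
#' identity >= threshold", lowering `min_identity` can only add positives
#' (monotone). Reference columns are processed independently, so the
#' matrix does not depend on their order.
#'
#' @param tiles Tibble from [tile_reference()].
#' @param nuclear_refs Named character vector or list of subject sequences.
#' @param min_identity Identity threshold over the covered span.
#' @param min_cov Minimum fraction of the tile that must be covered.
#' @param k Seed length.
#' @return A `pa_matrix`: tibble with `index`, `start`, `end` and, per
#'   reference, a logical column `<ref>` plus `<ref>_identity` and
#'   `<ref>_subject_start` for the best hit (NA when negative). Thresholds
#'   are stored as attributes.
#' @export
scan_tiles <- function(tiles, nuclear_refs, min_identity = 0.90,
                       min_cov = 0.90, k = 12L) {
  stopifnot(nrow(tiles) > 0, length(nuclear_refs) > 0)
  if (is.null(names(nuclear_refs)) || any(names(nuclear_refs) == "")) {
    stop("nuclear_refs must be named", call. = FALSE)
  }
  out <- tiles[, c("index", "start", "end")]
  for (ref_name in names(nuclear_refs)) {
    best <- best_tile_hits(tiles, nuclear_refs[[ref_name]], k, min_cov)
    pos <- !is.na(best$identity) & best$identity >= min_identity
    out[[ref_name]] <- pos
    out[[paste0(ref_name, "_identity")]] <-
      ifelse(pos, best$identity, NA_real_)
    out[[paste0(ref_name, "_subject_start")]] <-
      ifelse(pos, best$s_start, NA_integer_)
  }
  structure(out, min_identity = min_identity, min_cov = min_cov,
            class = c("pa_matrix", class(out)))
}

# Best ungapped placement per tile on one subject (either strand):
# identity over the covered span, requiring coverage >= min_cov.
best_tile_hits <- function(tiles, subject, k, min_cov) {
  subject <- check_iupac(subject, "subject")
  S <- nchar(subject)
  n <- nrow(tiles)
  res <- tibble(identity = rep(NA_real_, n), s_start = rep(NA_integer_, n))
  subj_raw <- list(`+` = charToRaw(subject), `-` = charToRaw(revcomp(subject)))
  s_tbl <- tibble(kmer = seq_kmers(subject, k), spos = seq_len(max(0L, S - k + 1L)))
  s_tbl_rc <- tibble(kmer = seq_kmers(revcomp(subject), k),
                     spos = seq_len(max(0L, S - k + 1L)))

  for (str in c("+", "-")) {
    idx <- if (str == "+") s_tbl else s_tbl_rc
    if (nrow(idx) == 0) next
    tk <- lapply(seq_len(n), function(i) {
      km <- seq_kmers(tiles$sequence[i], k)
      if (!length(km)) return(NULL)
      tibble(tile = i, toff = seq_along(km), kmer = km)
    })
    tk <- bind_rows(tk)
    if (is.null(tk) || nrow(tk) == 0) next
    hits <- inner_join(tk, idx, by = "kmer", relationship = "many-to-many")
    if (nrow(hits) == 0) next
    hits$place <- hits$spos - hits$toff + 1L
    hits <- distinct(hits[, c("tile", "place")])
    sr <- subj_raw[[str]]
    for (j in seq_len(nrow(hits))) {
      i <- hits$tile[j]
      tl <- nchar(tiles$sequence[i])
      p0 <- hits$place[j]
      lo <- max(1L, p0); hi <- min(S, p0 + tl - 1L)
      covered <- hi - lo + 1L
      if (covered < min_cov * tl) next
      t_raw <- charToRaw(tiles$sequence[i])
      ident <- mean(t_raw[(lo - p0 + 1L):(hi - p0 + 1L)] == sr[lo:hi])
      if (is.na(res$identity[i]) || ident > res$identity[i]) {
        res$identity[i] <- ident
        res$s_start[i] <- if (str == "+") lo else S - hi + 1L
      }
    }
  }
  res
}

#' Merge consecutive positive tiles into numt-homologous intervals
#'
#' Runs of positive tiles for a reference (allowing up to `max_gap_tiles`
#' negative tiles inside a run) are merged into maximal mtDNA intervals.
#'
#' @param matrix A `pa_matrix` from [scan_tiles()].
#' @param max_gap_tiles Number of interior negative tiles tolerated.
#' @return Named list (per reference) of tibbles `start`, `end`,
#'   `n_tiles`, `length`.
#' @export
merge_positive_tiles <- function(matrix, max_gap_tiles = 1L) {
  stopifnot(inherits(matrix, "pa_matrix"))
  refs <- setdiff(names(matrix)[vapply(matrix, is.logical, logical(1))],
                  c("index", "start", "end"))
  out <- list()
  for (ref_name in refs) {
    pos_idx <- which(matrix[[ref_name]])
    if (!length(pos_idx)) {
      out[[ref_name]] <- tibble(start = integer(), end = integer(),
                                n_tiles = integer(), length = integer())
      next
    }
    grp <- cumsum(c(1L, diff(pos_idx) > max_gap_tiles + 1L))
    iv <- lapply(split(pos_idx, grp), function(ii) {
      tibble(start = matrix$start[min(ii)], end = matrix$end[max(ii)],
             n_tiles = length(ii))
    })
    iv <- bind_rows(iv)
    iv$length <- iv$end - iv$start + 1L
    out[[ref_name]] <- iv
  }
  out
}

#' Size statistics of numt intervals
#'
#' Arithmetic mean (rounded to the nearest bp), mode (smallest value on
#' ties) and median of interval lengths. For even counts the default
#' median rule takes the lower of the two middle values (so the statistic
#' is always an observed length); `median_rule = "midpoint"` gives the
#' conventional average instead.
#'
#' @param lengths Numeric vector of interval lengths in bp (non-empty).
#' @param median_rule `"lower"` (default) or `"midpoint"`.
#' @return Named list `mean`, `mode`, `median`.
#' @export
numt_size_stats <- function(lengths, median_rule = c("lower", "midpoint")) {
  median_rule <- match.arg(median_rule)
  if (length(lengths) == 0) {
    stop("no numt intervals: size statistics undefined", call. = FALSE)
  }
  tb <- table(lengths)
  mode_val <- as.numeric(names(tb)[which.max(tb)])  # ties: smallest first
  s <- sort(lengths)
  n <- length(s)
  med <- if (median_rule == "midpoint") median(s) else s[ceiling(n / 2)]
  list(mean = round(mean(lengths)), mode = mode_val, median = med)
}

#' Group numt intervals into clusters or flag them solitary
#'
#' Single-linkage on subject coordinates: intervals whose nearest
#' neighbour lies within `cluster_gap` share a cluster; singleton clusters
#' are flagged solitary. Numts in real assemblies occur both ways —
#' isolated insertions and clusters spanning several kbp.
#'
#' @param intervals Tibble with `start`/`end` on one subject sequence.
#' @param cluster_gap Maximum gap in bp joining two intervals.
#' @return The input with `cluster_id` and `solitary` columns.
#' @export
classify_solitary_clustered <- function(intervals, cluster_gap = 5000L) {
  iv <- arrange(as_tibble(intervals), .data$start)
  n <- nrow(iv)
  if (n == 0) {
    iv$cluster_id <- integer()
    iv$solitary <- logical()
    return(iv)
  }
  gap <- iv$start[-1] - iv$end[-n] - 1L
  iv$cluster_id <- cumsum(c(1L, gap > cluster_gap))
  sizes <- table(iv$cluster_id)
  iv$solitary <- sizes[as.character(iv$cluster_id)] == 1L
  iv
}
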