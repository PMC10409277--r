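#' Classify every mtDNA position into the eight homology categories
#'
#' Each reference position is scored for three booleans — homologous to
#' another region of the mtDNA itself (self-repeat), to nuclear DNA, and to
#' plastid DNA — and the triple is encoded as categories 1–8:
#'
#' | category | self-repeat | nuDNA | ptDNA |
#' |---|---|---|---|
#' | 1 | yes | no | no |
#' | 2 | no | no | no |
#' | 3 | yes | yes | no |
#' | 4 | no | yes | no |
#' | 5 | yes | no | yes |
#' | 6 | no | no | yes |
#' | 7 | yes | yes | yes |
#' | 8 | no | yes | yes |
#'
#' Category 2 ("unique and single-copy") is the safe ground for heteroplasmy
#' screening: a variant there cannot be explained by cross-mapping from a
#' known repeat, numt or plastid block. Overlapping hits within one evidence
#' class are unioned; only the boolean per position matters.
#'
#' @param mt_length Reference length in bp.
#' @param self_hits,nu_hits,pt_hits Homology interval tibbles (as from
#'   [find_local_homologies()]); only `q_start`/`q_end` are used. `NULL` or
#'   zero-row tibbles mean no evidence of that class.
#' @return A `category_partition`: list with `labels` (integer vector of
#'   length `mt_length`), `intervals` (maximal runs of equal category) and
#'   `totals` (named per-category bp).
#' @export
classify_categories <- function(mt_length, self_hits = NULL, nu_hits = NULL,
                                pt_hits = NULL) {
  stopifnot(mt_length >= 1)
  flag <- function(hits) {
    if (is.null(hits) || nrow(hits) == 0) return(logical(mt_length))
    if (any(hits$q_start < 1 | hits$q_end > mt_length |
              hits$q_start > hits$q_end)) {
      stop("homology interval outside [1, mt_length]", call. = FALSE)
    }
    cover_positions(mt_length, hits$q_start, hits$q_end)
  }
  rep_f <- flag(self_hits); nu_f <- flag(nu_hits); pt_f <- flag(pt_hits)
  # truth-table encoding of (self, nu, pt)
  code <- rep_f * 4L + nu_f * 2L + pt_f  # 0..7
  map <- c(`0` = 2L, `1` = 6L, `2` = 4L, `3` = 8L,
           `4` = 1L, `5` = 5L, `6` = 3L, `7` = 7L)
  labels <- unname(map[as.character(code)])

  r <- rle(labels)
  ends <- cumsum(r$lengths)
  intervals <- tibble(start = ends - r$lengths + 1L, end = ends,
                      category = r$values)
  totals <- vapply(1:8, function(cat) sum(labels == cat), integer(1))
  names(totals) <- as.character(1:8)
  structure(list(labels = labels, intervals = intervals, totals = totals),
            class = "category_partition")
}

#' @export
print.category_partition <- function(x, ...) {
  cat("<category_partition> ", length(x$labels), " bp, ",
      nrow(x$intervals), " runs\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' Summarise a category partition
#'
#' Computes the aggregate views of the eight-category partition: repeated
#' bp (categories 1+3+5+7), single-copy bp (2+4+6+8), nuclear-homologous bp
#' (3+4+7+8), plastid-homologous bp (5+6+7+8), unique bp (1+2, no homology
#' to either other genome), plus derived percentages reported to the
#' nearest 1%: nuclear-homologous share of the reference, and the share of
#' plastid-homologous bp that also has a nuclear counterpart (7+8 over
#' 5+6+7+8).
#'
#' @param x A `category_partition`, or a numeric vector of eight
#'   per-category bp totals (in category order 1..8).
#' @return A list: `totals`, `repeated_bp`, `single_copy_bp`,
#'   `nu_homologous_bp`, `pt_homologous_bp`, `unique_bp`, `total_bp`,
#'   `pct_nu_homologous`, `pct_pt_with_nu`.
#' @export
summarize_partition <- function(x) {
  totals <- if (inherits(x, "category_partition")) x$totals else {
    stopifnot(is.numeric(x), length(x) == 8, all(x >= 0))
    stats::setNames(as.numeric(x), as.character(1:8))
  }
  tot <- sum(totals)
  g <- function(cats) sum(totals[as.character(cats)])
  list(
    totals = totals,
    total_bp = tot,
    repeated_bp = g(c(1, 3, 5, 7)),
    single_copy_bp = g(c(2, 4, 6, 8)),
    nu_homologous_bp = g(c(3, 4, 7, 8)),
    pt_homologous_bp = g(c(5, 6, 7, 8)),
    unique_bp = g(c(1, 2)),
    pct_nu_homologous = round(100 * g(c(3, 4, 7, 8)) / tot),
    pct_pt_with_nu = if (g(c(5, 6, 7, 8)) > 0) {
      round(100 * g(c(7, 8)) / g(c(5, 6, 7, 8)))
    } else NA_real_)
}

#' Flag plastid-homologous regions by read depth
#'
#' Total-cellular-DNA sequencing leaves plastid DNA in huge excess, so
#' mtDNA regions shared with the plastid show extreme coverage. Positions
#' with depth strictly greater than `threshold` (default 10,000) are
#' flagged; maximal runs are returned. This depth-based flag is reported
#' separately from the alignment-based plastid flag — combine them only
#' deliberately.
#'
#' @param depth_track Non-negative per-position read depths over the
#'   reference.
#' @param threshold Strict lower bound; a constant track exactly at the
#'   threshold yields no flags.
#' @return Tibble of `start`/`end` intervals (1-based inclusive).
#' @export
depth_flag_pt_homology <- function(depth_track, threshold = 10000) {
  if (any(depth_track < 0)) stop("depths must be >= 0", call. = FALSE)
  logical_runs(depth_track > threshold)
}

#' Export a category partition as BED
#'
#' One record per maximal run of equal category; BED is 0-based half-open,
#' so a run `start..end` (1-based inclusive) becomes `start-1`, `end`.
#'
#' @param partition A `category_partition`.
#' @param path Output path.
#' @param chrom Chromosome name for column 1.
#' @return Invisibly, `path`.
#' @export
write_partition_bed <- function(partition, path, chrom = "mt") {
  iv <- partition$intervals
  bed <- data.frame(chrom = chrom, start = iv$start - 1L, end = iv$end,
                    name = paste0("category", iv$category))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
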