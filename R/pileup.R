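#' Per-site base composition from alignments
#'
#' Counts A/C/G/T (plus insertion and deletion evidence) over every
#' reference position covered by mapped reads. Internal alignments from
#' [map_reads_lightweight()] are ungapped, so their indel counts are zero;
#' a SAM/BAM path (see `file`) picks up indel evidence from gapped external
#' mappers, with insertions counted at the anchor position left of the
#' event and deletions at each deleted position.
#'
#' @param alignments An `alignment_set`, or `NULL` when reading from
#'   `file`.
#' @param reference The reference nucleotide string the alignments were
#'   made against.
#' @param file Optional path to a SAM or BAM file (requires the Rsamtools
#'   package); the file's reference name must match `chrom`.
#' @param chrom Reference sequence name expected in `file` headers.
#' @return A `site_composition` tibble: `pos`, `ref`, `A`, `C`, `G`, `T`,
#'   `ins`, `del`, `depth` for positions 1..reference length.
#' @export
base_composition <- function(alignments = NULL, reference, file = NULL,
                             chrom = "mt") {
  reference <- check_iupac(reference, "reference")
  L <- nchar(reference)
  if (!is.null(file)) {
    return(base_composition_file(file, reference, chrom))
  }
  stopifnot(inherits(alignments, "alignment_set"))
  aln <- alignments[alignments$mapped, , drop = FALSE]
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, BASES))
  if (nrow(aln)) {
    rl <- nchar(aln$seq[1])
    pos <- rep(aln$pos, each = rl) + seq_len(rl) - 1L
    base_raw <- unlist(lapply(aln$seq, charToRaw), use.names = FALSE)
    code <- match(base_raw, charToRaw(paste(BASES, collapse = "")))
    keep <- !is.na(code)
    idx <- (pos[keep] - 1L) * 4L + code[keep]
    tab <- tabulate(idx, nbins = 4L * L)
    counts <- matrix(tab, ncol = 4, byrow = TRUE,
                     dimnames = list(NULL, BASES))
  }
  comp <- tibble(pos = seq_len(L), ref = str_chars(reference),
                 A = counts[, "A"], C = counts[, "C"],
                 G = counts[, "G"], T = counts[, "T"],
                 ins = 0L, del = 0L)
  comp$depth <- comp$A + comp$C + comp$G + comp$T + comp$del
  structure(comp, class = c("site_composition", class(comp)))
}

base_composition_file <- function(file, reference, chrom) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools package", call. = FALSE)
  }
  L <- nchar(reference)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE)
  }
  bf <- Rsamtools::BamFile(file)
  hdr <- Rsamtools::scanBamHeader(bf)$targets
  if (!chrom %in% names(hdr)) {
    stop(sprintf("reference '%s' not found in alignment file header", chrom),
         call. = FALSE)
  }
  if (hdr[[chrom]] != L) {
    stop("alignment file header length disagrees with the reference",
         call. = FALSE)
  }
  pp <- Rsamtools::PileupParam(max_depth = 1e6L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               include_deletions = TRUE,
                               include_insertions = TRUE)
  p <- Rsamtools::pileup(bf, pileupParam = pp)
  comp <- tibble(pos = seq_len(L), ref = str_chars(reference),
                 A = 0L, C = 0L, G = 0L, T = 0L, ins = 0L, del = 0L)
  for (nt in c("A", "C", "G", "T", "-", "+")) {
    sel <- p$nucleotide == nt & as.character(p$seqnames) == chrom
    if (!any(sel)) next
    col <- switch(nt, `-` = "del", `+` = "ins", nt)
    comp[[col]][p$pos[sel]] <- comp[[col]][p$pos[sel]] + p$count[sel]
  }
  comp$depth <- comp$A + comp$C + comp$G + comp$T + comp$del
  structure(comp, class = c("site_composition", class(comp)))
}

#' Extract intra-individual polymorphic sites
#'
#' A site is emitted when some non-reference allele (base, insertion or
#' deletion) reaches both thresholds: a fraction of the total coverage of
#' at least `min_fraction` (the classical 1% rule) and at least
#' `min_reads` supporting reads (minor alleles below ~10 reads are treated
#' as artifacts). Thresholds apply per allele; a site counts once, with
#' every qualifying allele listed and the best-supported one reported as
#' the primary variant. Zero-depth positions are skipped and counted in a
#' message.
#'
#' @param compositions A `site_composition` tibble.
#' @param min_fraction Minimum variant fraction of total depth.
#' @param min_reads Minimum variant read count.
#' @return A `polymorphic_sites` tibble: `pos`, `ref`, `variant` (primary),
#'   `variants` (comma-joined qualifying alleles), `count`, `depth`,
#'   `fraction`, `class` (`SNP` or `indel`).
#' @export
call_intraindividual_sites <- function(compositions, min_fraction = 0.01,
                                       min_reads = 10L) {
  stopifnot(inherits(compositions, "site_composition"))
  comp <- compositions
  zero <- comp$depth == 0
  if (any(zero)) {
    message(sum(zero), " zero-depth site(s) skipped")
    comp <- comp[!zero, , drop = FALSE]
  }
  alleles <- c(BASES, "ins", "del")
  rows <- list()
  cnt <- as.matrix(comp[, alleles])
  for (a in alleles) {
    is_ref <- comp$ref == a
    count <- cnt[, a]
    frac <- count / comp$depth
    hit <- !is_ref & count >= min_reads & frac >= min_fraction
    if (any(hit)) {
      rows[[a]] <- tibble(pos = comp$pos[hit], ref = comp$ref[hit],
                          allele = a, count = count[hit],
                          depth = comp$depth[hit], fraction = frac[hit])
    }
  }
  found <- bind_rows(rows)
  if (is.null(found) || nrow(found) == 0) {
    return(structure(tibble(pos = integer(), ref = character(),
                            variant = character(), variants = character(),
                            count = integer(), depth = integer(),
                            fraction = numeric(), class = character()),
                     class = c("polymorphic_sites", class(tibble()))))
  }
  found <- arrange(found, .data$pos, dplyr::desc(.data$count), .data$allele)
  site <- found %>%
    group_by(.data$pos) %>%
    summarise(ref = .data$ref[1],
              variant = .data$allele[1],
              variants = paste(.data$allele, collapse = ","),
              count = .data$count[1],
              depth = .data$depth[1],
              fraction = .data$fraction[1],
              class = if (.data$allele[1] %in% c("ins", "del")) "indel"
                      else "SNP",
              .groups = "drop")
  structure(site, class = c("polymorphic_sites", class(site)))
}

#' Restrict called sites to chosen partition categories
#'
#' The standard screen keeps category 2 only — unique, single-copy mtDNA
#' with no known nuclear or plastid counterpart — because a variant there
#' cannot be blamed on cross-mapping from an annotated homolog. Whether a
#' site survives this step depends entirely on which nuclear reference the
#' partition was computed against: a numt absent from the chosen assembly
#' leaves its cognate sites in category 2.
#'
#' @param sites A `polymorphic_sites` tibble.
#' @param partition A `category_partition` covering all site positions.
#' @param categories Categories to retain (default 2).
#' @return The filtered sites, with a `category` column added.
#' @export
restrict_to_category <- function(sites, partition, categories = 2L) {
  stopifnot(inherits(partition, "category_partition"))
  if (nrow(sites) == 0) {
    sites$category <- integer(0)
    return(sites)
  }
  if (any(sites$pos > length(partition$labels))) {
    stop("partition does not cover all site positions", call. = FALSE)
  }
  sites$category <- partition$labels[sites$pos]
  sites[sites$category %in% categories, , drop = FALSE]
}

#' Sites shared between two samples
#'
#' Positions called polymorphic in both site lists; with
#' `by_allele = TRUE` a shared position must also share at least one
#' variant allele.
#'
#' @param sites_a,sites_b `polymorphic_sites` tibbles on one reference.
#' @param by_allele Require a common variant allele as well.
#' @return Tibble of shared positions with each sample's variant alleles.
#' @export
shared_sites <- function(sites_a, sites_b, by_allele = FALSE) {
  pick <- function(s) {
    s <- as_tibble(s)
    if (!"variants" %in% names(s)) s$variants <- s$variant
    s[, c("pos", "variants")]
  }
  a <- pick(sites_a)
  b <- pick(sites_b)
  m <- inner_join(a, b, by = "pos", suffix = c("_a", "_b"))
  if (by_allele && nrow(m)) {
    common <- mapply(function(x, y) {
      length(intersect(strsplit(x, ",")[[1]], strsplit(y, ",")[[1]])) > 0
    }, m$variants_a, m$variants_b)
    m <- m[common, , drop = FALSE]
  }
  arrange(m, .data$pos)
}

#' Export called sites as TSV (VCF-like layout)
#'
#' @param sites A `polymorphic_sites` tibble (optionally after
#'   [restrict_to_category()]).
#' @param path Output path.
#' @param chrom Value for the CHROM column.
#' @return Invisibly, `path`.
#' @export
write_sites_tsv <- function(sites, path, chrom = "mt") {
  out <- data.frame(CHROM = rep(chrom, nrow(sites)), POS = sites$pos,
                    REF = sites$ref, ALT = sites$variants,
                    ALT_COUNT = sites$count, DEPTH = sites$depth,
                    FRACTION = signif(sites$fraction, 4),
                    CLASS = sites$class)
  if ("category" %in% names(sites)) out$CATEGORY <- sites$category
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
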