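#' Feature plans for synthetic genome systems
#'
#' A feature plan describes what gets planted into an otherwise random set of
#' genomes: internal mtDNA repeats, plastid-homologous blocks inside the
#' mitochondrial genome, and numts (nuclear insertions of mtDNA) that may be
#' present in some simulated lines and absent from others — the
#' presence/absence (P/A) polymorphism that confounds heteroplasmy detection.
#' All simulated lines share one nuclear background sequence, so two lines
#' can differ only in which numts they carry and in numt allele edits.
#'
#' @param mt_length,pt_length,nuclear_length Lengths in bp of the
#'   mitochondrial, plastid and nuclear background sequences. `pt_length = 0`
#'   omits the plastid entirely.
#' @param lines Character vector of line names; each gets its own nuclear
#'   sequence (common background, line-specific numts).
#' @param features List of feature specs from [numt_feature()],
#'   [mt_repeat_feature()] or [pt_block_feature()].
#' @return A `feature_plan` list.
#' @export
feature_plan <- function(mt_length, nuclear_length, lines = "A",
                         pt_length = 0, features = list()) {
  stopifnot(mt_length > 0, nuclear_length > 0, pt_length >= 0,
            length(lines) >= 1, !anyDuplicated(lines))
  structure(list(mt_length = as.integer(mt_length),
                 pt_length = as.integer(pt_length),
                 nuclear_length = as.integer(nuclear_length),
                 lines = lines, features = features),
            class = "feature_plan")
}

#' Plant a numt in one or more lines
#'
#' The numt sequence is the cognate mtDNA substring with the listed edits
#' applied, written over the shared nuclear background at `at` (overwriting
#' keeps nuclear coordinates identical across lines). Divergence can be
#' given explicitly (`edits`), drawn at random (`n_sub` substitutions at
#' distinct offsets), and/or include an internal tandem duplication
#' (`tandem_dup = c(offset, width)` duplicates the `width` bases ending at
#' `offset`, making the numt `width` bp longer than its cognate interval).
#'
#' @param lines Line name(s) carrying this numt.
#' @param at 1-based start position on the nuclear sequence.
#' @param cognate Length-2 vector: 1-based inclusive mtDNA interval.
#' @param edits Optional tibble with columns `offset` (1-based within the
#'   cognate interval) and `alt` (replacement base).
#' @param n_sub Number of random substitution edits to draw at build time.
#' @param tandem_dup Optional `c(offset, width)` internal duplication.
#' @param name Feature name (defaults to an automatic one).
#' @return A feature spec for [feature_plan()].
#' @export
numt_feature <- function(lines, at, cognate, edits = NULL, n_sub = 0,
                         tandem_dup = NULL, name = NULL) {
  stopifnot(length(cognate) == 2, cognate[2] >= cognate[1], at >= 1)
  structure(list(kind = "numt", lines = lines, at = as.integer(at),
                 cognate = as.integer(cognate), edits = edits,
                 n_sub = as.integer(n_sub), tandem_dup = tandem_dup,
                 name = name),
            class = "feature_spec")
}

#' Plant an internal repeat in the mitochondrial genome
#'
#' Copies the mtDNA segment `src` over the mtDNA at `at`, creating a
#' two-copy repeat (category 1/3/5/7 material in the homology partition).
#'
#' @param src Length-2 vector: source interval on mtDNA.
#' @param at 1-based destination start on mtDNA.
#' @inheritParams numt_feature
#' @export
mt_repeat_feature <- function(src, at, name = NULL) {
  stopifnot(length(src) == 2, src[2] >= src[1], at >= 1)
  structure(list(kind = "mt_repeat", src = as.integer(src),
                 at = as.integer(at), name = name),
            class = "feature_spec")
}

#' Plant a plastid-homologous block inside the mitochondrial genome
#'
#' Copies the plastid segment `pt_interval` over the mtDNA at `mt_at`,
#' emulating promiscuous plastid DNA found in plant mitochondrial genomes.
#'
#' @param pt_interval Length-2 vector: source interval on the plastid.
#' @param mt_at 1-based destination start on mtDNA.
#' @inheritParams numt_feature
#' @export
pt_block_feature <- function(pt_interval, mt_at, name = NULL) {
  stopifnot(length(pt_interval) == 2, pt_interval[2] >= pt_interval[1])
  structure(list(kind = "pt_homolog_in_mt", pt_interval = as.integer(pt_interval),
                 at = as.integer(mt_at), name = name),
            class = "feature_spec")
}

empty_features <- function() {
  tibble(name = character(), kind = character(), host = character(),
         start = integer(), end = integer(),
         cognate_host = character(), cognate_start = integer(),
         cognate_end = integer(), edits = list(),
         het_frequency = numeric(), linked_group = integer())
}

check_feature_overlap <- function(features, host, start, end, name) {
  prior <- features[features$host == host &
                      features$kind != "true_heteroplasmy_site", , drop = FALSE]
  hit <- which(prior$start <= end & prior$end >= start)
  if (length(hit)) {
    stop(sprintf("feature '%s' overlaps feature '%s' on host '%s'",
                 name, prior$name[hit[1]], host), call. = FALSE)
  }
}

apply_edits <- function(seq, edits) {
  # Substitution edits by offset; returns the edited string and the edit
  # table augmented with the reference base that was replaced.
  ch <- str_chars(seq)
  ref <- ch[edits$offset]
  if (any(ref == edits$alt)) {
    stop("edit alt allele equals the reference base at that offset",
         call. = FALSE)
  }
  ch[edits$offset] <- edits$alt
  list(seq = paste(ch, collapse = ""),
       edits = tibble(offset = as.integer(edits$offset), op = "sub",
                      ref = ref, alt = edits$alt))
}

#' Build a genome system from a feature plan
#'
#' Generates random mt/pt/nuclear sequences from the config seed, then plants
#' every feature in plan order. Numt sequences equal their cognate mtDNA
#' substring with the listed edits applied; ground truth for every planted
#' feature is kept on the object (and can be serialised with
#' [write_ground_truth()]).
#'
#' @param config A [sim_config()].
#' @param plan A [feature_plan()].
#' @return A `genome_system` with fields `mt_seq`, `pt_seq`, `nuclear_seqs`
#'   (one per line), `planted_features` (tibble), `circular_mt`.
#' @export
build_genome_system <- function(config, plan) {
  stopifnot(inherits(config, "sim_config"), inherits(plan, "feature_plan"))
  set.seed(config$seed)
  mt <- random_dna(plan$mt_length)
  pt <- random_dna(plan$pt_length)
  bg <- random_dna(plan$nuclear_length)
  nuclear <- stats::setNames(rep(bg, length(plan$lines)), plan$lines)
  features <- empty_features()

  for (i in seq_along(plan$features)) {
    f <- plan$features[[i]]
    stopifnot(inherits(f, "feature_spec"))
    nm <- f$name %||% sprintf("%s_%d", f$kind, i)

    if (f$kind == "mt_repeat") {
      seg <- substr(mt, f$src[1], f$src[2])
      end <- f$at + nchar(seg) - 1L
      if (end > nchar(mt)) stop("mt_repeat destination exceeds mtDNA length")
      check_feature_overlap(features, "mt", f$at, end, nm)
      substr(mt, f$at, end) <- seg
      features <- bind_rows(features, tibble(
        name = nm, kind = "mt_repeat", host = "mt",
        start = f$at, end = end, cognate_host = "mt",
        cognate_start = f$src[1], cognate_end = f$src[2],
        edits = list(NULL), het_frequency = NA_real_,
        linked_group = NA_integer_))

    } else if (f$kind == "pt_homolog_in_mt") {
      if (nchar(pt) == 0) stop("plan has no plastid sequence to copy from")
      seg <- substr(pt, f$pt_interval[1], f$pt_interval[2])
      end <- f$at + nchar(seg) - 1L
      if (end > nchar(mt)) stop("pt block destination exceeds mtDNA length")
      check_feature_overlap(features, "mt", f$at, end, nm)
      substr(mt, f$at, end) <- seg
      features <- bind_rows(features, tibble(
        name = nm, kind = "pt_homolog_in_mt", host = "mt",
        start = f$at, end = end, cognate_host = "pt",
        cognate_start = f$pt_interval[1], cognate_end = f$pt_interval[2],
        edits = list(NULL), het_frequency = NA_real_,
        linked_group = NA_integer_))

    } else if (f$kind == "numt") {
      seg <- substr(mt, f$cognate[1], f$cognate[2])
      edits <- f$edits
      if (is.null(edits) && f$n_sub > 0) {
        offs <- sort(sample.int(nchar(seg), f$n_sub))
        ref <- str_chars(seg)[offs]
        alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1),
                      character(1), USE.NAMES = FALSE)
        edits <- tibble(offset = offs, alt = alt)
      }
      edit_tbl <- NULL
      if (!is.null(edits) && nrow(edits) > 0) {
        ed <- apply_edits(seg, edits)
        seg <- ed$seq
        edit_tbl <- ed$edits
      }
      if (!is.null(f$tandem_dup)) {
        off <- f$tandem_dup[1]; width <- f$tandem_dup[2]
        stopifnot(off >= width, off <= nchar(seg))
        dup <- substr(seg, off - width + 1L, off)
        seg <- paste0(substr(seg, 1, off), dup,
                      substr(seg, off + 1L, nchar(seg)))
        edit_tbl <- bind_rows(edit_tbl, tibble(
          offset = as.integer(off), op = "ins", ref = "", alt = dup))
      }
      end <- f$at + nchar(seg) - 1L
      for (line in f$lines) {
        if (!line %in% names(nuclear)) {
          stop(sprintf("line '%s' is not in the plan", line), call. = FALSE)
        }
        if (end > nchar(nuclear[[line]])) {
          stop("numt destination exceeds nuclear sequence length")
        }
        check_feature_overlap(features[features$host == line, ],
                              line, f$at, end, nm)
        substr(nuclear[[line]], f$at, end) <- seg
        features <- bind_rows(features, tibble(
          name = nm, kind = "numt", host = line,
          start = f$at, end = end, cognate_host = "mt",
          cognate_start = f$cognate[1], cognate_end = f$cognate[2],
          edits = list(edit_tbl), het_frequency = NA_real_,
          linked_group = NA_integer_))
      }
    } else {
      stop("unknown feature kind: ", f$kind)
    }
  }

  structure(list(mt_seq = mt, pt_seq = pt, nuclear_seqs = as.list(nuclear),
                 planted_features = features,
                 circular_mt = config$circular_mt),
            class = "genome_system")
}

#' Inject true heteroplasmy into a genome system
#'
#' Marks mtDNA positions as heteroplasmic: during read simulation, reads of
#' mitochondrial origin carry the alternative allele at each site with the
#' stated frequency. With `linked = TRUE` all sites in the call form one
#' variant molecule class (coupling phase): a simulated mtDNA molecule either
#' carries every alternative allele or none, with the common frequency.
#' With `linked = FALSE` sites segregate independently across molecules.
#'
#' @param system A `genome_system`.
#' @param sites Data frame with columns `pos` (1-based mtDNA position),
#'   `alt` (alternative base) and `freq` (fraction strictly inside (0, 1);
#'   a frequency of 0 is rejected — remove the site instead).
#' @param linked Logical: one coupled molecule class (`TRUE`) or independent
#'   per-site segregation (`FALSE`, default).
#' @return The modified `genome_system`.
#' @export
inject_heteroplasmy <- function(system, sites, linked = FALSE) {
  stopifnot(inherits(system, "genome_system"))
  sites <- as_tibble(sites)
  stopifnot(all(c("pos", "alt", "freq") %in% names(sites)), nrow(sites) > 0)
  if (any(sites$freq <= 0 | sites$freq >= 1)) {
    stop("heteroplasmy frequencies must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  L <- nchar(system$mt_seq)
  if (any(sites$pos < 1 | sites$pos > L)) {
    stop("heteroplasmy position outside the mitochondrial sequence",
         call. = FALSE)
  }
  if (linked && length(unique(sites$freq)) != 1) {
    stop("linked sites must share one frequency", call. = FALSE)
  }
  ref <- substring(system$mt_seq, sites$pos, sites$pos)
  if (any(ref == sites$alt)) {
    stop("alternative allele equals the reference base", call. = FALSE)
  }
  prev <- system$planted_features$linked_group
  gid <- if (linked) max(0L, prev[!is.na(prev)]) + 1L else NA_integer_
  new <- tibble(
    name = sprintf("het_%d", sites$pos), kind = "true_heteroplasmy_site",
    host = "mt", start = as.integer(sites$pos), end = as.integer(sites$pos),
    cognate_host = NA_character_, cognate_start = NA_integer_,
    cognate_end = NA_integer_,
    edits = lapply(seq_len(nrow(sites)), function(i) {
      tibble(offset = 1L, op = "sub", ref = ref[i], alt = sites$alt[i])
    }),
    het_frequency = sites$freq, linked_group = gid)
  system$planted_features <- bind_rows(system$planted_features, new)
  system
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genome_system <- function(x, ...) {
  cat("<genome_system>\n")
  cat(sprintf("  mt %s bp | pt %s bp | %d nuclear line(s): %s (%s bp)\n",
              format(nchar(x$mt_seq), big.mark = ","),
              format(nchar(x$pt_seq), big.mark = ","),
              length(x$nuclear_seqs),
              paste(names(x$nuclear_seqs), collapse = ", "),
              format(nchar(x$nuclear_seqs[[1]]), big.mark = ",")))
  cat(sprintf("  %d planted feature(s): %s\n",
              nrow(x$planted_features),
              paste(unique(x$planted_features$kind), collapse = ", ")))
  invisible(x)
}

#' Write genome FASTA files
#'
#' @param system A `genome_system`.
#' @param dir Output directory (created if needed). Writes `mt.fa`, `pt.fa`
#'   (if a plastid exists) and `nuclear_<line>.fa`.
#' @return Invisibly, the written file paths.
#' @export
write_genome_fasta <- function(system, dir) {
  stopifnot(inherits(system, "genome_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(seqs, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
    path
  }
  paths <- c(paths, w(c(mt = system$mt_seq), file.path(dir, "mt.fa")))
  if (nchar(system$pt_seq) > 0) {
    paths <- c(paths, w(c(pt = system$pt_seq), file.path(dir, "pt.fa")))
  }
  for (line in names(system$nuclear_seqs)) {
    nm <- stats::setNames(system$nuclear_seqs[[line]], line)
    paths <- c(paths, w(nm, file.path(dir, sprintf("nuclear_%s.fa", line))))
  }
  invisible(paths)
}

#' Write the planted-feature ground truth as TSV
#'
#' One row per feature: kind, host, 1-based inclusive coordinates, cognate
#' coordinates, a compact edit string (`offset:op:ref>alt` joined by `;`),
#' heteroplasmy frequency and linkage group.
#'
#' @param system A `genome_system`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(system, path) {
  f <- system$planted_features
  edit_str <- vapply(f$edits, function(e) {
    if (is.null(e) || nrow(e) == 0) return("")
    paste(sprintf("%d:%s:%s>%s", e$offset, e$op, e$ref, e$alt),
          collapse = ";")
  }, character(1))
  out <- data.frame(f[, c("name", "kind", "host", "start", "end",
                          "cognate_host", "cognate_start", "cognate_end")],
                    edits = edit_str,
                    het_frequency = f$het_frequency,
                    linked_group = f$linked_group)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
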