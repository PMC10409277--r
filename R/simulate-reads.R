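#' Simulate copy-ratio-weighted paired-end reads
#'
#' Draws read pairs from the mitochondrial, plastid and one line's nuclear
#' sequence with per-host sampling weights proportional to copies x length,
#' where copies come from the config's per-cell copy ratios (mt:nu = r:1).
#' Under this model a single-copy numt identical to its cognate mtDNA
#' interval contributes a fraction of about 1/(r+1) of the reads over that
#' interval — roughly 2% at the 40–60:1 ratios typical of green leaves.
#'
#' Heteroplasmic sites registered with [inject_heteroplasmy()] are expressed
#' on mitochondrial fragments at their stated frequencies (coupled sites
#' share one molecule-class draw per fragment). Per-base substitution errors
#' are i.i.d. at the configured rate; indel errors are not simulated.
#'
#' @param system A `genome_system`.
#' @param line Which line's nuclear genome to sequence.
#' @param config A [sim_config()]; `config$mt_depth` of 0 gives an empty
#'   read set.
#' @return A `read_set`: a tibble with one row per pair (`id`, `mate1`,
#'   `mate2`, `host`, `strand`, fragment and per-mate 1-based coordinates,
#'   per-mate truth kinds among mt/pt/nuclear/numt-cognate), with the
#'   config and line stored as attributes.
#' @export
simulate_reads <- function(system, line, config) {
  stopifnot(inherits(system, "genome_system"), inherits(config, "sim_config"))
  if (!line %in% names(system$nuclear_seqs)) {
    stop(sprintf("line '%s' not present in the genome system", line),
         call. = FALSE)
  }
  rl <- config$read_len
  set.seed(config$seed)

  hosts <- c("mt", if (nchar(system$pt_seq) > 0) "pt", line)
  host_seq <- c(list(mt = system$mt_seq),
                if (nchar(system$pt_seq) > 0) list(pt = system$pt_seq),
                stats::setNames(list(system$nuclear_seqs[[line]]), line))
  host_len <- vapply(host_seq, nchar, integer(1))
  copies <- c(mt = config$copy_ratio_mt_nu,
              if (nchar(system$pt_seq) > 0) c(pt = config$copy_ratio_pt_nu),
              stats::setNames(1, line))
  w <- copies[hosts] * host_len[hosts]

  n_mt_pairs <- round(config$mt_depth * host_len[["mt"]] / (2 * rl))
  if (n_mt_pairs == 0) {
    return(empty_read_set(line, config))
  }
  n_pairs <- max(1L, round(n_mt_pairs / (w[["mt"]] / sum(w))))

  host <- sample(hosts, n_pairs, replace = TRUE, prob = w)
  len_i <- host_len[host]
  ins <- pmin(pmax(round(rnorm(n_pairs, config$insert_mean,
                               config$insert_sd)), rl), len_i)
  start <- floor(runif(n_pairs) * (len_i - ins + 1)) + 1L
  end <- start + ins - 1L

  frag <- character(n_pairs)
  for (h in hosts) {
    sel <- host == h
    frag[sel] <- substring(host_seq[[h]], start[sel], end[sel])
  }

  frag <- express_heteroplasmy(frag, host, start, end, system)

  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  left <- substring(frag, 1L, rl)
  right_rc <- revcomp(substring(frag, ins - rl + 1L, ins))
  mate1 <- ifelse(strand == "+", left, right_rc)
  mate2 <- ifelse(strand == "+", right_rc, left)
  m1_start <- ifelse(strand == "+", start, end - rl + 1L)
  m2_start <- ifelse(strand == "+", end - rl + 1L, start)

  if (config$error_rate > 0) {
    errs <- apply_sequencing_errors(c(mate1, mate2), config$error_rate)
    mate1 <- errs[seq_len(n_pairs)]
    mate2 <- errs[n_pairs + seq_len(n_pairs)]
  }

  numts <- system$planted_features[system$planted_features$kind == "numt" &
                                     system$planted_features$host == line, ]
  kind_of <- function(st) {
    k <- ifelse(host == "mt", "mt", ifelse(host == "pt", "pt", "nuclear"))
    if (nrow(numts)) {
      nuc <- host == line
      inumt <- rep(FALSE, length(st))
      for (j in seq_len(nrow(numts))) {
        inumt <- inumt | (st <= numts$end[j] & (st + rl - 1L) >= numts$start[j])
      }
      k[nuc & inumt] <- "numt-cognate"
    }
    k
  }

  reads <- tibble(
    id = sprintf("frag%07d", seq_len(n_pairs)),
    mate1 = mate1, mate2 = mate2, host = host, strand = strand,
    frag_start = as.integer(start), frag_end = as.integer(end),
    m1_start = as.integer(m1_start), m1_end = as.integer(m1_start + rl - 1L),
    m2_start = as.integer(m2_start), m2_end = as.integer(m2_start + rl - 1L),
    kind1 = kind_of(m1_start), kind2 = kind_of(m2_start))
  structure(reads, line = line, config = config, class = c("read_set",
                                                           class(reads)))
}

empty_read_set <- function(line, config) {
  structure(tibble(id = character(), mate1 = character(), mate2 = character(),
                   host = character(), strand = character(),
                   frag_start = integer(), frag_end = integer(),
                   m1_start = integer(), m1_end = integer(),
                   m2_start = integer(), m2_end = integer(),
                   kind1 = character(), kind2 = character()),
            line = line, config = config,
            class = c("read_set", class(tibble())))
}

# Express registered heteroplasmic sites on mitochondrial fragments.
express_heteroplasmy <- function(frag, host, start, end, system) {
  het <- system$planted_features[
    system$planted_features$kind == "true_heteroplasmy_site", , drop = FALSE]
  if (nrow(het) == 0) return(frag)
  mt_idx <- which(host == "mt")
  if (!length(mt_idx)) return(frag)

  apply_site <- function(idx, pos, alt) {
    off <- pos - start[idx] + 1L
    substr(frag[idx], off, off) <<- alt
  }
  groups <- split(seq_len(nrow(het)), ifelse(is.na(het$linked_group),
                                             -seq_len(nrow(het)),
                                             het$linked_group))
  for (g in groups) {
    f <- het$het_frequency[g[1]]
    carrier <- mt_idx[runif(length(mt_idx)) < f]
    for (i in g) {
      pos <- het$start[i]
      alt <- het$edits[[i]]$alt
      covered <- carrier[start[carrier] <= pos & end[carrier] >= pos]
      if (length(covered)) apply_site(covered, pos, alt)
    }
  }
  frag
}

# i.i.d. substitution errors: total error count is Binomial(N, rate) and
# positions are uniform without replacement, which is distributionally
# identical to independent per-base flips.
apply_sequencing_errors <- function(reads, rate) {
  rl <- nchar(reads[1])
  N <- length(reads) * rl
  k <- rbinom(1, N, rate)
  if (k == 0) return(reads)
  pos <- sample.int(N, k)
  ridx <- (pos - 1L) %/% rl + 1L
  off <- (pos - 1L) %% rl + 1L
  for (j in seq_len(k)) {
    cur <- substr(reads[ridx[j]], off[j], off[j])
    substr(reads[ridx[j]], off[j], off[j]) <-
      sample(setdiff(BASES, cur), 1)
  }
  reads
}

#' Write a read set as gzipped paired FASTQ
#'
#' Mate files get `_1.fastq.gz` / `_2.fastq.gz` suffixes and read ids the
#' `/1`, `/2` convention. Base qualities are a constant placeholder (Q37,
#' `F`), since quality trimming is upstream preprocessing outside this
#' package; disable any quality filter when consuming these files.
#'
#' @param reads A `read_set`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_reads <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_set"))
  qual <- strrep("F", attr(reads, "config")$read_len)
  paths <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  for (m in 1:2) {
    seqs <- reads[[paste0("mate", m)]]
    con <- gzfile(paths[m], "wb")
    writeLines(as.vector(rbind(sprintf("@%s/%d", reads$id, m),
                               seqs, "+", rep(qual, length(seqs)))), con)
    close(con)
  }
  invisible(paths)
}
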