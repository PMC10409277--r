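#' Published per-category totals for the sugar beet mtDNA reference
#'
#' The eight-category homology partition of the TK-81mm-O mitochondrial
#' reference (368,801 bp), from the published survey that classified every
#' position by homology to another mtDNA region, to EL10 nuclear DNA and
#' to plastid DNA. Feed these totals to [summarize_partition()] to
#' reproduce the aggregate arithmetic (repeated, single-copy,
#' nuclear-homologous and plastid-homologous bp and the derived
#' percentages).
#'
#' @return Tibble: `category` (1–8), the three homology booleans
#'   (`self_repeat`, `nu_homologous`, `pt_homologous`) and `bp`.
#' @export
beet_category_totals <- function() {
  tibble(
    category = 1:8,
    self_repeat = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    nu_homologous = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    pt_homologous = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    bp = c(14657L, 97099L, 61941L, 186351L, 0L, 248L, 151L, 8354L))
}

#' Published allele table of the 309-bp polymorphic region
#'
#' Nucleotide residues at the 14 intra-individual polymorphic positions
#' inside the 309-bp mtDNA window (reference positions 35,507–35,815)
#' for the TK-81mm-O mtDNA reference and sugar beet lines NK-195BRmm-O
#' and NK-291BRmm-O. Cells with two alleles (`X/Y`, reference first) mark
#' positions where a line's reads showed intra-individual polymorphism.
#' Twelve of the positions fall in 35,559–35,670; the two lines are both
#' polymorphic at six of them.
#'
#' @return Tibble: `pos`, `mt_ref`, `nk195`, `nk291`.
#' @export
beet_window_alleles <- function() {
  tibble(
    pos = c(35559L, 35578L, 35581L, 35595L, 35610L, 35611L, 35613L,
            35615L, 35633L, 35634L, 35653L, 35670L, 35738L, 35776L),
    mt_ref = c("A", "G", "C", "G", "C", "C", "C", "G", "A", "C", "A",
               "G", "G", "G"),
    nk195 = c("A/G", "G/T", "C", "G/A", "C/G", "C/T", "C/T", "G", "A/G",
              "C", "A/T", "G/A", "G/T", "G/T"),
    nk291 = c("A/G", "G", "C/T", "G/A", "C/G", "C", "C/T", "G/A", "A/G",
              "C/T", "A", "G/A", "G/T", "G/T"))
}

#' Published residues at polymorphic sites with a cognate numt
#'
#' Eleven intra-individual polymorphic positions (reference coordinates
#' 286,732–286,944) where line NK-195BRmm-O is polymorphic, NK-291BRmm-O
#' is not, and the variant alleles match the residues of a numt found on
#' a DH1440 scaffold — the signature of numt-derived "heteroplasmy".
#'
#' @return Tibble: `pos`, `mt_ref`, `nk195`, `nk291`, `dh1440_numt`.
#' @export
beet_numt_residues <- function() {
  tibble(
    pos = c(286732L, 286777L, 286781L, 286783L, 286790L, 286796L,
            286816L, 286821L, 286828L, 286903L, 286944L),
    mt_ref = c("G", "G", "G", "A", "C", "G", "G", "G", "T", "G", "T"),
    nk195 = c("G/T", "G/A", "G/C", "A/T", "C/A", "G/T", "G/A", "G/A",
              "T/A", "G/T", "T/A"),
    nk291 = c("G", "G", "G", "A", "C", "G", "G", "G", "T", "G", "T"),
    dh1440_numt = c("T", "A", "C", "T", "A", "T", "A", "A", "A", "T", "A"))
}

#' Positions where an allele-table sample is polymorphic
#'
#' @param alleles A tibble as from [beet_window_alleles()].
#' @param sample Column name of the sample.
#' @return Integer vector of polymorphic positions (cells containing `/`).
#' @export
polymorphic_positions <- function(alleles, sample) {
  alleles$pos[grepl("/", alleles[[sample]], fixed = TRUE)]
}
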