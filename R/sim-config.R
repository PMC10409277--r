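#' Simulation configuration
#'
#' Bundles every knob the genome and read simulator uses, with defaults that
#' mirror the sequencing design the pipeline targets: 150-bp paired-end reads
#' from ~350-bp fragments, and a per-cell copy number ratio of mtDNA to
#' nuclear DNA of about 50:1 (estimates for green leaves range 40:1 to 60:1).
#' Plastid DNA is present in high excess; its ratio only matters when a
#' plastid sequence is part of the simulated system.
#'
#' All randomness downstream (sequence generation, fragment sampling,
#' sequencing error, heteroplasmic allele assignment) is driven by `seed`,
#' so identical configs give bit-identical output.
#'
#' @param seed Integer seed driving every random draw.
#' @param read_len Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size distribution in bp.
#' @param error_rate Per-base substitution error rate, in `[0, 0.1]`.
#'   Substitutions only; indel sequencing errors are not modelled (indels of
#'   interest are planted as genome features instead).
#' @param copy_ratio_mt_nu mtDNA copies per nuclear genome copy (r in r:1).
#' @param copy_ratio_pt_nu ptDNA copies per nuclear genome copy.
#' @param mt_depth Target fold-coverage of the mitochondrial genome.
#' @param circular_mt Should fragments be allowed to wrap the mtDNA origin?
#'   Default `FALSE`: coordinates stay linear, which matches how positions
#'   on the reference are reported.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       read_len = 150L,
                       insert_mean = 350,
                       insert_sd = 35,
                       error_rate = 0.001,
                       copy_ratio_mt_nu = 50,
                       copy_ratio_pt_nu = 200,
                       mt_depth = 500,
                       circular_mt = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must lie in [0, 0.1]", call. = FALSE)
  }
  if (copy_ratio_mt_nu <= 0 || copy_ratio_pt_nu <= 0) {
    stop("copy ratios must be positive", call. = FALSE)
  }
  if (mt_depth < 0) stop("mt_depth must be >= 0", call. = FALSE)
  if (read_len < 20) stop("read_len must be >= 20", call. = FALSE)
  if (insert_mean < read_len) {
    stop("insert_mean must be at least read_len", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed),
         read_len = as.integer(read_len),
         insert_mean = insert_mean,
         insert_sd = insert_sd,
         error_rate = error_rate,
         copy_ratio_mt_nu = copy_ratio_mt_nu,
         copy_ratio_pt_nu = copy_ratio_pt_nu,
         mt_depth = mt_depth,
         circular_mt = isTRUE(circular_mt)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | reads %d bp, insert %g +/- %g bp, error %g\n",
              x$seed, x$read_len, x$insert_mean, x$insert_sd, x$error_rate))
  cat(sprintf("  copy ratios mt:nu = %g:1, pt:nu = %g:1 | mt depth %gx\n",
              x$copy_ratio_mt_nu, x$copy_ratio_pt_nu, x$mt_depth))
  invisible(x)
}
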