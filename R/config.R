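#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline with its default value.
#' The defaults are the standard operating point of the QTL summarisation
#' algorithm: genome-wide significance at `sig_p`, the suggestive tier at
#' `suggestive_p`, SNP grouping within `group_dist_bp` (the LD decay length at
#' r-squared 0.1), locus merging when any cross-locus SNP pair exceeds `ld_r2`
#' and the peaks are closer than `merge_dist_bp`, a minimum of `min_snps`
#' supporting SNPs per QTL, and a single `ext_bp` peak extension for loci short
#' of that support. `fdr_p` is the fixed threshold used when scoring false
#' discovery rates in the spike-in simulations and `simtwo_p` the cutoff of the
#' effect-gradient power simulation.
#'
#' @param sig_p Genome-wide significance p-value cutoff.
#' @param suggestive_p Suggestive p-value cutoff used when extending loci.
#' @param group_dist_bp Maximum gap (bp) between consecutive significant SNPs
#'   grouped into one locus.
#' @param ld_r2 r-squared above which two loci are linked for merging, and
#'   above which a significant SNP counts as tagging a simulated QTN.
#' @param merge_dist_bp Maximum peak-to-peak distance (bp) for merging loci.
#' @param min_snps Minimum supporting SNPs for an emitted QTL.
#' @param ext_bp Half-window (bp) of the single extension applied to loci with
#'   fewer than `min_snps` significant SNPs.
#' @param fdr_p Fixed p-value threshold used for FDR scoring in simulations.
#' @param simtwo_p Significance cutoff of the effect-gradient simulation.
#' @param min_subgroup Minimum samples per genotype class in a conditional
#'   scan.
#' @param max_extensions Number of times the suggestive extension may be
#'   applied (the algorithm default applies it once).
#' @param multiallelic How VCF multiallelic records are handled: `"skip"`
#'   (dropped with a logged count) or `"error"`.
#' @param seed Integer seed recorded alongside results.
#' @param ... Further named values stored verbatim.
#' @return An object of class `hf_config` (a named list).
#' @export
#' @examples
#' cfg <- hf_config()
#' cfg$sig_p
hf_config <- function(sig_p = 1e-6,
                      suggestive_p = 1e-4,
                      group_dist_bp = 800000L,
                      ld_r2 = 0.1,
                      merge_dist_bp = 5000000L,
                      min_snps = 10L,
                      ext_bp = 400000L,
                      fdr_p = 1e-5,
                      simtwo_p = 2.2e-7,
                      min_subgroup = 30L,
                      max_extensions = 1L,
                      multiallelic = c("skip", "error"),
                      seed = 1L,
                      ...) {
  multiallelic <- match.arg(multiallelic)
  cfg <- list(
    sig_p = sig_p, suggestive_p = suggestive_p,
    group_dist_bp = as.integer(group_dist_bp), ld_r2 = ld_r2,
    merge_dist_bp = as.integer(merge_dist_bp), min_snps = as.integer(min_snps),
    ext_bp = as.integer(ext_bp), fdr_p = fdr_p, simtwo_p = simtwo_p,
    min_subgroup = as.integer(min_subgroup),
    max_extensions = as.integer(max_extensions),
    multiallelic = multiallelic, seed = as.integer(seed), ...
  )
  for (nm in c("sig_p", "suggestive_p", "ld_r2", "fdr_p", "simtwo_p")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      hf_stop(sprintf("config '%s' must be a probability in (0, 1)", nm))
    }
  }
  for (nm in c("group_dist_bp", "merge_dist_bp", "ext_bp")) {
    if (cfg[[nm]] <= 0L) hf_stop(sprintf("config '%s' must be positive", nm))
  }
  structure(cfg, class = "hf_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their [hf_config()] defaults; unknown keys
#' are carried along.
#'
#' @param path Path to a YAML key-value file.
#' @return An `hf_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) hf_stop("config file must contain a key-value mapping")
  do.call(hf_config, vals)
}

#' @export
print.hf_config <- function(x, ...) {
  cat("hybridforge analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
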