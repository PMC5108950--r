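# TSV report tables mirroring the standard presentation of COI and SNP
# population-genetic results: per-population diversity, mismatch +
# neutrality, Phi-ST matrix, SNP summary, pairwise FST with CIs.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the standard report tables
#'
#' Emits TSV files into `out_dir` for whichever result components are
#' present in `results`:
#' \describe{
#'   \item{`diversity.tsv`}{per population: `population`, `n`,
#'     `n_haplotypes`, `haplotype_diversity`, `nucleotide_diversity`.}
#'   \item{`mismatch_neutrality.tsv`}{per population: `tau` with bounds,
#'     `theta0`/`theta1` with bounds, `SSD` + p, `raggedness` + p,
#'     `tajimas_D` + p, `fus_Fs` + p.}
#'   \item{`phist.tsv`}{pairwise Phi-ST with raw and BH-adjusted p.}
#'   \item{`snp_summary.tsv`}{per population: `N`, `p`, `Hobs`, `Hexp`,
#'     `pi`, `FIS`.}
#'   \item{`fst_ci.tsv`}{pairwise FST/G'ST/Jost D with CI bounds.}
#' }
#' Empty result components produce header-only files.
#'
#' @param results named list; recognised elements are `diversity`,
#'   `mismatch_neutrality`, `phist`, `snp_summary`, `fst_ci` (each a
#'   data.frame, possibly empty).
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_report_tables <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  templates <- list(
    diversity = c("population", "n", "n_haplotypes", "haplotype_diversity",
                  "nucleotide_diversity"),
    mismatch_neutrality = c("population", "tau", "tau_low", "tau_high",
                            "theta0", "theta0_low", "theta0_high",
                            "theta1", "theta1_low", "theta1_high",
                            "SSD", "p_SSD", "raggedness", "p_raggedness",
                            "tajimas_D", "p_D", "fus_Fs", "p_Fs"),
    phist = c("popA", "popB", "phist", "p", "p_adj", "nperm", "exhaustive"),
    snp_summary = c("population", "N", "p", "Hobs", "Hexp", "pi", "FIS",
                    "n_loci"),
    fst_ci = c("popA", "popB", "statistic", "estimate", "ci_low", "ci_high",
               "significant", "B"))
  files <- character()
  for (nm in names(templates)) {
    df <- results[[nm]]
    if (is.null(df)) {
      df <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(templates[[nm]])), templates[[nm]]))
    } else {
      missing_cols <- setdiff(templates[[nm]], names(df))
      for (mc in missing_cols) df[[mc]] <- NA
      df <- df[, templates[[nm]], drop = FALSE]
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(df, path)
    files <- c(files, path)
  }
  invisible(files)
}
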