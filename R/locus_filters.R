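#' Keep the first SNP per radtag locus
#'
#' RADseq SNPs on the same sequencing locus (radtag) are tightly linked;
#' retaining one SNP per radtag avoids pseudo-replication.  For each
#' radtag only the SNP with the smallest within-radtag position is kept,
#' so the output has one locus per distinct radtag.
#'
#' @param g a [genotype_matrix()] whose loci carry radtag/position ids.
#' @return a filtered [genotype_matrix()].
#' @export
first_snp_per_locus <- function(g) {
  li <- loci_info(g)
  ord <- order(li$radtag, li$pos)
  first <- ord[!duplicated(li$radtag[ord])]
  keep <- sort(first)
  subset_loci(g, keep)
}

#' Drop loci with too many missing genotypes
#'
#' A locus is retained iff its fraction of missing calls
#' (missing / individuals) is at most `max_missing_frac`.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction (default 0.20).
#' @return list with `genotypes` and `report` (a [filter_report()]).
#' @export
filter_missingness <- function(g, max_missing_frac = 0.20) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- colMeans(is.na(unclass(g)))
  keep <- frac <= max_missing_frac
  list(genotypes = subset_loci(g, which(keep)),
       report = filter_report(ncol(g), sum(keep), "missingness",
                              tallies = list(excess_missing = sum(!keep))))
}

#' Drop loci by minor allele frequency
#'
#' Minor allele frequency is computed over non-missing allele copies
#' (2 x genotyped individuals); a locus is retained iff MAF is strictly
#' greater than `maf_threshold`.  Monomorphic loci (MAF = 0) are removed
#' and tallied separately.
#'
#' @param g a [genotype_matrix()].
#' @param maf_threshold frequency threshold (default 0.06; with 33
#'   individuals this removes alleles carried by a single heterozygote,
#'   1/66 = 0.015).
#' @return list with `genotypes` and `report`.
#' @export
filter_maf <- function(g, maf_threshold = 0.06) {
  stopifnot(maf_threshold >= 0, maf_threshold < 0.5)
  m <- unclass(g)
  alt <- colSums(m, na.rm = TRUE)
  copies <- 2L * colSums(!is.na(m))
  p_alt <- ifelse(copies > 0, alt / copies, NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  mono <- !is.na(maf) & maf == 0
  keep <- !is.na(maf) & maf > maf_threshold
  list(genotypes = subset_loci(g, which(keep)),
       report = filter_report(ncol(g), sum(keep), "maf",
                              tallies = list(monomorphic = sum(mono),
                                             low_maf = sum(!keep & !mono))))
}

#' SNP-matrix filter pipeline
#'
#' Applies, in fixed order: first SNP per radtag, missingness, minor
#' allele frequency.  Counts for each step are logged and returned.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing_frac,maf_threshold see [filter_missingness()] and
#'   [filter_maf()].
#' @return list with `genotypes` and `reports` (list of [filter_report()]).
#' @export
snp_filter_pipeline <- function(g, max_missing_frac = 0.20, maf_threshold = 0.06) {
  g1 <- first_snp_per_locus(g)
  rep1 <- filter_report(ncol(g), ncol(g1), "first_snp_per_radtag")
  st2 <- filter_missingness(g1, max_missing_frac)
  st3 <- filter_maf(st2$genotypes, maf_threshold)
  reports <- list(first_snp = rep1, missingness = st2$report, maf = st3$report)
  for (r in reports) message(sprintf("filter %s: %d -> %d loci",
                                     r$rule, r$input, r$retained))
  list(genotypes = st3$genotypes, reports = reports)
}
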