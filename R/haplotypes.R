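#' Collapse aligned sequences into haplotypes
#'
#' Sites containing `N` or `-` in *any* sample are excluded from the
#' comparison (complete deletion); samples identical over the remaining
#' sites share a haplotype.
#'
#' @param aln a [seq_alignment()].
#' @param popmap optional named character vector (sample id to population);
#'   when supplied, per-population haplotype counts are tabulated.
#' @return an object of class `haplotype_table`: list with `haplotypes`
#'   (representative sequences over the compared sites), `counts`
#'   (haplotype x population count matrix; single column `all` without a
#'   popmap), `members` (list of sample ids per haplotype), `n` (samples
#'   collapsed) and `used_sites` (indices of compared sites).
#' @export
collapse_haplotypes <- function(aln, popmap = NULL) {
  keep <- usable_sites(aln)
  if (length(keep) == 0L)
    stop("no usable sites: every site carries N or '-' in some sample")
  m <- unclass(aln)[, keep, drop = FALSE]
  key <- apply(m, 1L, paste, collapse = "")
  uniq <- unique(key)
  hap_id <- paste0("H", seq_along(uniq))
  idx <- match(key, uniq)
  members <- split(rownames(aln), hap_id[idx])
  members <- members[hap_id]  # preserve first-seen order
  if (is.null(popmap)) {
    counts <- matrix(as.integer(table(factor(idx, levels = seq_along(uniq)))),
                     ncol = 1L, dimnames = list(hap_id, "all"))
  } else {
    miss <- setdiff(rownames(aln), names(popmap))
    if (length(miss))
      stop("sample id(s) missing from popmap: ", paste(miss, collapse = ", "))
    pops <- popmap[rownames(aln)]
    counts <- table(factor(idx, levels = seq_along(uniq)),
                    factor(pops, levels = unique(pops)))
    counts <- matrix(as.integer(counts), nrow = length(uniq),
                     dimnames = list(hap_id, colnames(counts)))
  }
  structure(list(haplotypes = stats::setNames(uniq, hap_id),
                 counts = counts, members = members,
                 n = nrow(aln), used_sites = keep),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotypes), "haplotypes from", x$n,
      "samples over", length(x$used_sites), "compared sites\n")
  invisible(x)
}

#' Haplotype (gene) diversity
#'
#' Nei's unbiased gene diversity `h = n (1 - sum p_i^2) / (n - 1)`: the
#' probability that two haplotypes drawn without replacement differ.
#'
#' @param counts integer vector of haplotype counts (n >= 2 in total).
#' @return `h` in `[0, 1]`; `NA` with a warning when n < 2 (undefined).
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) {
    warning("haplotype diversity undefined for n < 2")
    return(NA_real_)
  }
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Nucleotide diversity per site
#'
#' Mean number of pairwise differences divided by the number of compared
#' sites (complete deletion).
#'
#' @param aln a [seq_alignment()] with at least two sequences.
#' @return `pi` (per site).
#' @export
nucleotide_diversity <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) {
    warning("nucleotide diversity undefined for n < 2")
    return(NA_real_)
  }
  pd <- pairwise_diffs(aln, "complete")
  mean(pd$d[lower.tri(pd$d)]) / pd$L_used
}

#' Rarefied haplotype diversity
#'
#' Repeatedly subsamples each population (without replacement) to a common
#' size and reports the mean and standard error of the number of distinct
#' haplotypes and of haplotype diversity across replicates, removing the
#' sample-size dependence of both indices.  Populations smaller than
#' `size` are skipped with a warning.
#'
#' @param aln a [seq_alignment()].
#' @param popmap named character vector (sample id to population).
#' @param size subsample size (default 15).
#' @param reps number of replicates (default 30).
#' @param seed RNG seed.
#' @return data.frame with one row per analysed population: `population`,
#'   `n`, `mean_haplotypes`, `se_haplotypes`, `mean_h`, `se_h`, plus
#'   attributes `size`, `reps`, `seed`.
#' @export
rarefy_diversity <- function(aln, popmap, size = 15L, reps = 30L, seed = NULL) {
  if (size < 2L) stop("rarefaction size must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  tab <- collapse_haplotypes(aln, popmap)
  hap_of <- stats::setNames(rep(names(tab$members), lengths(tab$members)),
                            unlist(tab$members))
  pops <- popmap[rownames(aln)]
  res <- list()
  for (p in unique(pops)) {
    ids <- rownames(aln)[pops == p]
    if (length(ids) < size) {
      warning("population ", p, " has fewer than ", size,
              " samples; skipped from rarefaction", call. = FALSE)
      next
    }
    k <- h <- numeric(reps)
    for (r in seq_len(reps)) {
      sub <- sample(ids, size)
      cnt <- table(hap_of[sub])
      k[r] <- length(cnt)
      h[r] <- haplotype_diversity(as.integer(cnt))
    }
    res[[p]] <- data.frame(population = p, n = length(ids),
                           mean_haplotypes = mean(k),
                           se_haplotypes = stats::sd(k) / sqrt(reps),
                           mean_h = mean(h),
                           se_h = stats::sd(h) / sqrt(reps))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "size") <- size
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out
}

#' Count haplotypes private to a group of populations
#'
#' A haplotype is private to the group when every one of its carriers
#' belongs to a population in the group.
#'
#' @param table a [collapse_haplotypes()] result built with a popmap.
#' @param group character vector of population labels.
#' @return integer count.
#' @export
private_haplotypes <- function(table, group) {
  pops <- colnames(table$counts)
  unknown <- setdiff(group, pops)
  if (length(unknown))
    stop("unknown population(s): ", paste(unknown, collapse = ", "))
  inside <- rowSums(table$counts[, pops %in% group, drop = FALSE])
  outside <- rowSums(table$counts[, !(pops %in% group), drop = FALSE])
  sum(inside > 0L & outside == 0L)
}
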