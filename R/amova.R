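# Pairwise Phi-ST from sequence data via AMOVA, permutation p-values,
# and Benjamini-Hochberg correction across the pairwise matrix.

# Phi-ST from a squared-distance matrix and a two-level grouping.
# delta^2 = number of pairwise sequence differences (haplotypic AMOVA
# convention); variance components from the two-population AMOVA layout.
phist_from_d <- function(d2, grp) {
  N <- length(grp)
  stopifnot(nrow(d2) == N)
  lev <- unique(grp)
  stopifnot(length(lev) == 2L)
  lt <- lower.tri(d2)
  ss_t <- sum(d2[lt]) / N
  ss_w <- 0
  sizes <- numeric(2L)
  for (k in 1:2) {
    idx <- which(grp == lev[k])
    sizes[k] <- length(idx)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  sigma_w <- ss_w / (N - 2)
  n_prime <- (N - sum(sizes^2) / N)  # / (r - 1) with r = 2
  sigma_a <- (ss_a - sigma_w) / n_prime
  denom <- sigma_a + sigma_w
  if (denom == 0) return(0)
  sigma_a / denom
}

#' Pairwise Phi-ST between two populations
#'
#' AMOVA-based differentiation for sequence data, with the squared
#' molecular distance between two sequences taken as their number of
#' pairwise differences (pairwise deletion of missing sites within each
#' pair).  Small negative values are possible (unbiased estimator).
#'
#' @param aln a [seq_alignment()].
#' @param popmap named character vector (sample id to population).
#' @param popA,popB population labels (each with >= 2 samples).
#' @return Phi-ST (<= 1).
#' @export
pairwise_phist <- function(aln, popmap, popA, popB) {
  sel <- subset_pair(aln, popmap, popA, popB)
  phist_from_d(sel$d2, sel$grp)
}

subset_pair <- function(aln, popmap, popA, popB) {
  pops <- popmap[rownames(aln)]
  idx <- which(pops %in% c(popA, popB))
  for (p in c(popA, popB)) {
    np <- sum(pops == p, na.rm = TRUE)
    if (is.na(np) || np == 0L) stop("population ", p, " has no samples")
    if (np < 2L) stop("population ", p, " has fewer than 2 samples")
  }
  sub <- aln[idx, ]
  pd <- pairwise_diffs(sub, "pairwise")
  list(d2 = pd$d, grp = as.character(pops[idx]))
}

#' Permutation test for pairwise Phi-ST
#'
#' Individuals are permuted between the two populations, preserving the
#' sample sizes.  When the number of distinct reassignments `choose(N, nA)`
#' does not exceed `nperm`, all of them are enumerated and the exact
#' p-value `#{Phi_perm >= Phi_obs} / total` is returned; otherwise `nperm`
#' random permutations are drawn and the add-one-corrected Monte-Carlo
#' p-value `(hits + 1) / (nperm + 1)` is reported.
#'
#' @param aln,popmap,popA,popB as in [pairwise_phist()].
#' @param nperm number of permutations (>= 1).
#' @param seed RNG seed (used only in the Monte-Carlo branch).
#' @return list with `phist`, `p`, `nperm` (actual count used),
#'   `exhaustive` (logical).
#' @export
phist_permutation_test <- function(aln, popmap, popA, popB,
                                   nperm = 10000L, seed = NULL) {
  stopifnot(nperm >= 1)
  sel <- subset_pair(aln, popmap, popA, popB)
  d2 <- sel$d2
  grp <- sel$grp
  obs <- phist_from_d(d2, grp)
  N <- length(grp)
  nA <- sum(grp == grp[1])
  n_assign <- choose(N, nA)
  if (n_assign <= nperm) {
    combs <- utils::combn(N, nA)
    stat <- apply(combs, 2L, function(ia) {
      g <- rep("B", N); g[ia] <- "A"
      phist_from_d(d2, g)
    })
    p <- mean(stat >= obs - 1e-12)
    return(list(phist = obs, p = p, nperm = ncol(combs), exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (r in seq_len(nperm)) {
    g <- sample(grp)
    if (phist_from_d(d2, g) >= obs - 1e-12) hits <- hits + 1L
  }
  list(phist = obs, p = (hits + 1) / (nperm + 1), nperm = nperm,
       exhaustive = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (monotonicity enforced),
#' preserving the input order.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Full pairwise Phi-ST matrix with permutation tests and BH correction
#'
#' Runs [phist_permutation_test()] for every pair of populations and
#' applies the Benjamini-Hochberg correction jointly across all pairwise
#' tests.
#'
#' @param aln a [seq_alignment()].
#' @param popmap named character vector covering all samples.
#' @param nperm permutations per pair.
#' @param seed RNG seed.
#' @return object of class `phist_matrix`: data.frame with one row per
#'   pair (`popA`, `popB`, `phist`, `p`, `p_adj`, `nperm`, `exhaustive`)
#'   plus attribute `populations`.
#' @export
phist_matrix <- function(aln, popmap, nperm = 10000L, seed = NULL) {
  pops <- unique(popmap[rownames(aln)])
  if (length(pops) < 2L) stop("need at least two populations")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(length(pops) - 1L)) for (j in seq.int(i + 1L, length(pops))) {
    pt <- phist_permutation_test(aln, popmap, pops[i], pops[j], nperm = nperm)
    rows[[length(rows) + 1L]] <-
      data.frame(popA = pops[i], popB = pops[j], phist = pt$phist,
                 p = pt$p, nperm = pt$nperm, exhaustive = pt$exhaustive,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  attr(out, "populations") <- pops
  class(out) <- c("phist_matrix", "data.frame")
  out
}

#' @export
print.phist_matrix <- function(x, ...) {
  cat("pairwise Phi-ST over", length(attr(x, "populations")),
      "populations (BH-adjusted p across", nrow(x), "pairs)\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Square-matrix view of a pairwise Phi-ST table
#'
#' Phi-ST below the diagonal, BH-adjusted p-values above.
#'
#' @param x a [phist_matrix()] result.
#' @return square numeric matrix.
#' @export
phist_square <- function(x) {
  pops <- attr(x, "populations")
  m <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (r in seq_len(nrow(x))) {
    m[x$popB[r], x$popA[r]] <- x$phist[r]
    m[x$popA[r], x$popB[r]] <- x$p_adj[r]
  }
  m
}
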