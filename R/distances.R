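# Pairwise sequence difference machinery shared by the haplotype,
# neutrality, mismatch and Phi-ST modules.

BASES <- c("A", "C", "G", "T")

# columns where every sample carries an unambiguous base
usable_sites <- function(aln) {
  m <- unclass(aln)
  which(colSums(matrix(m %in% BASES, nrow = nrow(m))) == nrow(m))
}

#' Pairwise sequence difference counts
#'
#' Number of differing sites for every pair of samples.  Under
#' `"complete"` deletion, sites with `N`/`-` in *any* sample are excluded
#' before comparison; under `"pairwise"` deletion each pair is compared
#' over the sites where both members are unambiguous.
#'
#' @param aln a [seq_alignment()].
#' @param deletion missing-site handling, `"complete"` or `"pairwise"`.
#' @return list with `d` (n x n symmetric integer matrix of difference
#'   counts) and `L_used` (for complete deletion, the number of compared
#'   sites; for pairwise deletion, an n x n matrix of compared-site counts).
#' @export
pairwise_diffs <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- unclass(aln)
  n <- nrow(m)
  if (deletion == "complete") {
    keep <- usable_sites(aln)
    if (length(keep) == 0L)
      stop("no usable sites after complete deletion of missing data")
    m <- m[, keep, drop = FALSE]
    matches <- matrix(0, n, n)
    for (b in BASES) {
      ind <- matrix(as.numeric(m == b), nrow = n)
      matches <- matches + tcrossprod(ind)
    }
    d <- length(keep) - matches
    dimnames(d) <- list(rownames(m), rownames(m))
    list(d = round(d), L_used = length(keep))
  } else {
    valid <- matrix(as.numeric(matrix(m %in% BASES, nrow = n)), nrow = n)
    shared <- tcrossprod(valid)
    matches <- matrix(0, n, n)
    for (b in BASES) {
      ind <- matrix(as.numeric(m == b), nrow = n)
      matches <- matches + tcrossprod(ind)
    }
    d <- shared - matches
    dimnames(d) <- dimnames(shared) <- list(rownames(m), rownames(m))
    list(d = round(d), L_used = round(shared))
  }
}

# number of segregating sites among usable (complete-deletion) sites
segregating_sites <- function(aln) {
  m <- unclass(aln)[, usable_sites(aln), drop = FALSE]
  if (ncol(m) == 0L) return(0L)
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

# mean number of pairwise differences (complete deletion)
mean_pairwise_diff <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  pd <- pairwise_diffs(aln, "complete")
  sum(pd$d[lower.tri(pd$d)]) / choose(n, 2)
}
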