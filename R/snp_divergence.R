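# Per-population SNP summaries, Hardy-Weinberg exact screening, and
# pairwise Weir-Cockerham FST / Hedrick G'ST / Jost's D with
# across-locus bootstrap confidence intervals.

# per-locus per-population allele/genotype summaries
pop_locus_summary <- function(g, popmap, pop) {
  ids <- names(popmap)[popmap == pop]
  ids <- intersect(rownames(g), ids)
  if (length(ids) == 0L) stop("population ", pop, " absent from genotype matrix")
  m <- unclass(g)[ids, , drop = FALSE]
  n <- colSums(!is.na(m))
  alt <- colSums(m, na.rm = TRUE)
  p_alt <- ifelse(n > 0, alt / (2 * n), NA_real_)
  het <- colSums(m == 1L, na.rm = TRUE)
  hobs <- ifelse(n > 0, het / n, NA_real_)
  list(n = n, p_alt = p_alt, hobs = hobs)
}

#' Per-population, per-locus SNP statistics
#'
#' For every population and locus: `n` genotyped individuals, major-allele
#' frequency `p`, observed heterozygosity `Hobs`, expected heterozygosity
#' `Hexp = 1 - p^2 - q^2`, nucleotide diversity
#' `pi = 2n/(2n - 1) * Hexp` (the unbiased small-sample correction), and
#' `FIS = (pi - Hobs)/pi` (0 when `pi = 0`).  Per-population averages are
#' taken over loci polymorphic across the full dataset.
#'
#' @param g a [genotype_matrix()].
#' @param popmap named character vector (sample id to population).
#' @return list with `per_locus` (long data.frame) and `summary` (one row
#'   per population with averages, matching the usual RADseq summary
#'   table layout: N, p, Hobs, Hexp, pi, FIS).
#' @export
locus_pop_stats <- function(g, popmap) {
  miss <- setdiff(rownames(g), names(popmap))
  if (length(miss))
    stop("sample id(s) missing from popmap: ", paste(miss, collapse = ", "))
  pops <- unique(popmap[rownames(g)])
  overall_alt <- colSums(unclass(g), na.rm = TRUE)
  overall_n <- colSums(!is.na(unclass(g)))
  overall_p <- ifelse(overall_n > 0, overall_alt / (2 * overall_n), NA_real_)
  polymorphic <- !is.na(overall_p) & overall_p > 0 & overall_p < 1
  per <- list()
  summ <- list()
  for (pop in pops) {
    st <- pop_locus_summary(g, popmap, pop)
    p_major <- pmax(st$p_alt, 1 - st$p_alt)
    hexp <- 1 - st$p_alt^2 - (1 - st$p_alt)^2
    pi <- ifelse(st$n > 0, 2 * st$n / (2 * st$n - 1) * hexp, NA_real_)
    fis <- ifelse(!is.na(pi) & pi > 0, (pi - st$hobs) / pi, 0)
    per[[pop]] <- data.frame(population = pop, locus = colnames(g),
                             n = st$n, p_major = p_major, hobs = st$hobs,
                             hexp = hexp, pi = pi, fis = fis,
                             polymorphic = polymorphic,
                             stringsAsFactors = FALSE, row.names = NULL)
    use <- polymorphic & st$n > 0
    summ[[pop]] <- data.frame(population = pop,
                              N = mean(st$n[use]),
                              p = mean(p_major[use]),
                              Hobs = mean(st$hobs[use]),
                              Hexp = mean(hexp[use]),
                              pi = mean(pi[use]),
                              FIS = mean(fis[use]),
                              n_loci = sum(use),
                              stringsAsFactors = FALSE)
  }
  list(per_locus = do.call(rbind, per),
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}

#' Hardy-Weinberg exact test for a biallelic locus
#'
#' Exact conditional test: given the observed allele counts, all
#' heterozygote counts of matching parity are enumerated with their
#' conditional probabilities
#' `P(nAB | n, nA) = n! / (nAA! nAB! naa!) * 2^nAB * nA! na! / (2n)!`,
#' and the p-value is the total probability of configurations no more
#' probable than the observed one (two-sided, probability ordering).
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom ref, het, hom alt).
#' @return list with `p` and `probs` (named vector of configuration
#'   probabilities over possible heterozygote counts; sums to 1).
#'   Monomorphic loci give `p = 1`.
#' @export
hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n < 1L) stop("no genotyped individuals")
  nA <- 2L * n_aa + n_ab
  nB <- 2L * n_bb + n_ab
  if (nA == 0L || nB == 0L)
    return(list(p = 1, probs = stats::setNames(1, n_ab)))
  het_min <- if (nA %% 2L == 0L) 0L else 1L
  hets <- seq.int(het_min, min(nA, nB), by = 2L)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) %/% 2L
    bb <- (nB - h) %/% 2L
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, 0)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  names(probs) <- hets
  p_obs <- probs[as.character(n_ab)]
  p <- sum(probs[probs <= p_obs + 1e-12])
  list(p = min(p, 1), probs = probs)
}

#' Screen loci for Hardy-Weinberg deviation
#'
#' Runs [hwe_exact()] per locus within each population; a locus is
#' flagged when its p-value falls below `alpha` in any population.
#'
#' @param g a [genotype_matrix()].
#' @param popmap named character vector.
#' @param alpha flagging threshold (default 0.05).
#' @return data.frame per locus: `locus`, `min_p`, `flagged`.
#' @export
hwe_screen <- function(g, popmap, alpha = 0.05) {
  pops <- unique(popmap[rownames(g)])
  m <- unclass(g)
  min_p <- rep(1, ncol(g))
  for (pop in pops) {
    ids <- intersect(rownames(g), names(popmap)[popmap == pop])
    sub <- m[ids, , drop = FALSE]
    for (l in seq_len(ncol(g))) {
      col <- sub[, l]
      col <- col[!is.na(col)]
      if (length(col) < 2L) next
      p <- hwe_exact(sum(col == 0L), sum(col == 1L), sum(col == 2L))$p
      min_p[l] <- min(min_p[l], p)
    }
  }
  data.frame(locus = colnames(g), min_p = min_p, flagged = min_p < alpha,
             stringsAsFactors = FALSE)
}

# Weir-Cockerham variance components for one locus, two populations.
# Returns c(a, b, c) or NULL when the locus is unusable.
wc_components <- function(n_i, p_i, h_i) {
  r <- 2
  if (any(n_i == 0)) return(NULL)
  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Weir-Cockerham FST (theta) between two populations
#'
#' Moment estimator from allele-frequency variance components `a`
#' (among populations), `b` (among individuals within populations) and
#' `c` (within individuals).  The multilocus estimate is the
#' ratio of sums `sum(a) / sum(a + b + c)`, not the mean of per-locus
#' ratios.  Loci with no genotyped individual in either population, or
#' with `a + b + c = 0`, are skipped.
#'
#' @param g a [genotype_matrix()].
#' @param popmap named character vector.
#' @param popA,popB population labels.
#' @return list with `theta` (multilocus), `per_locus` (data.frame of
#'   `locus`, `a`, `b`, `c`, `theta`), `n_loci` used.
#' @export
wc_fst <- function(g, popmap, popA, popB) {
  stA <- pop_locus_summary(g, popmap, popA)
  stB <- pop_locus_summary(g, popmap, popB)
  comp <- matrix(NA_real_, ncol(g), 3L,
                 dimnames = list(colnames(g), c("a", "b", "c")))
  for (l in seq_len(ncol(g))) {
    cc <- wc_components(c(stA$n[l], stB$n[l]),
                        c(stA$p_alt[l], stB$p_alt[l]),
                        c(stA$hobs[l], stB$hobs[l]))
    if (!is.null(cc)) comp[l, ] <- cc
  }
  tot <- rowSums(comp)
  usable <- !is.na(tot) & tot != 0
  if (!any(usable)) stop("no usable loci for FST between ", popA, " and ", popB)
  theta <- sum(comp[usable, "a"]) / sum(tot[usable])
  per_locus <- data.frame(locus = colnames(g), a = comp[, "a"],
                          b = comp[, "b"], c = comp[, "c"],
                          theta = ifelse(usable, comp[, "a"] / tot, NA_real_),
                          row.names = NULL, stringsAsFactors = FALSE)
  list(theta = theta, per_locus = per_locus, n_loci = sum(usable))
}

# Nei & Chesser unbiased HS/HT for one locus, two populations
hs_ht_components <- function(n_i, p_i, h_i) {
  r <- 2
  if (any(n_i == 0)) return(NULL)
  ntilde <- r / sum(1 / n_i)  # harmonic mean sample size
  if (ntilde <= 1) return(NULL)
  hs_plug <- mean(2 * p_i * (1 - p_i))
  ho <- mean(h_i)
  hs <- (ntilde / (ntilde - 1)) * (hs_plug - ho / (2 * ntilde))
  pbar <- mean(p_i)
  ht_plug <- 2 * pbar * (1 - pbar)
  ht <- ht_plug + hs / (r * ntilde) - ho / (2 * r * ntilde)
  c(hs = hs, ht = ht)
}

#' Hedrick's G'ST and Jost's D between two populations
#'
#' Standardized differentiation measures built on Nei & Chesser unbiased
#' estimates of within- (`HS`) and total- (`HT`) heterozygosity, averaged
#' across loci before forming the multilocus ratios (k = 2
#' subpopulations): `GST = (HT - HS)/HT`,
#' `G'ST = GST (k - 1 + HS) / ((k - 1)(1 - HS))`,
#' `D = (HT - HS)/(1 - HS) * k/(k - 1)`.
#'
#' @param g a [genotype_matrix()].
#' @param popmap named character vector.
#' @param popA,popB population labels.
#' @return list with `gst`, `gst_prime`, `jost_d`, `hs`, `ht`, `n_loci`.
#' @export
gst_jost <- function(g, popmap, popA, popB) {
  stA <- pop_locus_summary(g, popmap, popA)
  stB <- pop_locus_summary(g, popmap, popB)
  hs <- ht <- rep(NA_real_, ncol(g))
  for (l in seq_len(ncol(g))) {
    cc <- hs_ht_components(c(stA$n[l], stB$n[l]),
                           c(stA$p_alt[l], stB$p_alt[l]),
                           c(stA$hobs[l], stB$hobs[l]))
    if (!is.null(cc)) { hs[l] <- cc["hs"]; ht[l] <- cc["ht"] }
  }
  usable <- !is.na(hs)
  if (!any(usable)) stop("no usable loci between ", popA, " and ", popB)
  HS <- mean(hs[usable])
  HT <- mean(ht[usable])
  k <- 2
  gst <- if (HT > 0) (HT - HS) / HT else 0
  gst_prime <- if (HS < 1 && HT > 0)
    gst * (k - 1 + HS) / ((k - 1) * (1 - HS)) else 0
  jost_d <- if (HS < 1) (HT - HS) / (1 - HS) * k / (k - 1) else 0
  list(gst = gst, gst_prime = gst_prime, jost_d = jost_d,
       hs = HS, ht = HT, n_loci = sum(usable))
}

# all three multilocus statistics for a given set of locus indices
pair_divergence_stats <- function(g, popmap, popA, popB, loci = NULL) {
  gg <- if (is.null(loci)) g else subset_loci_dup(g, loci)
  fst <- wc_fst(gg, popmap, popA, popB)$theta
  gj <- gst_jost(gg, popmap, popA, popB)
  c(fst = fst, gst_prime = gj$gst_prime, jost_d = gj$jost_d)
}

# like subset_loci but tolerates duplicated indices (bootstrap resamples)
subset_loci_dup <- function(g, idx) {
  li <- loci_info(g)[idx, , drop = FALSE]
  m <- unclass(g)[, idx, drop = FALSE]
  colnames(m) <- paste0(colnames(m), "#", seq_along(idx))
  genotype_matrix(m, radtag = paste0(li$radtag, "#", seq_along(idx)),
                  pos = li$pos)
}

#' Across-locus bootstrap CIs for pairwise divergence statistics
#'
#' Loci are resampled with replacement `B` times; the multilocus
#' Weir-Cockerham theta, G'ST and Jost's D are recomputed on each
#' resample, and bias-corrected (BC) percentile intervals are formed:
#' `z0 = qnorm(fraction of replicates below the point estimate)` shifts
#' the percentile levels to `pnorm(2 z0 +/- z_{alpha/2})`.  A confidence
#' interval containing 0 is flagged non-significant.
#'
#' @param g a [genotype_matrix()].
#' @param popmap named character vector.
#' @param popA,popB population labels.
#' @param B bootstrap replicates (>= 10; a warning is issued when fewer
#'   than 20 loci are available).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return data.frame with one row per statistic: `statistic`, `estimate`,
#'   `ci_low`, `ci_high`, `significant` (CI excludes 0), `B`.
#' @export
divergence_bootstrap_ci <- function(g, popmap, popA, popB, B = 100L,
                                    conf = 0.95, seed = NULL) {
  if (B < 10L) stop("B must be at least 10")
  if (ncol(g) < 20L)
    warning("fewer than 20 loci; bootstrap CIs will be unstable")
  if (!is.null(seed)) set.seed(seed)
  point <- pair_divergence_stats(g, popmap, popA, popB)
  boot <- matrix(NA_real_, B, 3L, dimnames = list(NULL, names(point)))
  for (b in seq_len(B)) {
    idx <- sample.int(ncol(g), replace = TRUE)
    boot[b, ] <- pair_divergence_stats(g, popmap, popA, popB, loci = idx)
  }
  zcrit <- stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
  rows <- lapply(names(point), function(s) {
    t_b <- boot[, s]
    if (all(t_b == t_b[1])) {           # degenerate: all resamples identical
      lo <- hi <- t_b[1]
    } else {
      frac <- mean(t_b < point[s])
      frac <- min(max(frac, 1 / (2 * B)), 1 - 1 / (2 * B))
      z0 <- stats::qnorm(frac)
      lv <- stats::pnorm(2 * z0 + zcrit)
      qs <- stats::quantile(t_b, lv, names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(statistic = s, estimate = unname(point[s]),
               ci_low = lo, ci_high = hi,
               significant = !(lo <= 0 && hi >= 0), B = B,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise divergence table with HWE screening
#'
#' Optionally removes loci flagged by [hwe_screen()] (p < `hwe_alpha` in
#' any population), then computes Weir-Cockerham theta, G'ST and Jost's D
#' with bootstrap CIs for every population pair.
#'
#' @param g a [genotype_matrix()].
#' @param popmap named character vector.
#' @param B bootstrap replicates per pair.
#' @param hwe_alpha HWE flagging threshold; `NULL` disables the screen.
#' @param seed RNG seed.
#' @return list with `table` (long data.frame over pairs x statistics),
#'   `hwe` (the screen result or NULL), `n_loci_used`.
#' @export
pairwise_divergence <- function(g, popmap, B = 100L, hwe_alpha = 0.05,
                                seed = NULL) {
  hwe <- NULL
  if (!is.null(hwe_alpha)) {
    hwe <- hwe_screen(g, popmap, alpha = hwe_alpha)
    if (any(hwe$flagged)) {
      message("excluding ", sum(hwe$flagged), " HWE-deviating locus/loci")
      g <- subset_loci(g, which(!hwe$flagged))
    }
  }
  if (ncol(g) == 0L) stop("no loci left after HWE screening")
  pops <- unique(popmap[rownames(g)])
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(length(pops) - 1L)) for (j in seq.int(i + 1L, length(pops))) {
    ci <- divergence_bootstrap_ci(g, popmap, pops[i], pops[j], B = B)
    ci$popA <- pops[i]; ci$popB <- pops[j]
    rows[[length(rows) + 1L]] <- ci
  }
  list(table = do.call(rbind, rows), hwe = hwe, n_loci_used = ncol(g))
}
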