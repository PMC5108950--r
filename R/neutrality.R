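# Tajima's D and Fu's Fs with coalescent-simulation p-values.

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from <- function(n, S, theta_pi) {
  if (S == 0L) return(NA_real_)  # undefined, flagged as NA rather than 0
  k <- tajima_constants(n)
  (theta_pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Contrasts the mean pairwise difference estimator of theta with the
#' Watterson (segregating sites) estimator; strongly negative values
#' indicate an excess of rare variants as expected after a demographic
#' expansion.  Sites are handled by complete deletion.
#'
#' @param aln a [seq_alignment()] with at least 4 sequences.
#' @return list with `D` (NA when no site segregates), `S`, `theta_pi`
#'   (mean pairwise differences) and `n`.
#' @export
tajimas_d <- function(aln) {
  n <- nrow(aln)
  if (n < 4L) stop("Tajima's D requires at least 4 sequences")
  S <- segregating_sites(aln)
  theta_pi <- mean_pairwise_diff(aln)
  list(D = tajima_d_from(n, S, theta_pi), S = S, theta_pi = theta_pi, n = n)
}

# log unsigned Stirling numbers of the first kind, row n: log|s(n, j)|,
# j = 1..n, via |s(n+1, j)| = |s(n, j-1)| + n |s(n, j)| in log space
log_stirling_row <- function(n) {
  lrow <- 0  # n = 1: |s(1,1)| = 1
  if (n == 1L) return(lrow)
  for (m in seq_len(n - 1L)) {
    prev <- c(-Inf, lrow)          # |s(m, j-1)| term
    shifted <- c(lrow, -Inf) + log(m)
    lrow <- pmax(prev, shifted) +
      log1p(exp(pmin(prev, shifted) - pmax(prev, shifted)))
    lrow[is.nan(lrow)] <- -Inf
  }
  lrow
}

#' Fu's Fs
#'
#' `Fs = ln(S' / (1 - S'))` where `S'` is the probability, under the Ewens
#' sampling distribution with theta equal to the mean pairwise difference,
#' of observing at least as many haplotypes as seen.  Large negative
#' values signal a haplotype excess typical of recent expansion.
#' Stirling numbers are handled in log space, so large samples (n well
#' beyond 60) do not overflow.
#'
#' @param n sample size (>= 2).
#' @param k observed number of distinct haplotypes (1 <= k <= n).
#' @param theta positive theta estimate (mean pairwise differences).
#' @return `Fs`; `NA` with a warning when `k = 1` or `theta <= 0`
#'   (the log-odds is degenerate).
#' @export
fu_fs <- function(n, k, theta) {
  stopifnot(n >= 2, k >= 1, k <= n)
  if (k == 1L || theta <= 0) {
    warning("Fu's Fs undefined for k = 1 or theta <= 0")
    return(NA_real_)
  }
  lst <- log_stirling_row(n)
  j <- seq_len(n)
  lp <- lst + j * log(theta) - sum(log(theta + 0:(n - 1L)))
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  l_ge <- lse(lp[j >= k])   # log S'
  l_lt <- if (k > 1L) lse(lp[j < k]) else -Inf  # log(1 - S')
  l_ge - l_lt
}

#' Fu's Fs from an alignment
#'
#' @param aln a [seq_alignment()].
#' @return list with `Fs`, `k` (haplotype count under complete deletion),
#'   `theta_pi`, `n`.
#' @export
fu_fs_aln <- function(aln) {
  n <- nrow(aln)
  tab <- collapse_haplotypes(aln)
  k <- length(tab$haplotypes)
  theta_pi <- mean_pairwise_diff(aln)
  Fs <- if (k == 1L || theta_pi <= 0) NA_real_ else fu_fs(n, k, theta_pi)
  list(Fs = Fs, k = k, theta_pi = theta_pi, n = n)
}

#' Neutrality tests with coalescent-simulation p-values
#'
#' Computes Tajima's D and Fu's Fs for an alignment and estimates their
#' p-values against a stationary neutral coalescent null.  By default the
#' null conditions on the observed number of segregating sites (`S`
#' mutations placed on each simulated genealogy in proportion to branch
#' length); `conditioning = "theta"` instead simulates with the scaled
#' mutation rate set to the observed mean pairwise difference.  The D
#' p-value is one-tailed in the direction of the observed statistic; the
#' Fs p-value is the lower tail.  Both use the add-one correction
#' `(hits + 1) / (nsim + 1)` and so are never exactly zero.
#'
#' @param aln a [seq_alignment()].
#' @param nsim number of null simulations (>= 100).
#' @param seed RNG seed.
#' @param conditioning `"fixed_S"` or `"theta"`.
#' @return object of class `neutrality_result`: list with `D`, `Fs`, `S`,
#'   `k`, `theta_pi`, `p_D`, `p_Fs`, `nsim`, `seed`, `conditioning`.
#' @export
neutrality_test <- function(aln, nsim = 1000L, seed = NULL,
                            conditioning = c("fixed_S", "theta")) {
  conditioning <- match.arg(conditioning)
  if (nsim < 100L) stop("nsim must be at least 100")
  n <- nrow(aln)
  obs_d <- tajimas_d(aln)
  obs_f <- fu_fs_aln(aln)
  if (!is.null(seed)) set.seed(seed)
  D_sim <- Fs_sim <- rep(NA_real_, nsim)
  for (r in seq_len(nsim)) {
    sim <- if (conditioning == "fixed_S") {
      simulate_fixed_s(n, obs_d$S, theta0 = 1,
                       L = max(2L * obs_d$S + 10L, 50L))
    } else {
      simulate_sequences(n, theta0 = max(obs_d$theta_pi, 1e-6),
                         L = max(200L, ceiling(20 * obs_d$theta_pi)))
    }
    st <- collapse_haplotypes(sim)
    k_s <- length(st$haplotypes)
    tp_s <- mean_pairwise_diff(sim)
    S_s <- segregating_sites(sim)
    D_sim[r] <- tajima_d_from(n, S_s, tp_s)
    Fs_sim[r] <- if (k_s > 1L && tp_s > 0) fu_fs(n, k_s, tp_s) else NA_real_
  }
  p_D <- if (is.na(obs_d$D)) NA_real_ else {
    hits <- if (obs_d$D < 0) sum(D_sim <= obs_d$D, na.rm = TRUE)
            else sum(D_sim >= obs_d$D, na.rm = TRUE)
    (hits + 1) / (nsim + 1)
  }
  p_Fs <- if (is.na(obs_f$Fs)) NA_real_ else
    (sum(Fs_sim <= obs_f$Fs, na.rm = TRUE) + 1) / (nsim + 1)
  structure(list(D = obs_d$D, Fs = obs_f$Fs, S = obs_d$S, k = obs_f$k,
                 theta_pi = obs_d$theta_pi, n = n,
                 p_D = p_D, p_Fs = p_Fs, nsim = nsim, seed = seed,
                 conditioning = conditioning),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("Tajima's D = %s (p = %s); Fu's Fs = %s (p = %s)  [n = %d, S = %d, k = %d]\n",
              format(x$D, digits = 3), format(x$p_D, digits = 3),
              format(x$Fs, digits = 3), format(x$p_Fs, digits = 3),
              x$n, x$S, x$k))
  invisible(x)
}
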