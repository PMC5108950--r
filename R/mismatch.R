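# Mismatch distributions and the sudden-demographic-expansion model:
# least-squares fit of (tau, theta0, theta1), SSD and raggedness with
# parametric-bootstrap p-values and percentile bootstrap CIs.

#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over all C(n,2) pairs
#' (complete deletion), as relative frequencies over classes `0..d`.
#'
#' @param aln a [seq_alignment()] with n >= 2.
#' @return object of class `mismatch_dist`: list with `freq` (named
#'   vector, classes `0..d`), `npairs`, `d`.
#' @export
observed_mismatch <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop("mismatch distribution requires at least 2 sequences")
  pd <- pairwise_diffs(aln, "complete")
  diffs <- pd$d[lower.tri(pd$d)]
  mismatch_from_diffs(diffs)
}

mismatch_from_diffs <- function(diffs) {
  d <- max(diffs)
  cnt <- tabulate(diffs + 1L, nbins = d + 1L)
  structure(list(freq = stats::setNames(cnt / length(diffs), 0:d),
                 npairs = length(diffs), d = d),
            class = "mismatch_dist")
}

#' @export
print.mismatch_dist <- function(x, ...) {
  cat("mismatch distribution over", x$npairs, "pairs, classes 0..", x$d, "\n")
  invisible(x)
}

# equilibrium mismatch probabilities theta^i / (1+theta)^(i+1), i = 0..imax
equilibrium_mismatch <- function(theta, imax) {
  i <- 0:imax
  if (theta == 0) return(as.numeric(i == 0L))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Expected mismatch probabilities under sudden expansion
#'
#' The instantaneous-expansion model: a population at mutation-drift
#' equilibrium with parameter `theta0` grew instantaneously to parameter
#' `theta1`, `tau` mutational time units ago.  The expected frequency of
#' pairs differing at `i` sites is
#' `F_i = Fhat_i(theta1) + exp(-tau (theta1 + 1) / theta1) *
#'   sum_{j=0}^{i} tau^j / j! * (Fhat_{i-j}(theta0) - Fhat_{i-j}(theta1))`
#' with the equilibrium distribution `Fhat_i(theta) =
#' theta^i / (1 + theta)^{i+1}`.  At `tau = 0` this reduces to
#' `Fhat(theta0)`; as `tau` grows it approaches `Fhat(theta1)`.
#'
#' @param i vector of difference classes (non-negative integers).
#' @param tau expansion age in mutational units (>= 0).
#' @param theta0 pre-expansion parameter (>= 0).
#' @param theta1 post-expansion parameter (> 0).
#' @return vector of probabilities for the requested classes.
#' @export
expected_mismatch <- function(i, tau, theta0, theta1) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 > 0)
  imax <- max(i)
  f0 <- equilibrium_mismatch(theta0, imax)
  f1 <- equilibrium_mismatch(theta1, imax)
  if (tau == 0) return(f0[i + 1L])
  j <- 0:imax
  pois <- exp(j * log(tau) - lgamma(j + 1))
  delta <- f0 - f1
  conv <- stats::convolve(pois, rev(delta), type = "open")[seq_len(imax + 1L)]
  out <- f1 + exp(-tau * (theta1 + 1) / theta1) * conv
  pmax(out[i + 1L], 0)
}

# model probabilities over classes 0..d, evaluated on an extended range
# (max(2d, 50)) and renormalized so the compared classes carry the mass
# assigned to them by the truncated model
mismatch_model_probs <- function(tau, theta0, theta1, d) {
  K <- max(2L * d, 50L)
  f <- expected_mismatch(0:K, tau, theta0, theta1)
  s <- sum(f)
  if (s <= 0) return(rep(0, d + 1L))
  (f / s)[seq_len(d + 1L)]
}

mismatch_ssd <- function(obs_freq, tau, theta0, theta1) {
  d <- length(obs_freq) - 1L
  sum((obs_freq - mismatch_model_probs(tau, theta0, theta1, d))^2)
}

#' Harpending's raggedness index
#'
#' Sum of squared successive differences of the mismatch class
#' frequencies, with zero frequencies appended at both ends of the class
#' range; smooth unimodal (expansion-like) distributions give small
#' values, while a distribution concentrated on a single class gives 2.
#'
#' @param obs a [observed_mismatch()] result (or a numeric frequency
#'   vector over classes `0..d`).
#' @return raggedness `r >= 0`.
#' @export
raggedness <- function(obs) {
  f <- if (inherits(obs, "mismatch_dist")) obs$freq else obs
  x <- c(0, as.numeric(f), 0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Constrained least squares: `(tau, theta0, theta1)` minimizing the sum
#' of squared deviations (SSD) between observed and model class
#' frequencies, subject to `tau >= 0`, `0 <= theta0 <= theta1 <= theta1_max`.
#' A coarse deterministic grid seeds a Nelder-Mead simplex refinement, so
#' the fit is reproducible for fixed input.  `theta1_max` (default 10000)
#' contains the well-known flat-likelihood ridge in `theta1`.
#'
#' @param obs a [observed_mismatch()] result.
#' @param n sample size behind `obs` (carried into bootstrap simulation).
#' @param theta1_max upper bound for `theta1`.
#' @param init optional `c(tau, theta0, theta1)` starting point; when
#'   supplied the grid search is skipped and the simplex starts there
#'   (used by the bootstrap, whose replicates are generated near the
#'   parent fit).
#' @return object of class `mismatch_fit`: list with `tau`, `theta0`,
#'   `theta1`, `ssd`, `raggedness`, `obs`, `n`.
#' @export
fit_expansion <- function(obs, n = NULL, theta1_max = 1e4, init = NULL) {
  stopifnot(inherits(obs, "mismatch_dist"))
  f <- as.numeric(obs$freq)
  d <- obs$d
  if (d == 0L) {
    # degenerate single-class observation: boundary fit
    fit <- structure(list(tau = 0, theta0 = 0, theta1 = 1e-6,
                          ssd = mismatch_ssd(f, 0, 0, 1e-6),
                          raggedness = raggedness(obs),
                          obs = obs, n = n, boundary = TRUE),
                     class = "mismatch_fit")
    return(fit)
  }
  if (is.null(init)) {
    mean_d <- sum((0:d) * f)
    tau_grid <- unique(pmax(c(0.5, 1, 2, 4, mean_d, d / 2), 1e-3))
    th0_grid <- c(0, 0.5, 2)
    th1_grid <- unique(c(0.5, 5, 50, 1000, max(mean_d, 0.5)))
    best <- NULL
    for (tau in tau_grid) for (th0 in th0_grid) for (th1 in th1_grid) {
      if (th1 < th0 || th1 <= 0) next
      s <- mismatch_ssd(f, tau, th0, th1)
      if (is.null(best) || s < best$ssd)
        best <- list(tau = tau, th0 = th0, th1 = th1, ssd = s)
    }
  } else {
    best <- list(tau = max(init[1], 1e-3), th0 = init[2],
                 th1 = min(max(init[3], init[2] + 1e-6, 1e-3), theta1_max))
  }
  # parameters squared to enforce the constraints; theta1 = theta0 + gap
  objective <- function(x) {
    tau <- x[1]^2
    th0 <- x[2]^2
    th1 <- min(th0 + x[3]^2, theta1_max)
    if (th1 <= 0) th1 <- 1e-8
    mismatch_ssd(f, tau, th0, th1)
  }
  start <- c(sqrt(best$tau), sqrt(best$th0),
             sqrt(max(best$th1 - best$th0, 1e-6)))
  opt <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  tau <- opt$par[1]^2
  theta0 <- opt$par[2]^2
  theta1 <- min(theta0 + opt$par[3]^2, theta1_max)
  structure(list(tau = tau, theta0 = theta0, theta1 = theta1,
                 ssd = opt$value, raggedness = raggedness(obs),
                 obs = obs, n = n, boundary = FALSE),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("expansion fit: tau = %.3f, theta0 = %.3f, theta1 = %.3f, SSD = %.5f, raggedness = %.4f\n",
              x$tau, x$theta0, x$theta1, x$ssd, x$raggedness))
  if (!is.null(x$p_ssd))
    cat(sprintf("  parametric bootstrap (%d reps): p_SSD = %.3f, p_raggedness = %.3f\n",
                x$nboot, x$p_ssd, x$p_raggedness))
  invisible(x)
}

#' Parametric bootstrap for the expansion-model fit
#'
#' For each replicate, `n` sequences are simulated under the fitted
#' `(tau, theta0, theta1)` demography, the model is re-fitted, and the
#' replicate SSD and raggedness are recorded.  Goodness-of-fit p-values
#' are `p_SSD = #{SSD_b >= SSD_obs} / nboot` (and analogously for the
#' raggedness index); a small p-value means the data fit the expansion
#' model *worse* than data generated under it.  Percentile 2.5%/97.5%
#' bounds of the re-fitted parameters give the reported CI for `tau`,
#' `theta0` and `theta1`.
#'
#' @param fit a [fit_expansion()] result with `n` set.
#' @param n sample size (defaults to `fit$n`).
#' @param nboot bootstrap replicates (a warning is issued below 100).
#' @param seed RNG seed.
#' @return the fit, augmented with `p_ssd`, `p_raggedness`, `ci`
#'   (2-row matrix of lower/upper bounds), `nboot`, `seed`.
#' @export
bootstrap_tests <- function(fit, n = fit$n, nboot = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "mismatch_fit"))
  if (is.null(n)) stop("sample size n is required for the parametric bootstrap")
  if (nboot < 100L) warning("nboot < 100 gives very coarse p-values")
  if (!is.null(seed)) set.seed(seed)
  theta1 <- max(fit$theta1, 1e-6)
  theta0 <- fit$theta0
  if (fit$tau <= 0 && theta0 <= 0) theta0 <- 1e-6  # degenerate boundary fit
  init <- c(fit$tau, theta0, theta1)
  ssd_b <- rag_b <- tau_b <- th0_b <- th1_b <- numeric(nboot)
  for (b in seq_len(nboot)) {
    dm <- simulate_pairwise_diffs(n, theta0 = theta0, tau = fit$tau,
                                  theta1 = theta1)
    obs_b <- mismatch_from_diffs(dm[lower.tri(dm)])
    fit_b <- fit_expansion(obs_b, n = n, init = init)
    ssd_b[b] <- fit_b$ssd
    rag_b[b] <- fit_b$raggedness
    tau_b[b] <- fit_b$tau
    th0_b[b] <- fit_b$theta0
    th1_b[b] <- fit_b$theta1
  }
  ci <- rbind(lower = c(tau = stats::quantile(tau_b, 0.025, names = FALSE),
                        theta0 = stats::quantile(th0_b, 0.025, names = FALSE),
                        theta1 = stats::quantile(th1_b, 0.025, names = FALSE)),
              upper = c(tau = stats::quantile(tau_b, 0.975, names = FALSE),
                        theta0 = stats::quantile(th0_b, 0.975, names = FALSE),
                        theta1 = stats::quantile(th1_b, 0.975, names = FALSE)))
  fit$p_ssd <- mean(ssd_b >= fit$ssd)
  fit$p_raggedness <- mean(rag_b >= fit$raggedness)
  fit$ci <- ci
  fit$nboot <- nboot
  fit$seed <- seed
  fit
}
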