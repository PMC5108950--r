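one_pop_fixture <- function(codes, pop = "P") {
  m <- matrix(codes, ncol = 1,
              dimnames = list(paste0("i", seq_along(codes)), "rt1:1"))
  list(g = genotype_matrix(m),
       pm = setNames(rep(pop, length(codes)), rownames(m)))
}

test_that("per-locus population statistics match hand arithmetic", {
  fx <- one_pop_fixture(c(0L, 1L, 2L))  # AA, Aa, aa
  st <- locus_pop_stats(fx$g, fx$pm)
  row <- st$per_locus
  expect_equal(row$p_major, 0.5)
  expect_equal(row$hobs, 1 / 3)
  expect_equal(row$hexp, 0.5)
  expect_equal(row$pi, 0.6)           # (2n/(2n-1)) Hexp with n = 3
  expect_equal(row$fis, (0.6 - 1 / 3) / 0.6)
  # the unbiased correction links pi and Hexp exactly
  expect_equal(row$pi, row$hexp * 2 * row$n / (2 * row$n - 1))
})

test_that("monomorphic loci are excluded from per-population averages", {
  m <- cbind("rt1:1" = c(0L, 1L, 2L), "rt2:1" = c(0L, 0L, 0L))
  rownames(m) <- paste0("i", 1:3)
  g <- genotype_matrix(m)
  pm <- setNames(rep("P", 3), rownames(m))
  st <- locus_pop_stats(g, pm)
  expect_equal(st$summary$n_loci, 1L)
  expect_equal(st$summary$Hexp, 0.5)
})

test_that("heterozygote excess yields negative FIS", {
  fx <- one_pop_fixture(rep(1L, 8))
  st <- locus_pop_stats(fx$g, fx$pm)
  expect_equal(st$per_locus$hobs, 1)
  expect_lt(st$per_locus$fis, 0)
})

test_that("HWE exact test reproduces full enumeration", {
  h <- hwe_exact(1, 2, 1)
  expect_equal(unname(h$probs * 70), c(6, 48, 16))  # het counts 0, 2, 4
  expect_equal(h$p, 1)
  expect_equal(sum(h$probs), 1)

  h2 <- hwe_exact(0, 4, 0)
  expect_equal(h2$p, 22 / 70)

  expect_equal(hwe_exact(5, 0, 0)$p, 1)  # monomorphic

  # probabilities over all heterozygote classes sum to 1 on random draws
  set.seed(101)
  for (rep in 1:5) {
    counts <- as.vector(rmultinom(1, 25, c(0.3, 0.4, 0.3)))
    expect_equal(sum(hwe_exact(counts[1], counts[2], counts[3])$probs), 1)
  }
})

test_that("HWE p-values are roughly uniform under equilibrium", {
  set.seed(103)
  p <- replicate(300, {
    geno <- rbinom(80, 2, 0.4)
    hwe_exact(sum(geno == 0), sum(geno == 1), sum(geno == 2))$p
  })
  # exact-test p-values are discrete and conservative; check the bulk
  expect_gt(mean(p > 0.05), 0.90)
  expect_gt(mean(p < 0.6), 0.2)
})

test_that("Weir-Cockerham theta matches the variance-component algebra", {
  m <- matrix(c(2L, 2L, 0L, 0L), ncol = 1,
              dimnames = list(c("a1", "a2", "b1", "b2"), "rt1:1"))
  g <- genotype_matrix(m)
  pm <- setNames(c("A", "A", "B", "B"), rownames(m))
  res <- wc_fst(g, pm, "A", "B")
  expect_equal(res$theta, 1.0)
  expect_equal(unname(res$per_locus$a), 0.5)
  expect_equal(unname(res$per_locus$b), 0)
  expect_equal(unname(res$per_locus$c), 0)

  # identical allele frequencies and heterozygosity: theta about 0
  # (the unbiased estimator is slightly negative at finite sample size)
  m2 <- matrix(rep(c(0L, 1L, 1L, 2L), 10), ncol = 1)
  rownames(m2) <- paste0("i", 1:40)
  colnames(m2) <- "rt1:1"
  pm2 <- setNames(rep(c("A", "B"), each = 20), rownames(m2))
  res2 <- wc_fst(genotype_matrix(m2), pm2, "A", "B")
  expect_lt(res2$theta, 0)
  expect_lt(abs(res2$theta), 0.05)

  # multilocus theta equals per-locus theta with a single locus
  expect_equal(res$theta, res$per_locus$theta[1])
})

test_that("multilocus theta is a ratio of sums, not a mean of ratios", {
  set.seed(107)
  sim <- simulate_genotypes(c(A = 15, B = 15), n_loci = 50, F = 0.1)
  res <- wc_fst(sim$genotypes, sim$popmap, "A", "B")
  per <- res$per_locus
  ok <- !is.na(per$theta)
  ratio_of_sums <- sum(per$a[ok]) / sum((per$a + per$b + per$c)[ok])
  expect_equal(res$theta, ratio_of_sums)
  expect_false(isTRUE(all.equal(res$theta, mean(per$theta, na.rm = TRUE))))
})

test_that("G'ST and Jost's D hit their theoretical extremes", {
  m <- matrix(c(2L, 2L, 0L, 0L), ncol = 1,
              dimnames = list(c("a1", "a2", "b1", "b2"), "rt1:1"))
  pm <- setNames(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2"))
  gj <- gst_jost(genotype_matrix(m), pm, "A", "B")
  expect_equal(gj$gst_prime, 1)
  expect_equal(gj$jost_d, 1)

  # identical populations: near zero (unbiased estimators leave a small
  # negative finite-sample remainder)
  m2 <- matrix(rep(c(0L, 1L, 1L, 2L), 10), ncol = 1)
  rownames(m2) <- paste0("i", 1:40)
  colnames(m2) <- "rt1:1"
  pm2 <- setNames(rep(c("A", "B"), each = 20), rownames(m2))
  gj2 <- gst_jost(genotype_matrix(m2), pm2, "A", "B")
  expect_lt(abs(gj2$gst_prime), 0.05)
  expect_lt(abs(gj2$jost_d), 0.05)
})

test_that("G'ST / Jost's D agree with a straight-line re-implementation", {
  set.seed(109)
  sim <- simulate_genotypes(c(A = 12, B = 14), n_loci = 30, F = 0.15,
                            missing_rate = 0.1)
  gj <- gst_jost(sim$genotypes, sim$popmap, "A", "B")

  # independent oracle straight from the estimator definitions
  m <- unclass(sim$genotypes)
  pops <- sim$popmap[rownames(m)]
  hs_l <- ht_l <- rep(NA_real_, ncol(m))
  for (l in seq_len(ncol(m))) {
    ni <- pi_ <- hi <- numeric(2)
    for (k in 1:2) {
      x <- m[pops == c("A", "B")[k], l]
      x <- x[!is.na(x)]
      ni[k] <- length(x)
      pi_[k] <- sum(x) / (2 * length(x))
      hi[k] <- mean(x == 1)
    }
    if (any(ni == 0)) next
    ntil <- 2 / (1 / ni[1] + 1 / ni[2])
    hs <- (ntil / (ntil - 1)) *
      (mean(2 * pi_ * (1 - pi_)) - mean(hi) / (2 * ntil))
    pbar <- mean(pi_)
    ht <- 2 * pbar * (1 - pbar) + hs / (2 * ntil) - mean(hi) / (4 * ntil)
    hs_l[l] <- hs; ht_l[l] <- ht
  }
  HS <- mean(hs_l, na.rm = TRUE)
  HT <- mean(ht_l, na.rm = TRUE)
  gst <- (HT - HS) / HT
  expect_equal(gj$gst_prime, gst * (1 + HS) / (1 - HS), tolerance = 1e-12)
  expect_equal(gj$jost_d, 2 * (HT - HS) / (1 - HS), tolerance = 1e-12)
})

test_that("theta increases with the simulated Balding-Nichols F", {
  set.seed(113)
  thetas <- vapply(c(0.01, 0.05, 0.2), function(F) {
    sim <- simulate_genotypes(c(A = 25, B = 25), n_loci = 800, F = F)
    wc_fst(sim$genotypes, sim$popmap, "A", "B")$theta
  }, 0)
  expect_true(all(diff(thetas) > 0))
})

test_that("bootstrap CIs are seeded, degenerate-safe and validated", {
  set.seed(127)
  sim <- simulate_genotypes(c(A = 12, B = 12), n_loci = 40, F = 0.1)
  ci1 <- divergence_bootstrap_ci(sim$genotypes, sim$popmap, "A", "B",
                                 B = 50, seed = 7)
  ci2 <- divergence_bootstrap_ci(sim$genotypes, sim$popmap, "A", "B",
                                 B = 50, seed = 7)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_low <= ci1$estimate + 1e-9))
  expect_true(all(ci1$ci_high >= ci1$estimate - 1e-9))
  expect_error(divergence_bootstrap_ci(sim$genotypes, sim$popmap, "A", "B",
                                       B = 5), "at least 10")

  # identical loci: zero-width interval at the point estimate
  m <- matrix(rep(c(0L, 2L, 1L, 1L, 2L, 0L), 25), nrow = 6)
  rownames(m) <- paste0("i", 1:6)
  colnames(m) <- paste0("rt", 1:25, ":1")
  pm <- setNames(rep(c("A", "B"), each = 3), rownames(m))
  g <- genotype_matrix(m)
  suppressWarnings(ci3 <- divergence_bootstrap_ci(g, pm, "A", "B",
                                                  B = 20, seed = 1))
  expect_equal(ci3$ci_low, ci3$estimate)
  expect_equal(ci3$ci_high, ci3$estimate)
})

test_that("HWE screening excludes flagged loci from divergence", {
  set.seed(131)
  sim <- simulate_genotypes(c(A = 15, B = 15), n_loci = 30, F = 0.05)
  m <- unclass(sim$genotypes)
  m[, 1] <- 1L   # all heterozygotes in both populations: extreme HWE deviation
  g <- genotype_matrix(m, radtag = attr(sim$genotypes, "loci")$radtag,
                       pos = attr(sim$genotypes, "loci")$pos)
  scr <- hwe_screen(g, sim$popmap)
  expect_true(scr$flagged[1])
  res <- suppressMessages(pairwise_divergence(g, sim$popmap, B = 20,
                                              seed = 2))
  expect_equal(res$n_loci_used, ncol(g) - sum(scr$flagged))
})
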