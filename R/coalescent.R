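# Coalescent simulation engine.
#
# Time is measured in mutational units of 1/(2u) generations, so that the
# scaled mutation parameters theta0/theta1 and the expansion age tau are
# directly comparable across samples: k lineages coalesce at rate
# k(k-1)/(2 theta(s)) with theta(s) = theta1 for s < tau (the large,
# post-expansion epoch, seen first looking back in time) and theta0 for
# s >= tau; mutations fall at rate 1/2 per lineage per unit time.  A
# stationary population (tau = 0) then has mean pairwise difference theta
# and mismatch distribution theta^i / (1 + theta)^(i+1).

#' Coalescent genealogy under sudden demographic expansion
#'
#' Simulates a genealogy for `n` samples under the instantaneous-expansion
#' demography described above.  `tau = 0` gives a stationary population of
#' parameter `theta0`.  `theta0 = 0` makes all lineages surviving at time
#' `tau` coalesce instantaneously (a star phylogeny beyond `tau`).
#'
#' @param n sample size (>= 2).
#' @param theta0 scaled mutation parameter of the ancestral (pre-expansion)
#'   epoch.
#' @param tau expansion age in mutational units.
#' @param theta1 scaled mutation parameter after the expansion (used only
#'   when `tau > 0`; must then be positive).
#' @param seed RNG seed.
#' @return object of class `genealogy`: list with `n`, `edge` (2-column
#'   matrix parent/child over node ids; tips are `1..n`), `edge_length`
#'   (in mutational time units), `node_time`.
#' @export
simulate_genealogy <- function(n, theta0, tau = 0, theta1 = theta0, seed = NULL) {
  stopifnot(n >= 2, tau >= 0, theta0 >= 0)
  if (tau > 0 && theta1 <= 0)
    stop("theta1 must be positive when tau > 0 (no coalescence possible)")
  if (tau == 0 && theta0 <= 0)
    stop("stationary simulation requires theta0 > 0")
  if (!is.null(seed)) set.seed(seed)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  s <- 0
  k <- n
  while (k > 1L) {
    if (tau > 0 && s < tau) {
      t_wait <- stats::rexp(1L, rate = k * (k - 1L) / (2 * theta1))
      if (s + t_wait > tau) { s <- tau; next }  # memoryless epoch switch
      s <- s + t_wait
    } else {
      if (theta0 == 0) {
        s <- max(s, tau)                        # instantaneous coalescence
      } else {
        s <- s + stats::rexp(1L, rate = k * (k - 1L) / (2 * theta0))
      }
    }
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    parent[a] <- parent[b] <- nxt
    node_time[nxt] <- s
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  child <- which(parent > 0L)
  edge <- cbind(parent = parent[child], child = child)
  edge_length <- node_time[edge[, "parent"]] - node_time[edge[, "child"]]
  structure(list(n = n, edge = edge, edge_length = edge_length,
                 node_time = node_time),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", x$n, "tips, TMRCA =",
      format(max(x$node_time), digits = 4), "mutational units\n")
  invisible(x)
}

total_branch_length <- function(tree) sum(tree$edge_length)

# logical matrix: edges x tips, TRUE when tip descends from the edge's child
edge_descendants <- function(tree) {
  n <- tree$n
  n_nodes <- 2L * n - 1L
  desc <- matrix(FALSE, n_nodes, n)
  desc[cbind(seq_len(n), seq_len(n))] <- TRUE
  ord <- order(tree$node_time[tree$edge[, "child"]])  # children before parents
  for (i in ord) {
    p <- tree$edge[i, "parent"]; ch <- tree$edge[i, "child"]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  desc[tree$edge[, "child"], , drop = FALSE]
}

# render per-edge mutation counts as an alignment (infinite sites: one new
# site per mutation, ancestral base A, derived base drawn from C/G/T)
render_mutations <- function(tree, mut_per_edge, L) {
  n <- tree$n
  S <- sum(mut_per_edge)
  if (S > L)
    stop(S, " mutations exceed L = ", L,
         " available sites under infinite sites; increase L")
  m <- matrix("A", n, L)
  if (S > 0) {
    desc <- edge_descendants(tree)
    sites <- sample.int(L, S)
    derived <- sample(c("C", "G", "T"), S, replace = TRUE)
    idx <- 1L
    for (e in seq_along(mut_per_edge)) {
      cnt <- mut_per_edge[e]
      while (cnt > 0L) {
        m[desc[e, ], sites[idx]] <- derived[idx]
        idx <- idx + 1L
        cnt <- cnt - 1L
      }
    }
  }
  rownames(m) <- paste0("s", seq_len(n))
  seq_alignment(m)
}

#' Drop mutations on a genealogy (infinite sites)
#'
#' Mutations occur at rate 1/2 per lineage per unit of mutational time
#' (Poisson along each branch); each mutation hits a previously unmutated
#' site, whose derived state is carried by all tips below the branch.
#'
#' @param tree a [simulate_genealogy()] result.
#' @param L number of sites available (default 710).
#' @param seed RNG seed.
#' @return a [seq_alignment()] with `n` sequences.
#' @export
drop_mutations <- function(tree, L = 710L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mut <- stats::rpois(length(tree$edge_length), tree$edge_length / 2)
  render_mutations(tree, mut, L)
}

#' Simulate an alignment conditioned on the number of segregating sites
#'
#' Simulates a genealogy from the given demography and places exactly `S`
#' mutations on branches with probability proportional to branch length.
#'
#' @param n sample size.
#' @param S number of segregating sites to place.
#' @param theta0,tau,theta1 demography (see [simulate_genealogy()]).
#' @param L sites (must be >= S).
#' @param seed RNG seed.
#' @return a [seq_alignment()]; the per-branch placement counts are kept
#'   in the `mutations` attribute.
#' @export
simulate_fixed_s <- function(n, S, theta0 = 1, tau = 0, theta1 = theta0,
                             L = max(710L, S), seed = NULL) {
  stopifnot(S >= 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_genealogy(n, theta0 = theta0, tau = tau, theta1 = theta1)
  len <- tree$edge_length
  mut <- if (S > 0 && sum(len) > 0) {
    as.integer(stats::rmultinom(1L, S, prob = len / sum(len)))
  } else rep(0L, length(len))
  aln <- render_mutations(tree, mut, L)
  attr(aln, "mutations") <- mut
  aln
}

#' Simulate a sequence sample under the expansion model
#'
#' Convenience wrapper: genealogy plus infinite-sites mutations.
#'
#' @param n sample size.
#' @param theta0,tau,theta1 demography (see [simulate_genealogy()]).
#' @param L sites.
#' @param seed RNG seed.
#' @return a [seq_alignment()].
#' @export
simulate_sequences <- function(n, theta0, tau = 0, theta1 = theta0,
                               L = 710L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_genealogy(n, theta0 = theta0, tau = tau, theta1 = theta1)
  drop_mutations(tree, L = L)
}

# pairwise difference counts of a simulated sample without rendering
# sequences: d_ij = mutations on edges separating i and j
simulate_pairwise_diffs <- function(n, theta0, tau = 0, theta1 = theta0) {
  tree <- simulate_genealogy(n, theta0 = theta0, tau = tau, theta1 = theta1)
  mut <- stats::rpois(length(tree$edge_length), tree$edge_length / 2)
  d <- matrix(0L, n, n)
  if (any(mut > 0L)) {
    desc <- edge_descendants(tree)
    for (e in which(mut > 0L)) {
      in_e <- desc[e, ]
      d[in_e, !in_e] <- d[in_e, !in_e] + mut[e]
    }
    d <- d + t(d)  # counts were accumulated on one orientation only
  }
  round(d)
}

#' Simulate multi-population sequence samples
#'
#' Two regimes: with `divergence = 0` a single panmictic genealogy is
#' simulated for the pooled sample and population labels are arbitrary
#' (true differentiation is nil); with `divergence > 0` each population
#' receives an independent genealogy and, additionally, a
#' Poisson(`divergence`)-distributed number of population-private fixed
#' mutations, giving controllable between-population divergence.
#'
#' @param n_per_pop integer vector of population sample sizes (names used
#'   as population labels when present).
#' @param theta within-population scaled mutation parameter.
#' @param divergence expected number of fixed differences private to each
#'   population (0 = panmixia).
#' @param L sites.
#' @param seed RNG seed.
#' @return list with `alignment` and `popmap`.
#' @export
simulate_populations <- function(n_per_pop, theta, divergence = 0,
                                 L = 710L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- names(n_per_pop)
  if (is.null(labels)) labels <- paste0("pop", seq_along(n_per_pop))
  N <- sum(n_per_pop)
  pop_of <- rep(labels, n_per_pop)
  if (divergence == 0) {
    aln <- simulate_sequences(N, theta0 = theta, L = L)
  } else {
    per_pop <- lapply(n_per_pop, function(np)
      simulate_sequences(max(np, 2L), theta0 = theta, L = L)[seq_len(np), ])
    m <- matrix("A", N, L)
    row0 <- 0L
    site_pool <- sample.int(L)            # disjoint site blocks per population
    pool_idx <- 1L
    for (p in seq_along(per_pop)) {
      sub <- unclass(per_pop[[p]])
      np <- nrow(sub)
      seg <- which(apply(sub, 2L, function(col) length(unique(col)) > 1L))
      nfix <- stats::rpois(1L, divergence)
      need <- length(seg) + nfix
      if (pool_idx + need - 1L > L) stop("L too small for requested divergence")
      sites <- site_pool[seq.int(pool_idx, pool_idx + need - 1L)]
      pool_idx <- pool_idx + need
      if (length(seg))
        m[row0 + seq_len(np), sites[seq_along(seg)]] <- sub[, seg]
      if (nfix > 0L)
        m[row0 + seq_len(np), sites[length(seg) + seq_len(nfix)]] <-
          matrix(sample(c("C", "G", "T"), nfix, replace = TRUE),
                 np, nfix, byrow = TRUE)
      row0 <- row0 + np
    }
    rownames(m) <- paste0("s", seq_len(N))
    aln <- seq_alignment(m)
  }
  ids <- paste0(pop_of, "_", unlist(lapply(n_per_pop, seq_len)))
  rownames(aln) <- ids
  list(alignment = aln, popmap = stats::setNames(pop_of, ids))
}

#' Simulate diploid genotypes under the Balding-Nichols model
#'
#' Per locus an ancestral allele frequency is drawn uniformly from
#' `anc_range`; each population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (with `F = 0` meaning all populations
#' share `p` exactly), and genotypes are Binomial(2, p_k) counts of the
#' alternate allele.  Missing calls are masked independently at
#' `missing_rate`.  The expected Weir-Cockerham theta between populations
#' is approximately `F`.
#'
#' @param n_per_pop integer vector of per-population sample sizes.
#' @param n_loci number of biallelic loci.
#' @param F Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param anc_range range of the uniform ancestral-frequency draw.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return list with `genotypes` (a [genotype_matrix()]) and `popmap`.
#' @export
simulate_genotypes <- function(n_per_pop, n_loci, F = 0,
                               anc_range = c(0.05, 0.95),
                               missing_rate = 0, seed = NULL) {
  stopifnot(F >= 0, F < 1, missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- names(n_per_pop)
  if (is.null(labels)) labels <- paste0("pop", seq_along(n_per_pop))
  N <- sum(n_per_pop)
  pop_of <- rep(labels, n_per_pop)
  p_anc <- stats::runif(n_loci, anc_range[1], anc_range[2])
  m <- matrix(NA_integer_, N, n_loci)
  row0 <- 0L
  for (k in seq_along(n_per_pop)) {
    np <- n_per_pop[k]
    if (F == 0) {
      p_k <- p_anc
    } else {
      p_k <- stats::rbeta(n_loci, p_anc * (1 - F) / F,
                          (1 - p_anc) * (1 - F) / F)
    }
    m[row0 + seq_len(np), ] <- matrix(
      stats::rbinom(np * n_loci, 2L, rep(p_k, each = np)), np, n_loci)
    row0 <- row0 + np
  }
  if (missing_rate > 0) {
    mask <- stats::runif(length(m)) < missing_rate
    m[mask] <- NA_integer_
  }
  ids <- paste0(pop_of, "_", unlist(lapply(n_per_pop, seq_len)))
  rownames(m) <- ids
  colnames(m) <- paste0("rt", seq_len(n_loci), ":1")
  g <- genotype_matrix(m, radtag = paste0("rt", seq_len(n_loci)),
                       pos = rep(1L, n_loci))
  list(genotypes = g, popmap = stats::setNames(pop_of, ids))
}
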