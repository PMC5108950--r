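test_that("haplotype collapsing follows the complete-deletion rule", {
  expect_equal(length(collapse_haplotypes(
    seq_alignment(c("AAA", "AAA", "AAA")))$haplotypes), 1L)

  tab <- collapse_haplotypes(seq_alignment(c("AAT", "AAA", "AAA")))
  expect_equal(length(tab$haplotypes), 2L)
  expect_equal(sort(as.vector(tab$counts)), c(1L, 2L))

  # N at site 3 excludes the site for every sample -> one haplotype
  tab2 <- collapse_haplotypes(seq_alignment(c("AAN", "AAA")))
  expect_equal(length(tab2$haplotypes), 1L)
  expect_equal(tab2$used_sites, 1:2)

  expect_error(collapse_haplotypes(seq_alignment(c("NN", "AA"))), "usable")
})

test_that("haplotype diversity matches hand arithmetic and bounds", {
  expect_warning(h1 <- haplotype_diversity(c(1)), "undefined")
  expect_true(is.na(h1))
  expect_equal(haplotype_diversity(rep(1, 15)), 1.0)
  expect_equal(haplotype_diversity(c(2, 2)), (4 / 3) * (1 - 0.5))
  expect_equal(haplotype_diversity(c(15, 0, 0)), 0)
})

test_that("nucleotide diversity matches direct pairwise counting", {
  expect_equal(nucleotide_diversity(
    seq_alignment(c(strrep("A", 10), paste0(strrep("A", 9), "T")))), 0.1)
  expect_equal(nucleotide_diversity(seq_alignment(c("AAAA", "AAAA"))), 0)
  expect_equal(nucleotide_diversity(seq_alignment(c("AAA", "AAT", "ATT"))),
               (1 + 2 + 1) / 3 / 3)
})

test_that("diversity statistics are invariant under sample reordering", {
  set.seed(5)
  sim <- simulate_sequences(12, theta0 = 4, L = 200)
  perm <- sample(nrow(sim))
  shuffled <- sim[perm, ]
  expect_equal(nucleotide_diversity(sim), nucleotide_diversity(shuffled))
  expect_equal(sort(as.vector(collapse_haplotypes(sim)$counts)),
               sort(as.vector(collapse_haplotypes(shuffled)$counts)))
  m1 <- observed_mismatch(sim)
  m2 <- observed_mismatch(shuffled)
  expect_equal(m1$freq, m2$freq)
})

test_that("private haplotype counting respects group membership", {
  aln <- seq_alignment(c(a1 = "AAAA", a2 = "AAAT", b1 = "AAAA", b2 = "TTAA",
                         c1 = "TCAA"))
  pm <- setNames(c("A", "A", "B", "B", "C"), rownames(aln))
  tab <- collapse_haplotypes(aln, pm)
  # haplotypes: AAAA (A+B), AAAT (A), TTAA (B), TCAA (C)
  expect_equal(private_haplotypes(tab, "A"), 1L)
  expect_equal(private_haplotypes(tab, c("A", "B")), 3L)
  expect_equal(private_haplotypes(tab, c("A", "B", "C")), 4L)
  expect_error(private_haplotypes(tab, "Z"), "unknown")
})

test_that("rarefaction handles degenerate and saturated populations", {
  base <- strrep("A", 20)
  # population of exactly the subsample size: every replicate identical
  aln <- seq_alignment(setNames(rep(base, 5), paste0("x", 1:5)))
  pm <- setNames(rep("P", 5), rownames(aln))
  rr <- rarefy_diversity(aln, pm, size = 5, reps = 10, seed = 1)
  expect_equal(rr$se_haplotypes, 0)
  expect_equal(rr$mean_haplotypes, 1)
  expect_equal(rr$mean_h, 0)

  # all-distinct population: every subsample is all-distinct
  seqs <- vapply(1:30, function(i) {
    s <- rep("A", 40)
    s[i] <- "T"
    paste(s, collapse = "")
  }, "")
  aln2 <- seq_alignment(setNames(seqs, paste0("y", 1:30)))
  pm2 <- setNames(rep("Q", 30), rownames(aln2))
  rr2 <- rarefy_diversity(aln2, pm2, size = 15, reps = 10, seed = 1)
  expect_equal(rr2$mean_haplotypes, 15)
  expect_equal(rr2$mean_h, 1.0)

  # undersized populations are skipped with a warning
  pm3 <- setNames(c(rep("Q", 30), rep("tiny", 5)),
                  c(rownames(aln2), paste0("z", 1:5)))
  aln3 <- seq_alignment(setNames(c(seqs, rep(strrep("A", 40), 5)),
                                 names(pm3)))
  expect_warning(rarefy_diversity(aln3, pm3, size = 15, reps = 5, seed = 1),
                 "tiny")
  expect_error(rarefy_diversity(aln2, pm2, size = 1, reps = 5), "at least 2")
})

test_that("rarefaction is reproducible under a fixed seed", {
  set.seed(9)
  sim <- simulate_populations(c(P = 20, Q = 18), theta = 5, L = 300)
  r1 <- rarefy_diversity(sim$alignment, sim$popmap, size = 15, reps = 20,
                         seed = 77)
  r2 <- rarefy_diversity(sim$alignment, sim$popmap, size = 15, reps = 20,
                         seed = 77)
  expect_identical(r1, r2)
})

test_that("minimum spanning network matches the MST-membership rule", {
  # two haplotypes at distance 3: single edge of weight 3
  net <- minimum_spanning_network(collapse_haplotypes(
    seq_alignment(c("AAAA", "TTTA"))))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 3)

  # distances (1,1,2): the weight-2 edge closes a lighter cycle -> excluded
  net2 <- minimum_spanning_network(collapse_haplotypes(
    seq_alignment(c("AAAA", "AAAT", "AATT"))))
  expect_equal(nrow(net2$edges), 2L)
  expect_true(all(net2$edges$weight == 1))

  # single haplotype: no edges
  net3 <- minimum_spanning_network(collapse_haplotypes(
    seq_alignment(c("AAAA", "AAAA"))))
  expect_equal(nrow(net3$edges), 0L)
})

test_that("MSN equals the union of all MSTs by exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:6) {
    k <- sample(3:6, 1)
    L <- 12
    seqs <- replicate(k, paste(sample(c("A", "C"), L, replace = TRUE),
                               collapse = ""))
    while (anyDuplicated(seqs)) {
      seqs <- replicate(k, paste(sample(c("A", "C"), L, replace = TRUE),
                                 collapse = ""))
    }
    tab <- collapse_haplotypes(seq_alignment(seqs))
    net <- minimum_spanning_network(tab)
    d <- as.matrix(outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
      sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]]))))
    expected <- oracle_mst_union(d)
    hap_idx <- setNames(seq_len(k), names(tab$haplotypes))
    got <- t(apply(cbind(hap_idx[net$edges$from], hap_idx[net$edges$to]),
                   1L, sort))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(expected))
  }
})

test_that("MSN exports to edge-list TSV and GML", {
  tab <- collapse_haplotypes(seq_alignment(c("AAAA", "AAAT", "TTAA")))
  net <- minimum_spanning_network(tab)
  tsv <- tempfile(fileext = ".tsv")
  write_msn(net, tsv, "tsv")
  edges <- read.delim(tsv)
  expect_equal(nrow(edges), nrow(net$edges))
  gml <- tempfile(fileext = ".gml")
  write_msn(net, gml, "gml")
  txt <- readLines(gml)
  expect_equal(sum(grepl("node \\[", txt)), nrow(net$nodes))
  expect_equal(sum(grepl("edge \\[", txt)), nrow(net$edges))
})
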