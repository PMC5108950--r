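test_that("chimera filter removes exactly the motif-bearing reads", {
  reads <- as_read_set_fixture(c("ACGTACGTACGT",      # clean
                                 "AAAGAATTCAAA",      # EcoRI site
                                 "TTTTCCGGTTTT"))     # MspI site
  res <- filter_chimeric_reads(reads)
  expect_equal(res$reads$seq, "ACGTACGTACGT")
  expect_equal(res$report$input, 3L)
  expect_equal(res$report$removed, 2L)
  expect_equal(res$report$tallies$GAATTC, 1L)
  expect_equal(res$report$tallies$CCGG, 1L)
})

test_that("chimera filter retained fraction matches a constructed fixture", {
  clean <- replicate(7, paste(sample(c("A", "C", "G", "T"), 20,
                                     replace = TRUE), collapse = ""))
  # scrub any accidental motif occurrences so exactly 3 reads carry one
  clean <- gsub("GAATTC", "GAATAC", clean, fixed = TRUE)
  clean <- gsub("CCGG", "CCAG", clean, fixed = TRUE)
  dirty <- c("AAAAGAATTCAAAA", "TTTCCGGTTT", "GGGAATTCGG")
  reads <- as_read_set_fixture(c(clean, dirty))
  res <- filter_chimeric_reads(reads)
  expect_equal(res$report$retained, 7L)
  expect_equal(res$report$retained_frac, 0.7)
})

test_that("chimera filter equals a brute-force substring scan", {
  set.seed(11)
  seqs <- replicate(200, paste(sample(c("A", "C", "G", "T"), 30,
                                      replace = TRUE), collapse = ""))
  reads <- as_read_set_fixture(seqs)
  res <- filter_chimeric_reads(reads, motifs = c("GAATTC", "CCGG"))
  brute <- vapply(seqs, function(s) {
    hit <- FALSE
    for (m in c("GAATTC", "CCGG"))
      for (i in seq_len(nchar(s) - nchar(m) + 1L))
        if (substr(s, i, i + nchar(m) - 1L) == m) hit <- TRUE
    !hit
  }, TRUE)
  expect_equal(res$reads$seq, unname(seqs[brute]))
  expect_equal(res$report$retained, sum(brute))
})

test_that("chimera filter validates motifs and round-trips FASTQ", {
  reads <- as_read_set_fixture(c("ACGT"))
  expect_error(filter_chimeric_reads(reads, motifs = c("GAATTC", "")),
               "empty motif")
  path <- write_tmp_fastq(c("ACGTGAATTCAA", "TTTTACGT"))
  rs <- read_fastq(path)
  expect_equal(nrow(rs), 2L)
  expect_equal(nchar(rs$seq), nchar(rs$qual))
  out <- tempfile(fileext = ".fastq")
  write_fastq(rs, out)
  expect_identical(readLines(path), readLines(out))
})

test_that("first SNP per radtag keeps the smallest position", {
  m <- matrix(0L, nrow = 2, ncol = 3,
              dimnames = list(c("i1", "i2"), c("rt7:40", "rt7:12", "rt9:3")))
  g <- genotype_matrix(m, radtag = c("rt7", "rt7", "rt9"), pos = c(40L, 12L, 3L))
  out <- first_snp_per_locus(g)
  expect_equal(sort(colnames(out)), c("rt7:12", "rt9:3"))

  # identity on single-SNP radtags
  g2 <- genotype_matrix(matrix(0L, 2, 2), radtag = c("a", "b"), pos = c(1L, 1L))
  expect_equal(colnames(first_snp_per_locus(g2)), colnames(g2))

  # 5 radtags, 9 SNPs -> 5 loci
  set.seed(3)
  rt <- c("r1", "r1", "r2", "r3", "r3", "r3", "r4", "r5", "r5")
  pos <- c(5L, 2L, 1L, 9L, 4L, 7L, 1L, 8L, 3L)
  g3 <- genotype_matrix(matrix(0L, 3, 9,
                               dimnames = list(NULL, paste0(rt, ":", pos))),
                        radtag = rt, pos = pos)
  expect_equal(ncol(first_snp_per_locus(g3)), 5L)
})

test_that("missingness filter applies the 20% rule at the boundary", {
  m <- matrix(0L, nrow = 33, ncol = 2, dimnames = list(NULL, c("keep:1", "drop:1")))
  m[1:6, 1] <- NA        # 6/33 = 0.182 <= 0.2 -> retained
  m[1:7, 2] <- NA        # 7/33 = 0.212 > 0.2 -> removed
  res <- filter_missingness(genotype_matrix(m), max_missing_frac = 0.20)
  expect_equal(colnames(res$genotypes), "keep:1")
  expect_equal(res$report$removed, 1L)

  full <- genotype_matrix(matrix(1L, 5, 1))
  expect_equal(ncol(filter_missingness(full)$genotypes), 1L)
})

test_that("MAF filter uses strict frequency over non-missing copies", {
  # single heterozygous carrier among 33 individuals: MAF 1/66 -> removed
  single <- matrix(0L, 33, 1)
  single[1, 1] <- 1L
  res <- filter_maf(genotype_matrix(single), maf_threshold = 0.06)
  expect_equal(ncol(res$genotypes), 0L)

  # MAF exactly at the threshold is removed (strict inequality)
  at_thr <- matrix(0L, 50, 1)
  at_thr[1:6, 1] <- 1L   # 6/100 = 0.06
  expect_equal(ncol(filter_maf(genotype_matrix(at_thr), 0.06)$genotypes), 0L)

  # minor count 3 of 20 copies: MAF 0.15 -> retained
  keep <- matrix(0L, 10, 1)
  keep[1:3, 1] <- 1L
  expect_equal(ncol(filter_maf(genotype_matrix(keep), 0.06)$genotypes), 1L)

  # monomorphic loci are tallied separately
  mono <- genotype_matrix(matrix(2L, 10, 1))
  res2 <- filter_maf(mono)
  expect_equal(ncol(res2$genotypes), 0L)
  expect_equal(res2$report$tallies$monomorphic, 1L)
})

test_that("filter reports reconcile on random fixtures and order is fixed", {
  set.seed(21)
  for (rep in 1:5) {
    sim <- simulate_genotypes(c(A = 12, B = 11), n_loci = 40, F = 0.05,
                              missing_rate = 0.25)
    res <- suppressMessages(snp_filter_pipeline(sim$genotypes))
    for (r in res$reports) {
      expect_equal(r$input, r$retained + r$removed)
      expect_gte(r$retained_frac, 0)
      expect_lte(r$retained_frac, 1)
    }
    # pipeline chains: output of one step is input of the next
    expect_equal(res$reports$missingness$input, res$reports$first_snp$retained)
    expect_equal(res$reports$maf$input, res$reports$missingness$retained)
    expect_equal(ncol(res$genotypes), res$reports$maf$retained)
  }
})
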