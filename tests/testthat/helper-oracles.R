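# Independent oracles and fixture builders used across the test files.
# Every oracle here is a deliberately naive, straight-line implementation
# kept separate from the package code paths it checks.

# ---- Tajima's D, constant by constant (naive re-derivation) ----
oracle_tajima_d <- function(n, S, theta_pi) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# ---- Ewens sampling distribution by full polynomial expansion ----
# unsigned Stirling numbers |s(n, j)| as coefficients of
# x (x + 1) ... (x + n - 1); exact in double precision for small n
oracle_stirling <- function(n) {
  coef <- 1  # polynomial "1"
  for (m in 0:(n - 1)) {
    # multiply by (x + m): shift + scale
    coef <- c(0, coef) + m * c(coef, 0)
  }
  coef[-1]  # drop x^0 term (zero); entry j is |s(n, j)|
}

oracle_fu_fs <- function(n, k, theta) {
  st <- oracle_stirling(n)
  w <- st * theta^seq_len(n)
  w <- w / sum(w)  # rising factorial cancels in the normalisation
  s_prime <- sum(w[k:n])
  log(s_prime / (1 - s_prime))
}

# ---- union of all minimum spanning trees by exhaustive enumeration ----
# all spanning trees of the complete graph on k labelled nodes via
# Pruefer sequences (k^(k-2) trees, fine for k <= 6)
oracle_mst_union <- function(d) {
  k <- nrow(d)
  if (k == 2L) return(matrix(c(1, 2), ncol = 2))
  decode_pruefer <- function(pr) {
    k <- length(pr) + 2L
    degree <- rep(1L, k)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, k - 1L, 2L)
    for (i in seq_along(pr)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, pr[i])
      degree[leaf] <- degree[leaf] - 1L
      degree[pr[i]] <- degree[pr[i]] - 1L
    }
    edges[k - 1L, ] <- which(degree == 1L)
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2L)))
  best <- Inf
  union_edges <- NULL
  for (r in seq_len(nrow(seqs))) {
    ed <- decode_pruefer(as.integer(seqs[r, ]))
    w <- sum(d[ed])
    if (w < best - 1e-9) {
      best <- w
      union_edges <- ed
    } else if (abs(w - best) <= 1e-9) {
      union_edges <- rbind(union_edges, ed)
    }
  }
  uu <- unique(t(apply(union_edges, 1L, sort)))
  uu[order(uu[, 1], uu[, 2]), , drop = FALSE]
}

# ---- exhaustive Phi-ST permutation distribution ----
oracle_phist_perm_p <- function(d2, grp) {
  N <- length(grp)
  nA <- sum(grp == grp[1])
  obs <- panmix:::phist_from_d(d2, grp)
  combs <- utils::combn(N, nA)
  stat <- apply(combs, 2L, function(ia) {
    g <- rep("B", N)
    g[ia] <- "A"
    panmix:::phist_from_d(d2, g)
  })
  mean(stat >= obs - 1e-12)
}

# ---- small fixture builders ----
toy_tajima_alignment <- function() {
  seq_alignment(c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAT",
                  s3 = "AAAAAAAATT", s4 = "AAAAAAATTT"))
}

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_tmp_popmap <- function(popmap) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(names(popmap), unname(popmap), sep = "\t"), path)
  path
}

write_tmp_vcf <- function(alt, gt_rows, samples = paste0("s", seq_along(gt_rows[[1]]))) {
  # alt: character vector of ALT fields; gt_rows: list (per locus) of GT strings
  path <- tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(samples, collapse = "\t")))
  body <- vapply(seq_along(alt), function(i) {
    paste(c(paste0("rt", i), "10", ".", "A", alt[i], ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

as_read_set_fixture <- function(seqs, ids = paste0("r", seq_along(seqs))) {
  panmix:::as_read_set(data.frame(id = ids, seq = unname(seqs),
                                  qual = vapply(nchar(seqs),
                                                function(n) strrep("I", n), ""),
                                  stringsAsFactors = FALSE))
}

write_tmp_fastq <- function(seqs, ids = paste0("r", seq_along(seqs))) {
  path <- tempfile(fileext = ".fastq")
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  path
}
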