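#' Minimum spanning haplotype network
#'
#' Builds the union of all minimum spanning trees over haplotypes, with
#' edge weights equal to the Hamming distance (mutational steps) between
#' haplotype sequences over the compared sites.  An edge `(u, v, w)` is
#' included iff `u` and `v` are not connected using only edges of weight
#' strictly less than `w` --- exactly the condition for the edge to belong
#' to at least one minimum spanning tree --- so the network is connected,
#' deterministic, and contains every alternative equally-short connection.
#'
#' @param table a [collapse_haplotypes()] result.
#' @return object of class `msn`: list with `nodes` (data.frame `id`,
#'   `freq`) and `edges` (data.frame `from`, `to`, `weight`).
#' @export
minimum_spanning_network <- function(table) {
  haps <- table$haplotypes
  k <- length(haps)
  freq <- rowSums(table$counts)
  nodes <- data.frame(id = names(haps), freq = as.integer(freq),
                      stringsAsFactors = FALSE)
  if (k == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(),
                                             to = character(),
                                             weight = integer())),
                     class = "msn"))
  }
  m <- do.call(rbind, strsplit(unname(haps), "", fixed = TRUE))
  d <- matrix(0L, k, k)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ew <- d[upper.tri(d)]
  ord <- order(ew)
  pairs <- pairs[ord, , drop = FALSE]
  ew <- ew[ord]

  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }

  keep <- logical(length(ew))
  i <- 1L
  while (i <= length(ew)) {
    j <- i
    while (j <= length(ew) && ew[j] == ew[i]) j <- j + 1L
    block <- seq.int(i, j - 1L)
    roots <- cbind(vapply(pairs[block, 1L], find, 1L),
                   vapply(pairs[block, 2L], find, 1L))
    keep[block] <- roots[, 1L] != roots[, 2L]
    for (b in block[keep[block]]) {       # merge after deciding the block
      r1 <- find(pairs[b, 1L]); r2 <- find(pairs[b, 2L])
      if (r1 != r2) parent[r1] <- r2
    }
    i <- j
  }
  edges <- data.frame(from = names(haps)[pairs[keep, 1L]],
                      to = names(haps)[pairs[keep, 2L]],
                      weight = ew[keep], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "msn")
}

#' @export
print.msn <- function(x, ...) {
  cat("minimum spanning network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Export a minimum spanning network
#'
#' @param net an `msn` object.
#' @param path output path.
#' @param format `"tsv"` (edge list) or `"gml"`.
#' @export
write_msn <- function(net, path, format = c("tsv", "gml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    idx <- stats::setNames(seq_len(nrow(net$nodes)) - 1L, net$nodes$id)
    lines <- c("graph [")
    for (i in seq_len(nrow(net$nodes)))
      lines <- c(lines, "  node [",
                 paste0("    id ", idx[net$nodes$id[i]]),
                 paste0("    label \"", net$nodes$id[i], "\""),
                 paste0("    freq ", net$nodes$freq[i]), "  ]")
    for (i in seq_len(nrow(net$edges)))
      lines <- c(lines, "  edge [",
                 paste0("    source ", idx[net$edges$from[i]]),
                 paste0("    target ", idx[net$edges$to[i]]),
                 paste0("    weight ", net$edges$weight[i]), "  ]")
    lines <- c(lines, "]")
    writeLines(lines, path)
  }
  invisible(path)
}
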