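#' Aligned sequence sample
#'
#' A `seq_alignment` is a character matrix of aligned, equal-length DNA
#' sequences (one row per sample, one column per site) with unique sample
#' identifiers as row names.  Sites may contain `A`, `C`, `G`, `T`, the
#' ambiguity/missing code `N` or the gap character `-`.
#'
#' @param seqs character vector of equal-length sequence strings, or a
#'   character matrix of single characters.
#' @param ids sample identifiers, unique, same length as `seqs` (taken from
#'   names/rownames when `NULL`).
#' @return an object of class `seq_alignment`.
#' @export
seq_alignment <- function(seqs, ids = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(ids)) ids <- rownames(m)
  } else {
    if (is.null(ids)) ids <- names(seqs)
    seqs <- toupper(as.character(seqs))
    if (length(seqs) == 0L) stop("empty alignment")
    w <- nchar(seqs)
    if (length(unique(w)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(w), collapse = ", "), ")")
    if (w[1] == 0L) stop("alignment has zero sites")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(m)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated sample ids in alignment")
  bad <- !(m %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) m[bad] <- "N"  # unknown IUPAC codes treated as missing
  dimnames(m) <- list(ids, NULL)
  structure(m, class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", nrow(x), "sequences x", ncol(x), "sites\n")
  invisible(x)
}

n_samples <- function(aln) nrow(aln)
n_sites <- function(aln) ncol(aln)

#' @export
`[.seq_alignment` <- function(x, i, j, ...) {
  m <- unclass(x)[i, j, drop = FALSE]
  structure(m, class = "seq_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path path to a FASTA file of aligned sequences.
#' @return a [seq_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L)
    stop("ragged alignment in ", path, ": sequence lengths differ")
  ids <- sub("\\s.*$", "", names(ss))
  seq_alignment(as.character(ss), ids = ids)
}

#' Write an alignment as FASTA
#'
#' @param aln a [seq_alignment()].
#' @param path output path.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two tab-separated columns: sample id, population label.  Labels are
#' case-sensitive exact strings.
#'
#' @param path path to the TSV file (a header line `sample<TAB>population`
#'   is accepted and skipped).
#' @return named character vector mapping sample id to population.
#' @export
read_popmap <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          comment.char = "#")
  if (ncol(df) < 2L) stop("popmap must have two tab-separated columns")
  if (nrow(df) > 0L && identical(tolower(df[1, 1]), "sample"))
    df <- df[-1L, , drop = FALSE]
  pm <- as_popmap(stats::setNames(df[[2L]], df[[1L]]))
  pm
}

#' Write a sample-to-population map as TSV
#'
#' @param popmap named character vector (sample id to population).
#' @param path output path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(data.frame(sample = names(popmap),
                                population = unname(popmap)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

as_popmap <- function(x) {
  x <- stats::setNames(as.character(x), names(x))
  if (any(!nzchar(names(x))) || any(is.na(names(x))))
    stop("popmap contains empty sample ids")
  if (any(!nzchar(x)) || any(is.na(x)))
    stop("popmap contains empty population labels")
  if (anyDuplicated(names(x)))
    stop("popmap contains duplicated sample ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

#' Trim an alignment to a site window
#'
#' Windows are 0-based, half-open: `trim_start` is the index of the first
#' retained site and `trim_length` the number of retained sites, so the
#' window covers sites `[trim_start, trim_start + trim_length)`.
#'
#' @param aln a [seq_alignment()].
#' @param trim_start 0-based index of the first site kept.
#' @param trim_length number of sites kept.
#' @export
trim_alignment <- function(aln, trim_start = 0L, trim_length = ncol(aln) - trim_start) {
  stopifnot(trim_start >= 0, trim_length >= 1)
  if (trim_start + trim_length > ncol(aln))
    stop("trim window [", trim_start, ", ", trim_start + trim_length,
         ") exceeds alignment length ", ncol(aln))
  aln[, seq.int(trim_start + 1L, trim_start + trim_length)]
}

#' Load a COI-style sequence dataset with sample-level inclusion rules
#'
#' Reads an aligned FASTA and a population map, trims the alignment to a
#' fixed window, then applies two inclusion rules in a fixed order:
#' (1) samples with too much missing terminal sequence are dropped --- a
#' sample is removed when the fraction of `N`/`-` characters within the
#' terminal 10% of trimmed sites at *either* end exceeds
#' `max_terminal_missing_frac`; (2) populations left with fewer than
#' `min_pop_size` samples are removed entirely.  All drop decisions are
#' recorded in the `drops` attribute and emitted as messages.
#'
#' @param fasta_path aligned FASTA file.
#' @param popmap_path two-column TSV sample/population map; every retained
#'   sample id must be mapped (an unmapped id is an error naming the id).
#' @param trim_start,trim_length 0-based half-open trim window
#'   (see [trim_alignment()]).
#' @param min_pop_size minimum retained samples for a population to be kept.
#' @param max_terminal_missing_frac threshold on the missing fraction in
#'   each terminal window.
#' @return list with elements `alignment` (a [seq_alignment()]) and
#'   `popmap` (named character vector), plus a `drops` attribute
#'   (data.frame of id, reason).
#' @export
load_coi_dataset <- function(fasta_path, popmap_path,
                             trim_start = 0L, trim_length = NULL,
                             min_pop_size = 10L,
                             max_terminal_missing_frac = 0.5) {
  aln <- read_fasta_alignment(fasta_path)
  popmap <- read_popmap(popmap_path)
  if (is.null(trim_length)) trim_length <- ncol(aln) - trim_start
  aln <- trim_alignment(aln, trim_start, trim_length)

  unmapped <- setdiff(rownames(aln), names(popmap))
  if (length(unmapped))
    stop("sample id(s) missing from popmap: ", paste(unmapped, collapse = ", "))

  drops <- data.frame(id = character(), reason = character(),
                      stringsAsFactors = FALSE)

  L <- ncol(aln)
  tw <- max(1L, ceiling(0.1 * L))  # terminal window: 10% of trimmed sites
  is_missing <- unclass(aln) %in% c("N", "-")
  dim(is_missing) <- dim(aln)
  head_frac <- rowMeans(is_missing[, seq_len(tw), drop = FALSE])
  tail_frac <- rowMeans(is_missing[, seq.int(L - tw + 1L, L), drop = FALSE])
  drop_terminal <- head_frac > max_terminal_missing_frac |
    tail_frac > max_terminal_missing_frac
  if (any(drop_terminal)) {
    ids <- rownames(aln)[drop_terminal]
    drops <- rbind(drops, data.frame(id = ids, reason = "terminal_missing"))
    message("dropped ", length(ids), " sample(s) for missing terminal sequence: ",
            paste(ids, collapse = ", "))
    aln <- aln[!drop_terminal, ]
  }

  pops <- popmap[rownames(aln)]
  tab <- table(pops)
  small <- names(tab)[tab < min_pop_size]
  if (length(small)) {
    ids <- rownames(aln)[pops %in% small]
    drops <- rbind(drops, data.frame(id = ids, reason = "small_population"))
    warning("dropped population(s) with fewer than ", min_pop_size,
            " samples: ", paste(small, collapse = ", "), call. = FALSE)
    aln <- aln[!(pops %in% small), ]
  }
  if (nrow(aln) == 0L) stop("no samples retained after filtering")

  out <- list(alignment = aln, popmap = popmap[rownames(aln)])
  attr(out, "drops") <- drops
  out
}
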