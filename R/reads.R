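#' Read a FASTQ file
#'
#' @param path FASTQ file (gzip accepted).
#' @return data.frame with columns `id`, `seq`, `qual` (class `read_set`).
#' @export
read_fastq <- function(path) {
  # Biostrings emits an informational warning about dropped metadata
  # columns when wrapping the qualities; it is irrelevant here
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  qual <- as.character(Biostrings::quality(ss))
  rs <- data.frame(id = sub("\\s.*$", "", names(ss)),
                   seq = as.character(ss),
                   qual = qual,
                   stringsAsFactors = FALSE)
  as_read_set(rs)
}

as_read_set <- function(df) {
  stopifnot(all(c("id", "seq", "qual") %in% names(df)))
  if (any(nchar(df$seq) != nchar(df$qual)))
    stop("FASTQ record with sequence/quality length mismatch")
  class(df) <- c("read_set", "data.frame")
  df
}

#' Write a FASTQ file
#'
#' @param reads a `read_set` data.frame (`id`, `seq`, `qual`).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads)
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = n)] <- reads$seq
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Remove reads carrying restriction-site motifs (potential chimeras)
#'
#' In double-digest RAD libraries, a read whose internal sequence contains
#' a recognition site of either digestion enzyme is a potential
#' ligation-chimera junction.  A read is removed iff any motif occurs as an
#' exact substring of its sequence, scanning the read as sequenced
#' (forward orientation); set `scan_revcomp = TRUE` to also scan each
#' motif's reverse complement.
#'
#' @param reads a `read_set` data.frame.
#' @param motifs uppercase ACGT recognition motifs; defaults are the EcoRI
#'   (`GAATTC`) and MspI (`CCGG`) sites.
#' @param scan_revcomp also scan reverse-complement motifs (default off).
#' @return list with `reads` (retained `read_set`) and `report`
#'   (a [filter_report()] with per-motif tallies).
#' @export
filter_chimeric_reads <- function(reads, motifs = c("GAATTC", "CCGG"),
                                  scan_revcomp = FALSE) {
  motifs <- toupper(motifs)
  if (any(!nzchar(motifs))) stop("empty motif")
  if (any(grepl("[^ACGT]", motifs))) stop("motifs must be ACGT strings")
  scan <- motifs
  if (scan_revcomp) {
    rc <- vapply(motifs, function(m) {
      comp <- chartr("ACGT", "TGCA", m)
      paste(rev(strsplit(comp, "")[[1]]), collapse = "")
    }, "")
    scan <- unique(c(motifs, rc))
  }
  hit_by_motif <- vapply(scan, function(m) grepl(m, reads$seq, fixed = TRUE),
                         logical(nrow(reads)))
  if (nrow(reads) == 1L) hit_by_motif <- matrix(hit_by_motif, nrow = 1L)
  hit <- if (nrow(reads)) rowSums(hit_by_motif) > 0L else logical(0)
  tallies <- if (nrow(reads)) colSums(hit_by_motif) else
    stats::setNames(rep(0L, length(scan)), scan)
  report <- filter_report(input = nrow(reads), retained = sum(!hit),
                          rule = "chimera_motif", tallies = as.list(tallies))
  list(reads = as_read_set(reads[!hit, , drop = FALSE]), report = report)
}

#' Filter report
#'
#' Bookkeeping record for a filtering step: input, retained and removed
#' counts (which must reconcile), per-rule tallies and the retained
#' fraction.
#'
#' @param input,retained item counts before/after the filter.
#' @param rule name of the filtering rule.
#' @param tallies named list of per-sub-rule removal/hit counts.
#' @export
filter_report <- function(input, retained, rule, tallies = list()) {
  removed <- input - retained
  stopifnot(input >= 0, retained >= 0, removed >= 0)
  structure(list(rule = rule, input = input, retained = retained,
                 removed = removed,
                 retained_frac = if (input > 0) retained / input else NA_real_,
                 tallies = tallies),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter [%s]: %d in, %d retained, %d removed (%.1f%% retained)\n",
              x$rule, x$input, x$retained, x$removed, 100 * x$retained_frac))
  if (length(x$tallies))
    cat("  tallies:", paste(names(x$tallies), unlist(x$tallies),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(rule = x$rule, input = x$input, retained = x$retained,
             removed = x$removed, retained_frac = x$retained_frac)
}
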