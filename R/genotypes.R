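#' Biallelic genotype matrix
#'
#' Individuals x loci integer matrix with codes 0/1/2 counting copies of
#' the designated alternate allele and `NA` for missing calls.  Each locus
#' carries a radtag (locus-of-origin) identifier and a SNP position within
#' that radtag, stored in the `loci` attribute.
#'
#' @param mat integer matrix (individuals x loci); values 0, 1, 2 or NA.
#' @param radtag,pos per-locus radtag id and within-radtag SNP position;
#'   recycled defaults treat each column as its own single-SNP radtag.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(mat, radtag = NULL, pos = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  vals <- mat[!is.na(mat)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(colnames(mat)) && ncol(mat) > 0L)
    colnames(mat) <- paste0("L", seq_len(ncol(mat)))
  if (anyDuplicated(colnames(mat))) stop("duplicated locus ids")
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("i", seq_len(nrow(mat)))
  if (is.null(radtag)) radtag <- colnames(mat)
  if (is.null(pos)) pos <- rep(1L, ncol(mat))
  stopifnot(length(radtag) == ncol(mat), length(pos) == ncol(mat))
  loci <- data.frame(locus = colnames(mat), radtag = as.character(radtag),
                     pos = as.integer(pos), stringsAsFactors = FALSE)
  structure(mat, loci = loci, class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x), "individuals x", ncol(x), "loci (",
      sum(is.na(x)), "missing calls )\n")
  invisible(x)
}

loci_info <- function(g) attr(g, "loci")

subset_loci <- function(g, keep) {
  li <- loci_info(g)[keep, , drop = FALSE]
  m <- unclass(g)[, keep, drop = FALSE]
  genotype_matrix(m, radtag = li$radtag, pos = li$pos)
}

#' Load a biallelic genotype matrix from VCF or TSV
#'
#' For VCF only the GT field is consulted; phasing separators are ignored
#' and `.` or `./.` is missing.  Records with more than one ALT allele are
#' rejected.  Radtag id and SNP position are taken from CHROM and POS.
#' The TSV layout is: header `sample` followed by locus columns named
#' `radtag:pos` (a bare name is treated as a single-SNP radtag), one row
#' per individual, cells 0/1/2 with `NA` or `.` for missing.
#'
#' @param path input file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return a [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") .load_genotypes_vcf(path) else .load_genotypes_tsv(path)
}

.load_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("non-biallelic locus (multiple ALT alleles) at ",
         paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (i in seq_len(nrow(gt))) {
    x <- gt[i, ]
    y <- unname(lookup[x])
    unknown <- !is.na(x) & x != "." & x != "./." & is.na(y)
    if (any(unknown))
      stop("unsupported GT value '", x[unknown][1], "' at locus ",
           fix[i, "CHROM"], ":", fix[i, "POS"])
    code[, i] <- y
  }
  rownames(code) <- colnames(gt)
  colnames(code) <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  genotype_matrix(code, radtag = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

.load_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty genotype TSV: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  nloc <- length(header) - 1L
  if (nloc < 1L) stop("genotype TSV has no locus columns")
  ids <- character(length(lines) - 1L)
  code <- matrix(NA_integer_, nrow = length(lines) - 1L, ncol = nloc)
  for (r in seq_along(ids)) {
    f <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != nloc + 1L)
      stop("malformed genotype TSV row at line ", r + 1L, ": expected ",
           nloc + 1L, " fields, found ", length(f))
    ids[r] <- f[1]
    cell <- f[-1]
    cell[cell %in% c("NA", ".", "")] <- NA
    val <- suppressWarnings(as.integer(cell))
    bad <- which(!is.na(cell) & (is.na(val) | val < 0L | val > 2L))
    if (length(bad))
      stop("malformed genotype '", cell[bad[1]], "' at line ", r + 1L,
           ", locus ", header[bad[1] + 1L])
    code[r, ] <- val
  }
  locus_ids <- header[-1]
  parts <- strsplit(locus_ids, ":", fixed = TRUE)
  radtag <- vapply(parts, `[`, "", 1L)
  pos <- vapply(parts, function(p) {
    if (length(p) >= 2L) suppressWarnings(as.integer(p[2])) else 1L
  }, 1L)
  pos[is.na(pos)] <- 1L
  rownames(code) <- ids
  colnames(code) <- locus_ids
  genotype_matrix(code, radtag = radtag, pos = pos)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [load_genotypes()] with `format = "tsv"`; the round trip
#' reproduces genotype codes exactly.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_tsv <- function(g, path) {
  li <- loci_info(g)
  header <- paste(c("sample", paste0(li$radtag, ":", li$pos)), collapse = "\t")
  body <- vapply(seq_len(nrow(g)), function(r) {
    cell <- unclass(g)[r, ]
    cell <- ifelse(is.na(cell), "NA", as.character(cell))
    paste(c(rownames(g)[r], cell), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
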