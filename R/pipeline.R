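# End-to-end orchestration of the COI (sequence) and SNP tracks, with a
# YAML-serializable configuration, explicit seeds, and report tables.

#' Default pipeline configuration
#'
#' The analysis-scale defaults (trim 710 sites, minimum population size
#' 10, rarefaction 30 x 15, 10 000 permutations and bootstrap replicates,
#' 100 across-locus bootstraps, MAF 0.06, missingness 0.20) match common
#' practice for COI/ddRADseq population studies; every value can be
#' reduced for desk-scale runs.
#'
#' @param ... overrides for individual entries.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    trim_start = 0L, trim_length = 710L,
    min_pop_size = 10L, max_terminal_missing_frac = 0.5,
    rarefaction_size = 15L, rarefaction_reps = 30L,
    nperm = 10000L,      # Phi-ST permutations
    nboot = 10000L,      # mismatch parametric bootstrap
    nsim = 10000L,       # neutrality null simulations
    B = 100L,            # across-locus bootstrap replicates
    maf_threshold = 0.06, max_missing_frac = 0.20,
    hwe_alpha = 0.05,
    seed = 1L)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file.
#' @return named list (read) or invisible path (write).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- default_config()
  out[names(cfg)] <- cfg
  out
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

run_manifest <- function(config, out_dir) {
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- c(
    paste0("panmix_version: ",
           as.character(utils::packageVersion("panmix"))),
    paste0("config_md5: ", unname(tools::md5sum(cfg_path))),
    paste0("seed: ", config$seed),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}

#' Run the COI (sequence) analysis track
#'
#' load -> haplotype collapsing -> diversity + rarefaction -> neutrality
#' tests -> mismatch/expansion analysis -> pairwise Phi-ST with BH
#' correction -> minimum spanning network, with all tables written to
#' `out_dir`.  Any stage failure aborts with a stage-named error.
#'
#' @param fasta_path,popmap_path inputs (see [load_coi_dataset()]); a
#'   preloaded dataset can be passed via `dataset` instead.
#' @param out_dir output directory.
#' @param config configuration list (see [default_config()]).
#' @param dataset optional list with `alignment` and `popmap`, bypassing
#'   file loading.
#' @return invisible list with all stage results (`diversity`,
#'   `rarefaction`, `neutrality`, `mismatch`, `phist`, `msn`, `files`).
#' @export
run_coi_pipeline <- function(fasta_path = NULL, popmap_path = NULL,
                             out_dir, config = default_config(),
                             dataset = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("COI pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- stage("load", {
    if (is.null(dataset)) {
      load_coi_dataset(fasta_path, popmap_path,
                       trim_start = config$trim_start,
                       trim_length = config$trim_length,
                       min_pop_size = config$min_pop_size,
                       max_terminal_missing_frac = config$max_terminal_missing_frac)
    } else dataset
  })
  aln <- ds$alignment
  popmap <- ds$popmap
  pops <- unique(popmap[rownames(aln)])

  tab <- stage("collapse", collapse_haplotypes(aln, popmap))
  diversity <- stage("diversity", {
    rows <- lapply(pops, function(p) {
      ids <- rownames(aln)[popmap[rownames(aln)] == p]
      sub <- aln[ids, ]
      cnt <- tab$counts[, p]
      data.frame(population = p, n = length(ids),
                 n_haplotypes = sum(cnt > 0),
                 haplotype_diversity = haplotype_diversity(cnt),
                 nucleotide_diversity = nucleotide_diversity(sub))
    })
    do.call(rbind, rows)
  })
  rarefaction <- stage("rarefaction",
    rarefy_diversity(aln, popmap, size = config$rarefaction_size,
                     reps = config$rarefaction_reps,
                     seed = config$seed))

  mm_rows <- list()
  neutrality <- list()
  mismatch <- list()
  for (p in pops) {
    ids <- rownames(aln)[popmap[rownames(aln)] == p]
    sub <- aln[ids, ]
    nt <- stage(paste0("neutrality:", p),
                neutrality_test(sub, nsim = config$nsim,
                                seed = config$seed))
    fit <- stage(paste0("mismatch:", p), {
      f <- fit_expansion(observed_mismatch(sub), n = length(ids))
      bootstrap_tests(f, nboot = config$nboot, seed = config$seed)
    })
    neutrality[[p]] <- nt
    mismatch[[p]] <- fit
    mm_rows[[p]] <- data.frame(
      population = p,
      tau = fit$tau, tau_low = fit$ci["lower", "tau"],
      tau_high = fit$ci["upper", "tau"],
      theta0 = fit$theta0, theta0_low = fit$ci["lower", "theta0"],
      theta0_high = fit$ci["upper", "theta0"],
      theta1 = fit$theta1, theta1_low = fit$ci["lower", "theta1"],
      theta1_high = fit$ci["upper", "theta1"],
      SSD = fit$ssd, p_SSD = fit$p_ssd,
      raggedness = fit$raggedness, p_raggedness = fit$p_raggedness,
      tajimas_D = nt$D, p_D = nt$p_D, fus_Fs = nt$Fs, p_Fs = nt$p_Fs)
  }
  mm_table <- do.call(rbind, c(mm_rows, list(make.row.names = FALSE)))

  phist <- if (length(pops) >= 2L) {
    stage("phist", phist_matrix(aln, popmap, nperm = config$nperm,
                                seed = config$seed))
  } else NULL
  msn <- stage("msn", minimum_spanning_network(tab))

  files <- write_report_tables(
    list(diversity = diversity, mismatch_neutrality = mm_table,
         phist = if (!is.null(phist)) as.data.frame(phist)),
    out_dir)
  write_tsv(rarefaction, file.path(out_dir, "rarefaction.tsv"))
  write_msn(msn, file.path(out_dir, "msn_edges.tsv"), format = "tsv")
  run_manifest(config, out_dir)
  invisible(list(alignment = aln, popmap = popmap, haplotypes = tab,
                 diversity = diversity, rarefaction = rarefaction,
                 neutrality = neutrality, mismatch = mismatch,
                 mismatch_table = mm_table, phist = phist, msn = msn,
                 files = files))
}

#' Run the SNP analysis track
#'
#' load -> first SNP per radtag -> missingness -> MAF -> HWE screen ->
#' per-population statistics -> pairwise FST / G'ST / Jost's D with
#' across-locus bootstrap CIs, with tables written to `out_dir`.
#'
#' @param genotype_path input VCF/TSV (see [load_genotypes()]); a
#'   preloaded [genotype_matrix()] can be passed via `genotypes`.
#' @param popmap_path popmap TSV; or pass `popmap` directly.
#' @param out_dir output directory.
#' @param config configuration list.
#' @param genotypes,popmap optional preloaded inputs.
#' @return invisible list with stage results (`filters`, `stats`,
#'   `divergence`, `files`).
#' @export
run_snp_pipeline <- function(genotype_path = NULL, popmap_path = NULL,
                             out_dir, config = default_config(),
                             genotypes = NULL, popmap = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("SNP pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- stage("load", if (is.null(genotypes)) load_genotypes(genotype_path)
                     else genotypes)
  pm <- stage("load", if (is.null(popmap)) read_popmap(popmap_path)
                      else popmap)
  flt <- stage("filters",
               snp_filter_pipeline(g, max_missing_frac = config$max_missing_frac,
                                   maf_threshold = config$maf_threshold))
  g <- flt$genotypes
  if (ncol(g) == 0L)
    stop("SNP pipeline aborted: no loci survive the filter chain", call. = FALSE)
  stats_ <- stage("pop_stats", locus_pop_stats(g, pm))
  div <- stage("divergence",
               pairwise_divergence(g, pm, B = config$B,
                                   hwe_alpha = config$hwe_alpha,
                                   seed = config$seed))
  fst_ci <- div$table[, c("popA", "popB", "statistic", "estimate",
                          "ci_low", "ci_high", "significant", "B")]
  files <- write_report_tables(
    list(snp_summary = stats_$summary, fst_ci = fst_ci), out_dir)
  audit <- merge(stats_$per_locus,
                 if (is.null(div$hwe)) data.frame(locus = colnames(g),
                                                  min_p = NA, flagged = FALSE)
                 else div$hwe, by = "locus")
  write_tsv(audit, file.path(out_dir, "locus_audit.tsv"))
  run_manifest(config, out_dir)
  invisible(list(genotypes = g, popmap = pm, filters = flt$reports,
                 stats = stats_, divergence = div, files = files))
}
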