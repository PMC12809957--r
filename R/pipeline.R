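#' Run the full diversity and structure pipeline
#'
#' Orchestrates pedigree metrics, subgroup summaries, founder/ancestor
#' analyses, effective population size, genotype QC, genomic inbreeding and
#' flock structure from a single configuration, producing a structured
#' report. Stages that need genotypes are marked `skipped` when no
#' genotypes are configured.
#'
#' Configuration entries (a named list, or a YAML file path):
#' \describe{
#'   \item{pedigree}{path to a pedigree CSV, or a `ped_table`}
#'   \item{genotypes}{optional PLINK prefix, or a `geno_ds`}
#'   \item{subgroups}{optional list: `recent_years` (length-2 range),
#'     `min_complete_generations`, `genotyped_ids` (path or vector)}
#'   \item{pci_depth}{ancestral depth for completeness (default 5)}
#'   \item{qc}{list of [qc_params()] arguments}
#'   \item{roh}{list of [roh_params()] arguments}
#'   \item{hbd}{list of [hbd_params()] arguments}
#'   \item{fst}{list: `n_boot`}
#'   \item{pca}{list: `max_per_flock`, `n_replicates`}
#'   \item{seed}{integer seed used for every stochastic step}
#'   \item{output_dir}{optional directory for TSV/JSON output}
#' }
#'
#' @param config named list or YAML path
#' @return list of class `flockdiv_report`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  report <- list(config = config, seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ped <- stage("pedigree", {
    if (inherits(config$pedigree, "ped_table")) config$pedigree
    else read_pedigree(config$pedigree)
  })

  gm <- stage("generation metrics", generation_metrics(ped))
  pci <- stage("completeness", pedigree_completeness(ped, config$pci_depth %||% 5L))
  gi <- stage("generation intervals", generation_intervals(ped))
  F <- stage("inbreeding", inbreeding_ml(ped))
  ar <- stage("average relatedness", average_relatedness(ped, F))

  sgdef <- config$subgroups %||% list()
  genotyped_ids <- NULL
  if (!is.null(sgdef$genotyped_ids)) {
    genotyped_ids <- if (length(sgdef$genotyped_ids) == 1L &&
                         file.exists(sgdef$genotyped_ids[[1L]]))
      readLines(sgdef$genotyped_ids[[1L]]) else as.character(sgdef$genotyped_ids)
  }
  subgroups <- stage("subgroups", {
    sg <- list(full = ped$id)
    if (!is.null(sgdef$recent_years)) {
      sg$sg1 <- build_subgroup(ped, "birth_years", years = sgdef$recent_years)
      sg$sg2 <- build_subgroup(ped, "complete_generations", base = sg$sg1,
                               min_complete = sgdef$min_complete_generations %||% 4L,
                               metrics = gm)
      sg$sg4 <- build_subgroup(ped, "sires_of", base = sg$sg1)
    }
    if (!is.null(genotyped_ids))
      sg$sg3 <- build_subgroup(ped, "id_list", ids = genotyped_ids)
    sg
  })

  report$diversity_by_subgroup <- stage("subgroup diversity", {
    do.call(rbind, lapply(names(subgroups), function(nm) {
      ids <- subgroups[[nm]]
      ri <- match(ids, ped$id)
      fc <- founder_contributions(ped, reference = ids)
      ma <- marginal_ancestors(ped, reference = ids)
      g <- gci(ped)
      data.frame(subgroup = nm, n = length(ids),
                 mean_f = mean(F[ri]), mean_ar = mean(ar[ri]),
                 mean_max_gen = mean(gm$max_generations[ri]),
                 mean_complete_gen = mean(gm$complete_generations[ri]),
                 mean_equiv_gen = mean(gm$equivalent_complete_generations[ri]),
                 mean_pci = mean(pci$pci[ri]),
                 f_e = fc$f_e, f_a = ma$f_a, fe_fa_ratio = fc$f_e / ma$f_a,
                 mean_gci = mean(g[ri]), n_50 = ma$n_50,
                 stringsAsFactors = FALSE)
    }))
  })

  report$generation_intervals <- gi
  report$top_ancestors <- stage("top ancestors", {
    ref <- subgroups$sg1 %||% ped$id
    ma <- marginal_ancestors(ped, reference = ref, max_ancestors = 10L)
    ma$ancestors
  })
  L <- if (!gi$flagged) gi$L else config$generation_interval %||% NA_real_
  report$delta_f <- stage("delta F trend", {
    if (is.na(L)) flagged(reason = "no generation interval available")
    else delta_f_trend(F, ped$birth_year, L)
  })
  report$ne_pedigree <- stage("pedigree Ne", {
    ref <- subgroups$sg1 %||% ped$id
    ne_summary(ped, L = L, reference = ref)
  })
  report$ped_fst <- stage("pedigree FST", {
    if (length(unique(ped$flock[!is.na(ped$flock)])) >= 2L)
      pedigree_fst_nei(ped)
    else flagged(reason = "fewer than 2 flocks in pedigree")
  })

  if (is.null(config$genotypes)) {
    report$genomic <- "skipped"
  } else {
    gd <- stage("genotype input", {
      if (inherits(config$genotypes, "geno_ds")) config$genotypes
      else read_plink(config$genotypes)
    })
    qc <- stage("QC", do.call(qc_pipeline,
                              c(list(gd = gd, ped = ped),
                                list(params = do.call(qc_params, config$qc %||% list())))))
    report$qc <- qc$report

    report$maf_spectrum <- stage("MAF spectrum", maf_spectrum(qc$full))
    het <- stage("heterozygosity",
                 heterozygosity(qc$reduced, by = qc$reduced$samples$flock))
    report$heterozygosity <- het

    roh_p <- do.call(roh_params, config$roh %||% list())
    segs <- stage("ROH", detect_roh(qc$full, roh_p))
    froh <- stage("F_ROH", f_roh(segs, qc$full))
    report$roh <- list(segments = segs, f_roh = froh)

    hbd_p <- do.call(hbd_params, config$hbd %||% list())
    hbd <- stage("HBD", hbd_posterior(qc$full, hbd_p))
    report$hbd <- hbd

    grm <- stage("GRM", grm_vanraden1(qc$reduced))
    report$f_grm <- grm$f_grm

    report$ld_decay <- stage("LD decay", ld_decay(qc$ld))
    report$ne_ld <- stage("LD Ne", ne_ld(qc$reduced, seed = seed))

    report$inbreeding_table <- stage("inbreeding table", {
      ids <- qc$full$samples$id
      inbreeding_table(f_ped = F[intersect(names(F), ids)],
                       f_ind = het$f_ind, roh = froh, f_grm = grm$f_grm,
                       f_hbd = hbd$f_hbd)
    })
    report$inbreeding_correlations <- stage("inbreeding correlations",
      inbreeding_correlations(report$inbreeding_table))

    fst_cfg <- config$fst %||% list()
    report$fst <- stage("genomic FST",
      pairwise_fst(qc$reduced, n_boot = fst_cfg$n_boot %||% 100L, seed = seed))
    pca_cfg <- config$pca %||% list()
    report$pca <- stage("PCA",
      pca_with_subsampling(qc$reduced,
                           max_per_flock = pca_cfg$max_per_flock %||% 30L,
                           n_replicates = pca_cfg$n_replicates %||% 5L,
                           seed = seed))
  }

  class(report) <- "flockdiv_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits TSV tables for the tabular sections and a JSON summary (including
#' the seed and configuration for reproducibility).
#'
#' @param report a `flockdiv_report`
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(report$diversity_by_subgroup, "diversity_by_subgroup")
  wtsv(report$top_ancestors, "top_ancestors")
  wtsv(report$ne_pedigree, "ne_pedigree")
  if (!is.null(report$heterozygosity) && !is.null(report$heterozygosity$groups))
    wtsv(report$heterozygosity$groups, "heterozygosity_by_flock")
  if (!is.null(report$inbreeding_table))
    wtsv(report$inbreeding_table, "inbreeding_table")
  if (!is.null(report$roh)) wtsv(as.data.frame(report$roh$segments), "roh_segments")
  summary <- list(
    seed = report$seed,
    generation_interval = if (!report$generation_intervals$flagged)
      report$generation_intervals$L else NA,
    ne_pedigree = report$ne_pedigree,
    ne_ld = if (!is.null(report$ne_ld)) report$ne_ld$ne else NULL,
    mean_fst = if (!is.null(report$fst)) report$fst$mean_fst else NULL)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}

#' @export
print.flockdiv_report <- function(x, ...) {
  cat("<flockdiv_report>\n")
  cat("  subgroups:\n")
  print(x$diversity_by_subgroup)
  if (!x$generation_intervals$flagged)
    cat(sprintf("  generation interval L = %.2f years\n", x$generation_intervals$L))
  cat("  pedigree Ne:\n")
  print(x$ne_pedigree)
  if (is.character(x$genomic %||% "")) {
    if (identical(x$genomic, "skipped")) cat("  genomic sections: skipped\n")
  }
  if (!is.null(x$ne_ld))
    cat(sprintf("  LD-method Ne = %.1f\n", x$ne_ld$ne))
  if (!is.null(x$fst))
    cat(sprintf("  mean flock FST = %.4f\n", x$fst$mean_fst))
  invisible(x)
}
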