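#' Quality-control parameters
#'
#' @param animal_call_rate minimum fraction of non-missing genotypes per
#'   animal (animals strictly below are removed)
#' @param snp_call_rate markers with call rate strictly above this are kept
#' @param maf_min markers with MAF below this are removed from the reduced
#'   and LD variants
#' @param ld_r2 r-squared threshold for pruning
#' @param ld_window_snps,ld_step sliding-window size and step for pruning
#' @param autosomes integer vector of autosomal chromosome codes
#' @return list of class `qc_params`
#' @export
qc_params <- function(animal_call_rate = 0.90, snp_call_rate = 0.90,
                      maf_min = 0.01, ld_r2 = 0.5, ld_window_snps = 50L,
                      ld_step = 5L, autosomes = 1:26) {
  structure(list(animal_call_rate = animal_call_rate,
                 snp_call_rate = snp_call_rate, maf_min = maf_min,
                 ld_r2 = ld_r2, ld_window_snps = as.integer(ld_window_snps),
                 ld_step = as.integer(ld_step), autosomes = as.integer(autosomes)),
            class = "qc_params")
}

#' Genotype quality control producing the three analysis dataset variants
#'
#' Stages, in order: (1) if a pedigree is supplied, remove animals whose
#' sire or dam is unrecorded; (2) remove animals with call rate below the
#' threshold; (3) keep autosomal markers with call rate above the threshold;
#' (4) LD-prune the surviving markers (pairwise r-squared within sliding
#' windows) to give the *full* variant; (5) drop markers with
#' MAF < `maf_min` from the full variant to give the *reduced* variant;
#' (6) drop markers with MAF < `maf_min` from the stage-3 output, without LD
#' pruning, to give the *LD* variant (used for linkage-disequilibrium decay,
#' where pruning would defeat the purpose).
#'
#' @param gd a [genotype_dataset()]
#' @param params a [qc_params()]
#' @param ped optional [ped_table()] used for the unknown-parentage filter
#' @return list with `full`, `reduced`, `ld` (each a `geno_ds`) and `report`
#'   (class `qc_report`)
#' @export
qc_pipeline <- function(gd, params = qc_params(), ped = NULL) {
  stopifnot(inherits(gd, "geno_ds"))
  n0 <- nrow(gd$geno); m0 <- ncol(gd$geno)
  report <- list(input = list(samples = n0, markers = m0))

  ## stage 1: unknown parentage
  drop_parentage <- 0L
  if (!is.null(ped)) {
    rows <- match(gd$samples$id, ped$id)
    unknown <- is.na(rows) | is.na(ped$sire[rows]) | is.na(ped$dam[rows])
    drop_parentage <- sum(unknown)
    if (all(unknown)) stop("QC stage 'parentage' removed all animals", call. = FALSE)
    gd <- subset_geno(gd, samples = which(!unknown))
  }
  report$removed_parentage <- drop_parentage

  ## stage 2: animal call rate
  cr <- rowMeans(!is.na(gd$geno))
  low <- cr < params$animal_call_rate
  report$removed_animal_callrate <- sum(low)
  if (all(low)) stop("QC stage 'animal call rate' removed all animals", call. = FALSE)
  gd <- subset_geno(gd, samples = which(!low))
  report$retained_samples <- nrow(gd$geno)

  ## stage 3: autosomal markers with call rate above threshold
  autosomal <- gd$map$chrom %in% params$autosomes
  mcr <- colMeans(!is.na(gd$geno))
  keep3 <- autosomal & mcr > params$snp_call_rate
  report$removed_nonautosomal <- sum(!autosomal)
  report$removed_snp_callrate <- sum(autosomal & mcr <= params$snp_call_rate)
  if (!any(keep3)) stop("QC stage 'marker call rate' removed all markers", call. = FALSE)
  base <- subset_geno(gd, markers = which(keep3))

  ## stage 4: LD pruning -> full
  full <- ld_prune(base, r2_threshold = params$ld_r2,
                   window_snps = params$ld_window_snps, step = params$ld_step)
  report$removed_ld_prune <- ncol(base$geno) - ncol(full$geno)
  report$full_markers <- ncol(full$geno)
  if (ncol(full$geno) == 0L) stop("QC stage 'LD prune' removed all markers", call. = FALSE)

  ## stage 5: full minus rare -> reduced
  rare_full <- .maf(full) < params$maf_min
  reduced <- subset_geno(full, markers = which(!rare_full))
  report$removed_maf_reduced <- sum(rare_full)
  report$reduced_markers <- ncol(reduced$geno)
  if (ncol(reduced$geno) == 0L) stop("QC stage 'MAF (reduced)' removed all markers", call. = FALSE)

  ## stage 6: stage-3 output minus rare, unpruned -> LD variant
  rare_base <- .maf(base) < params$maf_min
  ldds <- subset_geno(base, markers = which(!rare_base))
  report$removed_maf_ld <- sum(rare_base)
  report$ld_markers <- ncol(ldds$geno)
  if (ncol(ldds$geno) == 0L) stop("QC stage 'MAF (LD)' removed all markers", call. = FALSE)

  class(report) <- "qc_report"
  list(full = full, reduced = reduced, ld = ldds, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input: %d samples x %d markers\n", x$input$samples, x$input$markers))
  cat(sprintf("  animals removed: %d unknown parentage, %d low call rate -> %d retained\n",
              x$removed_parentage, x$removed_animal_callrate, x$retained_samples))
  cat(sprintf("  markers removed: %d non-autosomal, %d low call rate, %d LD-pruned\n",
              x$removed_nonautosomal, x$removed_snp_callrate, x$removed_ld_prune))
  cat(sprintf("  variants: full %d, reduced %d (-%d rare), LD %d (-%d rare)\n",
              x$full_markers, x$reduced_markers, x$removed_maf_reduced,
              x$ld_markers, x$removed_maf_ld))
  invisible(x)
}

#' Prune markers in high linkage disequilibrium
#'
#' Sliding windows of `window_snps` markers advance by `step` within each
#' chromosome. Within a window, while any surviving pair has squared dosage
#' correlation above the threshold, the member of the worst pair with the
#' lower MAF is removed (tie: the later position). The rule is deterministic
#' for a given input.
#'
#' @param gd a [genotype_dataset()]
#' @param r2_threshold pairs with r-squared strictly above this are split
#' @param window_snps window width in markers
#' @param step window advance in markers
#' @return a pruned `geno_ds`
#' @export
ld_prune <- function(gd, r2_threshold = 0.5, window_snps = 50L, step = 5L) {
  stopifnot(inherits(gd, "geno_ds"))
  m <- ncol(gd$geno)
  keep <- rep(TRUE, m)
  maf <- .maf(gd)
  for (cc in unique(gd$map$chrom)) {
    jj <- which(gd$map$chrom == cc)
    if (length(jj) < 2L) next
    starts <- unique(c(seq(1L, max(1L, length(jj) - 1L), by = step)))
    for (st in starts) {
      win <- jj[st:min(st + window_snps - 1L, length(jj))]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      X <- gd$geno[, win, drop = FALSE]
      r2 <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      diag(r2) <- 0
      repeat {
        w <- which(r2 > r2_threshold, arr.ind = TRUE)
        if (!nrow(w)) break
        w <- w[w[, 1L] < w[, 2L], , drop = FALSE]
        if (!nrow(w)) break
        ## worst pair first, deterministic order
        o <- order(-r2[w], w[, 1L], w[, 2L])
        pair <- w[o[1L], ]
        i1 <- win[pair[[1L]]]; i2 <- win[pair[[2L]]]
        drop_local <- if (maf[i1] < maf[i2]) pair[[1L]]
          else if (maf[i2] < maf[i1]) pair[[2L]]
          else pair[[2L]] # tie: later position
        keep[win[drop_local]] <- FALSE
        r2[drop_local, ] <- 0; r2[, drop_local] <- 0
      }
    }
  }
  subset_geno(gd, markers = which(keep))
}

#' Intersect genotype datasets on shared markers
#'
#' Markers are matched by chromosome and position. Allele labels are
#' reconciled against the first dataset: direct match, swapped labels
#' (dosage flipped to 2 - g), strand flip (A<->T, C<->G complement), or
#' swapped strand flip; markers that cannot be reconciled are dropped and
#' listed in the `dropped` attribute. Samples are concatenated with a
#' `source` column.
#'
#' @param dsets list of [genotype_dataset()] objects
#' @param sources character labels per dataset (defaults to ds1, ds2, ...)
#' @return a merged `geno_ds` with attribute `dropped` (data frame of
#'   irreconcilable markers)
#' @export
intersect_datasets <- function(dsets, sources = NULL) {
  stopifnot(is.list(dsets), length(dsets) >= 2L)
  if (is.null(sources)) sources <- paste0("ds", seq_along(dsets))
  keyof <- function(gd) paste(gd$map$chrom, gd$map$bp, sep = ":")
  keys <- Reduce(intersect, lapply(dsets, keyof))
  if (!length(keys)) stop("empty marker intersection", call. = FALSE)
  ref <- dsets[[1L]]
  ridx <- match(keys, keyof(ref))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- function(a) ifelse(a %in% names(comp), comp[a], a)
  genos <- vector("list", length(dsets))
  dropped <- character(0)
  ok <- rep(TRUE, length(keys))
  for (k in seq_along(dsets)) {
    gd <- dsets[[k]]
    mi <- match(keys, keyof(gd))
    g <- gd$geno[, mi, drop = FALSE]
    a1 <- gd$map$a1[mi]; a2 <- gd$map$a2[mi]
    r1 <- ref$map$a1[ridx]; r2a <- ref$map$a2[ridx]
    direct <- a1 == r1 & a2 == r2a
    swapped <- a1 == r2a & a2 == r1
    strand <- flip(a1) == r1 & flip(a2) == r2a
    strand_sw <- flip(a1) == r2a & flip(a2) == r1
    g[, which(swapped & !direct)] <- 2L - g[, which(swapped & !direct), drop = FALSE]
    g[, which(strand_sw & !direct & !swapped & !strand)] <-
      2L - g[, which(strand_sw & !direct & !swapped & !strand), drop = FALSE]
    bad <- !(direct | swapped | strand | strand_sw)
    ok <- ok & !bad
    genos[[k]] <- g
  }
  if (!any(ok)) stop("no markers with reconcilable alleles", call. = FALSE)
  dropped <- keys[!ok]
  geno <- do.call(rbind, lapply(genos, function(g) g[, ok, drop = FALSE]))
  samples <- do.call(rbind, lapply(seq_along(dsets), function(k) {
    sm <- dsets[[k]]$samples
    sm$source <- sources[[k]]
    sm
  }))
  map <- ref$map[ridx[ok], , drop = FALSE]
  out <- genotype_dataset(geno, map, samples)
  attr(out, "dropped") <- dropped
  out
}
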