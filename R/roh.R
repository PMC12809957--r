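#' Runs-of-homozygosity detection parameters
#'
#' Defaults follow common practice for medium-density livestock arrays: a
#' 50-SNP sliding window allowing at most one heterozygous and one missing
#' call (roughly a 3% per-window error allowance), a minimum run of 30 SNPs
#' and 1 Mb, a maximum within-run gap of 250 kb, and a window-support
#' threshold of 0.05.
#'
#' @param window_snps sliding-window width in SNPs
#' @param min_length_bp minimum segment length
#' @param max_gap_bp maximum gap between adjacent SNPs inside a segment
#' @param min_snps minimum SNPs per segment
#' @param max_missing_in_window,max_het_in_window allowances per window
#' @param window_threshold minimum fraction of covering windows that must be
#'   homozygous-compliant for a SNP to join a run (strict >)
#' @return list of class `roh_params`
#' @export
roh_params <- function(window_snps = 50L, min_length_bp = 1e6,
                       max_gap_bp = 2.5e5, min_snps = 30L,
                       max_missing_in_window = 1L, max_het_in_window = 1L,
                       window_threshold = 0.05) {
  stopifnot(window_snps >= 1, min_length_bp > 0, max_gap_bp > 0, min_snps >= 1,
            max_missing_in_window >= 0, max_het_in_window >= 0,
            window_threshold > 0, window_threshold <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 min_length_bp = min_length_bp, max_gap_bp = max_gap_bp,
                 min_snps = as.integer(min_snps),
                 max_missing_in_window = as.integer(max_missing_in_window),
                 max_het_in_window = as.integer(max_het_in_window),
                 window_threshold = window_threshold),
            class = "roh_params")
}

#' Detect runs of homozygosity by sliding windows
#'
#' Windows of `window_snps` advance one SNP at a time along each chromosome.
#' A window is homozygous-compliant when it contains at most
#' `max_het_in_window` heterozygous and `max_missing_in_window` missing
#' calls. Each SNP is scored by the fraction of windows covering it that
#' are compliant; SNPs scoring strictly above `window_threshold` are
#' run-eligible. Maximal stretches of eligible SNPs are split wherever the
#' gap between adjacent SNPs exceeds `max_gap_bp`, then retained as segments
#' if they span at least `min_length_bp` and contain at least `min_snps`
#' SNPs. Chromosomes with fewer SNPs than one window are skipped (recorded
#' in the `skipped_chromosomes` attribute).
#'
#' @param gd a [genotype_dataset()]
#' @param params a [roh_params()]
#' @return data frame of class `roh_set` with columns `id`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp`, `class` (1-6, >6-12,
#'   >12-24, >24 Mb)
#' @export
detect_roh <- function(gd, params = roh_params()) {
  stopifnot(inherits(gd, "geno_ds"), inherits(params, "roh_params"))
  W <- params$window_snps
  segs <- list()
  skipped <- integer(0)
  n <- nrow(gd$geno)
  for (cc in unique(gd$map$chrom)) {
    jj <- which(gd$map$chrom == cc)
    M <- length(jj)
    if (M < W) { skipped <- c(skipped, cc); next }
    G <- gd$geno[, jj, drop = FALSE]
    bp <- gd$map$bp[jj]
    elig <- .roh_eligible(G, params)      # n x M logical
    gapsplit <- c(FALSE, diff(bp) > params$max_gap_bp)
    for (i in seq_len(n)) {
      runs <- .eligible_runs(elig[i, ], gapsplit)
      if (!nrow(runs)) next
      len <- bp[runs[, 2L]] - bp[runs[, 1L]]
      nsnp <- runs[, 2L] - runs[, 1L] + 1L
      ok <- len >= params$min_length_bp & nsnp >= params$min_snps
      if (!any(ok)) next
      segs[[length(segs) + 1L]] <- data.frame(
        id = gd$samples$id[i], chrom = cc,
        start_bp = bp[runs[ok, 1L]], end_bp = bp[runs[ok, 2L]],
        n_snps = nsnp[ok], length_bp = len[ok], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(id = character(0), chrom = integer(0), start_bp = numeric(0),
               end_bp = numeric(0), n_snps = integer(0), length_bp = numeric(0),
               stringsAsFactors = FALSE)
  out$class <- .roh_class(out$length_bp)
  attr(out, "skipped_chromosomes") <- skipped
  class(out) <- c("roh_set", "data.frame")
  out
}

## per-SNP run eligibility for all animals on one chromosome
.roh_eligible <- function(G, params) {
  n <- nrow(G); M <- ncol(G); W <- params$window_snps
  het <- (G == 1L); het[is.na(het)] <- FALSE
  mis <- is.na(G)
  cs_h <- cbind(0L, t(apply(het, 1L, cumsum)))
  cs_m <- cbind(0L, t(apply(mis, 1L, cumsum)))
  nw <- M - W + 1L
  wi <- seq_len(nw)
  het_w <- cs_h[, wi + W, drop = FALSE] - cs_h[, wi, drop = FALSE]
  mis_w <- cs_m[, wi + W, drop = FALSE] - cs_m[, wi, drop = FALSE]
  comp <- (het_w <= params$max_het_in_window) &
          (mis_w <= params$max_missing_in_window)
  ## windows covering SNP j: w in [max(1, j-W+1), min(nw, j)]
  cs_c <- cbind(0L, t(apply(comp, 1L, cumsum)))
  lo <- pmax(1L, seq_len(M) - W + 1L)
  hi <- pmin(nw, seq_len(M))
  cover <- hi - lo + 1L
  ncomp <- cs_c[, hi + 1L, drop = FALSE] - cs_c[, lo, drop = FALSE]
  sweep(ncomp, 2L, cover, "/") > params$window_threshold
}

## maximal TRUE runs, split at positions where gapsplit is TRUE
.eligible_runs <- function(e, gapsplit) {
  brk <- e & c(TRUE, !e[-length(e)] | gapsplit[-1L])
  # run starts where eligibility begins anew or a gap splits
  starts <- which(e & (c(TRUE, !e[-length(e)]) | gapsplit))
  if (!length(starts)) return(matrix(integer(0), 0L, 2L))
  ends <- integer(length(starts))
  nexts <- c(starts[-1L], length(e) + 1L)
  for (k in seq_along(starts)) {
    j <- starts[k]
    while (j + 1L < nexts[k] && e[j + 1L] && !gapsplit[j + 1L]) j <- j + 1L
    ends[k] <- j
  }
  cbind(starts, ends)
}

.roh_class <- function(len) {
  cut(len / 1e6, breaks = c(0, 6, 12, 24, Inf),
      labels = c("1-6", ">6-12", ">12-24", ">24"), right = TRUE)
}

#' Genomic inbreeding from runs of homozygosity
#'
#' F_ROH per animal is the summed ROH length divided by the autosomal length
#' covered by the marker map (sum over chromosomes of last minus first SNP
#' position). Per-class components use the segment length classes and sum
#' exactly to the total.
#'
#' @param segs a `roh_set` from [detect_roh()]
#' @param gd the [genotype_dataset()] the segments were detected on
#' @return data frame: `id`, `n_segments`, `f_roh`, `f_roh_1_6`,
#'   `f_roh_6_12`, `f_roh_12_24`, `f_roh_gt24`
#' @export
f_roh <- function(segs, gd) {
  stopifnot(inherits(gd, "geno_ds"))
  denom <- sum(tapply(gd$map$bp, gd$map$chrom, function(x) max(x) - min(x)))
  ids <- gd$samples$id
  cls <- c("1-6", ">6-12", ">12-24", ">24")
  colnm <- c("f_roh_1_6", "f_roh_6_12", "f_roh_12_24", "f_roh_gt24")
  out <- data.frame(id = ids, n_segments = 0L, f_roh = 0,
                    stringsAsFactors = FALSE)
  for (cn in colnm) out[[cn]] <- 0
  if (nrow(segs)) {
    tot <- tapply(segs$length_bp, segs$id, sum)
    cntseg <- tapply(segs$length_bp, segs$id, length)
    i <- match(names(tot), ids)
    out$f_roh[i] <- as.numeric(tot) / denom
    out$n_segments[i] <- as.integer(cntseg)
    for (k in seq_along(cls)) {
      sel <- segs$class == cls[k]
      if (any(sel)) {
        tt <- tapply(segs$length_bp[sel], segs$id[sel], sum)
        out[[colnm[k]]][match(names(tt), ids)] <- as.numeric(tt) / denom
      }
    }
  }
  out
}
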