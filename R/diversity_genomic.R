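#' Minor allele frequency spectrum
#'
#' MAF per marker from non-missing genotypes, binned as [0, w], (w, 2w], ...,
#' (0.5 - w, 0.5] for bin width w.
#'
#' @param gd a [genotype_dataset()]
#' @param bin_width bin width (default 0.05)
#' @return data frame with `bin`, `lower`, `upper`, `count`, `proportion`
#' @export
maf_spectrum <- function(gd, bin_width = 0.05) {
  stopifnot(inherits(gd, "geno_ds"), bin_width > 0, bin_width <= 0.5)
  maf <- .maf(gd)
  breaks <- seq(0, 0.5, by = bin_width)
  if (max(breaks) < 0.5) breaks <- c(breaks, 0.5)
  cuts <- cut(maf, breaks = breaks, include.lowest = TRUE)
  cnt <- as.integer(table(cuts))
  data.frame(bin = levels(cuts),
             lower = breaks[-length(breaks)], upper = breaks[-1L],
             count = cnt, proportion = cnt / length(maf),
             stringsAsFactors = FALSE)
}

#' Heterozygosity and heterozygosity-based inbreeding
#'
#' Population statistics: expected heterozygosity H_E (mean over markers of
#' 2p(1-p)), observed heterozygosity H_O (overall heterozygote fraction),
#' and Nei's non-biased heterozygosity Hnb (H_E with the per-marker
#' small-sample factor 2n/(2n-1)). Per animal, the heterozygosity-based
#' inbreeding coefficient is F_IND = (H_E - H_O,i)/H_E, with H_O,i the
#' animal's own heterozygote fraction over its non-missing markers. Per
#' group (e.g. flock or country), Wright's F_IS = 1 - H_O,g / Hnb,g where
#' both terms are computed within the group.
#'
#' @param gd a [genotype_dataset()]
#' @param by optional grouping vector along samples (e.g. flock); per-group
#'   H_E/Hnb/H_O/F_IS are then reported
#' @return list of class `het_summary`: `H_E`, `H_O`, `Hnb`, `f_ind` (named,
#'   per animal), `mean_f_ind`, and `groups` (data frame or NULL)
#' @export
heterozygosity <- function(gd, by = NULL) {
  stopifnot(inherits(gd, "geno_ds"))
  stat <- .het_stats(gd$geno)
  if (stat$n_poly == 0L)
    return(structure(list(H_E = 0, H_O = stat$H_O, Hnb = 0,
                          f_ind = rep(NA_real_, nrow(gd$geno)),
                          mean_f_ind = NA_real_, groups = NULL,
                          flagged = TRUE,
                          reason = "all markers monomorphic"),
                     class = "het_summary"))
  het_i <- rowMeans(gd$geno == 1L, na.rm = TRUE)
  f_ind <- (stat$H_E - het_i) / stat$H_E
  names(f_ind) <- gd$samples$id
  groups <- NULL
  if (!is.null(by)) {
    by <- as.character(by)
    gl <- sort(unique(by[!is.na(by)]))
    groups <- do.call(rbind, lapply(gl, function(g) {
      sub <- gd$geno[!is.na(by) & by == g, , drop = FALSE]
      st <- .het_stats(sub)
      data.frame(group = g, n = nrow(sub), H_E = st$H_E, Hnb = st$Hnb,
                 H_O = st$H_O,
                 F_IS = if (st$Hnb > 0) 1 - st$H_O / st$Hnb else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(H_E = stat$H_E, H_O = stat$H_O, Hnb = stat$Hnb,
                 f_ind = f_ind, mean_f_ind = mean(f_ind, na.rm = TRUE),
                 groups = groups, flagged = FALSE),
            class = "het_summary")
}

.het_stats <- function(geno) {
  nn <- colSums(!is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  he_m <- 2 * p * (1 - p)
  valid <- nn > 0L
  H_E <- mean(he_m[valid])
  hnb_m <- ifelse(nn > 0L, 2 * nn / pmax(2 * nn - 1, 1), NA) * he_m
  Hnb <- mean(hnb_m[valid])
  H_O <- mean(geno == 1L, na.rm = TRUE)
  list(H_E = H_E, Hnb = Hnb, H_O = H_O,
       n_poly = sum(valid & p > 0 & p < 1))
}

#' @export
print.het_summary <- function(x, ...) {
  cat(sprintf("<het_summary> H_E = %.4f, Hnb = %.4f, H_O = %.4f, mean F_IND = %.4f\n",
              x$H_E, x$Hnb, x$H_O, x$mean_f_ind))
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' Linkage disequilibrium decay with physical distance
#'
#' Squared Pearson correlation of dosages over all within-chromosome marker
#' pairs up to `max_dist_bp`, binned by distance, plus a separate summary of
#' adjacent-marker pairs (mean distance and mean r-squared).
#'
#' @param gd a [genotype_dataset()]
#' @param max_dist_bp maximum pair distance considered
#' @param bin_width_bp distance bin width
#' @return list of class `ld_decay`: `bins` (data frame with `dist_mid`,
#'   `n_pairs`, `mean_r2`), `adjacent` (`mean_dist_bp`, `mean_r2`, `n_pairs`)
#' @export
ld_decay <- function(gd, max_dist_bp = 1e7, bin_width_bp = 2.5e5) {
  stopifnot(inherits(gd, "geno_ds"))
  dist_all <- numeric(0); r2_all <- numeric(0)
  adj_d <- numeric(0); adj_r2 <- numeric(0)
  for (cc in unique(gd$map$chrom)) {
    jj <- which(gd$map$chrom == cc)
    if (length(jj) < 2L) next
    X <- gd$geno[, jj, drop = FALSE]
    r2 <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))^2
    bp <- gd$map$bp[jj]
    dd <- abs(outer(bp, bp, "-"))
    ut <- upper.tri(dd)
    sel <- ut & dd <= max_dist_bp
    dist_all <- c(dist_all, dd[sel]); r2_all <- c(r2_all, r2[sel])
    adj <- cbind(seq_len(length(jj) - 1L), 2:length(jj))
    adj_d <- c(adj_d, bp[adj[, 2L]] - bp[adj[, 1L]])
    adj_r2 <- c(adj_r2, r2[adj])
  }
  keep <- !is.na(r2_all)
  dist_all <- dist_all[keep]; r2_all <- r2_all[keep]
  bin <- floor(dist_all / bin_width_bp)
  agg <- tapply(r2_all, bin, mean)
  cnt <- tapply(r2_all, bin, length)
  bins <- data.frame(dist_mid = (as.integer(names(agg)) + 0.5) * bin_width_bp,
                     n_pairs = as.integer(cnt), mean_r2 = as.numeric(agg))
  keep_adj <- !is.na(adj_r2)
  structure(list(bins = bins,
                 adjacent = list(mean_dist_bp = mean(adj_d[keep_adj]),
                                 mean_r2 = mean(adj_r2[keep_adj]),
                                 n_pairs = sum(keep_adj))),
            class = "ld_decay")
}

#' Assemble a per-animal inbreeding-coefficient table
#'
#' Joins the available per-animal estimates by id. Any argument may be NULL.
#'
#' @param f_ped named vector of pedigree F
#' @param f_ind named vector from [heterozygosity()]
#' @param roh data frame from [f_roh()] (per-animal totals and classes)
#' @param f_grm named vector from [grm_vanraden1()]
#' @param f_hbd named vector from [hbd_posterior()]
#' @return data frame, one row per animal, class `inbreeding_table`
#' @export
inbreeding_table <- function(f_ped = NULL, f_ind = NULL, roh = NULL,
                             f_grm = NULL, f_hbd = NULL) {
  pieces <- list()
  if (!is.null(f_ped)) pieces$F_PED <- f_ped
  if (!is.null(f_ind)) pieces$F_IND <- f_ind
  if (!is.null(f_grm)) pieces$F_GRM <- f_grm
  if (!is.null(f_hbd)) pieces$F_HBD <- f_hbd
  ids <- unique(c(unlist(lapply(pieces, names)), if (!is.null(roh)) roh$id))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (nm in names(pieces)) out[[nm]] <- unname(pieces[[nm]][match(ids, names(pieces[[nm]]))])
  if (!is.null(roh)) {
    ri <- match(ids, roh$id)
    out$F_ROH <- roh$f_roh[ri]
    for (cl in grep("^f_roh_", names(roh), value = TRUE))
      out[[toupper(cl)]] <- roh[[cl]][ri]
  }
  class(out) <- c("inbreeding_table", "data.frame")
  out
}

#' Pearson correlations among inbreeding coefficients
#'
#' Pairwise-complete Pearson correlations among the numeric columns of an
#' [inbreeding_table()]. Zero-variance columns yield `NA` entries and are
#' listed in the `flagged_columns` attribute rather than failing silently.
#'
#' @param tbl an [inbreeding_table()] (or any data frame with an `id` column
#'   and numeric estimate columns)
#' @return correlation matrix with attribute `flagged_columns`
#' @export
inbreeding_correlations <- function(tbl) {
  num <- tbl[, setdiff(names(tbl), "id"), drop = FALSE]
  num <- num[, vapply(num, is.numeric, TRUE), drop = FALSE]
  if (nrow(num) < 3L) stop("need at least 3 animals", call. = FALSE)
  sds <- vapply(num, stats::sd, 1, na.rm = TRUE)
  flag <- names(num)[!is.na(sds) & sds == 0]
  cm <- suppressWarnings(stats::cor(as.matrix(num), use = "pairwise.complete.obs"))
  attr(cm, "flagged_columns") <- flag
  cm
}
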