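#' Effective population size from the regression of F on a generation metric
#'
#' Ordinary least squares of individual inbreeding on the chosen pedigree
#' depth metric; the slope b estimates the per-generation increase in F and
#' Ne = 1/(2b). A non-positive slope gives a flagged (undefined) result.
#'
#' @param F inbreeding coefficients
#' @param metric per-animal generation metric (maximum, complete, or
#'   equivalent complete generations)
#' @return list with `ne`, `slope`, and `flagged`
#' @export
ne_regression_on_generations <- function(F, metric) {
  ok <- !is.na(F) & !is.na(metric)
  if (length(unique(metric[ok])) < 2L)
    return(flagged(reason = "fewer than 2 distinct metric values"))
  b <- unname(stats::coef(stats::lm(F[ok] ~ metric[ok]))[2L])
  if (!is.finite(b) || b <= 0)
    return(flagged(reason = "non-positive regression slope"))
  list(ne = 1 / (2 * b), slope = b, flagged = FALSE)
}

#' Effective population size from individual increases in inbreeding
#'
#' Delta F_i = 1 - (1 - F_i)^(1/(t_i - 1)) with t_i the equivalent complete
#' generations; Ne = 1/(2 mean Delta F_i) over the reference animals with
#' t > 1.
#'
#' @param F inbreeding coefficients (named when `reference` is used)
#' @param t equivalent complete generations, aligned with `F`
#' @param reference optional ids restricting the reference set
#' @return list with `ne`, `mean_delta_f`, `n`, and `flagged`
#' @export
ne_individual_deltaF <- function(F, t, reference = NULL) {
  stopifnot(length(F) == length(t))
  keep <- !is.na(F) & !is.na(t) & t > 1
  if (!is.null(reference)) keep <- keep & names(F) %in% reference
  if (!any(keep)) return(flagged(reason = "no animals with t > 1"))
  dFi <- 1 - (1 - F[keep])^(1 / (t[keep] - 1))
  mdf <- mean(dFi)
  if (mdf <= 0) return(flagged(reason = "mean individual delta F is zero"))
  list(ne = 1 / (2 * mdf), mean_delta_f = mdf, n = sum(keep), flagged = FALSE)
}

#' Effective population size from the regression of F on birth year
#'
#' The per-year slope is converted to a per-generation rate through the
#' generation interval L: Delta F = b_year * L and Ne = 1/(2 Delta F).
#'
#' @param F inbreeding coefficients
#' @param birth_year birth years aligned with `F`
#' @param L generation interval in years
#' @return list with `ne`, `slope_per_year`, `delta_f`, and `flagged`
#' @export
ne_birthyear_regression <- function(F, birth_year, L) {
  ok <- !is.na(F) & !is.na(birth_year)
  if (length(unique(birth_year[ok])) < 3L)
    return(flagged(reason = "fewer than 3 birth years"))
  b <- unname(stats::coef(stats::lm(F[ok] ~ birth_year[ok]))[2L])
  if (!is.finite(b) || b <= 0)
    return(flagged(reason = "non-positive slope on birth year"))
  dF <- b * L
  list(ne = 1 / (2 * dF), slope_per_year = b, delta_f = dF, flagged = FALSE)
}

#' Effective population size from the log regression of (1 - F) on generation
#'
#' Under a constant rate of inbreeding, ln(1 - Fbar_g) declines linearly in
#' generation g with slope ln(1 - Delta F); Ne = -1/(2 s) for fitted slope s.
#'
#' @param F inbreeding coefficients
#' @param generation per-animal generation numbers (cohort means are taken)
#' @return list with `ne`, `slope`, and `flagged`
#' @export
ne_log_regression <- function(F, generation) {
  ok <- !is.na(F) & !is.na(generation) & F < 1
  if (!any(ok)) return(flagged(reason = "no usable records"))
  fbar <- tapply(F[ok], generation[ok], mean)
  g <- as.numeric(names(fbar))
  if (length(g) < 2L) return(flagged(reason = "fewer than 2 generations"))
  s <- unname(stats::coef(stats::lm(log(1 - fbar) ~ g))[2L])
  if (!is.finite(s) || s >= -1e-12) # constant F fits a numerically-zero slope
    return(flagged(reason = "non-negative slope of log(1 - F)"))
  list(ne = -1 / (2 * s), slope = s, flagged = FALSE)
}

#' Effective population size from increases in pairwise coancestry
#'
#' For each pair (j, k) in the reference set, the per-generation increase in
#' coancestry is Delta c_jk = 1 - (1 - c_jk)^(1/((g_j + g_k)/2)) with c the
#' pedigree coancestry and g the equivalent complete generations;
#' Ne = 1/(2 mean Delta c). With more than `max_pairs` pairs a seeded random
#' subsample of pairs is used (whole-breed pair counts are otherwise
#' intractable, which is also why such analyses are usually restricted to a
#' recent cohort).
#'
#' @param ped a [ped_table()]
#' @param reference ids of the reference animals (default: all)
#' @param metrics optional precomputed [generation_metrics()]
#' @param max_pairs pair-count cap before subsampling
#' @param seed seed for the pair subsample
#' @return list with `ne`, `mean_delta_c`, `n_pairs`, and `flagged`
#' @export
ne_coancestry <- function(ped, reference = NULL, metrics = NULL,
                          max_pairs = 5e6, seed = 1L) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  reference <- reference %||% ped$id
  if (length(reference) < 2L) stop("need at least 2 reference animals", call. = FALSE)
  if (is.null(metrics)) metrics <- generation_metrics(ped)
  g <- metrics$equivalent_complete_generations[match(reference, metrics$id)]
  A <- kinship_matrix(ped, ids = reference) # coancestry = A/2 handled inside
  nr <- length(reference)
  npair <- nr * (nr - 1) / 2
  pr <- which(upper.tri(matrix(0, nr, nr)), arr.ind = TRUE)
  if (npair > max_pairs) {
    set.seed(seed)
    pr <- pr[sample.int(nrow(pr), max_pairs), , drop = FALSE]
  }
  cjk <- A[pr]
  gm <- (g[pr[, 1L]] + g[pr[, 2L]]) / 2
  keep <- !is.na(gm) & gm > 0
  if (!any(keep)) return(flagged(reason = "no pairs with positive generation depth"))
  dc <- 1 - (1 - cjk[keep])^(1 / gm[keep])
  mdc <- mean(dc)
  if (mdc <= 0) return(flagged(reason = "no coancestry accumulation"))
  list(ne = 1 / (2 * mdc), mean_delta_c = mdc, n_pairs = sum(keep),
       flagged = FALSE)
}

#' Pairwise kinship (coancestry) matrix for a set of animals
#'
#' Tabular computation of the additive relationship matrix restricted to the
#' ancestors of the requested ids, returned as coancestries f = a/2 for the
#' requested ids. Intended for reference sets up to a few thousand animals.
#'
#' @param ped a [ped_table()]
#' @param ids animals to return (default: all)
#' @return matrix of pairwise coancestries (self-coancestry (1 + F)/2 on the
#'   diagonal)
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  ids <- ids %||% ped$id
  ## restrict to ancestors of ids
  idx <- .ped_idx(ped)
  need <- logical(nrow(ped))
  need[match(ids, ped$id)] <- TRUE
  for (i in nrow(ped):1L) {
    if (need[i]) {
      if (idx$sire[i] > 0L) need[idx$sire[i]] <- TRUE
      if (idx$dam[i] > 0L) need[idx$dam[i]] <- TRUE
    }
  }
  sub <- ped[need, , drop = FALSE]
  class(sub) <- c("ped_table", "data.frame")
  sidx <- .ped_idx(sub)
  n <- nrow(sub)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- sidx$sire[i]; di <- sidx$dam[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      ai <- 0.5 * ((if (si > 0L) A[si, prev] else rep(0, i - 1L)) +
                   (if (di > 0L) A[di, prev] else rep(0, i - 1L)))
      A[i, prev] <- ai
      A[prev, i] <- ai
    }
    A[i, i] <- 1 + (if (si > 0L && di > 0L) 0.5 * A[si, di] else 0)
  }
  sel <- match(ids, sub$id)
  out <- A[sel, sel, drop = FALSE] / 2
  dimnames(out) <- list(ids, ids)
  out
}

#' Effective population size by the linkage-disequilibrium method
#'
#' Mean squared dosage correlation across marker pairs on different
#' chromosomes (physical linkage would otherwise inflate r-squared),
#' corrected for finite sample size S, then inverted with the
#' random-mating formula: Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2') for
#' S >= 30, with the small-sample coefficients 0.308/2.08 otherwise. The
#' confidence interval comes from a delete-one jackknife over individuals on
#' the corrected r-squared, transformed through the (monotone) Ne formula.
#'
#' @param gd a [genotype_dataset()]
#' @param jackknife compute a jackknife CI?
#' @param conf confidence level
#' @param max_pairs optional cap on the number of marker pairs (seeded
#'   subsample via `seed`)
#' @param seed seed for pair subsampling
#' @return list of class `ne_ld`: `ne`, `ci` (lower/upper), `r2_mean`,
#'   `r2_corrected`, `S`, `n_pairs`, `flagged` (TRUE with `ne = Inf` when
#'   the corrected r-squared is non-positive)
#' @export
ne_ld <- function(gd, jackknife = TRUE, conf = 0.95, max_pairs = NULL,
                  seed = 1L) {
  stopifnot(inherits(gd, "geno_ds"))
  S <- nrow(gd$geno)
  if (S < 10L) stop("need at least 10 individuals for the LD method", call. = FALSE)
  m <- ncol(gd$geno)
  if (m < 2L) stop("need at least 2 markers", call. = FALSE)
  chrom <- gd$map$chrom
  if (length(unique(chrom)) < 2L)
    stop("LD-method Ne needs markers on at least 2 chromosomes", call. = FALSE)
  ## mean-impute missing dosages once
  X <- gd$geno
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2L]]
  }
  keepcol <- apply(X, 2L, stats::sd) > 0
  X <- X[, keepcol, drop = FALSE]
  chrom <- chrom[keepcol]
  mask <- outer(chrom, chrom, "!=") & upper.tri(matrix(0, ncol(X), ncol(X)))
  sel <- which(mask)
  if (!is.null(max_pairs) && length(sel) > max_pairs) {
    set.seed(seed)
    sel <- sel[sort(sample.int(length(sel), max_pairs))]
  }
  mean_r2 <- function(Xs) {
    ## a delete-one subsample can make a marker constant; such pairs are
    ## uninformative and dropped from the mean
    r <- suppressWarnings(stats::cor(Xs))
    mean(r[sel]^2, na.rm = TRUE)
  }
  r2 <- mean_r2(X)
  expected <- function(S) if (S >= 30) 1 / S + 3.19 / S^2 else
    0.0018 + 0.907 / S + 4.44 / S^2
  ne_from <- function(phi, S) {
    if (!is.finite(phi) || phi <= 0) return(Inf)
    if (S >= 30) {
      disc <- 1 / 9 - 2.76 * phi
      if (disc < 0) return(Inf)
      (1 / 3 + sqrt(disc)) / (2 * phi)
    } else {
      disc <- 0.308^2 - 2.08 * phi
      if (disc < 0) return(Inf)
      (0.308 + sqrt(disc)) / (2 * phi)
    }
  }
  phi <- r2 - expected(S)
  ne <- ne_from(phi, S)
  ci <- c(NA_real_, NA_real_)
  if (jackknife) {
    phis <- vapply(seq_len(S), function(k) {
      mean_r2(X[-k, , drop = FALSE]) - expected(S - 1L)
    }, 1)
    se <- sqrt((S - 1) / S * sum((phis - mean(phis))^2))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    phi_hi <- phi + z * se
    phi_lo <- phi - z * se
    ci <- c(ne_from(phi_hi, S), ne_from(phi_lo, S))
  }
  structure(list(ne = ne, ci = ci, r2_mean = r2, r2_corrected = phi, S = S,
                 n_pairs = length(sel), flagged = !is.finite(ne),
                 reason = if (!is.finite(ne)) "corrected r2 non-positive" else NULL),
            class = "ne_ld")
}

#' All pedigree-based effective population size estimators
#'
#' Convenience wrapper running the six F-based estimators and the
#' coancestry estimator on one pedigree.
#'
#' @param ped a [ped_table()]
#' @param L generation interval in years for the birth-year regression
#' @param generation optional per-animal generation numbers for the log
#'   regression (defaults to rounded equivalent complete generations)
#' @param reference ids for the individual-increase and coancestry methods
#'   (defaults to all animals)
#' @return data frame with columns `method` and `ne` (NA when flagged)
#' @export
ne_summary <- function(ped, L, generation = NULL, reference = NULL) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  F <- inbreeding_ml(ped)
  gm <- generation_metrics(ped)
  generation <- generation %||% round(gm$equivalent_complete_generations)
  res <- list(
    f_max_generation = ne_regression_on_generations(F, gm$max_generations),
    f_complete_generation = ne_regression_on_generations(F, gm$complete_generations),
    f_equivalent_generation = ne_regression_on_generations(F, gm$equivalent_complete_generations),
    individual_delta_f = ne_individual_deltaF(F, gm$equivalent_complete_generations,
                                              reference = reference),
    birth_year_regression = ne_birthyear_regression(F, ped$birth_year, L),
    log_regression = ne_log_regression(F, generation),
    coancestry = ne_coancestry(ped, reference = reference, metrics = gm))
  data.frame(method = names(res),
             ne = vapply(res, function(x) if (is_flagged(x)) NA_real_ else x$ne, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
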