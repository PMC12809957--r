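## Mendelian sampling variances d_i for A = T D T', given parent indices and
## inbreeding coefficients of earlier animals. Unknown parents contribute
## their full founder variance.
.mendelian_d <- function(s, d, F) {
  n <- length(s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (s[i] > 0L && d[i] > 0L) 0.5 - 0.25 * (F[s[i]] + F[d[i]])
      else if (s[i] > 0L) 0.75 - 0.25 * F[s[i]]
      else if (d[i] > 0L) 0.75 - 0.25 * F[d[i]]
      else 1
  }
  out
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes F for every animal by the Meuwissen & Luo algorithm: for each
#' animal the ancestor contributions of its sire and dam are traced up the
#' pedigree and combined with the Mendelian sampling variances
#' d_j = 0.5 - 0.25 (F_sire(j) + F_dam(j)) of the shared ancestors, giving
#' F_i = a(sire, dam) / 2 without ever forming the relationship matrix. Work
#' per animal is proportional to its ancestor count, so whole-breed pedigrees
#' remain tractable.
#'
#' Animals with an unknown parent have F = 0 (the unknown side is assumed
#' unrelated).
#'
#' @param ped a [ped_table()] (or a data frame accepted by [ped_table()])
#' @return named numeric vector of inbreeding coefficients in pedigree order
#' @export
inbreeding_ml <- function(ped) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  idx <- .ped_idx(ped)
  s <- idx$sire; d <- idx$dam
  n <- nrow(ped)
  F <- numeric(n)
  D <- numeric(n)
  ts <- numeric(n); td <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    D[i] <- if (si > 0L && di > 0L) 0.5 - 0.25 * (F[si] + F[di])
      else if (si > 0L) 0.75 - 0.25 * F[si]
      else if (di > 0L) 0.75 - 0.25 * F[di]
      else 1
    if (si == 0L || di == 0L) next
    ## trace ancestor contributions of sire and dam simultaneously
    ts[si] <- ts[si] + 1
    td[di] <- td[di] + 1
    pending <- 2L
    acc <- 0
    for (j in max(si, di):1L) {
      a <- ts[j]; b <- td[j]
      if (a == 0 && b == 0) next
      pending <- pending - (a != 0) - (b != 0)
      acc <- acc + a * b * D[j]
      sj <- s[j]; dj <- d[j]
      if (a != 0) {
        if (sj > 0L) { pending <- pending + (ts[sj] == 0); ts[sj] <- ts[sj] + a / 2 }
        if (dj > 0L) { pending <- pending + (ts[dj] == 0); ts[dj] <- ts[dj] + a / 2 }
        ts[j] <- 0
      }
      if (b != 0) {
        if (sj > 0L) { pending <- pending + (td[sj] == 0); td[sj] <- td[sj] + b / 2 }
        if (dj > 0L) { pending <- pending + (td[dj] == 0); td[dj] <- td[dj] + b / 2 }
        td[j] <- 0
      }
      if (pending == 0L) break
    }
    F[i] <- acc / 2
  }
  stats::setNames(F, ped$id)
}

#' Average relatedness
#'
#' AR_i is twice the mean coancestry between animal i and every animal in the
#' pedigree including itself, i.e. the mean of row i of the additive
#' relationship matrix A. It is computed indirectly through the
#' decomposition A = T D T' with two linear passes over the pedigree, never
#' materializing A.
#'
#' @param ped a [ped_table()]
#' @param F optional precomputed [inbreeding_ml()] vector
#' @return named numeric vector of AR values
#' @export
average_relatedness <- function(ped, F = NULL) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  if (is.null(F)) F <- inbreeding_ml(ped)
  idx <- .ped_idx(ped)
  s <- idx$sire; d <- idx$dam
  n <- nrow(ped)
  D <- .mendelian_d(s, d, unname(F))
  ## u = T' 1 by a backward pass (total descendant flow into each ancestor)
  u <- rep(1, n)
  for (i in n:1L) {
    if (s[i] > 0L) u[s[i]] <- u[s[i]] + 0.5 * u[i]
    if (d[i] > 0L) u[d[i]] <- u[d[i]] + 0.5 * u[i]
  }
  w <- D * u
  ## v = T w by a forward pass; v_i = (1'A)_i
  v <- numeric(n)
  for (i in seq_len(n)) {
    v[i] <- w[i] +
      (if (s[i] > 0L) 0.5 * v[s[i]] else 0) +
      (if (d[i] > 0L) 0.5 * v[d[i]] else 0)
  }
  stats::setNames(v / n, ped$id)
}

## Mean coancestry between two id groups (including self pairs when g == h),
## f_gh = 1'_g A 1_h / (2 n_g n_h), via backward indicator passes.
.group_coancestry <- function(ped, D, groups) {
  idx <- .ped_idx(ped)
  s <- idx$sire; d <- idx$dam
  n <- nrow(ped)
  V <- sapply(groups, function(g) {
    c0 <- numeric(n)
    c0[match(g, ped$id)] <- 1
    for (i in n:1L) {
      if (s[i] > 0L) c0[s[i]] <- c0[s[i]] + 0.5 * c0[i]
      if (d[i] > 0L) c0[d[i]] <- c0[d[i]] + 0.5 * c0[i]
    }
    c0
  })
  sizes <- vapply(groups, length, 1L)
  cross <- crossprod(V * sqrt(D)) # t(V) %*% diag(D) %*% V
  sweep(sweep(cross, 1L, sizes, "/"), 2L, sizes, "/") / 2
}

#' Pedigree-based flock differentiation (Wright's FST and Nei's minimum distance)
#'
#' Coancestries are taken from the additive relationship (f = a/2), self
#' pairs included, so the mean within-flock coancestry of flock g is
#' 1'_g A 1_g / (2 n_g^2). Wright's fixation index is
#' FST = (fbar - ftilde) / (1 - ftilde) with fbar the flock-size-weighted
#' mean within-flock coancestry and ftilde the full-population mean
#' coancestry; Nei's minimum distance between flocks i and j is
#' D_ij = (f_ii + f_jj)/2 - f_ij.
#'
#' @param ped a [ped_table()]
#' @param flock flock labels along `ped` (default the `flock` column);
#'   animals with `NA` flock are excluded from flock means but kept in the
#'   population mean
#' @return list of class `ped_fst` with `fst`, `f_within` (per flock),
#'   `f_population`, `nei_d` (symmetric matrix), `flock_sizes`
#' @export
pedigree_fst_nei <- function(ped, flock = ped$flock) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  flock <- as.character(flock)
  fl <- sort(unique(flock[!is.na(flock)]))
  if (length(fl) < 2L)
    stop("need at least two flocks", call. = FALSE)
  groups <- lapply(fl, function(f) ped$id[!is.na(flock) & flock == f])
  sizes <- vapply(groups, length, 1L)
  if (any(sizes == 0L)) stop("empty flock", call. = FALSE)
  F <- inbreeding_ml(ped)
  idx <- .ped_idx(ped)
  D <- .mendelian_d(idx$sire, idx$dam, unname(F))
  fmat <- .group_coancestry(ped, D, c(groups, list(ped$id)))
  k <- length(fl)
  f_within <- diag(fmat)[seq_len(k)]
  f_pop <- fmat[k + 1L, k + 1L]
  fbar <- sum(sizes * f_within) / sum(sizes)
  fst <- (fbar - f_pop) / (1 - f_pop)
  nei <- matrix(0, k, k, dimnames = list(fl, fl))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    nei[i, j] <- (fmat[i, i] + fmat[j, j]) / 2 - fmat[i, j]
  structure(list(fst = fst, f_within = stats::setNames(f_within, fl),
                 f_population = f_pop, nei_d = nei,
                 flock_sizes = stats::setNames(sizes, fl)),
            class = "ped_fst")
}

#' Rate of inbreeding over generation cohorts
#'
#' Animals are binned into cohorts of width `L` years anchored at the
#' earliest birth year. Delta F between successive cohorts is
#' (Fbar_g - Fbar_{g-1}) / (1 - Fbar_{g-1}); the function reports the mean
#' Delta F and an ordinary least squares test of zero slope of Delta F on
#' cohort index.
#'
#' @param F inbreeding coefficients (named or aligned with `birth_year`)
#' @param birth_year numeric birth years
#' @param L cohort width in years (the generation interval)
#' @return list of class `delta_f_trend` with `cohorts` data frame, `mean_delta_f`,
#'   `slope`, `p_value`, and `flagged` when fewer than 3 cohorts exist
#' @export
delta_f_trend <- function(F, birth_year, L) {
  stopifnot(length(F) == length(birth_year), L > 0)
  ok <- !is.na(F) & !is.na(birth_year)
  F <- F[ok]; birth_year <- birth_year[ok]
  g <- floor((birth_year - min(birth_year)) / L)
  fbar <- tapply(F, g, mean)
  gi <- as.integer(names(fbar))
  o <- order(gi); gi <- gi[o]; fbar <- fbar[o]
  if (length(fbar) < 3L) {
    return(structure(list(cohorts = data.frame(cohort = gi, mean_f = as.numeric(fbar)),
                          mean_delta_f = NA_real_, slope = NA_real_,
                          p_value = NA_real_, flagged = TRUE,
                          reason = "fewer than 3 cohorts"),
                     class = "delta_f_trend"))
  }
  dF <- (fbar[-1L] - fbar[-length(fbar)]) / (1 - fbar[-length(fbar)])
  fit <- stats::lm(dF ~ gi[-1L])
  co <- summary(fit)$coefficients
  slope <- unname(co[2L, 1L])
  pval <- if (nrow(co) >= 2L && ncol(co) >= 4L) unname(co[2L, 4L]) else NA_real_
  structure(list(
    cohorts = data.frame(cohort = gi, mean_f = as.numeric(fbar),
                         delta_f = c(NA, as.numeric(dF))),
    mean_delta_f = mean(dF), slope = slope, p_value = pval, flagged = FALSE),
    class = "delta_f_trend")
}
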