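#' Parameters for the homozygosity-by-descent hidden Markov model
#'
#' Single-rate two-state model. The HBD state emits a heterozygote only
#' through genotyping error (probability `error`) and a homozygote for
#' allele a with probability (1 - error) * freq(a); the non-HBD state emits
#' Hardy-Weinberg genotype probabilities. Moving a map distance d Morgans,
#' the chain "resets" with probability 1 - exp(-rate * d) and then draws the
#' new state from the prior (`rho`, 1 - `rho`), so 1/rate is the expected
#' HBD segment length in Morgans and `rho` is the prior HBD proportion.
#'
#' @param rate segment length rate per Morgan (inverse expected length)
#' @param rho prior probability of the HBD state
#' @param error genotyping error probability
#' @param estimate_rate if `TRUE` the rate is chosen per animal by maximum
#'   likelihood over `rate_grid`
#' @param rate_grid log-spaced candidate rates
#' @return list of class `hbd_params`
#' @export
hbd_params <- function(rate = 20, rho = 0.05, error = 0.002,
                       estimate_rate = FALSE,
                       rate_grid = 2^seq(0, 9, by = 1)) {
  stopifnot(rate > 0, rho > 0, rho < 1, error > 0, error < 1,
            all(rate_grid > 0))
  structure(list(rate = rate, rho = rho, error = error,
                 estimate_rate = isTRUE(estimate_rate),
                 rate_grid = as.numeric(rate_grid)),
            class = "hbd_params")
}

#' Posterior homozygosity-by-descent probabilities (two-state HMM)
#'
#' Runs the scaled forward-backward algorithm per chromosome, vectorized
#' across animals. F_HBD per animal is the mean posterior HBD probability
#' over all markers. Missing genotypes are uninformative (emission 1 in
#' both states). Allele frequencies default to the analyzed sample; supply
#' `freq` (e.g. founder frequencies in simulations) to override.
#'
#' @param gd a [genotype_dataset()]
#' @param params an [hbd_params()]
#' @param freq optional per-marker allele-1 frequencies
#' @param keep_posterior return the per-SNP posterior matrix (samples x
#'   markers)?
#' @return list of class `hbd_result`: `f_hbd` (named, per animal),
#'   `loglik_forward`, `loglik_backward` (per animal), `rate` (per animal),
#'   and `posterior` when requested
#' @export
hbd_posterior <- function(gd, params = hbd_params(), freq = NULL,
                          keep_posterior = FALSE) {
  stopifnot(inherits(gd, "geno_ds"), inherits(params, "hbd_params"))
  p <- freq %||% .allele_freq(gd)
  ## clamp so HW emissions are never exactly degenerate at fixed markers
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  n <- nrow(gd$geno); M <- ncol(gd$geno)
  if (params$estimate_rate) {
    lls <- sapply(params$rate_grid, function(r) {
      .hbd_run(gd, params, p, r, keep_posterior = FALSE)$loglik_forward
    })
    best <- params$rate_grid[apply(as.matrix(lls), 1L, which.max)]
    ## rerun per distinct best rate, collecting posteriors per animal
    out_f <- numeric(n); llf <- numeric(n); llb <- numeric(n)
    post <- if (keep_posterior) matrix(NA_real_, n, M) else NULL
    for (r in unique(best)) {
      sel <- which(best == r)
      sub <- subset_geno(gd, samples = sel)
      res <- .hbd_run(sub, params, p, r, keep_posterior)
      out_f[sel] <- res$f_hbd; llf[sel] <- res$loglik_forward
      llb[sel] <- res$loglik_backward
      if (keep_posterior) post[sel, ] <- res$posterior
    }
    res <- list(f_hbd = stats::setNames(out_f, gd$samples$id),
                loglik_forward = llf, loglik_backward = llb, rate = best)
    if (keep_posterior) res$posterior <- post
  } else {
    res <- .hbd_run(gd, params, p, params$rate, keep_posterior)
    res$rate <- rep(params$rate, n)
    names(res$f_hbd) <- gd$samples$id
  }
  structure(res, class = "hbd_result")
}

## forward-backward over all chromosomes; vectorized across animals
.hbd_run <- function(gd, params, p, rate, keep_posterior) {
  n <- nrow(gd$geno)
  rho <- params$rho; e <- params$error
  llf <- numeric(n); llb <- numeric(n)
  post_sum <- numeric(n); m_tot <- 0L
  post <- if (keep_posterior) matrix(NA_real_, n, ncol(gd$geno)) else NULL
  for (cc in unique(gd$map$chrom)) {
    jj <- which(gd$map$chrom == cc)
    M <- length(jj)
    G <- gd$geno[, jj, drop = FALSE]
    pj <- p[jj]
    d <- diff(gd$map$cm[jj]) / 100 # Morgans
    a_keep <- exp(-rate * d)
    ## emissions: n x M for each state
    E1 <- matrix(1, n, M); E2 <- matrix(1, n, M)
    for (m in seq_len(M)) {
      g <- G[, m]
      E1[, m] <- ifelse(is.na(g), 1,
                        ifelse(g == 1L, e,
                               ifelse(g == 2L, (1 - e) * pj[m], (1 - e) * (1 - pj[m]))))
      E2[, m] <- ifelse(is.na(g), 1,
                        ifelse(g == 1L, 2 * pj[m] * (1 - pj[m]),
                               ifelse(g == 2L, pj[m]^2, (1 - pj[m])^2)))
    }
    ## scaled forward
    A1 <- matrix(0, n, M); A2 <- matrix(0, n, M)
    sc <- matrix(0, n, M)
    a1 <- rho * E1[, 1L]; a2 <- (1 - rho) * E2[, 1L]
    s <- a1 + a2
    if (any(!is.finite(s)) || any(s <= 0))
      stop("non-finite likelihood at marker index ", jj[1L], call. = FALSE)
    A1[, 1L] <- a1 / s; A2[, 1L] <- a2 / s; sc[, 1L] <- s
    for (m in seq_len(M)[-1L]) {
      k <- a_keep[m - 1L]
      p1 <- k * A1[, m - 1L] + (1 - k) * rho
      p2 <- k * A2[, m - 1L] + (1 - k) * (1 - rho)
      a1 <- p1 * E1[, m]; a2 <- p2 * E2[, m]
      s <- a1 + a2
      if (any(!is.finite(s)) || any(s <= 0))
        stop("non-finite likelihood at marker index ", jj[m], call. = FALSE)
      A1[, m] <- a1 / s; A2[, m] <- a2 / s; sc[, m] <- s
    }
    llf <- llf + rowSums(log(sc))
    ## scaled backward
    B1 <- matrix(0, n, M); B2 <- matrix(0, n, M)
    scb <- matrix(1, n, M)
    B1[, M] <- 1; B2[, M] <- 1
    for (m in rev(seq_len(M - 1L))) {
      k <- a_keep[m]
      t11 <- k + (1 - k) * rho; t12 <- (1 - k) * (1 - rho)
      t21 <- (1 - k) * rho; t22 <- k + (1 - k) * (1 - rho)
      b1 <- t11 * E1[, m + 1L] * B1[, m + 1L] + t12 * E2[, m + 1L] * B2[, m + 1L]
      b2 <- t21 * E1[, m + 1L] * B1[, m + 1L] + t22 * E2[, m + 1L] * B2[, m + 1L]
      s <- b1 + b2
      B1[, m] <- b1 / s; B2[, m] <- b2 / s
      scb[, m] <- s
    }
    lb <- log(rho * E1[, 1L] * B1[, 1L] + (1 - rho) * E2[, 1L] * B2[, 1L]) +
      rowSums(log(scb))
    llb <- llb + lb
    ## posterior from scaled quantities
    g1 <- A1 * B1; g2 <- A2 * B2
    gamma <- g1 / (g1 + g2)
    post_sum <- post_sum + rowSums(gamma)
    m_tot <- m_tot + M
    if (keep_posterior) post[, jj] <- gamma
  }
  out <- list(f_hbd = post_sum / m_tot, loglik_forward = llf,
              loglik_backward = llb)
  if (keep_posterior) out$posterior <- post
  out
}
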