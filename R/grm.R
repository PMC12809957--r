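#' VanRaden (method 1) genomic relationship matrix
#'
#' G = Z Z' / (2 * sum p(1-p)) with Z the dosage matrix centered by twice
#' the allele frequency; missing genotypes are mean-imputed per marker
#' (equivalently, centered to zero). The genomic inbreeding coefficient is
#' F_GRM = diag(G) - 1.
#'
#' @param gd a [genotype_dataset()]
#' @param freq optional per-marker allele-1 frequencies (defaults to the
#'   analyzed sample's); in simulations the founder frequencies can be
#'   supplied for base-population scaling
#' @return list with `G` (n x n matrix) and `f_grm` (named vector)
#' @export
grm_vanraden1 <- function(gd, freq = NULL) {
  stopifnot(inherits(gd, "geno_ds"))
  p <- freq %||% .allele_freq(gd)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: GRM denominator is zero",
                       call. = FALSE)
  Z <- sweep(gd$geno, 2L, 2 * p, "-")
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(gd$samples$id, gd$samples$id)
  list(G = G, f_grm = stats::setNames(diag(G) - 1, gd$samples$id))
}
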