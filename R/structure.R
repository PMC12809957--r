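#' Pairwise flock FST (Weir-Cockerham) with a locus bootstrap
#'
#' For each pair of flocks the Weir & Cockerham (1984) variance components
#' a (among populations), b (among individuals within populations) and c
#' (within individuals) are computed per marker and combined across markers
#' as a ratio of sums, theta = sum(a) / sum(a + b + c). Negative per-pair
#' estimates are retained. Bootstrapping resamples markers with replacement
#' and reports percentile confidence intervals.
#'
#' @param gd a [genotype_dataset()]
#' @param flock flock labels along samples (default the samples' `flock`)
#' @param n_boot bootstrap replicates (0 disables the CI)
#' @param conf confidence level
#' @param seed RNG seed for the bootstrap
#' @return list of class `fst_matrix`: `fst` (symmetric matrix, 0 diagonal),
#'   `lower`, `upper`, `mean_fst` (mean over pairs), `flocks`, `excluded`
#' @export
pairwise_fst <- function(gd, flock = gd$samples$flock, n_boot = 100L,
                         conf = 0.95, seed = 1L) {
  stopifnot(inherits(gd, "geno_ds"))
  flock <- as.character(flock)
  sizes <- table(flock[!is.na(flock)])
  excluded <- names(sizes)[sizes < 2L]
  if (length(excluded))
    warning("excluding flock(s) with < 2 animals: ",
            paste(excluded, collapse = ", "))
  fl <- sort(setdiff(names(sizes), excluded))
  if (length(fl) < 2L) stop("need at least two flocks with >= 2 animals", call. = FALSE)
  k <- length(fl)
  fst <- matrix(0, k, k, dimnames = list(fl, fl))
  lower <- upper <- matrix(NA_real_, k, k, dimnames = list(fl, fl))
  set.seed(seed)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    gi <- gd$geno[!is.na(flock) & flock == fl[i], , drop = FALSE]
    gj <- gd$geno[!is.na(flock) & flock == fl[j], , drop = FALSE]
    comp <- .wc_components(gi, gj)
    ok <- is.finite(comp$a) & is.finite(comp$abc)
    a <- comp$a[ok]; abc <- comp$abc[ok]
    theta <- sum(a) / sum(abc)
    fst[i, j] <- fst[j, i] <- theta
    if (n_boot > 0L) {
      m <- length(a)
      bt <- vapply(seq_len(n_boot), function(b) {
        w <- sample.int(m, m, replace = TRUE)
        sum(a[w]) / sum(abc[w])
      }, 1)
      qs <- stats::quantile(bt, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            na.rm = TRUE, names = FALSE)
      lower[i, j] <- lower[j, i] <- qs[1L]
      upper[i, j] <- upper[j, i] <- qs[2L]
    }
  }
  mean_fst <- mean(fst[upper.tri(fst)])
  structure(list(fst = fst, lower = lower, upper = upper, mean_fst = mean_fst,
                 flocks = fl, excluded = excluded),
            class = "fst_matrix")
}

## Weir & Cockerham (1984) per-marker variance components for two
## populations of genotype matrices (dosage 0/1/2, NA missing)
.wc_components <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colMeans(g1, na.rm = TRUE) / 2; p2 <- colMeans(g2, na.rm = TRUE) / 2
  h1 <- colMeans(g1 == 1L, na.rm = TRUE); h2 <- colMeans(g2 == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  ## monomorphic-overall markers carry no information
  mono <- pbar <= 0 | pbar >= 1
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  list(a = a, abc = a + b + cc)
}

#' Principal component analysis with per-flock subsampling
#'
#' To avoid over-representation of heavily genotyped flocks, each replicate
#' randomly subsamples flocks above `max_per_flock` down to the cap (flocks
#' at or under the cap enter complete). The VanRaden GRM of the subsample,
#' with allele frequencies from the subsample itself (so the GRM is doubly
#' centered), is eigendecomposed; scores for the leading components and the
#' percentage of variance per component are returned per replicate.
#'
#' @param gd a [genotype_dataset()]
#' @param flock flock labels along samples
#' @param max_per_flock subsampling cap
#' @param n_replicates number of subsampling replicates
#' @param n_pc number of leading components to return
#' @param seed RNG seed
#' @return list of class `pca_subsample`: `replicates`, a list with per
#'   replicate `ids`, `scores` (samples x PCs), `eigenvalues`,
#'   `pct_variance`
#' @export
pca_with_subsampling <- function(gd, flock = gd$samples$flock,
                                 max_per_flock = 30L, n_replicates = 5L,
                                 n_pc = 3L, seed = 1L) {
  stopifnot(inherits(gd, "geno_ds"))
  flock <- as.character(flock)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sel <- unlist(lapply(sort(unique(flock[!is.na(flock)])), function(f) {
      ix <- which(!is.na(flock) & flock == f)
      if (length(ix) > max_per_flock) sort(sample(ix, max_per_flock)) else ix
    }))
    if (length(sel) < 3L) stop("fewer than 3 samples after subsampling", call. = FALSE)
    sub <- subset_geno(gd, samples = sel)
    G <- grm_vanraden1(sub)$G
    eg <- eigen(G, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    if (sum(ev) <= 0) stop("degenerate (rank-zero) genotype subsample", call. = FALSE)
    npc <- min(n_pc, ncol(eg$vectors))
    scores <- eg$vectors[, seq_len(npc), drop = FALSE]
    rownames(scores) <- sub$samples$id
    colnames(scores) <- paste0("PC", seq_len(npc))
    reps[[r]] <- list(ids = sub$samples$id, flock = flock[sel],
                      scores = scores,
                      eigenvalues = eg$values[seq_len(npc)],
                      pct_variance = 100 * ev[seq_len(npc)] / sum(ev))
  }
  structure(list(replicates = reps, max_per_flock = max_per_flock),
            class = "pca_subsample")
}
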