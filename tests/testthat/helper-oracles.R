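# Independent brute-force oracles used across the test files. These share no
# code with the package implementations they check.

# Tabular (recursive) additive relationship matrix. Quadratic and simple;
# the reference for inbreeding (diag(A) - 1) and average relatedness.
tabular_A <- function(ped) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- 0
      if (!is.na(si[i])) a <- a + 0.5 * A[si[i], j]
      if (!is.na(di[i])) a <- a + 0.5 * A[di[i], j]
      A[i, j] <- A[j, i] <- a
    }
    A[i, i] <- 1 + (if (!is.na(si[i]) && !is.na(di[i])) 0.5 * A[si[i], di[i]] else 0)
  }
  A
}

# Random valid pedigree: animals appear in birth order; each non-founder
# draws parents from earlier animals of the right sex.
random_pedigree <- function(n, p_founder = 0.2, seed = 1) {
  set.seed(seed)
  id <- paste0("X", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(NA_character_, n)
  year <- integer(n); year[1:2] <- 2000L
  for (i in 3:n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (runif(1) > p_founder && length(males) && length(females)) {
      s <- males[sample.int(length(males), 1L)]
      d <- females[sample.int(length(females), 1L)]
      sire[i] <- id[s]; dam[i] <- id[d]
      year[i] <- max(year[s], year[d]) + sample(1:3, 1L)
    } else {
      year[i] <- 2000L + sample(0:5, 1L)
    }
  }
  ped_table(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                       birth_year = year, stringsAsFactors = FALSE))
}

# Repeated full-sib mating line: generation g pair are full sibs whose
# parents were the generation g-1 pair. Returns the ped and the id of one
# offspring per generation.
fullsib_line <- function(n_generations) {
  id <- c("m0", "f0"); sire <- c(NA, NA); dam <- c(NA, NA)
  sex <- c("M", "F"); year <- c(2000L, 2000L)
  prev <- c("m0", "f0")
  gen_ids <- character(n_generations)
  for (g in seq_len(n_generations)) {
    ids <- paste0(c("m", "f"), g)
    id <- c(id, ids); sire <- c(sire, prev[1L], prev[1L])
    dam <- c(dam, prev[2L], prev[2L]); sex <- c(sex, "M", "F")
    year <- c(year, rep(2000L + g, 2L))
    gen_ids[g] <- ids[1L]
    prev <- ids
  }
  list(ped = ped_table(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                                  birth_year = year, stringsAsFactors = FALSE)),
       generation_ids = gen_ids)
}

# Expected founder contributions by exhaustive path enumeration: the
# contribution of ancestor a to animal x is sum over all distinct
# parent-paths of (1/2)^length.
path_contribution <- function(ped, ancestor, x) {
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  target <- match(ancestor, ped$id)
  recur <- function(i, w) {
    tot <- 0
    if (i == target) tot <- tot + w
    if (!is.na(si[i])) tot <- tot + recur(si[i], w / 2)
    if (!is.na(di[i])) tot <- tot + recur(di[i], w / 2)
    tot
  }
  recur(match(x, ped$id), 1)
}

# Brute-force ROH reference: per-SNP eligibility by explicitly enumerating
# every window, then maximal eligible runs with the gap/min rules.
brute_roh <- function(gd, params) {
  out <- list()
  for (cc in unique(gd$map$chrom)) {
    jj <- which(gd$map$chrom == cc)
    M <- length(jj); W <- params$window_snps
    if (M < W) next
    bp <- gd$map$bp[jj]
    for (i in seq_len(nrow(gd$geno))) {
      g <- gd$geno[i, jj]
      score_num <- integer(M); score_den <- integer(M)
      for (w in seq_len(M - W + 1L)) {
        win <- w:(w + W - 1L)
        ok <- sum(g[win] == 1L, na.rm = TRUE) <= params$max_het_in_window &&
          sum(is.na(g[win])) <= params$max_missing_in_window
        score_den[win] <- score_den[win] + 1L
        if (ok) score_num[win] <- score_num[win] + 1L
      }
      elig <- score_num / score_den > params$window_threshold
      # maximal runs, split at big gaps
      run_start <- NULL
      flush <- function(st, en) {
        len <- bp[en] - bp[st]
        if (len >= params$min_length_bp && (en - st + 1L) >= params$min_snps)
          out[[length(out) + 1L]] <<- data.frame(
            id = gd$samples$id[i], chrom = cc, start_bp = bp[st],
            end_bp = bp[en], n_snps = en - st + 1L, length_bp = len,
            stringsAsFactors = FALSE)
      }
      for (j in seq_len(M)) {
        if (elig[j]) {
          if (is.null(run_start)) run_start <- j
          else if (bp[j] - bp[j - 1L] > params$max_gap_bp) {
            flush(run_start, j - 1L); run_start <- j
          }
        } else if (!is.null(run_start)) {
          flush(run_start, j - 1L); run_start <- NULL
        }
      }
      if (!is.null(run_start)) flush(run_start, M)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(id = character(0), chrom = integer(0), start_bp = numeric(0),
               end_bp = numeric(0), n_snps = integer(0), length_bp = numeric(0))
}

# Independent two-state HMM oracle in plain log space (log-sum-exp), scalar
# per animal, matching the model: HBD emits het with prob e, hom allele a
# with (1-e) freq(a); non-HBD emits Hardy-Weinberg; transitions reset with
# prob 1 - exp(-rate d) to the prior (rho, 1-rho).
dp_hbd_oracle <- function(g, p, cm, rate, rho, e) {
  M <- length(g)
  em <- function(m, state) {
    if (is.na(g[m])) return(0) # log 1
    pj <- min(max(p[m], 1e-6), 1 - 1e-6)
    if (state == 1L) {
      log(if (g[m] == 1L) e else if (g[m] == 2L) (1 - e) * pj else (1 - e) * (1 - pj))
    } else {
      log(if (g[m] == 1L) 2 * pj * (1 - pj) else if (g[m] == 2L) pj^2 else (1 - pj)^2)
    }
  }
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  la <- matrix(-Inf, M, 2L)
  la[1L, ] <- c(log(rho) + em(1L, 1L), log(1 - rho) + em(1L, 2L))
  for (m in 2:M) {
    k <- exp(-rate * (cm[m] - cm[m - 1L]) / 100)
    lt <- log(matrix(c(k + (1 - k) * rho, (1 - k) * rho,
                       (1 - k) * (1 - rho), k + (1 - k) * (1 - rho)), 2L, 2L))
    for (st in 1:2)
      la[m, st] <- lse(la[m - 1L, ] + lt[, st]) + em(m, st)
  }
  lb <- matrix(0, M, 2L)
  for (m in (M - 1L):1L) {
    k <- exp(-rate * (cm[m + 1L] - cm[m]) / 100)
    lt <- log(matrix(c(k + (1 - k) * rho, (1 - k) * rho,
                       (1 - k) * (1 - rho), k + (1 - k) * (1 - rho)), 2L, 2L))
    for (st in 1:2)
      lb[m, st] <- lse(lt[st, ] + c(em(m + 1L, 1L), em(m + 1L, 2L)) + lb[m + 1L, ])
  }
  ll <- lse(la[M, ])
  post <- exp(la + lb - ll)
  list(loglik = ll, posterior_hbd = post[, 1L])
}

# small helper building a geno_ds directly from a dosage matrix
make_gd <- function(geno, chrom = NULL, bp = NULL, flock = NULL,
                    cm_per_mb = 1) {
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(bp)) {
    bp <- integer(m)
    for (ix in split(seq_len(m), chrom)) bp[ix] <- seq_along(ix) * 50000L
  }
  map <- data.frame(chrom = chrom, snp_id = paste0("s", seq_len(m)),
                    cm = bp / 1e6 * cm_per_mb, bp = bp,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  samples <- data.frame(id = paste0("i", seq_len(nrow(geno))),
                        sex = NA, birth_year = NA,
                        flock = flock %||% NA, stringsAsFactors = FALSE)
  genotype_dataset(geno, map, samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
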