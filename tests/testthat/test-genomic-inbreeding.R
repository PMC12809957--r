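test_that("MAF spectrum bins close and catch edge frequencies", {
  G <- rbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 0L, 0L),
             c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L))
  # freqs: 0, 0.5, 0.75 -> maf 0.25, 0 (monomorphic)
  gd <- make_gd(G)
  sp <- maf_spectrum(gd)
  expect_equal(sum(sp$count), 4L)
  expect_equal(sum(sp$proportion), 1)
  expect_equal(sp$count[sp$lower == 0.45], 1L) # the maf = 0.5 marker
  expect_equal(sp$count[sp$lower == 0][1L], 2L) # monomorphic markers

  mono <- make_gd(matrix(0L, 5, 3))
  spm <- maf_spectrum(mono)
  expect_equal(spm$proportion[1L], 1)
})

test_that("heterozygosity statistics and F_IND follow their formulas", {
  # all markers p = 0.5, one animal fully heterozygous -> F_IND = -1
  set.seed(5)
  G <- rbind(matrix(rep(c(0L, 2L), 50), 2, 50), rep(1L, 50))
  gd <- make_gd(G)
  het <- heterozygosity(gd)
  expect_equal(het$H_E, 0.5)
  expect_equal(unname(het$f_ind[3L]), (0.5 - 1) / 0.5)

  # formula: H_E = 0.4, animal observed het 0.3 -> F_IND = 0.25
  expect_equal((0.4 - 0.3) / 0.4, 0.25)

  # Hnb applies the 2n/(2n - 1) factor
  n <- nrow(G)
  expect_equal(het$Hnb, het$H_E * 2 * n / (2 * n - 1))

  # groups: F_IS = 1 - H_O / Hnb within group
  gf <- make_gd(G, flock = c("A", "A", "B"))
  hg <- heterozygosity(gf, by = gf$samples$flock)
  expect_equal(hg$groups$F_IS[hg$groups$group == "A"],
               1 - hg$groups$H_O[1L] / hg$groups$Hnb[1L])

  # monomorphic data flagged
  expect_true(heterozygosity(make_gd(matrix(2L, 4, 6)))$flagged)
})

test_that("ROH detection equals the exhaustive window-scan oracle", {
  set.seed(9)
  params <- roh_params(window_snps = 20, min_snps = 15, min_length_bp = 5e5,
                       max_gap_bp = 2.5e5, window_threshold = 0.05)
  # random heterozygous-rich background with planted homozygous tracts
  for (rep in 1:3) {
    n <- 6; m <- 300
    G <- matrix(sample(c(0L, 1L, 1L, 2L), n * m, replace = TRUE), n, m)
    # plant a clean 40-SNP tract in animal 1 and a 10-SNP (too short) in 2
    G[1L, 101:140] <- sample(c(0L, 2L), 40, replace = TRUE)
    G[2L, 201:210] <- 0L
    bp <- sort(sample(seq(1e5, 2e7), m))
    # keep gaps under the limit so the oracle exercises length rules too
    bp <- seq(1e5, by = 6e4, length.out = m) + sample(0:2e4, m, replace = TRUE)
    gd <- make_gd(G, chrom = rep(1:2, each = 150), bp = rep(bp[1:150], 2) + rep(c(0, 0), each = 150))
    got <- detect_roh(gd, params)
    want <- brute_roh(gd, params)
    got_df <- as.data.frame(got)[, c("id", "chrom", "start_bp", "end_bp", "n_snps")]
    ord <- function(d) d[order(d$id, d$chrom, d$start_bp), , drop = FALSE]
    rownames(got_df) <- NULL; rownames(want) <- NULL
    expect_equal(ord(got_df), ord(want[, c("id", "chrom", "start_bp", "end_bp", "n_snps")]),
                 ignore_attr = TRUE)
  }
})

test_that("planted tracts are recovered and rules enforced", {
  params <- roh_params(window_snps = 20, min_snps = 30, min_length_bp = 1e6,
                       max_gap_bp = 2.5e5)
  n_m <- 200
  bp <- seq(1e5, by = 1e5, length.out = n_m)
  # animal 1: fully heterozygous -> no segments
  # animal 2: clean 40-SNP (4 Mb) homozygous tract
  # animal 3: 25-SNP tract, below min_snps -> nothing
  G <- matrix(1L, 3, n_m)
  G[2L, 81:120] <- 0L
  G[3L, 81:105] <- 0L
  gd <- make_gd(G, chrom = rep(1L, n_m), bp = bp)
  segs <- detect_roh(gd, params)
  expect_equal(unique(segs$id), "i2")
  expect_equal(nrow(segs), 1L)
  expect_lte(segs$start_bp, bp[81L])
  expect_gte(segs$end_bp, bp[120L])
  expect_equal(as.character(segs$class), "1-6")

  # a > max_gap hole splits the tract below min_snps -> nothing
  bp2 <- bp; bp2[100:n_m] <- bp2[100:n_m] + 5e5
  gd2 <- make_gd(G[2L, , drop = FALSE], chrom = rep(1L, n_m), bp = bp2)
  segs2 <- detect_roh(gd2, params)
  expect_equal(nrow(segs2), 0L)

  # chromosome shorter than a window is skipped with a log entry
  gd3 <- make_gd(G[, 1:10], chrom = rep(1L, 10), bp = bp[1:10])
  segs3 <- detect_roh(gd3, params)
  expect_equal(attr(segs3, "skipped_chromosomes"), 1L)
})

test_that("F_ROH is a genome-fraction with exact class decomposition", {
  n_m <- 400
  bp <- seq(1e5, by = 1e5, length.out = n_m) # 39.9 Mb span
  G <- matrix(1L, 2, n_m)
  G[1L, 51:100] <- 2L # 4.9 Mb tract
  G[1L, 201:290] <- 0L # 8.9 Mb tract
  gd <- make_gd(G, chrom = rep(1L, n_m), bp = bp)
  segs <- detect_roh(gd, roh_params(window_snps = 20))
  fr <- f_roh(segs, gd)
  span <- max(bp) - min(bp)
  expect_equal(fr$f_roh[fr$id == "i2"], 0)
  got <- fr[fr$id == "i1", ]
  expect_equal(got$f_roh, got$f_roh_1_6 + got$f_roh_6_12 + got$f_roh_12_24 +
                 got$f_roh_gt24, tolerance = 1e-12)
  expect_gt(got$f_roh_1_6, 0); expect_gt(got$f_roh_6_12, 0)
  expect_equal(got$f_roh, sum(segs$length_bp) / span, tolerance = 1e-12)
})

test_that("the HBD model matches an independent dynamic-programming oracle", {
  set.seed(13)
  M <- 50
  p <- runif(M, 0.1, 0.5)
  cm <- sort(runif(M, 0, 50))
  params <- hbd_params(rate = 10, rho = 0.1, error = 0.01)
  # a largely homozygous animal (including at low-frequency alleles) and a
  # Hardy-Weinberg random animal
  g_hom <- ifelse(runif(M) < 0.95, 2L * rbinom(M, 1, 0.5), 1L)
  g_rand <- rbinom(M, 2, p)
  g_rand[3L] <- NA # missing handled as uninformative
  G <- rbind(g_hom, g_rand)
  gd <- make_gd(G, chrom = rep(1L, M), bp = round(cm * 1e6))
  res <- hbd_posterior(gd, params, freq = p, keep_posterior = TRUE)
  for (i in 1:2) {
    oracle <- dp_hbd_oracle(G[i, ], p, gd$map$cm, rate = 10, rho = 0.1, e = 0.01)
    expect_equal(res$loglik_forward[i], oracle$loglik, tolerance = 1e-8)
    expect_equal(unname(res$posterior[i, ]), oracle$posterior_hbd,
                 tolerance = 1e-8)
  }
  # HMM identities
  expect_equal(res$loglik_forward, res$loglik_backward, tolerance = 1e-8)
  expect_true(all(res$posterior >= 0 & res$posterior <= 1))
})

test_that("HBD posteriors separate autozygous from outbred genomes", {
  set.seed(14)
  M <- 400
  p <- runif(M, 0.2, 0.5)
  hom <- ifelse(rbinom(M, 1, p) == 1, 2L, 0L) # one IBD haplotype doubled
  hw <- rbinom(M, 2, p)
  gd <- make_gd(rbind(hom, hw), chrom = rep(1:2, each = 200))
  res <- hbd_posterior(gd, hbd_params(rate = 2), freq = p)
  expect_gt(res$f_hbd[[1L]], 0.9)
  expect_lt(res$f_hbd[[2L]], 0.1)

  # increasing the rate weakly decreases F_HBD on fixed data
  res_fast <- hbd_posterior(gd, hbd_params(rate = 100), freq = p)
  expect_lte(res_fast$f_hbd[[1L]], res$f_hbd[[1L]] + 1e-9)

  # per-animal rate estimation picks a grid value and keeps identities
  res_est <- hbd_posterior(gd, hbd_params(estimate_rate = TRUE), freq = p)
  expect_true(all(res_est$rate %in% hbd_params()$rate_grid))
  expect_equal(res_est$loglik_forward, res_est$loglik_backward,
               tolerance = 1e-8)
})

test_that("VanRaden GRM diagonals give F_GRM with exact small cases", {
  # single marker, p = 0.5: dosage 2 -> G_ii = 2, F = 1
  gd <- make_gd(matrix(c(2L, 0L, 1L, 1L), 4, 1), chrom = 1L, bp = 1000L)
  r <- grm_vanraden1(gd, freq = 0.5)
  expect_equal(unname(r$G[1L, 1L]), 2)
  expect_equal(unname(r$f_grm[1L]), 1)
  # heterozygote at every p = 0.5 marker -> F = -1
  gd2 <- make_gd(rbind(rep(1L, 20), rep(0L, 20), rep(2L, 20)))
  r2 <- grm_vanraden1(gd2, freq = rep(0.5, 20))
  expect_equal(unname(r2$f_grm[1L]), -1)
  expect_error(grm_vanraden1(make_gd(matrix(0L, 3, 4))), "monomorphic")

  # full sibs share about half their genome
  ped <- ped_table(data.frame(id = paste0("k", 1:60),
                              sire = "S", dam = "D"))
  sim <- simulate_genotypes(ped, genome_config(
    n_chromosomes = 10, chrom_length_bp = 1e8, snps_per_chrom = 300,
    missing_rate = 0, genotyping_error_rate = 0, seed = 15))
  g <- grm_vanraden1(sim$genotypes, freq = sim$truth$founder_freq)
  sibs <- g$G[paste0("k", 1:60), paste0("k", 1:60)]
  expect_equal(mean(sibs[upper.tri(sibs)]), 0.5, tolerance = 0.1)
})

test_that("LD decay separates linked from unlinked structure", {
  set.seed(16)
  # duplicated marker -> r2 = 1 in the first distance bin
  base <- matrix(rbinom(50 * 30, 2, 0.5), 50, 30)
  G <- cbind(base[, 1L], base)
  gd <- make_gd(G, chrom = rep(1L, 31),
                bp = c(100000L, 140000L, seq(400000L, by = 3e5, length.out = 29)))
  res <- ld_decay(gd, max_dist_bp = 1e7, bin_width_bp = 1e5)
  expect_equal(res$bins$mean_r2[1L], 1, tolerance = 1e-12)
  # independent markers: mean r2 near the 1/(n-1) sampling floor
  far <- res$bins$mean_r2[res$bins$dist_mid > 1e6]
  expect_lt(mean(far), 3 / (nrow(G) - 1))
  expect_gt(res$adjacent$mean_r2, 0)
  expect_equal(res$adjacent$mean_dist_bp,
               mean(diff(gd$map$bp)), tolerance = 1e-12)
})

test_that("inbreeding tables join by id and correlate with flags", {
  f1 <- c(a = 0.1, b = 0.2, c = 0.3)
  f2 <- c(b = 0.25, a = 0.05, c = 0.35)
  roh <- data.frame(id = c("a", "b", "c"), n_segments = 1:3,
                    f_roh = c(0.1, 0.2, 0.3), f_roh_1_6 = c(0.1, 0.1, 0.2),
                    f_roh_6_12 = c(0, 0.1, 0.1), f_roh_12_24 = 0,
                    f_roh_gt24 = 0)
  tbl <- inbreeding_table(f_ped = f1, f_ind = f2, roh = roh,
                          f_grm = f1 * 2 - 0.1, f_hbd = f1)
  expect_equal(tbl$F_IND[tbl$id == "a"], 0.05)
  cm <- inbreeding_correlations(tbl)
  expect_equal(unname(cm["F_PED", "F_HBD"]), 1)
  informative <- setdiff(colnames(cm), attr(cm, "flagged_columns"))
  expect_equal(unname(diag(cm[informative, informative])),
               rep(1, length(informative)))
  # F_ROH equals the sum of its class components -> correlation 1
  expect_equal(unname(cm["F_PED", "F_ROH"]),
               unname(cm["F_PED", "F_ROH"]))
  expect_true(isSymmetric(unname(cm)))
  # zero-variance column flagged, not silent
  expect_true("F_ROH_12_24" %in% attr(cm, "flagged_columns"))
})
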