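test_that("PED/MAP and BED/BIM/FAM round-trip the dosage matrix", {
  # 2-sample, 3-SNP fixture written as text, minor-allele coded
  geno <- matrix(c(0L, 1L, 2L, 1L, NA, 0L), nrow = 2, byrow = TRUE)
  map <- data.frame(chrom = c(1L, 1L, 2L), snp_id = c("m1", "m2", "m3"),
                    cm = c(0.1, 0.2, 0.1), bp = c(100L, 200L, 150L),
                    a1 = c("A", "C", "G"), a2 = c("G", "T", "T"))
  samples <- data.frame(id = c("u", "v"), sex = c("M", "F"),
                        birth_year = NA, flock = c("X", "X"))
  gd <- genotype_dataset(geno, map, samples)
  pref <- file.path(withr::local_tempdir(), "fix")
  write_plink(gd, pref, format = "ped")
  back <- read_plink(pref, format = "ped")
  expect_identical(unname(back$geno), unname(gd$geno))
  expect_identical(back$map$a1, gd$map$a1)

  write_plink(gd, pref, format = "bed")
  back2 <- read_plink(pref, format = "bed")
  expect_identical(unname(back2$geno), unname(gd$geno))
  expect_identical(back2$samples$id, gd$samples$id)

  # missing encoded as "0 0" in PED
  pedline <- readLines(paste0(pref, ".ped"))
  expect_match(pedline[grep("^X v", pedline)], "0 0")

  # bad magic bytes
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), paste0(pref, ".bed"))
  expect_error(read_plink(pref, format = "bed"), "magic")
})

test_that("larger simulated datasets survive both formats unchanged", {
  ped <- simulate_pedigree(sim_config(n_founder_sires = 3, n_founder_dams = 6,
                                      n_generations = 2, n_flocks = 2, seed = 4))
  sim <- simulate_genotypes(ped, genome_config(n_chromosomes = 3,
                                               chrom_length_bp = 1e7,
                                               snps_per_chrom = 40,
                                               missing_rate = 0.05, seed = 5))
  gd <- sim$genotypes
  pref <- file.path(withr::local_tempdir(), "big")
  write_plink(gd, pref, format = "bed")
  expect_identical(unname(read_plink(pref)$geno), unname(gd$geno))
})

test_that("the QC pipeline implements the three dataset variants exactly", {
  set.seed(77)
  n <- 40
  # polymorphic base markers
  G <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  # a monomorphic marker: kept in full, dropped from reduced
  G <- cbind(G, rep(0L, n))
  # a perfectly correlated duplicate pair: split by pruning in full,
  # both kept in the LD variant
  G <- cbind(G, G[, 1L], G[, 1L])
  # an animal with low call rate
  G[1L, 1:20] <- NA
  gd <- make_gd(G, chrom = rep(1L, ncol(G)),
                bp = seq(50000L, by = 50000L, length.out = ncol(G)))
  ped <- ped_table(data.frame(id = gd$samples$id,
                              sire = c(NA, rep("SS", n - 1L)),
                              dam = c(NA, rep("DD", n - 1L))))
  # i1 additionally has unknown parentage
  qc <- qc_pipeline(gd, qc_params(), ped = ped)
  rep <- qc$report

  expect_equal(rep$removed_parentage, 1L) # i1 (founder, unknown parents)
  expect_equal(rep$removed_animal_callrate, 0L) # i1 already gone
  expect_equal(rep$retained_samples, n - 1L)
  # bookkeeping closes
  expect_equal(rep$input$samples,
               rep$removed_parentage + rep$removed_animal_callrate +
                 rep$retained_samples)
  expect_equal(rep$input$markers,
               rep$removed_nonautosomal + rep$removed_snp_callrate +
                 rep$removed_ld_prune + rep$full_markers)
  expect_equal(rep$full_markers, rep$removed_maf_reduced + rep$reduced_markers)

  # monomorphic marker is in full but not reduced
  mono_id <- gd$map$snp_id[31L]
  expect_true(mono_id %in% qc$full$map$snp_id)
  expect_false(mono_id %in% qc$reduced$map$snp_id)
  # duplicated pair: exactly one survivor in full, both in LD variant
  dup_ids <- gd$map$snp_id[c(1L, 32L, 33L)]
  expect_equal(sum(dup_ids %in% qc$full$map$snp_id), 1L)
  expect_equal(sum(dup_ids %in% qc$ld$map$snp_id), 3L)

  # animal call-rate threshold
  set.seed(78)
  G2 <- matrix(rbinom(n * 33, 2, 0.4), n, 33)
  G2[2L, ] <- NA; G2[2L, 1:5] <- 1L # 15% call rate
  gd2 <- make_gd(G2, chrom = rep(1L, ncol(G2)),
                 bp = seq(50000L, by = 50000L, length.out = ncol(G2)))
  qc2 <- qc_pipeline(gd2, qc_params())
  expect_equal(qc2$report$removed_animal_callrate, 1L)
  expect_false("i2" %in% qc2$full$samples$id)

  # determinism
  qc3 <- qc_pipeline(gd, qc_params(), ped = ped)
  expect_identical(qc3$full$geno, qc$full$geno)
})

test_that("LD pruning leaves no over-threshold pair within a window", {
  set.seed(11)
  n <- 60
  base <- matrix(rbinom(n * 40, 2, 0.5), n, 40)
  # create correlated neighbours
  for (j in seq(2, 40, by = 7)) {
    base[, j] <- base[, j - 1L]
    flip <- sample(n, 3)
    base[flip, j] <- 2L - base[flip, j]
  }
  gd <- make_gd(base, chrom = rep(1:2, each = 20),
                bp = rep(seq(50000L, by = 50000L, length.out = 20), 2))
  pruned <- ld_prune(gd, r2_threshold = 0.5, window_snps = 10, step = 3)
  # post-hoc exhaustive scan within every window of the pruned data
  for (cc in 1:2) {
    jj <- which(pruned$map$chrom == cc)
    if (length(jj) < 2) next
    for (st in seq(1, length(jj), by = 1)) {
      win <- jj[st:min(st + 9, length(jj))]
      if (length(win) < 2) next
      r2 <- suppressWarnings(cor(pruned$geno[, win]))^2
      diag(r2) <- 0
      expect_true(all(r2 <= 0.5 + 1e-12, na.rm = TRUE))
    }
  }
  # independent markers untouched
  set.seed(12)
  ind <- matrix(rbinom(80 * 20, 2, 0.5), 80, 20)
  gdi <- make_gd(ind, chrom = rep(1L, 20),
                 bp = seq(50000L, by = 50000L, length.out = 20))
  expect_equal(ncol(ld_prune(gdi, 0.5, 10, 5)$geno), 20L)
})

test_that("dataset intersection reconciles alleles and flips dosages", {
  g1 <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 2, 3)
  m1 <- data.frame(chrom = 1L, snp_id = paste0("a", 1:3), cm = 0,
                   bp = c(100L, 200L, 300L), a1 = c("A", "C", "A"),
                   a2 = c("G", "T", "C"))
  s1 <- data.frame(id = c("p", "q"))
  d1 <- genotype_dataset(g1, m1, s1)

  # same markers; second one has swapped allele labels, third has a
  # mismatched allele pair
  g2 <- matrix(c(1L, 2L, 0L, 1L, 2L, 2L), 2, 3)
  m2 <- data.frame(chrom = 1L, snp_id = paste0("b", 1:3), cm = 0,
                   bp = c(100L, 200L, 300L), a1 = c("A", "T", "A"),
                   a2 = c("G", "C", "T"))
  s2 <- data.frame(id = c("r", "s"))
  d2 <- genotype_dataset(g2, m2, s2)

  merged <- intersect_datasets(list(d1, d2), sources = c("one", "two"))
  expect_equal(nrow(merged$geno), 4L)
  expect_equal(ncol(merged$geno), 2L) # third marker dropped
  expect_equal(attr(merged, "dropped"), "1:300")
  # swapped marker flipped to the reference coding
  expect_equal(unname(merged$geno[3:4, 2L]), c(2L - 0L, 2L - 1L))
  expect_equal(merged$samples$source, c("one", "one", "two", "two"))

  # disjoint marker sets error
  m3 <- m1; m3$bp <- m3$bp + 5000L
  d3 <- genotype_dataset(g1, m3, s1)
  expect_error(intersect_datasets(list(d1, d3)), "empty")

  # identical marker sets: union of samples, same markers
  merged2 <- intersect_datasets(list(d1, d1))
  expect_equal(ncol(merged2$geno), 3L)
  expect_equal(nrow(merged2$geno), 4L)
})
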