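#' Pedigree simulation settings
#'
#' Defaults emulate a multi-flock sheep population with overlapping birth
#' years recorded through a national improvement program: a modest number of
#' widely used rams, many more dams, several flocks with occasional ram
#' exchange, and a roughly three-year generation turnover.
#'
#' @param n_founder_sires,n_founder_dams founder counts
#' @param n_generations number of discrete generations to simulate (0 =
#'   founders only)
#' @param offspring_per_dam litter-career total per dam per generation
#' @param sire_reuse_max progeny cap per sire; when all local rams are at
#'   their cap the least-used ram is reused
#' @param n_flocks number of flocks; founders are assigned round-robin
#' @param migration_rate probability a dam is mated to a ram from another
#'   flock
#' @param mating_scheme `"random"`, `"circular"` (rotational ram exchange
#'   between neighbouring flocks) or `"inbred_line"` (repeated full-sib
#'   mating within founder-pair lines)
#' @param birth_year_start year of birth of the founder generation
#' @param generation_span_years years between generation midpoints; births
#'   are jittered by up to one year around the generation midpoint
#' @param seed RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_founder_sires = 50, n_founder_dams = 200,
                       n_generations = 8, offspring_per_dam = 3,
                       sire_reuse_max = 30, n_flocks = 8,
                       migration_rate = 0.1,
                       mating_scheme = c("random", "circular", "inbred_line"),
                       birth_year_start = 2000, generation_span_years = 3,
                       seed = 1) {
  cfg <- list(
    n_founder_sires = .assert_count(n_founder_sires, "n_founder_sires"),
    n_founder_dams = .assert_count(n_founder_dams, "n_founder_dams"),
    n_generations = .assert_count(n_generations, "n_generations", min = 0L),
    offspring_per_dam = .assert_count(offspring_per_dam, "offspring_per_dam"),
    sire_reuse_max = .assert_count(sire_reuse_max, "sire_reuse_max"),
    n_flocks = .assert_count(n_flocks, "n_flocks"),
    migration_rate = .assert_prob(migration_rate, "migration_rate"),
    mating_scheme = match.arg(mating_scheme),
    birth_year_start = .assert_count(birth_year_start, "birth_year_start"),
    generation_span_years = .assert_count(generation_span_years,
                                          "generation_span_years"),
    seed = .assert_count(seed, "seed", min = 0L))
  class(cfg) <- "sim_config"
  cfg
}

#' Genome / genotyping simulation settings
#'
#' Defaults emulate a filtered medium-density (50K class) ovine array: 26
#' autosomes, a constant 1 cM/Mb map, a U-shaped founder allele-frequency
#' spectrum truncated at the array's typical MAF filter, and low missingness
#' and genotyping error rates.
#'
#' @param n_chromosomes autosome count
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal)
#' @param snps_per_chrom markers per chromosome (>= 2)
#' @param cM_per_Mb constant recombination rate
#' @param maf_beta length-2 Beta shape parameters for founder minor-allele
#'   frequencies
#' @param maf_range truncation range for founder frequencies
#' @param missing_rate per-genotype missingness probability
#' @param genotyping_error_rate per-allele symmetric flip probability
#' @param seed RNG seed
#' @return list of class `genome_config`
#' @export
genome_config <- function(n_chromosomes = 26, chrom_length_bp = 1e8,
                          snps_per_chrom = 2000, cM_per_Mb = 1,
                          maf_beta = c(0.5, 0.5), maf_range = c(0.01, 0.5),
                          missing_rate = 0.005,
                          genotyping_error_rate = 0.001, seed = 1) {
  stopifnot(length(maf_beta) == 2L, all(maf_beta > 0),
            length(maf_range) == 2L, maf_range[1] >= 0, maf_range[2] <= 0.5,
            cM_per_Mb >= 0, chrom_length_bp >= 1)
  cfg <- list(
    n_chromosomes = .assert_count(n_chromosomes, "n_chromosomes"),
    chrom_length_bp = chrom_length_bp,
    snps_per_chrom = .assert_count(snps_per_chrom, "snps_per_chrom", min = 2L),
    cM_per_Mb = cM_per_Mb,
    maf_beta = as.numeric(maf_beta), maf_range = as.numeric(maf_range),
    missing_rate = .assert_prob(missing_rate, "missing_rate"),
    genotyping_error_rate = .assert_prob(genotyping_error_rate,
                                         "genotyping_error_rate"),
    seed = .assert_count(seed, "seed", min = 0L))
  class(cfg) <- "genome_config"
  cfg
}

#' Simulate a multi-flock pedigree
#'
#' Discrete generations with jittered birth years. Dams are the females of
#' the previous generation; each produces `offspring_per_dam` offspring by a
#' ram chosen according to the mating scheme. Offspring sexes alternate
#' within each flock so every flock retains rams and ewes. Offspring belong
#' to their dam's flock; migration only changes which flock the ram is drawn
#' from.
#'
#' @param cfg a [sim_config()]
#' @return a [ped_table()]
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mating_scheme == "inbred_line") {
    if (cfg$n_founder_sires != cfg$n_founder_dams)
      stop("inbred_line requires equal numbers of founder sires and dams",
           call. = FALSE)
    if (cfg$n_generations >= 2L && cfg$offspring_per_dam < 2L)
      stop("inbred_line with >= 2 generations needs offspring_per_dam >= 2",
           call. = FALSE)
  }
  set.seed(cfg$seed)
  flocks <- paste0("FL", seq_len(cfg$n_flocks))
  nf <- cfg$n_founder_sires + cfg$n_founder_dams
  id <- paste0("A", seq_len(nf))
  sex <- c(rep("M", cfg$n_founder_sires), rep("F", cfg$n_founder_dams))
  flock <- c(flocks[(seq_len(cfg$n_founder_sires) - 1L) %% cfg$n_flocks + 1L],
             flocks[(seq_len(cfg$n_founder_dams) - 1L) %% cfg$n_flocks + 1L])
  year <- rep(cfg$birth_year_start, nf) +
    sample(c(-1L, 0L, 1L), nf, replace = TRUE)
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  counter <- nf
  ## line bookkeeping for inbred_line: current (sire, dam) pair per line
  lines <- if (cfg$mating_scheme == "inbred_line")
    Map(c, id[sex == "M"], id[sex == "F"]) else NULL

  prev_idx <- seq_len(nf)
  for (g in seq_len(cfg$n_generations)) {
    base_year <- cfg$birth_year_start + g * cfg$generation_span_years
    new_id <- character(0); new_sire <- character(0); new_dam <- character(0)
    new_sex <- character(0); new_flock <- character(0); new_year <- integer(0)

    if (cfg$mating_scheme == "inbred_line") {
      next_lines <- vector("list", length(lines))
      for (li in seq_along(lines)) {
        pr <- lines[[li]]
        k <- cfg$offspring_per_dam
        counter_new <- counter + seq_len(k)
        ids <- paste0("A", counter_new)
        counter <- counter + k
        sx <- rep(c("M", "F"), length.out = k)
        new_id <- c(new_id, ids); new_sire <- c(new_sire, rep(pr[[1L]], k))
        new_dam <- c(new_dam, rep(pr[[2L]], k)); new_sex <- c(new_sex, sx)
        new_flock <- c(new_flock, rep(flock[match(pr[[2L]], id)], k))
        py <- max(year[match(pr, id)])
        yy <- pmax(base_year + sample(c(-1L, 0L, 1L), k, replace = TRUE), py + 1L)
        new_year <- c(new_year, yy)
        next_lines[[li]] <- c(ids[match("M", sx)], ids[match("F", sx)])
      }
      lines <- next_lines
    } else {
      prev_m <- prev_idx[sex[prev_idx] == "M"]
      prev_f <- prev_idx[sex[prev_idx] == "F"]
      if (!length(prev_f)) stop("no dams available in generation ", g, call. = FALSE)
      if (!length(prev_m)) stop("no sires available in generation ", g, call. = FALSE)
      use <- integer(length(id) + length(prev_f) * cfg$offspring_per_dam) # progeny per sire idx
      per_flock_count <- stats::setNames(integer(length(flocks)), flocks)
      for (dm in prev_f) {
        dfl <- flock[dm]
        sfl <- dfl
        if (cfg$mating_scheme == "circular" && cfg$n_flocks > 1L) {
          sfl <- flocks[(match(dfl, flocks) %% cfg$n_flocks) + 1L]
        } else if (cfg$n_flocks > 1L && cfg$migration_rate > 0 &&
                   stats::runif(1) < cfg$migration_rate) {
          sfl <- sample(setdiff(flocks, dfl), 1L)
        }
        cand <- prev_m[flock[prev_m] == sfl]
        if (!length(cand)) cand <- prev_m # fallback: no ram in target flock
        under <- cand[use[cand] + cfg$offspring_per_dam <= cfg$sire_reuse_max]
        sr <- if (length(under)) under[sample.int(length(under), 1L)]
          else cand[which.min(use[cand])]
        use[sr] <- use[sr] + cfg$offspring_per_dam
        k <- cfg$offspring_per_dam
        ids <- paste0("A", counter + seq_len(k))
        counter <- counter + k
        sx <- character(k)
        for (j in seq_len(k)) {
          sx[j] <- if (per_flock_count[[dfl]] %% 2L == 0L) "M" else "F"
          per_flock_count[[dfl]] <- per_flock_count[[dfl]] + 1L
        }
        py <- max(year[c(sr, dm)])
        yy <- pmax(base_year + sample(c(-1L, 0L, 1L), k, replace = TRUE), py + 1L)
        new_id <- c(new_id, ids); new_sire <- c(new_sire, rep(id[sr], k))
        new_dam <- c(new_dam, rep(id[dm], k)); new_sex <- c(new_sex, sx)
        new_flock <- c(new_flock, rep(dfl, k)); new_year <- c(new_year, yy)
      }
    }
    first_new <- length(id) + 1L
    id <- c(id, new_id); sire <- c(sire, new_sire); dam <- c(dam, new_dam)
    sex <- c(sex, new_sex); flock <- c(flock, new_flock); year <- c(year, new_year)
    prev_idx <- first_new:length(id)
  }
  ped_table(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                       birth_year = year, flock = flock,
                       stringsAsFactors = FALSE))
}

#' Gene-drop genotypes through a pedigree with tracked founder origins
#'
#' Founder haplotypes carry unique origin labels and alleles drawn per locus
#' from the founder frequency spectrum. Each meiosis recombines between
#' adjacent loci with probability 0.5 (1 - exp(-2 d)) for map distance d in
#' Morgans (Haldane, no interference), and the origin label travels with the
#' allele. True autozygosity (fraction of loci where the two homologs carry
#' the same founder-haplotype label) is recorded *before* genotyping error
#' and missingness are applied.
#'
#' @param ped a [ped_table()]; every non-founder must have both parents
#'   recorded and every parent must have a recorded sex (use the `ped_table`
#'   constructor's `check_sex_conflict = FALSE` only for deliberate
#'   degenerate cases such as selfing)
#' @param gcfg a [genome_config()]
#' @return list with `genotypes` (a [genotype_dataset()]) and `truth` (class
#'   `sim_truth`: `autozygosity` per animal, `founder_origin` label matrices,
#'   `founder_freq` per marker)
#' @export
simulate_genotypes <- function(ped, gcfg) {
  stopifnot(inherits(gcfg, "genome_config"))
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  idx <- .ped_idx(ped)
  s <- idx$sire; d <- idx$dam
  if (any(xor(s == 0L, d == 0L)))
    stop("non-founders must have both parents recorded", call. = FALSE)
  parents <- unique(c(s[s > 0L], d[d > 0L]))
  if (any(is.na(ped$sex[parents])))
    stop("parent with unknown sex: ", ped$id[parents[is.na(ped$sex[parents])][1L]],
         call. = FALSE)
  set.seed(gcfg$seed)
  n <- nrow(ped)
  nc <- gcfg$n_chromosomes
  m_per <- gcfg$snps_per_chrom
  M <- nc * m_per

  ## marker positions: jittered regular grid, emulating array design spacing
  bp <- integer(0); chrom <- integer(0)
  spacing <- gcfg$chrom_length_bp / m_per
  for (cc in seq_len(nc)) {
    pos <- round((seq_len(m_per) - 0.5) * spacing +
                   stats::runif(m_per, -0.3, 0.3) * spacing)
    pos <- pmin(pmax(pos, 1), gcfg$chrom_length_bp)
    pos <- sort(pos)
    while (anyDuplicated(pos)) { # nudge rare collisions apart
      dupi <- which(duplicated(pos))
      pos[dupi] <- pos[dupi] + 1L
      pos <- sort(pmin(pos, gcfg$chrom_length_bp))
    }
    bp <- c(bp, pos); chrom <- c(chrom, rep(cc, m_per))
  }
  cm <- bp / 1e6 * gcfg$cM_per_Mb
  ## recombination prob between adjacent loci (Haldane), 0.5 across chromosomes
  rr <- numeric(M)
  for (cc in seq_len(nc)) {
    j <- which(chrom == cc)
    rr[j] <- c(0.5, 0.5 * (1 - exp(-2 * diff(cm[j]) / 100)))
  }
  rr[1L] <- 0.5

  p <- stats::rbeta(M, gcfg$maf_beta[1L], gcfg$maf_beta[2L])
  bad <- p < gcfg$maf_range[1L] | p > gcfg$maf_range[2L]
  while (any(bad)) {
    p[bad] <- stats::rbeta(sum(bad), gcfg$maf_beta[1L], gcfg$maf_beta[2L])
    bad <- p < gcfg$maf_range[1L] | p > gcfg$maf_range[2L]
  }

  H1 <- matrix(0L, n, M); H2 <- matrix(0L, n, M)
  L1 <- matrix(0L, n, M); L2 <- matrix(0L, n, M)
  next_label <- 1L
  chrom_starts <- which(c(TRUE, diff(chrom) != 0))

  gamete <- function(pi) {
    ## switch process over the whole map; chromosome starts have r = 0.5
    sw <- stats::rbinom(M, 1L, rr)
    src <- (cumsum(sw) %% 2L) == 0L
    list(allele = ifelse(src, H1[pi, ], H2[pi, ]),
         label = ifelse(src, L1[pi, ], L2[pi, ]))
  }

  for (i in seq_len(n)) {
    if (s[i] == 0L) { # founder
      H1[i, ] <- stats::rbinom(M, 1L, p)
      H2[i, ] <- stats::rbinom(M, 1L, p)
      L1[i, ] <- next_label; L2[i, ] <- next_label + 1L
      next_label <- next_label + 2L
    } else {
      g1 <- gamete(s[i]); g2 <- gamete(d[i])
      H1[i, ] <- g1$allele; H2[i, ] <- g2$allele
      L1[i, ] <- g1$label; L2[i, ] <- g2$label
    }
  }

  autoz <- rowMeans(L1 == L2)
  names(autoz) <- ped$id
  truth <- structure(list(autozygosity = autoz,
                          founder_origin = list(hap1 = L1, hap2 = L2),
                          founder_freq = p),
                     class = "sim_truth")

  e <- gcfg$genotyping_error_rate
  if (e > 0) {
    H1 <- abs(H1 - matrix(stats::rbinom(n * M, 1L, e), n, M))
    H2 <- abs(H2 - matrix(stats::rbinom(n * M, 1L, e), n, M))
  }
  G <- H1 + H2
  if (gcfg$missing_rate > 0)
    G[matrix(stats::runif(n * M) < gcfg$missing_rate, n, M)] <- NA_integer_
  rownames(G) <- ped$id

  map <- data.frame(chrom = chrom, snp_id = sprintf("snp%d_%d", chrom, bp),
                    cm = cm, bp = bp, a1 = "A", a2 = "B",
                    stringsAsFactors = FALSE)
  samples <- data.frame(id = ped$id, sex = ped$sex,
                        birth_year = ped$birth_year, flock = ped$flock,
                        stringsAsFactors = FALSE)
  list(genotypes = genotype_dataset(G, map, samples), truth = truth)
}

#' True autozygosity from simulation truth
#'
#' Fraction of loci at which the two homologs carry the same founder
#' haplotype label. Founders, whose two haplotypes are labelled distinctly,
#' score exactly 0.
#'
#' @param truth a `sim_truth` from [simulate_genotypes()]
#' @return named numeric vector in pedigree order
#' @export
true_autozygosity <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- rowMeans(truth$founder_origin$hap1 == truth$founder_origin$hap2)
  names(out) <- names(truth$autozygosity)
  out
}

#' Write simulated data to disk
#'
#' Pedigree as CSV (unknown parent = "0"), genotypes as PLINK PED/MAP, and
#' truth as a TSV of per-animal true autozygosity.
#'
#' @param sim result of [simulate_genotypes()]
#' @param ped the simulated [ped_table()]
#' @param dir output directory (created if needed)
#' @param prefix basename for outputs
#' @return invisibly, the paths written
#' @export
write_simulation <- function(sim, ped, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pped <- file.path(dir, paste0(prefix, "_pedigree.csv"))
  write_pedigree(ped, pped)
  write_plink(sim$genotypes, file.path(dir, prefix), format = "ped")
  ptr <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(
    data.frame(id = names(sim$truth$autozygosity),
               true_autozygosity = as.numeric(sim$truth$autozygosity)),
    ptr, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(pped, file.path(dir, paste0(prefix, c(".ped", ".map"))), ptr))
}
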