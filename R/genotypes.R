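#' Construct a SNP genotype dataset
#'
#' Container for a sample-by-marker dosage matrix in {0, 1, 2, NA} together
#' with a marker map and sample metadata. Markers are sorted by chromosome
#' and position on construction; positions must be strictly increasing
#' within a chromosome.
#'
#' @param geno integer/numeric matrix, samples in rows, markers in columns,
#'   values 0/1/2/NA counting copies of allele `a1`
#' @param map data frame with columns `chrom` (integer), `snp_id`, `cm`,
#'   `bp`, `a1`, `a2`
#' @param samples data frame with columns `id` and optionally `sex`,
#'   `birth_year`, `flock`
#' @return object of class `geno_ds`
#' @export
genotype_dataset <- function(geno, map, samples) {
  stopifnot(is.matrix(geno), is.data.frame(map), is.data.frame(samples))
  if (ncol(geno) != nrow(map))
    stop("geno has ", ncol(geno), " markers but map has ", nrow(map), call. = FALSE)
  if (nrow(geno) != nrow(samples))
    stop("geno has ", nrow(geno), " samples but samples has ", nrow(samples),
         call. = FALSE)
  need <- c("chrom", "snp_id", "cm", "bp", "a1", "a2")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("map lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"id" %in% names(samples)) stop("samples needs an `id` column", call. = FALSE)
  for (col in c("sex", "birth_year", "flock"))
    if (!col %in% names(samples)) samples[[col]] <- NA
  bad <- !(geno %in% c(0, 1, 2)) & !is.na(geno)
  if (any(bad)) stop("genotype values outside {0,1,2,NA}", call. = FALSE)
  o <- order(map$chrom, map$bp)
  map <- map[o, , drop = FALSE]
  geno <- geno[, o, drop = FALSE]
  dup <- stats::ave(map$bp, map$chrom, FUN = function(x) c(FALSE, diff(x) <= 0))
  if (any(dup == 1))
    stop("marker positions not strictly increasing within chromosome",
         call. = FALSE)
  rownames(map) <- NULL; rownames(samples) <- NULL
  storage.mode(geno) <- "integer"
  rownames(geno) <- samples$id
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map, samples = samples), class = "geno_ds")
}

#' @export
print.geno_ds <- function(x, ...) {
  cat(sprintf("<geno_ds> %d samples x %d markers on %d chromosome(s); %.2f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.geno_ds <- function(x) dim(x$geno)

#' Subset a genotype dataset
#'
#' @param gd a `geno_ds`
#' @param samples logical/integer/character selector of samples
#' @param markers logical/integer selector of markers
#' @return a `geno_ds`
#' @export
subset_geno <- function(gd, samples = NULL, markers = NULL) {
  stopifnot(inherits(gd, "geno_ds"))
  si <- if (is.null(samples)) seq_len(nrow(gd$geno))
        else if (is.character(samples)) match(samples, gd$samples$id)
        else samples
  mi <- if (is.null(markers)) seq_len(ncol(gd$geno)) else markers
  genotype_dataset(gd$geno[si, mi, drop = FALSE],
                   gd$map[mi, , drop = FALSE],
                   gd$samples[si, , drop = FALSE])
}

## per-marker allele-1 frequency from non-missing genotypes
.allele_freq <- function(gd) colMeans(gd$geno, na.rm = TRUE) / 2

## per-marker minor allele frequency
.maf <- function(gd) {
  p <- .allele_freq(gd)
  pmin(p, 1 - p)
}

#' Read PLINK-format genotypes
#'
#' Supports text PED/MAP and binary BED/BIM/FAM (v1.9 SNP-major BED). Dosage
#' is normalized to count the minor allele (A1 in BIM terms; for PED input
#' the minor allele is determined from the data, ties broken towards the
#' lexicographically smaller allele). `"0 0"` allele pairs (PED) and the
#' 01 bit pattern (BED) are missing. The PLINK family ID is carried as the
#' `flock` label.
#'
#' @param prefix path prefix (without extension)
#' @param format `"auto"` (default: BED if present), `"ped"` or `"bed"`
#' @return a [genotype_dataset()]
#' @export
read_plink <- function(prefix, format = c("auto", "ped", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (file.exists(paste0(prefix, ".bed"))) "bed" else "ped"
  if (format == "bed") .read_bed(prefix) else .read_ped(prefix)
}

.read_map <- function(path) {
  map <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp"))
  map$chrom <- suppressWarnings(as.integer(map$chrom))
  if (anyNA(map$chrom))
    stop("malformed variant line ", which(is.na(map$chrom))[1L], " in ", path,
         call. = FALSE)
  map
}

.read_ped <- function(prefix) {
  map <- .read_map(paste0(prefix, ".map"))
  m <- nrow(map)
  lines <- readLines(paste0(prefix, ".ped"))
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- 6L + 2L * m
  badlen <- which(vapply(toks, length, 1L) != nfield)
  if (length(badlen))
    stop("malformed PED line ", badlen[1L], ": expected ", nfield, " fields",
         call. = FALSE)
  n <- length(toks)
  fam <- t(vapply(toks, function(x) x[1:6], character(6L)))
  al <- matrix("", n, 2L * m)
  for (i in seq_len(n)) al[i, ] <- toks[[i]][-(1:6)]
  a_first <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a_second <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  geno <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x <- c(a_first[, j], a_second[, j])
    x[x == "0"] <- NA
    alle <- sort(unique(x[!is.na(x)]))
    if (length(alle) > 2L)
      stop("marker ", map$snp_id[j], " has more than two alleles", call. = FALSE)
    if (length(alle) == 0L) alle <- c("0", "0")
    cnt <- table(factor(x, levels = alle))
    minor <- if (length(alle) == 1L) alle else
      alle[order(as.integer(cnt), alle)][1L]
    major <- setdiff(alle, minor)[1L]
    if (is.na(major)) major <- minor
    a1[j] <- minor; a2[j] <- major
    g <- (a_first[, j] == minor) + (a_second[, j] == minor)
    g[a_first[, j] == "0" | a_second[, j] == "0"] <- NA_integer_
    geno[, j] <- g
  }
  map$a1 <- a1; map$a2 <- a2
  samples <- data.frame(id = fam[, 2L],
                        sex = c("M", "F")[match(fam[, 5L], c("1", "2"))],
                        birth_year = NA_integer_, flock = fam[, 1L],
                        stringsAsFactors = FALSE)
  genotype_dataset(geno, map, samples)
}

.read_bed <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp", "a1", "a2"))
  bim$chrom <- suppressWarnings(as.integer(bim$chrom))
  if (anyNA(bim$chrom))
    stop("malformed variant line ", which(is.na(bim$chrom))[1L], " in ",
         prefix, ".bim", call. = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + m * bytes_per_snp)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", prefix, ".bed", call. = FALSE)
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major BED files are supported", call. = FALSE)
  if (length(raw) != 3L + m * bytes_per_snp)
    stop("BED file size does not match FAM/BIM dimensions", call. = FALSE)
  ## 2-bit codes per byte, low bits first: 00 = hom A1 (dosage 2),
  ## 01 = missing, 10 = het, 11 = hom A2 (dosage 0)
  lut <- matrix(NA_integer_, 256L, 4L)
  codes <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  for (b in 0:255) {
    q <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
    lut[b + 1L, ] <- codes[as.character(q)]
  }
  body <- as.integer(raw[-(1:3)])
  gm <- matrix(t(lut[body + 1L, , drop = FALSE]), nrow = 4L * bytes_per_snp)
  geno <- gm[seq_len(n), , drop = FALSE]
  map <- bim[, c("chrom", "snp_id", "cm", "bp", "a1", "a2")]
  samples <- data.frame(id = fam$iid,
                        sex = c("M", "F")[match(fam$sex, c(1L, 2L))],
                        birth_year = NA_integer_, flock = fam$fid,
                        stringsAsFactors = FALSE)
  genotype_dataset(geno, map, samples)
}

#' Write PLINK-format genotypes
#'
#' @param gd a [genotype_dataset()]
#' @param prefix output path prefix
#' @param format `"ped"` (text PED/MAP) or `"bed"` (binary BED/BIM/FAM,
#'   SNP-major)
#' @return invisibly, the paths written
#' @export
write_plink <- function(gd, prefix, format = c("ped", "bed")) {
  stopifnot(inherits(gd, "geno_ds"))
  format <- match.arg(format)
  sexcode <- ifelse(gd$samples$sex %in% "M", "1",
                    ifelse(gd$samples$sex %in% "F", "2", "0"))
  fid <- ifelse(is.na(gd$samples$flock), "0", gd$samples$flock)
  if (format == "ped") {
    utils::write.table(gd$map[, c("chrom", "snp_id", "cm", "bp")],
                       paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    n <- nrow(gd$geno); m <- ncol(gd$geno)
    out <- matrix("0", n, 2L * m)
    for (j in seq_len(m)) {
      g <- gd$geno[, j]
      f <- rep(gd$map$a2[j], n); s <- rep(gd$map$a2[j], n)
      f[g >= 1 & !is.na(g)] <- gd$map$a1[j]
      s[g == 2 & !is.na(g)] <- gd$map$a1[j]
      f[is.na(g)] <- "0"; s[is.na(g)] <- "0"
      out[, 2L * j - 1L] <- f; out[, 2L * j] <- s
    }
    lines <- cbind(fid, gd$samples$id, "0", "0", sexcode, "-9", out)
    utils::write.table(lines, paste0(prefix, ".ped"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(paste0(prefix, c(".ped", ".map")))
  } else {
    utils::write.table(
      cbind(fid, gd$samples$id, "0", "0", sexcode, "-9"),
      paste0(prefix, ".fam"), sep = " ", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(gd$map[, c("chrom", "snp_id", "cm", "bp", "a1", "a2")],
                       paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    n <- nrow(gd$geno); m <- ncol(gd$geno)
    bytes_per_snp <- ceiling(n / 4)
    code <- function(g) { # dosage of a1 -> 2-bit code
      out <- integer(length(g))
      out[is.na(g)] <- 1L
      out[!is.na(g) & g == 2L] <- 0L
      out[!is.na(g) & g == 1L] <- 2L
      out[!is.na(g) & g == 0L] <- 3L
      out
    }
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    pad <- 4L * bytes_per_snp - n
    mult <- c(1L, 4L, 16L, 64L)
    for (j in seq_len(m)) {
      q <- c(code(gd$geno[, j]), rep(0L, pad))
      qm <- matrix(q, nrow = 4L)
      writeBin(as.raw(colSums(qm * mult)), con)
    }
    invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
  }
}
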