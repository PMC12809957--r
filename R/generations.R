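#' Per-animal generation-depth metrics
#'
#' Computes, for every animal, the maximum number of generations to its
#' furthest known ancestor, the number of complete generations (the deepest
#' generation in which *all* ancestors are known), and the equivalent
#' complete generations, the sum of (1/2)^n over all known ancestors where n
#' is the generation separating the ancestor from the animal. Founders score
#' zero on all three.
#'
#' @param ped a [ped_table()]
#' @return data frame with columns `id`, `max_generations`,
#'   `complete_generations`, `equivalent_complete_generations`
#' @export
generation_metrics <- function(ped) {
  idx <- .ped_idx(ped)
  s <- idx$sire; d <- idx$dam
  n <- nrow(ped)
  gmax <- integer(n); gcomp <- integer(n); teq <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    gmax[i] <- if (si == 0L && di == 0L) 0L else
      1L + max(if (si > 0L) gmax[si] else 0L, if (di > 0L) gmax[di] else 0L)
    gcomp[i] <- if (si == 0L || di == 0L) 0L else 1L + min(gcomp[si], gcomp[di])
    teq[i] <- 0.5 * ((if (si > 0L) 1 + teq[si] else 0) +
                     (if (di > 0L) 1 + teq[di] else 0))
  }
  data.frame(id = ped$id, max_generations = gmax,
             complete_generations = gcomp,
             equivalent_complete_generations = teq,
             stringsAsFactors = FALSE)
}

#' Pedigree completeness index
#'
#' MacCluer-style completeness over a fixed ancestral depth `d`. For each
#' parental line, C = (1/d) * sum over generations i = 1..d of the proportion
#' of known ancestors in generation i of that line (generation 1 of the
#' paternal line is the sire itself). The index is the harmonic-type mean
#' PCI = 2 * C_sire * C_dam / (C_sire + C_dam), and 0 when either side is
#' entirely unknown.
#'
#' @param ped a [ped_table()]
#' @param depth number of ancestral generations to score (default 5)
#' @return data frame with columns `id`, `pci`
#' @export
pedigree_completeness <- function(ped, depth = 5L) {
  depth <- .assert_count(depth, "depth")
  idx <- .ped_idx(ped)
  s <- idx$sire; d <- idx$dam
  n <- nrow(ped)
  ## known[i, j]: number of known ancestors of animal i at generation j
  known <- matrix(0, n, depth)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    known[i, 1L] <- (si > 0L) + (di > 0L)
    if (depth > 1L) {
      for (j in 2:depth) {
        known[i, j] <- (if (si > 0L) known[si, j - 1L] else 0) +
                       (if (di > 0L) known[di, j - 1L] else 0)
      }
    }
  }
  line_c <- function(pidx) {
    ## generation i of the line = parent's generation i-1 (gen 0 = the parent)
    c_val <- numeric(n)
    has <- pidx > 0L
    prop <- matrix(0, n, depth)
    prop[has, 1L] <- 1
    if (depth > 1L) {
      for (j in 2:depth)
        prop[has, j] <- known[pidx[has], j - 1L] / 2^(j - 1L)
    }
    rowMeans(prop)
  }
  cs <- line_c(s); cd <- line_c(d)
  pci <- ifelse(cs + cd > 0, 2 * cs * cd / (cs + cd), 0)
  data.frame(id = ped$id, pci = pci, stringsAsFactors = FALSE)
}

#' Generation intervals by the four-path method
#'
#' Mean parent age at the birth of offspring that were themselves used for
#' breeding, split into the four selection paths sire-son, sire-daughter,
#' dam-son and dam-daughter. A parent-offspring pair contributes only when
#' both birth years are recorded and the offspring has at least one recorded
#' progeny. The overall interval L is the mean of the four path means
#' weighted by their pair counts; its standard error is propagated from the
#' per-path standard errors with the same weights.
#'
#' @param ped a [ped_table()]
#' @return list of class `generation_intervals` with a `paths` data frame
#'   (path, n, mean, sd, se), `L`, `L_se`, and `flagged` when no path has any
#'   eligible pair.
#' @export
generation_intervals <- function(ped) {
  idx <- .ped_idx(ped)
  has_progeny <- tabulate(c(idx$sire, idx$dam), nbins = nrow(ped)) > 0L
  paths <- c("sire-son", "sire-daughter", "dam-son", "dam-daughter")
  vals <- stats::setNames(vector("list", 4L), paths)
  for (p in c("sire", "dam")) {
    pidx <- idx[[p]]
    ok <- pidx > 0L & has_progeny & !is.na(ped$birth_year)
    ok[ok] <- !is.na(ped$birth_year[pidx[ok]])
    iv <- ped$birth_year[ok] - ped$birth_year[pidx[ok]]
    osex <- ped$sex[ok]
    vals[[paste0(p, "-son")]] <- iv[osex %in% "M"]
    vals[[paste0(p, "-daughter")]] <- iv[osex %in% "F"]
  }
  tab <- data.frame(
    path = paths,
    n = vapply(vals, length, 1L),
    mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, 1),
    sd = vapply(vals, function(v) if (length(v) > 1L) stats::sd(v) else NA_real_, 1),
    stringsAsFactors = FALSE)
  tab$se <- tab$sd / sqrt(pmax(tab$n, 1L))
  N <- sum(tab$n)
  if (N == 0L) {
    return(structure(list(paths = tab, L = NA_real_, L_se = NA_real_,
                          flagged = TRUE, reason = "no eligible parent-offspring path"),
                     class = "generation_intervals"))
  }
  use <- tab$n > 0L
  w <- tab$n[use] / N
  L <- sum(w * tab$mean[use])
  L_se <- sqrt(sum((w * tab$se[use])^2, na.rm = TRUE))
  structure(list(paths = tab, L = L, L_se = L_se, flagged = FALSE),
            class = "generation_intervals")
}

#' @export
print.generation_intervals <- function(x, ...) {
  if (x$flagged) {
    cat("<generation_intervals> flagged:", x$reason, "\n")
  } else {
    cat(sprintf("<generation_intervals> L = %.3f +/- %.3f years\n", x$L, x$L_se))
    print(x$paths)
  }
  invisible(x)
}

#' Build an analysis subgroup of animals
#'
#' Subgroups mirror the reference-population definitions used in breed-level
#' diversity studies: a birth-year window (`"birth_years"`), the members of a
#' base set with a minimum number of complete pedigree generations
#' (`"complete_generations"`), an explicit id list such as the genotyped
#' animals (`"id_list"`), or the sires of a base set (`"sires_of"`).
#'
#' @param ped a [ped_table()]
#' @param type one of `"birth_years"`, `"complete_generations"`, `"id_list"`,
#'   `"sires_of"`
#' @param years length-2 numeric range (inclusive) for `"birth_years"`
#' @param min_complete minimum complete generations for
#'   `"complete_generations"`
#' @param base character vector of ids the rule is applied to (defaults to
#'   all animals for `"birth_years"`; required for the other relative types)
#' @param ids explicit id vector for `"id_list"`
#' @param metrics optional precomputed [generation_metrics()] table
#' @return sorted character vector of animal ids
#' @export
build_subgroup <- function(ped, type = c("birth_years", "complete_generations",
                                         "id_list", "sires_of"),
                           years = NULL, min_complete = 4L, base = NULL,
                           ids = NULL, metrics = NULL) {
  type <- match.arg(type)
  out <- switch(type,
    birth_years = {
      stopifnot(length(years) == 2L)
      ped$id[!is.na(ped$birth_year) &
               ped$birth_year >= years[[1L]] & ped$birth_year <= years[[2L]]]
    },
    complete_generations = {
      if (is.null(base)) base <- ped$id
      if (is.null(metrics)) metrics <- generation_metrics(ped)
      gc <- metrics$complete_generations[match(base, metrics$id)]
      base[!is.na(gc) & gc >= min_complete]
    },
    id_list = {
      stopifnot(!is.null(ids))
      intersect(as.character(ids), ped$id)
    },
    sires_of = {
      stopifnot(!is.null(base))
      rows <- match(base, ped$id)
      unique(ped$sire[rows[!is.na(rows)]][!is.na(ped$sire[rows[!is.na(rows)]])])
    })
  sort(unique(out))
}
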