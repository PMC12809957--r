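## Expected genetic contribution of every animal to a reference set:
## backward halving pass from the reference indicator. `blocked` animals
## absorb incoming flow (it is credited to them but not propagated to their
## parents). Unknown-parent slots of non-founders spill into phantom
## founders, one per slot, so total founder flow always sums to 1.
.contribution_pass <- function(ped, reference, blocked = NULL) {
  idx <- .ped_idx(ped)
  s <- idx$sire; d <- idx$dam
  n <- nrow(ped)
  cvec <- numeric(n)
  cvec[match(reference, ped$id)] <- 1 / length(reference)
  phantom <- numeric(n) # phantom flow per animal (unknown-parent slots)
  blk <- logical(n)
  if (!is.null(blocked)) blk[match(blocked, ped$id)] <- TRUE
  contrib <- numeric(n)
  for (i in n:1L) {
    contrib[i] <- contrib[i] + cvec[i]
    if (blk[i]) next
    half <- cvec[i] / 2
    if (half == 0) next
    if (s[i] > 0L) cvec[s[i]] <- cvec[s[i]] + half
    else if (d[i] > 0L) phantom[i] <- phantom[i] + half
    if (d[i] > 0L) cvec[d[i]] <- cvec[d[i]] + half
    else if (s[i] > 0L) phantom[i] <- phantom[i] + half
  }
  list(contrib = contrib, phantom = phantom)
}

#' Expected founder contributions and the effective number of founders
#'
#' The expected proportional contribution q_k of founder k to the reference
#' set is obtained by halving each animal's contribution up through its
#' parents. Unknown parents of non-founders count as phantom founders so
#' that contributions always sum to one. The effective number of founders
#' is f_e = 1 / sum(q_k^2): the number of equally contributing founders
#' that would yield the same founder-contribution diversity.
#'
#' @param ped a [ped_table()]
#' @param reference ids of the reference population (default: all animals)
#' @return list with `contributions` (data frame `founder`, `q`, phantom
#'   founders labelled `<id>:phantom`), `f_e`
#' @export
founder_contributions <- function(ped, reference = NULL) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  reference <- reference %||% ped$id
  stopifnot(length(reference) >= 1L)
  cp <- .contribution_pass(ped, reference)
  fdr <- is_founder(ped)
  ph <- which(cp$phantom > 0)
  q <- c(cp$contrib[fdr], cp$phantom[ph])
  founder <- c(ped$id[fdr],
               if (length(ph)) paste0(ped$id[ph], ":phantom") else character(0))
  keep <- q > 0
  df <- data.frame(founder = founder[keep], q = q[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$q, df$founder), ]
  rownames(df) <- NULL
  list(contributions = df, f_e = 1 / sum(df$q^2))
}

#' Marginal ancestor contributions and the effective number of ancestors
#'
#' Greedy selection of the most influential ancestors: at each round the
#' expected contributions to the reference set are recomputed with all
#' previously selected ancestors acting as absorbing pseudo-founders (their
#' parent links do not transmit), and the animal with the largest remaining
#' contribution is selected; that value is its marginal contribution. Ties
#' break to the older birth year, then the lexically smaller id. The
#' effective number of ancestors is f_a = 1 / sum(p_i^2), and n_50 is the
#' smallest number of ancestors whose marginal contributions reach 50%.
#'
#' @param ped a [ped_table()]
#' @param reference ids of the reference population (default: all animals)
#' @param max_ancestors optional cap on selection rounds
#' @param tol stop when the largest marginal contribution falls below this
#' @return list with `ancestors` (data frame `id`, `marginal`, `cumulative`,
#'   `birth_year`, `flock`, `n_progeny`), `f_a`, `n_50`
#' @export
marginal_ancestors <- function(ped, reference = NULL, max_ancestors = NULL,
                               tol = 1e-10) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  reference <- reference %||% ped$id
  stopifnot(length(reference) >= 1L)
  max_ancestors <- max_ancestors %||% nrow(ped)
  idx <- .ped_idx(ped)
  n_prog <- tabulate(c(idx$sire, idx$dam), nbins = nrow(ped))
  s <- idx$sire; d <- idx$dam
  selected <- character(0)
  marg <- numeric(0)
  total <- 0
  while (length(selected) < max_ancestors && total < 1 - 1e-12) {
    cp <- .contribution_pass(ped, reference, blocked = selected)
    ## discount each candidate by the fraction of its own genome that the
    ## already-selected ancestors explain (forward pass, selected = 1)
    expl <- numeric(nrow(ped))
    seli <- match(selected, ped$id)
    issel <- logical(nrow(ped)); issel[seli] <- TRUE
    for (i in seq_len(nrow(ped))) {
      if (issel[i]) { expl[i] <- 1; next }
      expl[i] <- 0.5 * ((if (s[i] > 0L) expl[s[i]] else 0) +
                        (if (d[i] > 0L) expl[d[i]] else 0))
    }
    contrib <- cp$contrib * (1 - expl)
    contrib[seli] <- -Inf
    best <- max(contrib)
    if (best < tol) break
    cand <- which(contrib >= best - 1e-15)
    if (length(cand) > 1L) {
      by <- ped$birth_year[cand]
      by[is.na(by)] <- -Inf # unknown birth year treated as oldest
      cand <- cand[order(by, ped$id[cand])]
    }
    pick <- cand[[1L]]
    selected <- c(selected, ped$id[pick])
    marg <- c(marg, contrib[pick])
    total <- total + contrib[pick]
  }
  ri <- match(selected, ped$id)
  df <- data.frame(id = selected, marginal = marg, cumulative = cumsum(marg),
                   birth_year = ped$birth_year[ri], flock = ped$flock[ri],
                   n_progeny = n_prog[ri], stringsAsFactors = FALSE)
  reach <- df$cumulative >= 0.5 - 1e-9 # guard against accumulation rounding
  n50 <- if (any(reach)) which(reach)[1L] else NA_integer_
  list(ancestors = df, f_a = 1 / sum(marg^2), n_50 = n50)
}

#' Genetic conservation index
#'
#' Per animal, the effective number of founders in its own pedigree:
#' GCI_i = 1 / sum over founders k of P_ik^2, where P_ik is the proportion
#' of animal i's genes deriving from founder k (unknown parents of
#' non-founders count as distinct phantom founders). A founder has GCI 1;
#' an animal with 2^g equally contributing founder ancestors has GCI 2^g.
#'
#' @param ped a [ped_table()]
#' @return named numeric vector of GCI values
#' @export
gci <- function(ped) {
  if (!inherits(ped, "ped_table")) ped <- ped_table(ped)
  idx <- .ped_idx(ped)
  s <- idx$sire; d <- idx$dam
  n <- nrow(ped)
  ## sparse founder-proportion vectors, named by founder/phantom key
  P <- vector("list", n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) {
      P[[i]] <- stats::setNames(1, ped$id[i])
    } else {
      ps <- if (s[i] > 0L) P[[s[i]]] / 2 else stats::setNames(0.5, paste0(ped$id[i], ":ph_s"))
      pd <- if (d[i] > 0L) P[[d[i]]] / 2 else stats::setNames(0.5, paste0(ped$id[i], ":ph_d"))
      v <- c(ps, pd)
      P[[i]] <- tapply(v, names(v), sum)
    }
    out[i] <- 1 / sum(P[[i]]^2)
  }
  stats::setNames(out, ped$id)
}
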