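#' Construct a validated pedigree table
#'
#' A `ped_table` is a data frame with one row per animal and columns `id`,
#' `sire`, `dam` (character; `NA` = unknown parent), `sex` (`"M"`, `"F"` or
#' `NA`), `birth_year` (integer or `NA`) and `flock` (character or `NA`).
#' Construction validates the pedigree and reorders records topologically so
#' that parents always precede their offspring, the order required by the
#' recursive algorithms downstream.
#'
#' Validation enforces: unique animal ids; no id used both as a sire and as a
#' dam (a sex conflict); an acyclic parent graph (a cycle is reported by
#' naming one of its members); and, when both are recorded, a parent born
#' strictly before its offspring. Parents that appear only in the `sire`/`dam`
#' columns are added as founder records with inferred sex.
#'
#' @param df data frame with at least columns `id`, `sire`, `dam`; optional
#'   `sex`, `birth_year`, `flock`. The strings `"0"` and `""` in the parent
#'   columns are read as unknown.
#' @param check_sex_conflict if `FALSE`, skip the sire/dam disjointness check
#'   (needed only for deliberately degenerate test pedigrees such as selfing).
#' @return a `ped_table` (data frame, topologically ordered)
#' @export
ped_table <- function(df, check_sex_conflict = TRUE) {
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns id, sire, dam", call. = FALSE)

  id   <- as.character(df$id)
  sire <- .clean_parent(df$sire)
  dam  <- .clean_parent(df$dam)
  sex  <- if ("sex" %in% names(df)) toupper(as.character(df$sex)) else rep(NA_character_, nrow(df))
  sex[!sex %in% c("M", "F")] <- NA_character_
  by   <- if ("birth_year" %in% names(df)) suppressWarnings(as.integer(df$birth_year)) else rep(NA_integer_, nrow(df))
  fl   <- if ("flock" %in% names(df)) as.character(df$flock) else rep(NA_character_, nrow(df))
  fl[!is.na(fl) & fl == ""] <- NA_character_

  if (anyDuplicated(id))
    stop("duplicated animal id(s): ", paste(unique(id[duplicated(id)])[1:3], collapse = ", "),
         call. = FALSE)

  ## parents appearing only as parents become founder records
  extra <- setdiff(c(sire, dam), c(id, NA))
  if (length(extra)) {
    ex_sex <- ifelse(extra %in% sire, "M", "F")
    id   <- c(id, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam  <- c(dam, rep(NA_character_, length(extra)))
    sex  <- c(sex, ex_sex)
    by   <- c(by, rep(NA_integer_, length(extra)))
    fl   <- c(fl, rep(NA_character_, length(extra)))
  }

  if (check_sex_conflict) {
    both <- intersect(sire[!is.na(sire)], dam[!is.na(dam)])
    if (length(both))
      stop("sex conflict: id used as both sire and dam: ", both[[1L]], call. = FALSE)
    ## recorded sex must agree with parental role
    s_idx <- match(sire[!is.na(sire)], id)
    if (any(sex[s_idx] %in% "F"))
      stop("sex conflict: animal recorded as F used as sire: ",
           id[s_idx][which(sex[s_idx] %in% "F")[1L]], call. = FALSE)
    d_idx <- match(dam[!is.na(dam)], id)
    if (any(sex[d_idx] %in% "M"))
      stop("sex conflict: animal recorded as M used as dam: ",
           id[d_idx][which(sex[d_idx] %in% "M")[1L]], call. = FALSE)
    sex[match(unique(sire[!is.na(sire)]), id)] <- "M"
    sex[match(unique(dam[!is.na(dam)]), id)] <- "F"
  }

  ord <- .topo_order(id, sire, dam)

  ped <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    sex = sex[ord], birth_year = by[ord], flock = fl[ord],
                    stringsAsFactors = FALSE)
  rownames(ped) <- NULL

  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  bad <- which((!is.na(si) & !is.na(ped$birth_year) & !is.na(ped$birth_year[si]) &
                  ped$birth_year[si] >= ped$birth_year) |
               (!is.na(di) & !is.na(ped$birth_year) & !is.na(ped$birth_year[di]) &
                  ped$birth_year[di] >= ped$birth_year))
  if (length(bad))
    stop("parent born in the same year or later than offspring: ",
         ped$id[bad[[1L]]], call. = FALSE)

  class(ped) <- c("ped_table", "data.frame")
  ped
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("0", "", "NA", ".")] <- NA_character_
  x
}

## Kahn topological order on parent->offspring edges; errors naming a cycle
## member when no order exists.
.topo_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  npar <- (!is.na(si)) + (!is.na(di))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) kids[[si[i]]] <- c(kids[[si[i]]], i)
    if (!is.na(di[i])) kids[[di[i]]] <- c(kids[[di[i]]], i)
  }
  queue <- which(npar == 0L)
  ord <- integer(0)
  placed <- logical(n)
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    placed[i] <- TRUE
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      npar[k] <- npar[k] - 1L
      if (npar[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    member <- id[which(!placed)[1L]]
    stop("pedigree contains a cycle involving animal ", member, call. = FALSE)
  }
  ord
}

#' Read a pedigree from delimited text
#'
#' Expects a header with columns `id`, `sire`, `dam` and optionally `sex`,
#' `birth_year`, `flock`. Unknown parents are encoded `"0"` (or empty).
#'
#' @param path file path
#' @param sep field separator (default `,`)
#' @return a [ped_table()]
#' @export
read_pedigree <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  ped_table(df)
}

#' Write a pedigree as CSV
#'
#' Unknown parents/fields are written as `"0"` for parents and empty strings
#' otherwise, matching [read_pedigree()].
#'
#' @param ped a `ped_table`
#' @param path output path
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## integer parent indices (0 = unknown) for a topologically ordered ped_table
.ped_idx <- function(ped) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  list(sire = si, dam = di)
}

#' @export
print.ped_table <- function(x, ...) {
  cat(sprintf("<ped_table> %d animals (%d founders), %d flock(s)\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam)),
              length(unique(x$flock[!is.na(x$flock)]))))
  NextMethod()
}

#' Identify founders
#'
#' Founders are animals with both parents unknown.
#' @param ped a `ped_table`
#' @return logical vector along `ped`
#' @export
is_founder <- function(ped) is.na(ped$sire) & is.na(ped$dam)
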