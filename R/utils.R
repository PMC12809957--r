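`%||%` <- function(x, y) if (is.null(x)) y else x

.assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

#' Result flagged as undefined
#'
#' Several estimators can be undefined on degenerate inputs (for example a
#' non-positive regression slope, or a pedigree without inbreeding). Rather
#' than returning a silent `NA`, such results carry a flag and a reason.
#'
#' @param value numeric value (typically `NA_real_`)
#' @param reason character explanation
#' @return a list with elements `value`, `flagged = TRUE`, `reason`
#' @keywords internal
flagged <- function(value = NA_real_, reason = "") {
  structure(list(value = value, flagged = TRUE, reason = reason),
            class = "flockdiv_flagged")
}

#' Test whether a result is flagged as undefined
#'
#' @param x a result object
#' @return `TRUE` if the result carries an undefined/degenerate flag
#' @export
is_flagged <- function(x) inherits(x, "flockdiv_flagged") ||
  (is.list(x) && isTRUE(x$flagged))

#' @export
print.flockdiv_flagged <- function(x, ...) {
  cat("<flagged result> ", x$reason, "\n")
  invisible(x)
}
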