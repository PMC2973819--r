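#' Ordered collections of chains
#'
#' A `structure_set` is an ordered list of labelled [fold_chain] members with
#' optional per-member timestamps in picoseconds.  It represents either a
#' trajectory (frames in time order) or a structure library.
#'
#' @param chains list of `fold_chain` objects.
#' @param labels character vector of unique member labels; defaults to
#'   `member_1..member_n`.
#' @param time_ps optional numeric vector of non-negative, non-decreasing
#'   timestamps (ps); either all members have one or none do.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(chains, labels = NULL, time_ps = NULL) {
  if (!is.list(chains) ||
      !all(vapply(chains, inherits, logical(1), "fold_chain")))
    stopf("chains must be a list of fold_chain objects")
  n <- length(chains)
  labels <- labels %||% sprintf("member_%d", seq_len(n))
  if (length(labels) != n) stopf("labels length != number of chains")
  if (anyDuplicated(labels)) stopf("member labels must be unique")
  if (!is.null(time_ps)) {
    time_ps <- as.numeric(time_ps)
    if (length(time_ps) != n) stopf("time_ps length != number of chains")
    if (anyNA(time_ps) || any(time_ps < 0)) stopf("time_ps must be non-negative")
    if (is.unsorted(time_ps)) stopf("time_ps must be non-decreasing")
  }
  structure(list(chains = chains, labels = as.character(labels),
                 time_ps = time_ps),
            class = "structure_set")
}

#' @export
length.structure_set <- function(x) length(x$chains)

#' @export
`[.structure_set` <- function(x, i) {
  structure_set(x$chains[i], labels = x$labels[i],
                time_ps = if (is.null(x$time_ps)) NULL else x$time_ps[i])
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d members%s\n", length(x),
              if (is.null(x$time_ps)) "" else
                sprintf(", t = %g..%g ps", min(x$time_ps), max(x$time_ps))))
  invisible(x)
}

#' Retrieve one member chain by position or label
#' @param set a `structure_set`.
#' @param i integer position or character label.
#' @return The `fold_chain` member.
#' @export
set_member <- function(set, i) {
  if (is.character(i)) {
    j <- match(i, set$labels)
    if (is.na(j)) stopf("no member labelled '%s'", i)
    i <- j
  }
  set$chains[[i]]
}
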