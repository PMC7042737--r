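#' Apply the cohort exclusion filters
#'
#' Drops breeding events flagged as same-year renesting attempts and events
#' from experimentally treated breeders, plus records lacking coordinates.
#' A record matching several reasons is listed under each reason but counted
#' once in the kept-loss.
#'
#' @param records nest data frame (missing flag columns are treated as all
#'   `FALSE`).
#' @return A list with `kept` (filtered data frame) and `report`: per-reason
#'   counts, number excluded, and the input/kept totals.
#' @export
filter_cohort <- function(records) {
  n_in <- nrow(records)
  flag <- function(col) {
    v <- records[[col]]
    if (is.null(v)) rep(FALSE, n_in) else !is.na(v) & as.logical(v)
  }
  renest <- flag("renest_flag")
  treated <- flag("treated_flag")
  no_coord <- if (all(c("x", "y") %in% names(records)))
    is.na(records$x) | is.na(records$y) else rep(FALSE, n_in)
  drop <- renest | treated | no_coord
  kept <- records[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) warning("all records excluded by cohort filters")
  list(
    kept = kept,
    report = list(
      n_input = n_in,
      n_kept = nrow(kept),
      n_excluded = sum(drop),
      reasons = c(renest = sum(renest), treated = sum(treated),
                  missing_coordinates = sum(no_coord))
    )
  )
}

#' Distance from each nest to the nearest settlement
#'
#' Exact Euclidean distance from the nest point to the closest settlement
#' point (no raster approximation).
#'
#' @param records nest data frame with `x`, `y`.
#' @param settlements data frame with `x`, `y`; must be non-empty.
#' @return `records` with a `dist_settlement` column (m).
#' @export
distance_to_settlements <- function(records, settlements) {
  if (is.null(settlements) || nrow(settlements) == 0L)
    stop("settlement set is empty")
  d2 <- outer(records$x, settlements$x, "-")^2 +
    outer(records$y, settlements$y, "-")^2
  records$dist_settlement <- sqrt(apply(d2, 1L, min))
  records
}

#' Classify nests as close to or far from settlements
#'
#' `close` if and only if `dist_settlement < breakpoint` (strict inequality:
#' a nest exactly at the breakpoint is `far`). The breakpoint used is recorded
#' as an attribute for provenance.
#'
#' @param records nest data frame with `dist_settlement`.
#' @param breakpoint threshold distance (m).
#' @return `records` with a `proximity` factor (levels `far`, `close`).
#' @export
classify_proximity <- function(records, breakpoint) {
  stopifnot(is.numeric(breakpoint), breakpoint > 0,
            !is.null(records$dist_settlement))
  records$proximity <- factor(
    ifelse(records$dist_settlement < breakpoint, "close", "far"),
    levels = c("far", "close")
  )
  attr(records, "breakpoint") <- breakpoint
  records
}
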