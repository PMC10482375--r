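# Small shared helpers: interval arithmetic on 0-based half-open coordinates,
# half-up rounding for report percentages, and input validation.

#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going away from zero
#' (so 3.35 -> 3.4 at one decimal), the convention used for the percentage
#' tables of the reporting stage. Base `round()` rounds half to even, which
#' silently changes printed percentages at .x5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(100 * 469 / 13833, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Merge intervals into a sorted disjoint union
#'
#' Collapses 0-based half-open intervals into their union. Book-ended
#' intervals (end of one equal to start of the next) are merged.
#'
#' @param start,end integer vectors of equal length; each `start < end`.
#' @return tibble with columns `start`, `end`, sorted and non-overlapping.
#' @export
merge_intervals <- function(start, end) {
  if (length(start) != length(end)) {
    abort("`start` and `end` must have equal length.")
  }
  if (length(start) == 0L) {
    return(tibble(start = numeric(), end = numeric()))
  }
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start >= end)) {
    abort("every interval must satisfy start < end with finite bounds.")
  }
  o <- order(start, end)
  s <- start[o]
  e <- end[o]
  cme <- cummax(e)
  grp <- cumsum(c(TRUE, s[-1L] > cme[-length(e)]))
  f <- factor(grp, levels = unique(grp))
  tibble(
    start = as.numeric(tapply(s, f, min)),
    end = as.numeric(tapply(e, f, max))
  )
}

# Total bp of [qstart, qend) covered by a *disjoint* interval set.
# Vectorized over queries; `ms`/`me` come from merge_intervals().
interval_overlap_bp <- function(qstart, qend, ms, me) {
  if (length(ms) == 0L) {
    return(numeric(length(qstart)))
  }
  vapply(
    seq_along(qstart),
    function(i) sum(pmax(0, pmin(qend[i], me) - pmax(qstart[i], ms))),
    numeric(1)
  )
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# Genome-level view of the replicon metadata table (one row per genome).
genome_table <- function(metadata) {
  check_columns(metadata, c("genome_id", "phylum", "genus", "species"), "metadata")
  distinct(metadata, genome_id, phylum, genus, species)
}
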