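# Spatial distribution of hits along linear replicons: normalized start
# positions in [0, 1), extremity fractions at configurable thresholds
# (arms vs core of linear chromosomes), and an exact binomial test of
# uniformity against the 2 * threshold baseline.

#' Normalized start positions on linear replicons
#'
#' Each hit's position is its smallest gene start divided by the replicon
#' length, in \[0, 1). Positions are only meaningful on linear replicons;
#' hits on circular replicons raise an error (filter the metadata to
#' `topology == "linear"` first, mirroring the exclusion of
#' circular-annotated chromosomes from arm/core analyses).
#'
#' @param hits long-format hit tibble.
#' @param metadata replicon metadata (`topology`, `length`).
#' @return tibble with one row per hit: `hit_id`, `genome_id`,
#'   `replicon_id`, `category`, `system_type`, `position`.
#' @export
normalized_positions <- function(hits, metadata) {
  check_columns(hits, c("hit_id", "replicon_id", "gene_start"), "hits")
  check_columns(metadata, c("replicon_id", "topology", "length"), "metadata")
  joined <- hits %>%
    group_by(hit_id) %>%
    summarise(
      genome_id = first(genome_id),
      replicon_id = first(replicon_id),
      category = first(category),
      system_type = first(system_type),
      min_start = min(gene_start),
      .groups = "drop"
    ) %>%
    left_join(distinct(metadata, replicon_id, topology, length), by = "replicon_id")
  if (anyNA(joined$topology)) {
    abort("hit(s) on replicon(s) absent from metadata.")
  }
  circ <- joined$replicon_id[joined$topology != "linear"]
  if (length(circ) > 0L) {
    abort(sprintf(
      paste(
        "normalized positions are undefined on circular replicons (%d hit(s)",
        "affected); filter hits/metadata to topology == 'linear' first."
      ),
      length(circ)
    ))
  }
  joined %>%
    mutate(position = min_start / length) %>%
    mutate(.hit_ord = match(hit_id, unique(hits$hit_id))) %>%
    arrange(.hit_ord) %>%
    select(hit_id, genome_id, replicon_id, category, system_type, position)
}

#' Fraction of positions in the replicon extremities
#'
#' A position `x` is in the extremities when `x < threshold` or
#' `x >= 1 - threshold` (half-open on both sides, so the boundary
#' `1 - threshold` counts as extremity). Under a uniform distribution the
#' expected fraction is `2 * threshold`.
#'
#' @param positions numeric vector of normalized positions in \[0, 1).
#' @param threshold extremity half-width in (0, 0.5), e.g. 0.10 or 0.01.
#' @return fraction in \[0, 1\].
#' @export
extremity_fraction <- function(positions, threshold) {
  if (length(positions) == 0L) {
    abort("`positions` is empty; the extremity fraction is undefined.")
  }
  if (threshold <= 0 || threshold >= 0.5) {
    abort("`threshold` must lie in (0, 0.5).")
  }
  if (any(positions < 0 | positions >= 1)) {
    abort("positions must lie in [0, 1).")
  }
  mean(positions < threshold | positions >= 1 - threshold)
}

#' Per-type spatial profiles on linear replicons
#'
#' Computes normalized positions on linear replicons and summarises each
#' system type passing the occurrence floor with extremity fractions at the
#' arm (10 %) and chromosome-end (1 %) thresholds. Hits on non-linear
#' replicons are dropped (the paper-style exclusion of circular-annotated
#' chromosomes), and types with `n <= min_occurrences` are not reported.
#'
#' @param hits long-format hit tibble.
#' @param metadata replicon metadata.
#' @param min_occurrences strict occurrence floor; only types with more
#'   occurrences than this are profiled (default 45).
#' @param thresholds two extremity thresholds (default `c(0.10, 0.01)`).
#' @return tibble with columns `system_type`, `n`, `extremity_fraction_10`,
#'   `extremity_fraction_1` (named after the default thresholds).
#' @export
spatial_profiles <- function(hits, metadata, min_occurrences = 45L,
                             thresholds = c(0.10, 0.01)) {
  linear <- filter(metadata, topology == "linear")
  hits_linear <- semi_join(hits, linear, by = "replicon_id")
  if (nrow(hits_linear) == 0L) {
    return(tibble(
      system_type = character(), n = integer(),
      extremity_fraction_10 = numeric(), extremity_fraction_1 = numeric()
    ))
  }
  positions <- normalized_positions(hits_linear, linear)
  positions %>%
    group_by(system_type) %>%
    summarise(
      n = n(),
      extremity_fraction_10 = extremity_fraction(position, thresholds[1L]),
      extremity_fraction_1 = extremity_fraction(position, thresholds[2L]),
      .groups = "drop"
    ) %>%
    filter(n > min_occurrences) %>%
    arrange(dplyr::desc(extremity_fraction_10))
}

#' Exact binomial test of uniform extremity occupancy
#'
#' Two-sided exact binomial test of the observed extremity count against
#' the uniform expectation `p0 = 2 * threshold`, with the two-sided p
#' computed as twice the smaller exact tail, capped at one.
#'
#' @param positions numeric vector of normalized positions in \[0, 1).
#' @param threshold extremity half-width in (0, 0.5).
#' @return an object of class `htest`.
#' @export
uniformity_test <- function(positions, threshold = 0.1) {
  frac <- extremity_fraction(positions, threshold) # validates inputs
  n <- length(positions)
  k <- round(frac * n)
  p0 <- 2 * threshold
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  structure(
    list(
      statistic = c(extremity_count = k),
      parameter = c(n = n, p0 = p0),
      estimate = c(extremity_fraction = frac),
      p.value = p,
      method = "Exact binomial test of uniform extremity occupancy (doubled tail)",
      alternative = "two.sided",
      data.name = deparse(substitute(positions))
    ),
    class = "htest"
  )
}
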