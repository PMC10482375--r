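# Differential abundance of system types between a focal group and the
# background. The statistic is the difference of group abundances (mean
# copies per genome) normalized by the pooled abundance, so heterogeneous
# systems are comparable on one scale; significance comes from a one-way
# ANOVA on per-genome copy counts with Bonferroni control across types.

#' Normalized differential-abundance estimator
#'
#' `(abundance_in - abundance_out) / abundance_all`. Negative values mark a
#' system rarer in the focal group than in the background, positive values a
#' more abundant one. For a system absent from the background the estimator
#' attains its upper bound `(n_in + n_out) / n_in`; symmetrically
#' `-(n_in + n_out) / n_out` for a system absent from the focal group.
#'
#' @param abundance_in,abundance_out mean copies per genome in the focal and
#'   background groups.
#' @param abundance_all pooled mean copies per genome; must be > 0 (a type
#'   absent everywhere has no defined estimator and must be excluded by the
#'   caller).
#' @return numeric estimator (vectorized).
#' @export
da_estimator <- function(abundance_in, abundance_out, abundance_all) {
  if (any(abundance_all <= 0)) {
    abort("`abundance_all` must be > 0; exclude types absent from the whole cohort.")
  }
  (abundance_in - abundance_out) / abundance_all
}

#' Two-group one-way ANOVA on copy counts
#'
#' Fixed-effects one-way ANOVA with two groups: F on (1, n - 2) degrees of
#' freedom, upper-tail p. For two groups F equals the square of the
#' pooled-variance t statistic. Degenerate inputs (zero within-group
#' variance) are resolved explicitly: equal means give F = 0, p = 1;
#' unequal means give an infinite F, p = 0 and `degenerate = TRUE`.
#'
#' @param copies_in,copies_out per-genome copy counts in the two groups
#'   (non-empty; combined length >= 3).
#' @return list with `f_stat`, `p_value`, `degenerate`.
#' @export
two_group_anova <- function(copies_in, copies_out) {
  n1 <- length(copies_in)
  n2 <- length(copies_out)
  if (n1 == 0L || n2 == 0L) {
    abort("both groups must be non-empty.")
  }
  if (n1 + n2 < 3L) {
    abort("need at least 3 observations in total.")
  }
  ssw <- sum((copies_in - mean(copies_in))^2) + sum((copies_out - mean(copies_out))^2)
  if (ssw == 0) {
    if (isTRUE(all.equal(mean(copies_in), mean(copies_out)))) {
      return(list(f_stat = 0, p_value = 1, degenerate = FALSE))
    }
    return(list(f_stat = Inf, p_value = 0, degenerate = TRUE))
  }
  fit <- oneway.test(
    value ~ grp,
    data = data.frame(
      value = c(copies_in, copies_out),
      grp = factor(rep(c("in", "out"), c(n1, n2)))
    ),
    var.equal = TRUE
  )
  list(
    f_stat = unname(fit$statistic),
    p_value = unname(fit$p.value),
    degenerate = FALSE
  )
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`, order preserved. The family size `m` defaults to
#' the number of p-values but can be set larger (e.g. to the full size of
#' the detectable-system catalogue) for fidelity with screens corrected
#' across a fixed model set.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param m family size; must be >= `length(p_values)`.
#' @return adjusted p-values.
#' @export
p_bonferroni <- function(p_values, m = NULL) {
  check_prob(p_values, "p_values")
  m <- m %||% length(p_values)
  if (m < length(p_values)) {
    abort("`m` must be at least the number of p-values.")
  }
  if (length(p_values) == 0L) {
    return(numeric())
  }
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Classify differential-abundance results
#'
#' `absent` when the focal group has no copies but the background does (no
#' test is run); `enriched`/`depleted` when the Bonferroni-adjusted p is at
#' most `alpha` and the estimator is positive/negative; otherwise
#' `not_significant` (including the rounding-only corner of a zero estimator
#' with a significant p).
#'
#' @param results tibble with columns `abundance_in`, `abundance_out`,
#'   `estimator`, `p_adj`.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return the input with a `class_label` column.
#' @export
da_classify <- function(results, alpha = 0.05) {
  check_columns(results, c("abundance_in", "abundance_out", "estimator", "p_adj"), "results")
  results %>%
    mutate(class_label = dplyr::case_when(
      abundance_in == 0 & abundance_out > 0 ~ "absent",
      !is.na(p_adj) & p_adj <= alpha & estimator > 0 ~ "enriched",
      !is.na(p_adj) & p_adj <= alpha & estimator < 0 ~ "depleted",
      TRUE ~ "not_significant"
    ))
}

#' Differential-abundance screen between a focal group and the background
#'
#' Computes per-type abundances in the focal group, the background and the
#' pooled cohort, the normalized estimator, a two-group ANOVA on per-genome
#' copy counts, Bonferroni-adjusted p-values, and the
#' absent/enriched/depleted/not-significant classification. Types absent
#' from the focal group are classified `absent` without a test; the
#' Bonferroni family size defaults to the number of types tested.
#'
#' @param hits long-format hit tibble.
#' @param metadata replicon metadata.
#' @param focal unquoted logical expression on the genome-level metadata
#'   selecting the focal group, e.g. `phylum == "Actinobacteria"`.
#' @param alpha significance level (default 0.05).
#' @param m Bonferroni family size; default = number of types tested.
#' @return tibble of class `da_result`, one row per system type, with
#'   columns `system_type`, `n_in`, `n_out`, `abundance_in`,
#'   `abundance_out`, `abundance_all`, `estimator`, `f_stat`, `p_raw`,
#'   `p_adj`, `degenerate`, `class_label`.
#' @export
diff_abundance <- function(hits, metadata, focal, alpha = 0.05, m = NULL) {
  genomes <- genome_table(metadata)
  focal_quo <- enquo(focal)
  is_focal <- eval_tidy(focal_quo, data = genomes)
  if (!is.logical(is_focal) || length(is_focal) != nrow(genomes) || anyNA(is_focal)) {
    abort("`focal` must evaluate to a complete logical vector over genomes.")
  }
  n_in <- sum(is_focal)
  n_out <- sum(!is_focal)
  if (n_in == 0L || n_out == 0L) {
    abort("both the focal group and the background must contain genomes.")
  }
  types <- sort(unique(hits$system_type))
  copies <- hits %>%
    distinct(hit_id, genome_id, system_type) %>%
    count(genome_id, system_type, name = "copies")
  copy_matrix <- tidyr::expand_grid(
    genome_id = genomes$genome_id,
    system_type = types
  ) %>%
    left_join(copies, by = c("genome_id", "system_type")) %>%
    mutate(copies = dplyr::coalesce(copies, 0L)) %>%
    left_join(
      tibble(genome_id = genomes$genome_id, is_focal = is_focal),
      by = "genome_id"
    )

  res <- copy_matrix %>%
    group_by(system_type) %>%
    summarise(
      abundance_in = sum(copies[is_focal]) / n_in,
      abundance_out = sum(copies[!is_focal]) / n_out,
      .groups = "drop"
    ) %>%
    mutate(
      n_in = n_in,
      n_out = n_out,
      abundance_all = (n_in * abundance_in + n_out * abundance_out) / (n_in + n_out),
      estimator = da_estimator(abundance_in, abundance_out, abundance_all)
    )

  tested <- res$abundance_in > 0 | res$abundance_out == 0
  tests <- purrr::map(res$system_type[tested], function(ty) {
    v <- copy_matrix$copies[copy_matrix$system_type == ty]
    f <- copy_matrix$is_focal[copy_matrix$system_type == ty]
    two_group_anova(v[f], v[!f])
  })
  res$f_stat <- NA_real_
  res$p_raw <- NA_real_
  res$degenerate <- NA
  res$f_stat[tested] <- purrr::map_dbl(tests, "f_stat")
  res$p_raw[tested] <- purrr::map_dbl(tests, "p_value")
  res$degenerate[tested] <- purrr::map_lgl(tests, "degenerate")
  m_eff <- m %||% sum(tested)
  res$p_adj <- NA_real_
  res$p_adj[tested] <- p_bonferroni(res$p_raw[tested], m = m_eff)

  res <- da_classify(res, alpha = alpha) %>%
    select(
      system_type, n_in, n_out, abundance_in, abundance_out, abundance_all,
      estimator, f_stat, p_raw, p_adj, degenerate, class_label
    )
  attr(res, "alpha") <- alpha
  attr(res, "m") <- m_eff
  attr(res, "focal") <- as_label(focal_quo)
  class(res) <- c("da_result", class(res))
  res
}
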