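# Attribution of each hit to chromosome, plasmid or prophage, and the
# GC-ratio score used as a horizontal-transfer marker. Attribution is a
# tri-partition with prophage precedence: a defence system is
# prophage-encoded as soon as one of its genes overlaps a prophage interval
# by >= 1 bp (robust to imprecise prophage boundaries); a BGC only when at
# least half of its span (first gene start to last gene end) lies within
# the merged prophage union. Otherwise the replicon annotation decides
# plasmid vs chromosome.

#' Attribute hits to chromosome, plasmid or prophage
#'
#' @param hits long-format hit tibble.
#' @param metadata replicon metadata (provides `replicon_type`).
#' @param prophages tibble of prophage intervals (`replicon_id`, `start`,
#'   `end`, 0-based half-open); merged internally per replicon.
#' @return tibble with one row per hit: `hit_id`, `genome_id`,
#'   `replicon_id`, `category`, `system_type`, `location`,
#'   `prophage_overlap_bp` (bp of gene sequence inside prophages),
#'   `overlap_fraction` (prophage-covered fraction of the hit's span).
#' @export
attribute_location <- function(hits, metadata, prophages) {
  check_columns(
    hits,
    c("hit_id", "genome_id", "replicon_id", "category", "system_type", "gene_start", "gene_end"),
    "hits"
  )
  check_columns(metadata, c("replicon_id", "replicon_type"), "metadata")
  check_columns(prophages, c("replicon_id", "start", "end"), "prophages")
  unknown <- setdiff(unique(hits$replicon_id), metadata$replicon_id)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "hit(s) on replicon(s) absent from metadata: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  pp <- prophages %>%
    group_by(replicon_id) %>%
    group_modify(~ merge_intervals(.x$start, .x$end)) %>%
    ungroup()
  pp_by_repl <- split(pp[c("start", "end")], pp$replicon_id)

  gene_ov <- hits %>%
    group_by(replicon_id) %>%
    group_modify(function(g, key) {
      iv <- pp_by_repl[[key$replicon_id[[1L]]]]
      ms <- if (is.null(iv)) numeric() else iv$start
      me <- if (is.null(iv)) numeric() else iv$end
      g$gene_overlap <- interval_overlap_bp(g$gene_start, g$gene_end, ms, me)
      g$span_start <- min(g$gene_start)
      g$span_end <- max(g$gene_end)
      g
    }) %>%
    ungroup()

  span_ov <- gene_ov %>%
    group_by(replicon_id, hit_id) %>%
    summarise(
      category = first(category),
      genome_id = first(genome_id),
      system_type = first(system_type),
      prophage_overlap_bp = sum(gene_overlap),
      any_gene_in = any(gene_overlap > 0),
      span_start = first(span_start),
      span_end = first(span_end),
      .groups = "drop"
    )
  # Span coverage needs its own overlap pass (genes can leave gaps).
  span_cov <- span_ov %>%
    group_by(replicon_id) %>%
    group_modify(function(g, key) {
      iv <- pp_by_repl[[key$replicon_id[[1L]]]]
      ms <- if (is.null(iv)) numeric() else iv$start
      me <- if (is.null(iv)) numeric() else iv$end
      g$span_overlap <- interval_overlap_bp(g$span_start, g$span_end, ms, me)
      g
    }) %>%
    ungroup()

  span_cov %>%
    left_join(
      distinct(metadata, replicon_id, replicon_type),
      by = "replicon_id"
    ) %>%
    mutate(
      overlap_fraction = span_overlap / (span_end - span_start),
      in_prophage = ifelse(
        category == "bgc",
        overlap_fraction >= 0.5,
        any_gene_in
      ),
      location = dplyr::case_when(
        in_prophage ~ "prophage",
        replicon_type == "plasmid" ~ "plasmid",
        TRUE ~ "chromosome"
      )
    ) %>%
    mutate(.hit_ord = match(hit_id, unique(hits$hit_id))) %>%
    arrange(.hit_ord) %>%
    select(
      hit_id, genome_id, replicon_id, category, system_type, location,
      prophage_overlap_bp, overlap_fraction
    )
}

#' Per-type contribution of genetic elements
#'
#' Fraction of each system type's occurrences found on the chromosome, on a
#' plasmid, or within a prophage; the three fractions sum to one. `pct_*`
#' columns give report-style percentages, rounded half-up to one decimal.
#'
#' @param calls location calls from [attribute_location()].
#' @return tibble with one row per system type.
#' @export
mge_contribution <- function(calls) {
  check_columns(calls, c("hit_id", "system_type", "location"), "calls")
  calls %>%
    group_by(system_type) %>%
    summarise(
      n_total = n(),
      fraction_chromosome = mean(location == "chromosome"),
      fraction_plasmid = mean(location == "plasmid"),
      fraction_prophage = mean(location == "prophage"),
      .groups = "drop"
    ) %>%
    mutate(
      pct_chromosome = round_half_up(100 * fraction_chromosome, 1),
      pct_plasmid = round_half_up(100 * fraction_plasmid, 1),
      pct_prophage = round_half_up(100 * fraction_prophage, 1)
    )
}

#' GC score of each hit
#'
#' Per-gene score = gene GC / replicon GC; the hit's score is the mean over
#' its genes. Scores well below one mark AT-enriched systems, candidate
#' horizontal transfers; `low_gc` flags hits with mean score below the
#' threshold.
#'
#' @param hits long-format hit tibble (`gene_gc` per gene).
#' @param metadata replicon metadata (`gc` per replicon, must be > 0).
#' @param threshold low-GC flag threshold on the mean score (default 0.8).
#' @return tibble with one row per hit: `hit_id`, `genome_id`,
#'   `replicon_id`, `category`, `system_type`, `n_genes`, `gene_scores`
#'   (list column), `mean_gc_score`, `low_gc`.
#' @export
gc_score <- function(hits, metadata, threshold = 0.8) {
  check_columns(hits, c("hit_id", "gene_gc", "replicon_id"), "hits")
  check_columns(metadata, c("replicon_id", "gc"), "metadata")
  joined <- left_join(hits, distinct(metadata, replicon_id, gc), by = "replicon_id")
  if (anyNA(joined$gc)) {
    abort("hit(s) on replicon(s) absent from metadata.")
  }
  if (any(joined$gc <= 0)) {
    abort("replicon GC must be > 0 to compute GC scores.")
  }
  joined %>%
    mutate(score = gene_gc / gc) %>%
    group_by(hit_id) %>%
    summarise(
      genome_id = first(genome_id),
      replicon_id = first(replicon_id),
      category = first(category),
      system_type = first(system_type),
      n_genes = n(),
      gene_scores = list(score),
      mean_gc_score = mean(score),
      .groups = "drop"
    ) %>%
    mutate(low_gc = mean_gc_score < threshold) %>%
    mutate(.hit_ord = match(hit_id, unique(hits$hit_id))) %>%
    arrange(.hit_ord) %>%
    select(-.hit_ord)
}

#' Join genus frequency, MGE fraction and GC score per system type
#'
#' One row per (genus, system type) pair observed in the genus, relating
#' how widespread the system is in the genus (frequency), how often its
#' occurrences sit on mobile elements, and its mean GC score. Rare systems
#' are expected to be the MGE-borne, AT-shifted ones; the table exposes the
#' two scatter relationships without forcing a statistic.
#'
#' @param hits long-format hit tibble.
#' @param metadata replicon metadata.
#' @param calls location calls from [attribute_location()].
#' @param scores GC scores from [gc_score()].
#' @return tibble with columns `genus`, `system_type`, `n_occurrences`,
#'   `frequency`, `mge_fraction`, `mean_gc_score`.
#' @export
frequency_vs_mge <- function(hits, metadata, calls, scores) {
  summ <- arsenal_summary(hits, metadata, group = genus) %>%
    rename(genus = group_label) %>%
    filter(n_copies > 0L)
  genome_genus <- genome_table(metadata) %>% select(genome_id, genus)
  per_call <- calls %>%
    left_join(genome_genus, by = "genome_id") %>%
    left_join(select(scores, hit_id, mean_gc_score), by = "hit_id")
  per_call %>%
    group_by(genus, system_type) %>%
    summarise(
      n_occurrences = n(),
      mge_fraction = mean(location != "chromosome"),
      mean_gc_score = mean(mean_gc_score),
      .groups = "drop"
    ) %>%
    inner_join(
      select(summ, genus, system_type, frequency),
      by = c("genus", "system_type")
    ) %>%
    select(genus, system_type, n_occurrences, frequency, mge_fraction, mean_gc_score)
}
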