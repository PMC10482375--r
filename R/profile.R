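# Descriptive statistics of the defence arsenal: per-genome system counts,
# per-group frequency/abundance summaries, the genome fraction devoted to
# defence, and defence-island detection from CDS ordinals.

#' Count systems per genome
#'
#' @param hits long-format hit tibble (one gene per row).
#' @param metadata replicon metadata; genomes with no hits are reported
#'   with a count of 0.
#' @return tibble with columns `genome_id`, `n_systems`.
#' @export
systems_per_genome <- function(hits, metadata) {
  check_columns(hits, c("hit_id", "genome_id"), "hits")
  genomes <- genome_table(metadata)
  orphan <- setdiff(unique(hits$genome_id), genomes$genome_id)
  if (length(orphan) > 0L) {
    abort(sprintf(
      "hit(s) reference genome(s) absent from metadata: %s",
      paste(orphan, collapse = ", ")
    ))
  }
  counts <- hits %>%
    distinct(hit_id, genome_id) %>%
    count(genome_id, name = "n_systems")
  genomes %>%
    select(genome_id) %>%
    left_join(counts, by = "genome_id") %>%
    mutate(n_systems = dplyr::coalesce(n_systems, 0L))
}

#' Per-group arsenal summary
#'
#' For each group and system type: the frequency (fraction of the group's
#' genomes carrying at least one copy) and the abundance (mean copies per
#' genome, which unlike frequency counts multi-copy genomes multiply).
#' Abundance is always >= frequency, and the per-type abundances of a group
#' sum to its mean number of systems per genome.
#'
#' @param hits long-format hit tibble.
#' @param metadata replicon metadata.
#' @param group grouping column of the metadata (unquoted), e.g. `genus` or
#'   `phylum`; default `NULL` treats the whole cohort as one group labelled
#'   `"all"`.
#' @return tibble with columns `group_label`, `n_genomes`, `system_type`,
#'   `n_copies`, `frequency`, `abundance`.
#' @export
arsenal_summary <- function(hits, metadata, group = NULL) {
  genomes <- genome_table(metadata)
  grp <- enquo(group)
  if (rlang::quo_is_null(grp)) {
    genomes$group_label <- "all"
  } else {
    genomes <- mutate(genomes, group_label = as.character(!!grp))
  }
  group_sizes <- count(genomes, group_label, name = "n_genomes")
  types <- sort(unique(hits$system_type))
  if (length(types) == 0L) {
    return(tibble(
      group_label = character(), n_genomes = integer(),
      system_type = character(), n_copies = integer(),
      frequency = numeric(), abundance = numeric()
    ))
  }
  copies <- hits %>%
    distinct(hit_id, genome_id, system_type) %>%
    count(genome_id, system_type, name = "copies") %>%
    inner_join(select(genomes, genome_id, group_label), by = "genome_id")
  tidyr::expand_grid(group_label = group_sizes$group_label, system_type = types) %>%
    left_join(
      copies %>%
        group_by(group_label, system_type) %>%
        summarise(
          n_copies = sum(copies),
          n_with = n_distinct(genome_id),
          .groups = "drop"
        ),
      by = c("group_label", "system_type")
    ) %>%
    left_join(group_sizes, by = "group_label") %>%
    mutate(
      n_copies = dplyr::coalesce(n_copies, 0L),
      n_with = dplyr::coalesce(n_with, 0L),
      frequency = n_with / n_genomes,
      abundance = n_copies / n_genomes
    ) %>%
    select(group_label, n_genomes, system_type, n_copies, frequency, abundance) %>%
    arrange(group_label, system_type)
}

#' Fraction of each genome devoted to defence
#'
#' Sums the bp covered by defence genes (overlapping genes merged per
#' replicon, so shared bp are not double counted) and divides by the total
#' replicon length of the genome.
#'
#' @param hits long-format hit tibble; only rows with `category ==
#'   "defence"` contribute.
#' @param metadata replicon metadata.
#' @return tibble with columns `genome_id`, `defence_bp`, `genome_bp`,
#'   `fraction`.
#' @export
defence_genome_fraction <- function(hits, metadata) {
  genomes <- genome_table(metadata)
  genome_bp <- metadata %>%
    group_by(genome_id) %>%
    summarise(genome_bp = sum(length), .groups = "drop")
  def <- filter(hits, category == "defence")
  if (nrow(def) > 0L) {
    defence_bp <- def %>%
      group_by(genome_id, replicon_id) %>%
      group_modify(~ merge_intervals(.x$gene_start, .x$gene_end)) %>%
      ungroup() %>%
      group_by(genome_id) %>%
      summarise(defence_bp = sum(end - start), .groups = "drop")
  } else {
    defence_bp <- tibble(genome_id = character(), defence_bp = numeric())
  }
  genomes %>%
    select(genome_id) %>%
    left_join(genome_bp, by = "genome_id") %>%
    left_join(defence_bp, by = "genome_id") %>%
    mutate(
      defence_bp = dplyr::coalesce(defence_bp, 0),
      fraction = defence_bp / genome_bp
    )
}

#' Detect defence islands from CDS ordinals
#'
#' Two systems on the same replicon chain into one island when fewer than
#' `max_intervening` protein-coding genes lie strictly between them (between
#' the largest gene ordinal of the upstream system and the smallest ordinal
#' of the downstream one). Islands are maximal chains; singletons are not
#' reported.
#'
#' @param hits long-format hit tibble; every gene must carry a `gene_index`
#'   (ordinal position among the replicon's CDS).
#' @param max_intervening chaining threshold; strictly fewer than this many
#'   intervening CDS links two systems (default 20).
#' @return tibble with one row per island: `replicon_id`, `island_id`,
#'   `n_systems`, `hit_ids` (comma-separated, ordered by position), `span_start`,
#'   `span_end` (bp).
#' @export
detect_islands <- function(hits, max_intervening = 20L) {
  check_columns(hits, c("hit_id", "replicon_id", "gene_index", "gene_start", "gene_end"), "hits")
  if (nrow(hits) == 0L) {
    return(tibble(
      replicon_id = character(), island_id = character(), n_systems = integer(),
      hit_ids = character(), span_start = numeric(), span_end = numeric()
    ))
  }
  if (anyNA(hits$gene_index)) {
    abort(paste(
      "island detection needs CDS ordinals: every gene must carry a",
      "non-missing `gene_index`."
    ))
  }
  sys <- hits %>%
    group_by(replicon_id, hit_id) %>%
    summarise(
      min_idx = min(gene_index), max_idx = max(gene_index),
      span_start = min(gene_start), span_end = max(gene_end),
      .groups = "drop"
    ) %>%
    arrange(replicon_id, min_idx, max_idx)
  sys <- sys %>%
    group_by(replicon_id) %>%
    mutate(
      run_max = cummax(max_idx),
      # Gap to the previous chained block; the first system opens a block.
      new_block = dplyr::coalesce(min_idx - lag(run_max) - 1L >= max_intervening, TRUE),
      block = cumsum(new_block)
    ) %>%
    ungroup()
  sys %>%
    group_by(replicon_id, block) %>%
    summarise(
      n_systems = n(),
      hit_ids = paste(hit_id, collapse = ","),
      span_start = min(span_start),
      span_end = max(span_end),
      .groups = "drop"
    ) %>%
    filter(n_systems >= 2L) %>%
    group_by(replicon_id) %>%
    mutate(island_id = sprintf("%s_island%02d", replicon_id, row_number())) %>%
    ungroup() %>%
    select(replicon_id, island_id, n_systems, hit_ids, span_start, span_end)
}
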