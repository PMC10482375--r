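# Readers and writers for the tabular dialects the pipeline exchanges:
# long-format hit tables (one gene per row), replicon metadata, BED-style
# prophage intervals, Newick trees, and TSV result tables. All coordinates
# are 0-based half-open; readers validate invariants at the boundary so the
# statistics can assume clean input. The column dialects are documented in
# inst/extdata/schema.md.

HIT_COLUMNS <- c(
  "hit_id", "genome_id", "replicon_id", "system_type",
  "gene_start", "gene_end", "strand", "gene_gc"
)

META_COLUMNS <- c(
  "genome_id", "phylum", "genus", "species", "replicon_id",
  "replicon_type", "topology", "length", "gc"
)

#' Read a system/BGC hit table
#'
#' Hit tables are long-format TSV: one row per gene, rows grouped by
#' `hit_id`. Required columns: `hit_id`, `genome_id`, `replicon_id`,
#' `system_type`, `gene_start`, `gene_end` (0-based half-open), `strand`,
#' `gene_gc`. Optional: `subtype`, `gene_index` (ordinal position of the
#' gene among the replicon's CDS, required only for defence-island
#' detection). Lines starting with `#` are ignored.
#'
#' @param path path to a TSV file.
#' @param category `"defence"` or `"bgc"`; recorded on every hit and used by
#'   the prophage attribution rules.
#' @param metadata optional replicon metadata (see
#'   [read_replicon_metadata()]); when supplied, genes falling outside their
#'   replicon's bounds raise an error naming the offending hit.
#' @return tibble of validated gene rows, genes sorted by start within hit.
#' @export
read_hits <- function(path, category = c("defence", "bgc"), metadata = NULL) {
  category <- match.arg(category)
  hits <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (nrow(hits) == 0L && ncol(hits) == 0L) {
    abort(sprintf("'%s' has no header line.", path))
  }
  check_columns(hits, HIT_COLUMNS, sprintf("hit table '%s'", path))
  hits$category <- category
  if (!"subtype" %in% names(hits)) hits$subtype <- NA_character_
  if (!"gene_index" %in% names(hits)) hits$gene_index <- NA_integer_
  hits <- select(
    hits, hit_id, genome_id, replicon_id, category, system_type, subtype,
    gene_start, gene_end, strand, gene_gc, gene_index
  )
  validate_hits(hits, metadata = metadata)
}

#' Validate a hit table against its invariants
#'
#' Checks coordinates (`0 <= start < end`), GC fractions, strand symbols,
#' and per-hit consistency (a hit lives on one replicon of one genome with
#' one system type). With `metadata`, also checks genes against replicon
#' bounds. Genes are returned sorted by start within each hit; hit order
#' follows first appearance.
#'
#' @param hits long-format hit tibble (see [read_hits()]).
#' @param metadata optional replicon metadata for bounds checking.
#' @return the validated (and within-hit sorted) tibble.
#' @export
validate_hits <- function(hits, metadata = NULL) {
  check_columns(hits, c(HIT_COLUMNS, "category"), "hit table")
  if (nrow(hits) == 0L) {
    return(as_tibble(hits))
  }
  bad <- !is.finite(hits$gene_start) | !is.finite(hits$gene_end) |
    hits$gene_start < 0 | hits$gene_start >= hits$gene_end
  if (any(bad)) {
    abort(sprintf(
      "invalid gene coordinates (need 0 <= start < end) in hit(s): %s",
      paste(unique(hits$hit_id[bad]), collapse = ", ")
    ))
  }
  check_prob(hits$gene_gc, "gene_gc")
  if (!all(hits$strand %in% c("+", "-"))) {
    abort("`strand` must be '+' or '-'.")
  }
  per_hit <- hits %>%
    group_by(hit_id) %>%
    summarise(
      n_type = n_distinct(system_type),
      n_repl = n_distinct(replicon_id),
      n_gen = n_distinct(genome_id),
      .groups = "drop"
    )
  incons <- per_hit$hit_id[per_hit$n_type > 1L | per_hit$n_repl > 1L | per_hit$n_gen > 1L]
  if (length(incons) > 0L) {
    abort(sprintf(
      "hit(s) with inconsistent system_type/replicon/genome across rows: %s",
      paste(incons, collapse = ", ")
    ))
  }
  if (!is.null(metadata)) {
    check_columns(metadata, c("replicon_id", "length"), "metadata")
    joined <- left_join(hits, select(metadata, replicon_id, length), by = "replicon_id")
    if (anyNA(joined$length)) {
      abort(sprintf(
        "hit(s) on replicon(s) absent from metadata: %s",
        paste(unique(joined$hit_id[is.na(joined$length)]), collapse = ", ")
      ))
    }
    out_of_bounds <- joined$gene_end > joined$length
    if (any(out_of_bounds)) {
      abort(sprintf(
        "gene(s) beyond replicon bounds in hit(s): %s",
        paste(unique(joined$hit_id[out_of_bounds]), collapse = ", ")
      ))
    }
  }
  hits %>%
    mutate(.hit_ord = match(hit_id, unique(hit_id))) %>%
    arrange(.hit_ord, gene_start) %>%
    select(-.hit_ord)
}

#' Read a replicon metadata table
#'
#' One row per replicon with its genome's taxonomy. Required columns:
#' `genome_id`, `phylum`, `genus`, `species`, `replicon_id`, `replicon_type`
#' (`chromosome`/`plasmid`), `topology` (`linear`/`circular`), `length` (bp),
#' `gc` (fraction in \[0, 1\]).
#'
#' @param path path to a TSV file.
#' @return validated tibble.
#' @export
read_replicon_metadata <- function(path) {
  meta <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_columns(meta, META_COLUMNS, sprintf("metadata '%s'", path))
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  check_columns(meta, META_COLUMNS, "metadata")
  if (anyDuplicated(meta$replicon_id) > 0L) {
    abort("`replicon_id` must be unique within a cohort.")
  }
  if (!all(meta$replicon_type %in% c("chromosome", "plasmid"))) {
    abort("`replicon_type` must be 'chromosome' or 'plasmid'.")
  }
  if (!all(meta$topology %in% c("linear", "circular"))) {
    abort("`topology` must be 'linear' or 'circular'.")
  }
  if (any(!is.finite(meta$length)) || any(meta$length <= 0)) {
    abort("`length` must be a positive number of bp.")
  }
  check_prob(meta$gc, "gc")
  as_tibble(meta)
}

#' Read a BED-style interval file
#'
#' Three or more tab-separated columns (`replicon_id`, `start`, `end`,
#' 0-based half-open, no header); extra columns are ignored. Intervals are
#' merged and sorted per replicon, so downstream overlap arithmetic can
#' assume a disjoint union.
#'
#' @param path path to a BED file.
#' @return tibble with columns `replicon_id`, `start`, `end`.
#' @export
read_intervals <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = FALSE, comment = "#", show_col_types = FALSE
  )
  if (nrow(bed) == 0L) {
    return(tibble(replicon_id = character(), start = numeric(), end = numeric()))
  }
  if (ncol(bed) < 3L) {
    abort(sprintf("'%s': BED input needs at least 3 columns.", path))
  }
  bed <- tibble(
    replicon_id = as.character(bed[[1L]]),
    start = as.numeric(bed[[2L]]),
    end = as.numeric(bed[[3L]])
  )
  if (any(bed$start >= bed$end)) {
    abort("BED intervals must satisfy start < end (0-based half-open).")
  }
  if (any(bed$start < 0)) {
    abort("BED intervals must have start >= 0.")
  }
  bed %>%
    group_by(replicon_id) %>%
    group_modify(~ merge_intervals(.x$start, .x$end)) %>%
    ungroup() %>%
    arrange(replicon_id, start)
}

#' Read a Newick tree
#'
#' Parses a Newick string with branch lengths and validates the invariants
#' the phylogenetic-signal stage relies on: unique leaf labels and
#' non-negative branch lengths.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort(sprintf("'%s' could not be parsed as Newick.", path))
  }
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label) > 0L) {
    abort("tree has duplicated leaf labels.")
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths.")
  }
  if (any(tree$edge.length < 0)) {
    abort("tree has negative branch lengths.")
  }
  tree
}

#' Write a result table as TSV
#'
#' Writes any result tibble with a stable column order, optionally preceded
#' by `#`-prefixed comment lines (used by the pipeline to record version,
#' seed and configuration hash). Numbers round-trip through
#' [read_results()]: exactly for integers, beyond 12 significant digits for
#' reals.
#'
#' @param table data frame (no list columns).
#' @param path output path.
#' @param comments optional character vector of comment lines (without the
#'   leading `#`).
#' @return the input, invisibly.
#' @export
write_results <- function(table, path, comments = NULL) {
  if (is.null(table)) {
    abort("`table` must be a data frame, not NULL.")
  }
  if (any(vapply(table, is.list, logical(1)))) {
    abort("list columns cannot be written; flatten them first.")
  }
  lines <- character()
  if (!is.null(comments)) {
    lines <- paste0("# ", comments)
  }
  body <- readr::format_tsv(table)
  body <- sub("\n$", "", body)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(lines, strsplit(body, "\n", fixed = TRUE)[[1L]]), con)
  invisible(table)
}

#' Read a result table written by [write_results()]
#'
#' @param path path to a TSV file; `#` comment lines are skipped.
#' @return tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
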