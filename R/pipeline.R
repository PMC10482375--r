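# End-to-end orchestration. Stages communicate through TSV files in the
# output directory so intermediates are inspectable and stages can be
# rerun; every file starts with comment lines recording the package
# version, the configuration hash and the seed. A markdown report
# summarises the stage tables without any report-only arithmetic.

#' Build a pipeline configuration
#'
#' Inputs are either a [cohort_spec()] (synthetic run) or paths to a hit
#' table, replicon metadata and optional prophage BED / Newick tree files.
#'
#' @param out_dir output directory (created if missing).
#' @param cohort optional [cohort_spec()] to simulate.
#' @param hits,metadata,prophages,tree optional input file paths (TSV, TSV,
#'   BED, Newick); `hits` and `metadata` are required when no cohort is
#'   given.
#' @param focal focal-group expression on the genome metadata, as a string
#'   (default `"phylum == 'Actinobacteria'"`).
#' @param alpha significance level of the differential-abundance screen.
#' @param gc_threshold low-GC flag threshold.
#' @param extremity_thresholds two spatial extremity thresholds.
#' @param min_occurrences strict occurrence floor of the spatial profiles.
#' @param max_intervening defence-island chaining threshold.
#' @param bonferroni_m optional fixed Bonferroni family size.
#' @param seed integer seed for the stages that draw (tree simulation).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       cohort = NULL,
                       hits = NULL,
                       metadata = NULL,
                       prophages = NULL,
                       tree = NULL,
                       focal = "phylum == 'Actinobacteria'",
                       alpha = 0.05,
                       gc_threshold = 0.8,
                       extremity_thresholds = c(0.10, 0.01),
                       min_occurrences = 45L,
                       max_intervening = 20L,
                       bonferroni_m = NULL,
                       seed = 1L) {
  if (is.null(cohort) && (is.null(hits) || is.null(metadata))) {
    abort("provide either a `cohort` spec or `hits` + `metadata` paths.")
  }
  if (!is.null(cohort) && !inherits(cohort, "cohort_spec")) {
    abort("`cohort` must be a cohort_spec().")
  }
  check_prob(alpha, "alpha")
  structure(
    list(
      out_dir = out_dir, cohort = cohort, hits = hits, metadata = metadata,
      prophages = prophages, tree = tree, focal = focal, alpha = alpha,
      gc_threshold = gc_threshold,
      extremity_thresholds = extremity_thresholds,
      min_occurrences = min_occurrences, max_intervening = max_intervening,
      bonferroni_m = bonferroni_m, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full arsenal-analysis pipeline
#'
#' Simulates or loads the cohort, then runs profiling, the
#' differential-abundance screen, MGE attribution and GC scoring, spatial
#' profiling (linear replicons only) and the phylogenetic-signal screen,
#' writing one TSV per stage plus a markdown report. Stages that lack their
#' input (no tree, no linear replicon, one-sided focal split, missing CDS
#' ordinals) are skipped with a warning; any stage error stops the run
#' naming the stage, keeping earlier outputs on disk.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the stage tibbles and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("`config` must come from run_config().")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- c(
    sprintf("defarsenal %s", as.character(packageVersion("defarsenal"))),
    sprintf("config hash: %s", hash(unclass(config))),
    sprintf("seed: %d", config$seed)
  )
  out <- function(name) file.path(config$out_dir, name)
  emit <- function(table, name) {
    write_results(table, out(name), comments = c(stamp, sprintf("table: %s", name)))
  }

  inputs <- run_stage("input", {
    if (!is.null(config$cohort)) {
      simulate_cohort(config$cohort)
    } else {
      meta <- read_replicon_metadata(config$metadata)
      list(
        metadata = meta,
        hits = read_hits(config$hits, category = "defence", metadata = meta),
        prophages = if (is.null(config$prophages)) {
          tibble(replicon_id = character(), start = numeric(), end = numeric())
        } else {
          read_intervals(config$prophages)
        }
      )
    }
  })
  metadata <- inputs$metadata
  hits <- inputs$hits
  prophages <- inputs$prophages
  emit(metadata, "metadata.tsv")
  emit(hits, "hits.tsv")
  emit(prophages, "prophages.tsv")

  tables <- list()
  tables$per_genome <- run_stage("profile", systems_per_genome(hits, metadata))
  emit(tables$per_genome, "per_genome_counts.tsv")
  tables$summary <- run_stage("profile", arsenal_summary(hits, metadata, group = genus))
  emit(tables$summary, "group_summary.tsv")
  tables$fraction <- run_stage("profile", defence_genome_fraction(hits, metadata))
  emit(tables$fraction, "defence_fraction.tsv")
  if (nrow(hits) > 0L && !anyNA(hits$gene_index)) {
    tables$islands <- run_stage(
      "islands",
      detect_islands(hits, max_intervening = config$max_intervening)
    )
    emit(tables$islands, "defence_islands.tsv")
  } else {
    warn("islands stage skipped: hits carry no CDS ordinals (gene_index).")
  }

  focal_expr <- rlang::parse_expr(config$focal)
  genomes <- genome_table(metadata)
  is_focal <- eval_tidy(focal_expr, data = genomes)
  if (any(is_focal) && any(!is_focal)) {
    tables$diffabund <- run_stage("diffabund", {
      res <- diff_abundance(hits, metadata,
        focal = !!focal_expr,
        alpha = config$alpha, m = config$bonferroni_m
      )
      as_tibble(res)
    })
    emit(tables$diffabund, "diff_abundance.tsv")
  } else {
    warn("diffabund stage skipped: focal expression selects zero or all genomes.")
  }

  tables$calls <- run_stage("mge", attribute_location(hits, metadata, prophages))
  emit(tables$calls, "location_calls.tsv")
  tables$contribution <- run_stage("mge", mge_contribution(tables$calls))
  emit(tables$contribution, "mge_contribution.tsv")
  tables$gc <- run_stage(
    "mge",
    gc_score(hits, metadata, threshold = config$gc_threshold) %>%
      select(-gene_scores)
  )
  emit(tables$gc, "gc_scores.tsv")

  linear <- filter(metadata, topology == "linear")
  hits_linear <- semi_join(hits, linear, by = "replicon_id")
  if (nrow(hits_linear) > 0L) {
    tables$positions <- run_stage("spatial", normalized_positions(hits_linear, linear))
    emit(tables$positions, "spatial_positions.tsv")
    tables$profiles <- run_stage("spatial", spatial_profiles(
      hits, metadata,
      min_occurrences = config$min_occurrences,
      thresholds = config$extremity_thresholds
    ))
    emit(tables$profiles, "spatial_profiles.tsv")
  } else {
    warn("spatial stage skipped: no hits on linear replicons.")
  }

  tree <- NULL
  if (!is.null(config$tree)) {
    if (file.exists(config$tree)) {
      tree <- run_stage("physig", read_tree(config$tree))
    } else {
      warn(sprintf("physig stage skipped: tree file '%s' not found.", config$tree))
    }
  } else if (!is.null(config$cohort) && sum(is_focal) >= 4L) {
    tree <- run_stage("physig", simulate_tree(
      sum(is_focal),
      seed = config$seed + 1L,
      labels = genomes$genome_id[is_focal]
    ))
  }
  if (!is.null(tree)) {
    tables$physig <- run_stage("physig", {
      pres <- presence_matrix(hits, metadata) %>%
        filter(label %in% tree$tip.label)
      signal_screen(pres, tree)
    })
    emit(tables$physig, "phylo_signal.tsv")
  }

  report <- build_report(tables, config, stamp)
  writeLines(report, out("report.md"))
  invisible(list(tables = tables, out_dir = config$out_dir, report = out("report.md")))
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA",
    ifelse(abs(x - round(x)) < 1e-12, format(round(x)), formatC(x, digits = digits, format = "g"))
  )
}

md_table <- function(df, digits = 4) {
  if (nrow(df) == 0L) {
    return("(empty table)")
  }
  cells <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col, digits) else as.character(col)
  })
  m <- do.call(cbind, cells)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  body <- apply(m, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

build_report <- function(tables, config, stamp) {
  lines <- c(
    "# Anti-phage arsenal analysis report",
    "",
    paste0("_", stamp, "_"),
    ""
  )
  if (!is.null(tables$per_genome)) {
    lines <- c(
      lines, "## Arsenal overview", "",
      sprintf(
        "- Genomes: %d; mean systems per genome: %s",
        nrow(tables$per_genome), fmt_num(mean(tables$per_genome$n_systems))
      ),
      sprintf(
        "- Mean genome fraction devoted to defence: %s",
        fmt_num(mean(tables$fraction$fraction))
      ),
      ""
    )
  }
  if (!is.null(tables$islands)) {
    lines <- c(lines, sprintf("- Defence islands detected: %d", nrow(tables$islands)), "")
  }
  if (!is.null(tables$diffabund)) {
    cls <- table(factor(
      tables$diffabund$class_label,
      levels = c("absent", "enriched", "depleted", "not_significant")
    ))
    lines <- c(
      lines, "## Differential abundance", "",
      sprintf(
        "- Focal group: `%s` (alpha = %g, Bonferroni m = %d)",
        config$focal, config$alpha, attr(tables$diffabund, "m") %||% sum(!is.na(tables$diffabund$p_adj))
      ),
      sprintf(
        "- absent: %d, enriched: %d, depleted: %d, not significant: %d",
        cls[["absent"]], cls[["enriched"]], cls[["depleted"]], cls[["not_significant"]]
      ),
      "",
      md_table(tables$diffabund[, c(
        "system_type", "abundance_in", "abundance_out",
        "estimator", "p_adj", "class_label"
      )]),
      ""
    )
  }
  if (!is.null(tables$contribution)) {
    lines <- c(
      lines, "## Mobile-genetic-element contribution", "",
      md_table(tables$contribution[, c(
        "system_type", "n_total", "pct_chromosome",
        "pct_plasmid", "pct_prophage"
      )]),
      ""
    )
  }
  if (!is.null(tables$profiles)) {
    lines <- c(
      lines, "## Spatial profiles (linear replicons)", "",
      md_table(tables$profiles), ""
    )
  }
  if (!is.null(tables$physig)) {
    screened <- filter(tables$physig, is.na(skipped))
    lines <- c(
      lines, "## Phylogenetic signal", "",
      sprintf(
        "- Types screened: %d (of %d); with signal: %d; patchy: %d",
        nrow(screened), nrow(tables$physig),
        sum(screened$signal, na.rm = TRUE), sum(screened$patchy, na.rm = TRUE)
      ),
      "",
      md_table(tables$physig[, c(
        "system_type", "n_present", "lambda", "p_value", "signal", "skipped"
      )]),
      ""
    )
  }
  lines
}
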