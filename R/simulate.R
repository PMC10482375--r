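# Synthetic cohort generator. Emits the same tables the readers produce
# (replicon metadata, long-format hit tables, merged prophage intervals)
# with controlled statistical structure: per-group system abundances,
# MGE carriage probabilities, GC shifts of transferred genes, and
# core/arm/end placement mixtures on linear chromosomes. Ground truth
# (the planted location of each copy) is carried in a `planted_location`
# column so recovery tests can score every downstream stage.

#' Describe one simulated system type
#'
#' @param system_type label of the system (e.g. `"RM"`, `"Wadjet"`).
#' @param abundance_in,abundance_out mean copies per genome in the focal and
#'   background groups (>= 0).
#' @param copies_model `"poisson"` (multi-copy) or `"bernoulli"`
#'   (presence/absence; means are clamped to \[0, 1\]).
#' @param mge_prob probability that a copy is placed on a mobile genetic
#'   element (inside a prophage interval, or on a plasmid when the genome
#'   carries one).
#' @param gc_shift multiplicative factor applied to gene GC relative to the
#'   replicon GC (values < 1 emulate AT-enriched horizontal transfers);
#'   the product is clamped to \[0.05, 0.95\].
#' @param placement chromosomal placement family for non-MGE copies:
#'   `"uniform"`; `"core_biased"` (position fraction ~ Beta(5, 5));
#'   `"arm_biased"` (equal mixture of Beta(1, 9) and Beta(9, 1));
#'   `"end_biased"` (equal mixture of Beta(0.2, 20) and Beta(20, 0.2)).
#' @param n_genes genes per copy (>= 1).
#' @param category `"defence"` or `"bgc"`.
#' @return a `system_spec` list.
#' @export
system_spec <- function(system_type,
                        abundance_in,
                        abundance_out,
                        copies_model = c("poisson", "bernoulli"),
                        mge_prob = 0,
                        gc_shift = 1,
                        placement = c("uniform", "core_biased", "arm_biased", "end_biased"),
                        n_genes = 2L,
                        category = c("defence", "bgc")) {
  copies_model <- match.arg(copies_model)
  placement <- match.arg(placement)
  category <- match.arg(category)
  if (abundance_in < 0 || abundance_out < 0) {
    abort("abundances must be >= 0.")
  }
  check_prob(mge_prob, "mge_prob")
  if (gc_shift <= 0) {
    abort("`gc_shift` must be > 0.")
  }
  if (n_genes < 1L) {
    abort("`n_genes` must be >= 1.")
  }
  structure(
    list(
      system_type = system_type, abundance_in = abundance_in,
      abundance_out = abundance_out, copies_model = copies_model,
      mge_prob = mge_prob, gc_shift = gc_shift, placement = placement,
      n_genes = as.integer(n_genes), category = category
    ),
    class = "system_spec"
  )
}

#' Describe a synthetic cohort
#'
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @param n_genomes_in,n_genomes_out genomes in the focal and background
#'   groups.
#' @param systems list of [system_spec()] objects.
#' @param genera_in,genera_out number of genera the focal/background genomes
#'   are spread across (round-robin), or a named integer vector of per-genus
#'   genome counts summing to the group size.
#' @param prophage_rate mean prophages per genome (Poisson); prophage
#'   intervals are 10-60 kb, placed uniformly on the chromosome and merged.
#' @param plasmid_prob probability a genome carries one plasmid (50-300 kb,
#'   annotated circular).
#' @param chromosome_length_range min/max chromosome length in bp.
#' @param topology chromosome topology, `"linear"` or `"circular"`.
#'   Non-uniform placement families require linear chromosomes.
#' @param gc_range min/max replicon GC fraction.
#' @param phylum_in,phylum_out phylum labels for the two groups.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(seed,
                        n_genomes_in = 100L,
                        n_genomes_out = 100L,
                        systems = list(),
                        genera_in = 4L,
                        genera_out = 4L,
                        prophage_rate = 1,
                        plasmid_prob = 0.3,
                        chromosome_length_range = c(6e6, 9e6),
                        topology = c("linear", "circular"),
                        gc_range = c(0.45, 0.75),
                        phylum_in = "Actinobacteria",
                        phylum_out = "OtherBacteria") {
  topology <- match.arg(topology)
  if (n_genomes_in < 0 || n_genomes_out < 0) {
    abort("genome counts must be >= 0.")
  }
  if (prophage_rate < 0) {
    abort("`prophage_rate` must be >= 0.")
  }
  check_prob(plasmid_prob, "plasmid_prob")
  if (length(chromosome_length_range) != 2L ||
    chromosome_length_range[1L] > chromosome_length_range[2L] ||
    chromosome_length_range[1L] <= 0) {
    abort("`chromosome_length_range` must be c(min, max) with 0 < min <= max.")
  }
  if (!all(vapply(systems, inherits, logical(1), "system_spec"))) {
    abort("`systems` must be a list of system_spec() objects.")
  }
  structure(
    list(
      seed = as.integer(seed), n_genomes_in = as.integer(n_genomes_in),
      n_genomes_out = as.integer(n_genomes_out), systems = systems,
      genera_in = genera_in, genera_out = genera_out,
      prophage_rate = prophage_rate, plasmid_prob = plasmid_prob,
      chromosome_length_range = chromosome_length_range,
      topology = topology, gc_range = gc_range,
      phylum_in = phylum_in, phylum_out = phylum_out
    ),
    class = "cohort_spec"
  )
}

resolve_genera <- function(n, genera, prefix) {
  if (n == 0L) {
    return(character())
  }
  if (length(genera) == 1L && is.null(names(genera))) {
    k <- max(1L, as.integer(genera))
    return(paste0(prefix, "_genus", ((seq_len(n) - 1L) %% k) + 1L))
  }
  if (is.null(names(genera)) || sum(genera) != n) {
    abort("named genus counts must sum to the group's genome count.")
  }
  rep(names(genera), times = genera)
}

placement_fraction <- function(n, placement) {
  if (n == 0L) {
    return(numeric())
  }
  switch(placement,
    uniform = runif(n),
    core_biased = rbeta(n, 5, 5),
    arm_biased = {
      x <- rbeta(n, 1, 9)
      ifelse(runif(n) < 0.5, x, 1 - x)
    },
    end_biased = {
      x <- rbeta(n, 0.2, 20)
      ifelse(runif(n) < 0.5, x, 1 - x)
    }
  )
}

#' Simulate a cohort of genomes, hits and prophages
#'
#' Deterministic given the spec (one RNG stream seeded from `spec$seed`).
#' Copy numbers per genome follow the group mean under the system's copies
#' model; MGE-designated copies land inside a prophage interval or on a
#' plasmid (falling back to the chromosome when the genome carries neither);
#' chromosomal copies follow the placement family; gene GC equals replicon
#' GC times `gc_shift`, clamped to \[0.05, 0.95\].
#'
#' The returned hit table carries a `planted_location` ground-truth column
#' (not part of the reader dialect) used by recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @return list with tibbles `metadata`, `hits`, `prophages`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec().")
  }
  nonuniform <- vapply(spec$systems, function(s) s$placement != "uniform", logical(1))
  if (spec$topology == "circular" && any(nonuniform)) {
    abort("non-uniform placement families require linear chromosomes.")
  }
  withr::with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_genomes_in + spec$n_genomes_out
  in_group <- c(rep(TRUE, spec$n_genomes_in), rep(FALSE, spec$n_genomes_out))
  genome_id <- sprintf("G%05d", seq_len(n))
  genus <- c(
    resolve_genera(spec$n_genomes_in, spec$genera_in, "focal"),
    resolve_genera(spec$n_genomes_out, spec$genera_out, "bg")
  )
  chrom_len <- floor(runif(
    n, spec$chromosome_length_range[1L],
    spec$chromosome_length_range[2L]
  ))
  chrom_gc <- runif(n, spec$gc_range[1L], spec$gc_range[2L])
  has_plasmid <- runif(n) < spec$plasmid_prob
  plasmid_len <- floor(runif(n, 5e4, 3e5))
  plasmid_gc <- pmin(0.95, pmax(0.05, chrom_gc + runif(n, -0.05, 0.05)))

  genomes <- tibble(
    genome_id = genome_id,
    in_group = in_group,
    phylum = ifelse(in_group, spec$phylum_in, spec$phylum_out),
    genus = genus,
    species = paste0(genus, "_sp"),
    chrom_id = paste0(genome_id, "_chr"),
    chrom_len = chrom_len,
    chrom_gc = chrom_gc,
    has_plasmid = has_plasmid,
    plasmid_id = ifelse(has_plasmid, paste0(genome_id, "_pls"), NA_character_),
    plasmid_len = ifelse(has_plasmid, plasmid_len, NA_real_),
    plasmid_gc = ifelse(has_plasmid, plasmid_gc, NA_real_)
  )

  metadata <- bind_rows(
    genomes %>%
      transmute(genome_id, phylum, genus, species,
        replicon_id = chrom_id, replicon_type = "chromosome",
        topology = spec$topology, length = chrom_len, gc = chrom_gc
      ),
    genomes %>%
      filter(has_plasmid) %>%
      transmute(genome_id, phylum, genus, species,
        replicon_id = plasmid_id, replicon_type = "plasmid",
        topology = "circular", length = plasmid_len, gc = plasmid_gc
      )
  )

  # Prophage intervals on chromosomes, merged per replicon.
  n_pp <- rpois(n, spec$prophage_rate)
  pp <- tibble(
    genome_id = rep(genomes$genome_id, n_pp),
    replicon_id = rep(genomes$chrom_id, n_pp),
    chrom_len = rep(genomes$chrom_len, n_pp)
  )
  if (nrow(pp) > 0L) {
    pp$len <- floor(runif(nrow(pp), 1e4, 6e4))
    pp$start <- floor(runif(nrow(pp)) * pmax(1, pp$chrom_len - pp$len))
    pp$end <- pp$start + pp$len
    prophages <- pp %>%
      group_by(replicon_id) %>%
      group_modify(~ merge_intervals(.x$start, .x$end)) %>%
      ungroup() %>%
      arrange(replicon_id, start)
  } else {
    prophages <- tibble(replicon_id = character(), start = numeric(), end = numeric())
  }
  pp_per_genome <- prophages %>%
    left_join(select(genomes, genome_id, chrom_id), by = c("replicon_id" = "chrom_id")) %>%
    group_by(genome_id) %>%
    mutate(pp_index = row_number()) %>%
    ungroup()
  n_pp_merged <- pp_per_genome %>% count(genome_id, name = "n_pp")

  hits_list <- lapply(spec$systems, function(sys) {
    simulate_system_hits(sys, genomes, pp_per_genome, n_pp_merged, spec$topology)
  })
  hits <- bind_rows(hits_list)
  if (nrow(hits) == 0L) {
    hits <- tibble(
      hit_id = character(), genome_id = character(), replicon_id = character(),
      category = character(), system_type = character(), subtype = character(),
      gene_start = numeric(), gene_end = numeric(), strand = character(),
      gene_gc = numeric(), gene_index = integer(), planted_location = character()
    )
  }
  list(
    metadata = metadata,
    hits = hits,
    prophages = select(prophages, replicon_id, start, end)
  )
}

simulate_system_hits <- function(sys, genomes, pp_per_genome, n_pp_merged, topology) {
  mean_per_genome <- ifelse(genomes$in_group, sys$abundance_in, sys$abundance_out)
  copies <- switch(sys$copies_model,
    poisson = rpois(nrow(genomes), mean_per_genome),
    bernoulli = rbinom(nrow(genomes), 1L, pmin(1, mean_per_genome))
  )
  if (sum(copies) == 0L) {
    return(NULL)
  }
  span <- sys$n_genes * 1000L - 100L

  cp <- genomes[rep(seq_len(nrow(genomes)), copies), ] %>%
    left_join(n_pp_merged, by = "genome_id") %>%
    mutate(n_pp = dplyr::coalesce(n_pp, 0L))
  cp$want_mge <- runif(nrow(cp)) < sys$mge_prob
  u <- runif(nrow(cp))
  cp$planted_location <- dplyr::case_when(
    !cp$want_mge ~ "chromosome",
    cp$n_pp > 0L & cp$has_plasmid ~ ifelse(u < 0.5, "prophage", "plasmid"),
    cp$n_pp > 0L ~ "prophage",
    cp$has_plasmid ~ "plasmid",
    TRUE ~ "chromosome"
  )

  # Prophage-carried copies: pick one merged interval, place inside it.
  pp_draw <- runif(nrow(cp))
  cp$pp_index <- ifelse(
    cp$planted_location == "prophage",
    floor(pp_draw * pmax(1L, cp$n_pp)) + 1L, NA_integer_
  )
  cp <- left_join(
    cp,
    select(pp_per_genome, genome_id, pp_index, pp_start = start, pp_end = end),
    by = c("genome_id", "pp_index")
  )

  frac <- placement_fraction(nrow(cp), sys$placement)
  inner <- runif(nrow(cp))
  cp <- cp %>%
    mutate(
      replicon_id = dplyr::case_when(
        planted_location == "plasmid" ~ plasmid_id,
        TRUE ~ chrom_id
      ),
      replicon_len = dplyr::case_when(
        planted_location == "plasmid" ~ plasmid_len,
        TRUE ~ as.numeric(chrom_len)
      ),
      replicon_gc = dplyr::case_when(
        planted_location == "plasmid" ~ plasmid_gc,
        TRUE ~ chrom_gc
      ),
      start = dplyr::case_when(
        planted_location == "prophage" ~
          pp_start + floor(inner * pmax(1, (pp_end - pp_start) - span)),
        planted_location == "plasmid" ~ floor(inner * pmax(1, replicon_len - span)),
        TRUE ~ floor(frac * pmax(1, replicon_len - span))
      )
    ) %>%
    group_by(genome_id) %>%
    mutate(copy_idx = row_number()) %>%
    ungroup() %>%
    mutate(hit_id = sprintf("%s_%s_%02d", genome_id, sys$system_type, copy_idx))

  # Expand copies into genes: 900 bp CDS every 1 kb; gene ordinal is the
  # position on a nominal 1-CDS-per-kb backbone, shared across systems of
  # the replicon so intervening-gene counts are meaningful.
  genes <- cp[rep(seq_len(nrow(cp)), each = sys$n_genes), ]
  offset <- rep(seq_len(sys$n_genes) - 1L, times = nrow(cp))
  genes$gene_start <- genes$start + offset * 1000L
  genes$gene_end <- pmin(genes$gene_start + 900L, genes$replicon_len)
  genes$gene_index <- as.integer(genes$gene_start %/% 1000L)
  genes$strand <- ifelse(runif(nrow(genes)) < 0.5, "+", "-")
  genes$gene_gc <- pmin(0.95, pmax(0.05, genes$replicon_gc * sys$gc_shift))

  genes %>%
    transmute(
      hit_id, genome_id, replicon_id,
      category = sys$category, system_type = sys$system_type,
      subtype = NA_character_, gene_start, gene_end, strand, gene_gc,
      gene_index, planted_location
    )
}

#' Simulate an ultrametric tree with unit depth
#'
#' Pure-birth (Yule) tree rescaled so every root-to-leaf path has length 1.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed integer seed.
#' @param labels optional leaf labels (length `n_leaves`).
#' @return an [ape::phylo] object.
#' @export
simulate_tree <- function(n_leaves, seed, labels = NULL) {
  if (n_leaves < 2L) {
    abort("`n_leaves` must be >= 2.")
  }
  tree <- withr::with_seed(seed, ape::rphylo(n_leaves, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  max_depth <- max(depths[seq_len(n_leaves)])
  tree$edge.length <- tree$edge.length / max_depth
  if (!is.null(labels)) {
    if (length(labels) != n_leaves) {
      abort("`labels` must have length `n_leaves`.")
    }
    tree$tip.label <- labels
  }
  tree
}

#' Simulate a (possibly binarized) trait under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal trait with covariance `sigma2 * C(lambda)`,
#' where `C` is the Brownian tree covariance (shared root-to-MRCA path
#' lengths) and `lambda` scales its off-diagonal entries. With
#' `binarize_at = q`, the draw is thresholded at its empirical `q`-quantile
#' into a 0/1 presence/absence trait.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @param lambda signal strength in \[0, 1\].
#' @param sigma2 Brownian rate (> 0).
#' @param seed integer seed.
#' @param binarize_at optional quantile in (0, 1).
#' @param root root state (default 0).
#' @return tibble with columns `label`, `value`.
#' @export
simulate_trait <- function(tree, lambda, sigma2 = 1, seed = 1L,
                           binarize_at = NULL, root = 0) {
  if (lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1].")
  }
  if (sigma2 <= 0) {
    abort("`sigma2` must be > 0.")
  }
  validate_tree(tree)
  C <- tree_covariance(tree)
  Cl <- lambda_scale(C, lambda)
  R <- chol(sigma2 * Cl)
  y <- withr::with_seed(seed, {
    drop(root + crossprod(R, rnorm(nrow(C))))
  })
  names(y) <- rownames(C)
  if (!is.null(binarize_at)) {
    if (binarize_at <= 0 || binarize_at >= 1) {
      abort("`binarize_at` must lie in (0, 1).")
    }
    y <- as.numeric(y > quantile(y, binarize_at))
    names(y) <- rownames(C)
  }
  tibble(label = rownames(C), value = unname(y))
}
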