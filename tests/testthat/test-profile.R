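test_that("systems per genome counts hits and reports zero for hit-less genomes", {
  meta <- dplyr::bind_rows(
    meta_row("g1", "g1_chr"), meta_row("g2", "g2_chr"), meta_row("g3", "g3_chr")
  )
  hits <- dplyr::bind_rows(
    make_hit("h1", list(c(0, 900)), genome_id = "g1"),
    make_hit("h2", list(c(5000, 5900), c(6000, 6900)), genome_id = "g1"),
    make_hit("h3", list(c(0, 900)), genome_id = "g3", replicon_id = "g3_chr")
  )
  counts <- systems_per_genome(hits, meta)
  expect_equal(
    setNames(counts$n_systems, counts$genome_id),
    c(g1 = 2L, g2 = 0L, g3 = 1L)
  )
  expect_equal(sum(counts$n_systems), dplyr::n_distinct(hits$hit_id))

  none <- systems_per_genome(hits[0, ], meta)
  expect_true(all(none$n_systems == 0L))

  orphan <- make_hit("hx", list(c(0, 900)), genome_id = "gZ", replicon_id = "gZ_chr")
  expect_error(systems_per_genome(orphan, meta), "gZ")
})

test_that("group summaries compute frequency and abundance per type", {
  meta <- dplyr::bind_rows(lapply(paste0("g", 1:4), function(g) {
    meta_row(g, paste0(g, "_chr"))
  }))
  # copies of RM per genome: g1 0, g2 2, g3 1, g4 1
  hits <- dplyr::bind_rows(
    make_hit("h1", list(c(0, 900)), genome_id = "g2", replicon_id = "g2_chr"),
    make_hit("h2", list(c(5000, 5900)), genome_id = "g2", replicon_id = "g2_chr"),
    make_hit("h3", list(c(0, 900)), genome_id = "g3", replicon_id = "g3_chr"),
    make_hit("h4", list(c(0, 900)), genome_id = "g4", replicon_id = "g4_chr")
  )
  summ <- arsenal_summary(hits, meta)
  expect_equal(summ$group_label, "all")
  expect_equal(summ$frequency, 0.75)
  expect_equal(summ$abundance, 1.0)
  expect_true(all(summ$abundance >= summ$frequency))

  # one copy everywhere: frequency = abundance = 1
  one_each <- dplyr::bind_rows(lapply(paste0("g", 1:4), function(g) {
    make_hit(paste0("h_", g), list(c(0, 900)), genome_id = g, replicon_id = paste0(g, "_chr"))
  }))
  s1 <- arsenal_summary(one_each, meta)
  expect_equal(s1$frequency, 1)
  expect_equal(s1$abundance, 1)

  # a type absent from a group shows frequency = abundance = 0
  meta2 <- dplyr::bind_rows(
    meta_row("g1", "g1_chr", genus = "A"),
    meta_row("g2", "g2_chr", genus = "B")
  )
  h <- make_hit("h1", list(c(0, 900)), genome_id = "g1")
  s2 <- arsenal_summary(h, meta2, group = genus)
  b_row <- s2[s2$group_label == "B", ]
  expect_equal(b_row$frequency, 0)
  expect_equal(b_row$abundance, 0)
})

test_that("whole-cohort summary conserves per-type totals of a simulated cohort", {
  spec <- cohort_spec(
    seed = 8, n_genomes_in = 30, n_genomes_out = 30,
    systems = list(system_spec("RM", 1.5, 0.5), system_spec("Wadjet", 0.3, 0.3))
  )
  co <- simulate_cohort(spec)
  summ <- arsenal_summary(co$hits, co$metadata)
  totals <- co$hits %>%
    dplyr::distinct(hit_id, system_type) %>%
    dplyr::count(system_type)
  expect_equal(
    setNames(summ$n_copies, summ$system_type),
    setNames(totals$n, totals$system_type)
  )
  n_genomes <- dplyr::n_distinct(co$metadata$genome_id)
  expect_equal(
    sum(summ$abundance),
    mean(systems_per_genome(co$hits, co$metadata)$n_systems)
  )
  expect_equal(unique(summ$n_genomes), n_genomes)
})

test_that("defence genome fraction merges overlapping genes and uses total replicon length", {
  meta <- meta_row("g1", "g1_chr", length = 1e6)
  hits <- make_hit("h1", list(c(1000, 3950), c(5000, 7950)))
  expect_equal(defence_genome_fraction(hits, meta)$fraction, 5900 / 1e6)

  # overlapping genes are merged before summing: (0,100) + (50,150) -> 150 bp
  ov <- make_hit("h2", list(c(0, 100), c(50, 150)))
  expect_equal(defence_genome_fraction(ov, meta)$defence_bp, 150)

  expect_equal(defence_genome_fraction(hits[0, ], meta)$fraction, 0)

  # BGC hits do not count toward the defence fraction
  bgc <- make_hit("h3", list(c(0, 5000)), category = "bgc")
  expect_equal(defence_genome_fraction(bgc, meta)$fraction, 0)
})

island_hit <- function(hit_id, idx, replicon_id = "g1_chr") {
  make_hit(hit_id, lapply(idx, function(i) c(i * 1000, i * 1000 + 900)),
    replicon_id = replicon_id, gene_index = idx
  )
}

test_that("island chaining follows the strict intervening-CDS rule", {
  # systems at gene indices 10-12 and 25-27: 25 - 12 - 1 = 12 intervening < 20
  two <- dplyr::bind_rows(island_hit("a", 10:12), island_hit("b", 25:27))
  isl <- detect_islands(two)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$n_systems, 2L)
  expect_equal(isl$hit_ids, "a,b")

  # 40 - 12 - 1 = 27 intervening -> no island (singletons unreported)
  far <- dplyr::bind_rows(island_hit("a", 10:12), island_hit("b", 40:41))
  expect_equal(nrow(detect_islands(far)), 0L)

  # exactly 20 intervening is not chained ("fewer than 20")
  at20 <- dplyr::bind_rows(island_hit("a", 10:12), island_hit("b", 33:34))
  expect_equal(nrow(detect_islands(at20)), 0L)
  at19 <- dplyr::bind_rows(island_hit("a", 10:12), island_hit("b", 32:34))
  expect_equal(nrow(detect_islands(at19)), 1L)

  expect_equal(nrow(detect_islands(island_hit("solo", 5:6))), 0L)

  no_idx <- make_hit("h1", list(c(0, 900)))
  expect_error(detect_islands(no_idx), "gene_index")
})

test_that("island chaining equals the transitive closure of the pairwise criterion", {
  set.seed(55)
  for (rep in 1:100) {
    n_sys <- sample(2:7, 1)
    hits <- dplyr::bind_rows(lapply(seq_len(n_sys), function(i) {
      lo <- sample(0:120, 1)
      island_hit(paste0("s", i), lo:(lo + sample(1:4, 1)))
    }))
    isl <- detect_islands(hits, max_intervening = 20L)

    spans <- hits %>%
      dplyr::group_by(hit_id) %>%
      dplyr::summarise(lo = min(gene_index), hi = max(gene_index), .groups = "drop")
    adj <- outer(seq_len(n_sys), seq_len(n_sys), Vectorize(function(i, j) {
      if (i == j) {
        return(FALSE)
      }
      up <- if (spans$lo[i] <= spans$lo[j]) i else j
      dn <- if (up == i) j else i
      (spans$lo[dn] - spans$hi[up] - 1) < 20
    }))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    oracle <- sort(table(comp)[table(comp) >= 2], decreasing = TRUE)
    expect_equal(sort(isl$n_systems, decreasing = TRUE), as.integer(sort(oracle, decreasing = TRUE)))
    # membership sets must match, not just sizes
    oracle_sets <- split(spans$hit_id, comp)
    oracle_sets <- Filter(function(s) length(s) >= 2, oracle_sets)
    got_sets <- lapply(strsplit(isl$hit_ids, ","), sort)
    expect_setequal(
      vapply(got_sets, paste, character(1), collapse = ","),
      vapply(lapply(oracle_sets, sort), paste, character(1), collapse = ",")
    )
  }
})
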