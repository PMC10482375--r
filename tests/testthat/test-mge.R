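test_that("defence hits are prophage-encoded on any >= 1 bp gene overlap", {
  meta <- meta_row()
  hit <- make_hit("h1", list(c(100, 400), c(500, 900)))
  # prophage starts inside the second gene
  call <- attribute_location(hit, meta, pp(c(850, 2000)))
  expect_equal(call$location, "prophage")
  expect_equal(call$prophage_overlap_bp, 50)

  # book-ended but not overlapping (half-open): not prophage
  call2 <- attribute_location(hit, meta, pp(c(900, 2000)))
  expect_equal(call2$location, "chromosome")

  # no prophages on a plasmid replicon -> plasmid
  pmeta <- meta_row("g1", "g1_pls", replicon_type = "plasmid", topology = "circular")
  phit <- make_hit("h2", list(c(0, 900)), replicon_id = "g1_pls")
  expect_equal(
    attribute_location(phit, pmeta, pp(c(1, 2))[0, ])$location,
    "plasmid"
  )
})

test_that("BGC hits need at least half their span inside prophages; prophage beats plasmid", {
  meta <- meta_row()
  bgc <- make_hit("b1", list(c(0, 450), c(600, 1000)), category = "bgc")
  # span is [0, 1000); 499 bp covered -> below half -> chromosome
  expect_equal(attribute_location(bgc, meta, pp(c(0, 499)))$location, "chromosome")
  # exactly half counts as prophage ("at least 50 %")
  at_half <- attribute_location(bgc, meta, pp(c(0, 500)))
  expect_equal(at_half$location, "prophage")
  expect_equal(at_half$overlap_fraction, 0.5)

  # defence rule is one gene, not span coverage: tiny overlap suffices
  expect_equal(
    attribute_location(
      make_hit("d1", list(c(0, 450), c(600, 1000))), meta, pp(c(449, 460))
    )$location,
    "prophage"
  )

  # a prophage on a plasmid is "prophage" (precedence)
  pmeta <- meta_row("g1", "g1_pls", replicon_type = "plasmid", topology = "circular")
  phit <- make_hit("d2", list(c(100, 1000)), replicon_id = "g1_pls")
  ppl <- tibble::tibble(replicon_id = "g1_pls", start = 0, end = 5000)
  expect_equal(attribute_location(phit, pmeta, ppl)$location, "prophage")
})

test_that("attribution matches a per-base brute-force oracle on random layouts", {
  set.seed(303)
  repl_len <- 10000
  meta <- meta_row(length = repl_len)
  for (rep in 1:300) {
    n_genes <- sample(1:4, 1)
    gs <- sort(sample(0:(repl_len - 400), n_genes))
    genes <- lapply(gs, function(s) c(s, s + sample(50:300, 1)))
    category <- sample(c("defence", "bgc"), 1)
    hit <- make_hit("h", genes, category = category)
    n_pp <- sample(0:4, 1)
    ps <- if (n_pp > 0) sample(0:(repl_len - 500), n_pp) else integer()
    pe <- ps + sample(100:3000, n_pp, replace = TRUE)
    pe <- pmin(pe, repl_len)
    prophages <- tibble::tibble(replicon_id = "g1_chr", start = ps, end = pe)

    call <- attribute_location(hit, meta, prophages)

    gene_ov <- vapply(genes, function(g) {
      overlap_oracle(g[1], g[2], ps, pe, repl_len)
    }, numeric(1))
    span <- c(min(gs), max(vapply(genes, `[`, numeric(1), 2)))
    span_ov <- overlap_oracle(span[1], span[2], ps, pe, repl_len)
    expected <- if (category == "defence") {
      if (any(gene_ov > 0)) "prophage" else "chromosome"
    } else {
      if (span_ov / (span[2] - span[1]) >= 0.5) "prophage" else "chromosome"
    }
    expect_equal(call$location, expected)
    expect_equal(call$prophage_overlap_bp, sum(gene_ov))
    expect_equal(call$overlap_fraction, span_ov / (span[2] - span[1]))
  }
})

test_that("per-type element contributions count occurrences and sum to one", {
  calls <- tibble::tibble(
    hit_id = sprintf("h%02d", 1:10),
    system_type = "RM",
    location = c(rep("chromosome", 7), "plasmid", "plasmid", "prophage")
  )
  contrib <- mge_contribution(calls)
  expect_equal(contrib$fraction_chromosome, 0.7)
  expect_equal(contrib$fraction_plasmid, 0.2)
  expect_equal(contrib$fraction_prophage, 0.1)
  expect_equal(
    contrib$fraction_chromosome + contrib$fraction_plasmid + contrib$fraction_prophage,
    1
  )

  all_chr <- mge_contribution(dplyr::mutate(calls, location = "chromosome"))
  expect_equal(all_chr$fraction_chromosome, 1)
  expect_equal(all_chr$pct_chromosome, 100)
})

test_that("GC scores normalize gene GC by replicon GC and flag low-GC systems", {
  meta <- meta_row(gc = 0.70)
  low <- gc_score(make_hit("h1", list(c(0, 900)), gc = 0.35), meta)
  expect_equal(low$mean_gc_score, 0.5)
  expect_true(low$low_gc)

  same <- gc_score(make_hit("h2", list(c(0, 900)), gc = 0.70), meta)
  expect_equal(same$mean_gc_score, 1)
  expect_false(same$low_gc)

  hit <- make_hit("h3", list(c(0, 900), c(1000, 1900)))
  hit$gene_gc <- c(0.6, 0.8)
  multi <- gc_score(hit, meta)
  expect_equal(multi$gene_scores[[1]], c(0.6, 0.8) / 0.7)
  expect_equal(multi$mean_gc_score, mean(c(0.6, 0.8) / 0.7))

  expect_error(gc_score(hit, meta_row(gc = 0)), "> 0")
})

test_that("rare systems planted on MGEs show the negative frequency/MGE-fraction trend", {
  spec <- cohort_spec(
    seed = 23, n_genomes_in = 120, n_genomes_out = 0,
    genera_in = 2L,
    systems = list(
      system_spec("CommonA", 1.8, 0, mge_prob = 0, copies_model = "poisson"),
      system_spec("CommonB", 1.2, 0, mge_prob = 0),
      system_spec("RareA", 0.15, 0, mge_prob = 0.8, gc_shift = 0.7),
      system_spec("RareB", 0.1, 0, mge_prob = 0.8, gc_shift = 0.7)
    ),
    prophage_rate = 3, plasmid_prob = 0.5
  )
  co <- simulate_cohort(spec)
  calls <- attribute_location(co$hits, co$metadata, co$prophages)
  scores <- gc_score(co$hits, co$metadata)
  tab <- frequency_vs_mge(co$hits, co$metadata, calls, scores)
  expect_true(all(c("genus", "system_type", "frequency", "mge_fraction", "mean_gc_score") %in% names(tab)))
  expect_lt(cor(tab$frequency, tab$mge_fraction, method = "spearman"), 0)
  # the planted low-GC systems carry the low scores
  rare <- tab$mean_gc_score[grepl("^Rare", tab$system_type)]
  common <- tab$mean_gc_score[grepl("^Common", tab$system_type)]
  expect_lt(max(rare), min(common))
})
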