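balanced4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("the tree covariance holds shared path lengths", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(tree_covariance(t2)), diag(2))

  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- tree_covariance(t3)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(C), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3))

  # ultrametric trees have constant diagonal
  tr <- simulate_tree(16, seed = 2)
  expect_true(all(abs(diag(tree_covariance(tr)) - 1) < 1e-9))
})

test_that("the lambda transform scales the off-diagonal and detects infeasibility", {
  C <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(lambda_transform(C, 0.5), matrix(c(2, 0.5, 0.5, 2), 2))
  expect_equal(lambda_transform(C, 0), diag(c(2, 2)))
  expect_equal(lambda_transform(C, 1), C)
  # singular at lambda = 1 when leaves share their entire depth
  expect_error(lambda_transform(matrix(c(1, 1, 1, 1), 2), 1), "positive definite")
  expect_error(lambda_transform(C, -0.2), ">= 0")
})

test_that("the ML fit dominates a dense grid and matches the lambda = 0 closed form", {
  for (cfg in list(list(tree = balanced4, seed = 5), list(tree = simulate_tree(16, seed = 6), seed = 7))) {
    tr <- cfg$tree
    y <- simulate_trait(tr, lambda = 1, sigma2 = 1, seed = cfg$seed)
    fit <- fit_lambda(y, tr)
    C <- tree_covariance(tr)
    yv <- setNames(y$value, y$label)[tr$tip.label]
    grid <- seq(0, 1, length.out = 1001)
    ll <- vapply(grid, function(l) defarsenal:::lambda_profile_loglik(yv, C, l)$logLik, numeric(1))
    expect_gte(fit$logLik, max(ll) - 1e-9) # oracle dominance
    expect_lt(abs(fit$lambda - grid[which.max(ll)]), 1e-3 + 1e-9)

    # lambda = 0: independent normals with variance sigma2_hat * C_ii
    at0 <- defarsenal:::lambda_profile_loglik(yv, C, 0)
    closed <- sum(dnorm(yv,
      mean = at0$root,
      sd = sqrt(at0$sigma2 * diag(C)), log = TRUE
    ))
    expect_equal(at0$logLik, closed, tolerance = 1e-9)
    expect_gte(fit$logLik, fit$logLik0 - 1e-9)
  }
})

test_that("a star tree has a flat likelihood and returns lambda = 0", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  y <- tibble::tibble(label = star$tip.label, value = c(0.3, -1, 2, 0.1, 0.7))
  fit <- fit_lambda(y, star)
  expect_equal(fit$lambda, 0)
  expect_equal(fit$lr_stat, 0, tolerance = 1e-9)
  expect_equal(fit$p_value, 1)
})

test_that("the likelihood is equivariant under branch-length rescaling", {
  tr <- simulate_tree(12, seed = 41)
  y <- simulate_trait(tr, lambda = 0.7, sigma2 = 2, seed = 8)
  fit1 <- fit_lambda(y, tr)
  scaled <- tr
  scaled$edge.length <- tr$edge.length * 5
  fit2 <- fit_lambda(y, scaled)
  expect_equal(fit2$lambda, fit1$lambda, tolerance = 1e-5)
  expect_equal(fit2$sigma2, fit1$sigma2 / 5, tolerance = 1e-6)
  # max log-likelihoods agree once the Jacobian of the scaling is absorbed
  expect_equal(fit2$logLik, fit1$logLik, tolerance = 1e-6)
})

test_that("fit agrees with an independent phylogenetics implementation", {
  tr <- simulate_tree(32, seed = 15)
  y <- simulate_trait(tr, lambda = 0.8, sigma2 = 1, seed = 16)
  yv <- setNames(y$value, y$label)
  fit <- fit_lambda(yv, tr)
  ref <- phytools::phylosig(tr, yv, method = "lambda", test = TRUE)
  expect_equal(fit$lambda, ref$lambda, tolerance = 1e-4)
  expect_equal(fit$logLik, ref$logL, tolerance = 1e-6)
  expect_equal(fit$p_value, ref$P, tolerance = 1e-4)
})

test_that("constant traits and mismatched labels are rejected", {
  tr <- simulate_tree(8, seed = 3)
  const <- tibble::tibble(label = tr$tip.label, value = 1)
  expect_error(fit_lambda(const, tr), "constant")
  bad <- tibble::tibble(label = paste0("x", 1:8), value = rnorm(8))
  expect_error(fit_lambda(bad, tr), "labels")
})

test_that("the screen fits eligible types and reports skips with reasons", {
  spec <- cohort_spec(
    seed = 19, n_genomes_in = 24, n_genomes_out = 0,
    systems = list(
      system_spec("Everywhere", 1, 0, copies_model = "bernoulli"),
      system_spec("Half", 0.5, 0, copies_model = "bernoulli"),
      system_spec("Rare", 0.04, 0, copies_model = "bernoulli")
    )
  )
  co <- simulate_cohort(spec)
  tree <- simulate_tree(24, seed = 20, labels = sort(unique(co$metadata$genome_id)))
  pres <- presence_matrix(co$hits, co$metadata)
  pres$Everywhere <- 1 # force a constant trait
  res <- signal_screen(pres, tree)
  expect_equal(nrow(res), sum(names(pres) != "label"))
  expect_match(res$skipped[res$system_type == "Everywhere"], "constant")
  fitted <- res[is.na(res$skipped), ]
  expect_true(all(!is.na(fitted$lambda)))
  expect_true(all(fitted$lambda >= 0 & fitted$lambda <= 1))
  expect_true(all(fitted$logLik >= fitted$logLik0 - 1e-9))

  # frequency filter skips widespread types
  res2 <- signal_screen(pres, tree, max_frequency = 0.05)
  expect_match(
    res2$skipped[res2$system_type == "Half"][1], "max_frequency"
  )
})
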