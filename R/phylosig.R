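# Pagel's lambda phylogenetic signal, implemented from scratch under the
# Gaussian (Brownian-motion) comparative model. The tree induces a
# covariance C whose entries are shared root-to-MRCA path lengths; lambda
# scales the off-diagonal of C. The likelihood profiles the root state (GLS
# mean) and the Brownian rate analytically, leaving a bounded 1-D search in
# lambda; significance is a likelihood-ratio test against lambda = 0 on a
# chi-square(1) upper tail. Presence/absence traits are treated as
# continuous 0/1 values, mirroring the common practice of applying the
# continuous-trait statistic to binary data; see the methods vignette for
# the caveats this carries.

#' Brownian-motion covariance of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of leaves `i` and `j`;
#' the diagonal holds leaf depths. Symmetric positive semidefinite.
#'
#' @param tree an [ape::phylo] object with branch lengths >= 0.
#' @return numeric matrix with leaf labels as dimnames.
#' @export
tree_covariance <- function(tree) {
  validate_tree(tree)
  C <- ape::vcv(tree)
  if (max(diag(C)) <= 0) {
    abort("tree has zero depth; the Brownian covariance is degenerate.")
  }
  C
}

# Off-diagonal scaling without the positive-definiteness check (hot path).
lambda_scale <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal unchanged. Errors when the result is not positive definite
#' (lambda above the feasibility bound of the tree).
#'
#' @param C covariance matrix from [tree_covariance()].
#' @param lambda scaling factor >= 0.
#' @return transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (lambda < 0) {
    abort("`lambda` must be >= 0.")
  }
  Cl <- lambda_scale(C, lambda)
  ok <- tryCatch(
    {
      chol(Cl)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) {
    abort("C(lambda) is not positive definite; lambda exceeds the feasible bound.")
  }
  Cl
}

# Profile log-likelihood at a fixed lambda. Returns -Inf when C(lambda)
# fails the Cholesky (infeasible lambda), so optimize() can skirt the bound.
lambda_profile_loglik <- function(y, C, lambda) {
  n <- length(y)
  Cl <- lambda_scale(C, lambda)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) {
    return(list(logLik = -Inf, sigma2 = NA_real_, root = NA_real_))
  }
  logdet <- 2 * sum(log(diag(R)))
  u <- backsolve(R, y, transpose = TRUE)
  v <- backsolve(R, rep(1, n), transpose = TRUE)
  root <- sum(v * u) / sum(v * v)
  r <- u - root * v
  sigma2 <- sum(r^2) / n
  if (sigma2 <= 0) {
    return(list(logLik = -Inf, sigma2 = sigma2, root = root))
  }
  logLik <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(logLik = logLik, sigma2 = sigma2, root = root)
}

#' Maximum-likelihood fit of Pagel's lambda
#'
#' Maximizes the Gaussian log-likelihood of the trait on the
#' lambda-transformed tree covariance. The root state (GLS mean) and the
#' Brownian rate are profiled analytically; lambda is optimized by bounded
#' one-dimensional search (tolerance 1e-8), with the bounds themselves
#' evaluated as candidates. When the likelihood is flat in lambda (e.g. on
#' a star tree) the smallest candidate - lambda = 0 under the default
#' bounds - is returned. The p-value is the upper chi-square(1) tail of the
#' likelihood-ratio statistic against lambda = 0.
#'
#' @param trait tibble with columns `label`, `value` (or a named numeric
#'   vector); labels must match the tree's leaves and the trait must not be
#'   constant.
#' @param tree an [ape::phylo] object.
#' @param bounds search interval for lambda (default `c(0, 1)`).
#' @param tol optimizer tolerance (default 1e-8).
#' @return object of class `pagel_lambda` with elements `lambda`, `sigma2`,
#'   `root`, `logLik`, `logLik0`, `lr_stat`, `p_value`, `n_leaves`,
#'   `bounds`. Has [tidy()] and [glance()] methods.
#' @export
fit_lambda <- function(trait, tree, bounds = c(0, 1), tol = 1e-8) {
  validate_tree(tree)
  if (is.data.frame(trait)) {
    check_columns(trait, c("label", "value"), "trait")
    y <- setNames(trait$value, trait$label)
  } else {
    y <- trait
  }
  if (is.null(names(y)) || !setequal(names(y), tree$tip.label) ||
    length(y) != length(tree$tip.label)) {
    abort("trait labels must match the tree's leaves exactly.")
  }
  if (length(y) < 4L) {
    abort("need at least 4 leaves to fit lambda.")
  }
  y <- y[tree$tip.label]
  if (diff(range(y)) == 0) {
    abort("trait is constant; the signal is undefined (no variance).")
  }
  C <- tree_covariance(tree)

  obj <- function(lam) lambda_profile_loglik(y, C, lam)$logLik
  opt <- optimize(obj, interval = bounds, maximum = TRUE, tol = tol)
  cands <- sort(unique(c(bounds[1L], opt$maximum, bounds[2L])))
  ll <- vapply(cands, obj, numeric(1))
  best_ll <- max(ll)
  # Flat-likelihood tie-break: smallest lambda attaining the maximum.
  lambda_hat <- cands[which(ll >= best_ll - 1e-9)[1L]]
  at_hat <- lambda_profile_loglik(y, C, lambda_hat)
  at_zero <- lambda_profile_loglik(y, C, 0)
  lr <- max(0, 2 * (at_hat$logLik - at_zero$logLik))
  structure(
    list(
      lambda = lambda_hat,
      sigma2 = at_hat$sigma2,
      root = at_hat$root,
      logLik = at_hat$logLik,
      logLik0 = at_zero$logLik,
      lr_stat = lr,
      p_value = pchisq(lr, df = 1, lower.tail = FALSE),
      n_leaves = length(y),
      bounds = bounds
    ),
    class = "pagel_lambda"
  )
}

#' @export
print.pagel_lambda <- function(x, ...) {
  cat("Pagel's lambda (ML fit)\n")
  cat(sprintf("  lambda = %.6g  (bounds %g..%g)\n", x$lambda, x$bounds[1], x$bounds[2]))
  cat(sprintf("  sigma2 = %.6g,  root = %.6g\n", x$sigma2, x$root))
  cat(sprintf(
    "  logLik = %.6g,  logLik(lambda = 0) = %.6g\n",
    x$logLik, x$logLik0
  ))
  cat(sprintf(
    "  LR = %.6g,  p = %.4g  (chi-square, 1 df)  [n = %d leaves]\n",
    x$lr_stat, x$p_value, x$n_leaves
  ))
  invisible(x)
}

#' @rdname fit_lambda
#' @param x a `pagel_lambda` fit.
#' @param ... unused.
#' @export
tidy.pagel_lambda <- function(x, ...) {
  tibble(
    term = c("lambda", "sigma2", "root"),
    estimate = c(x$lambda, x$sigma2, x$root)
  )
}

#' @rdname fit_lambda
#' @export
glance.pagel_lambda <- function(x, ...) {
  tibble(
    lambda = x$lambda, sigma2 = x$sigma2, root = x$root,
    logLik = x$logLik, logLik0 = x$logLik0, lr_stat = x$lr_stat,
    p_value = x$p_value, n_leaves = x$n_leaves
  )
}

#' Presence/absence matrix of system types per genome
#'
#' @param hits long-format hit tibble.
#' @param metadata replicon metadata (supplies the full genome set,
#'   including genomes with no hits).
#' @return wide tibble: one row per genome (`label` column), one 0/1 column
#'   per system type.
#' @export
presence_matrix <- function(hits, metadata) {
  genomes <- genome_table(metadata)
  pres <- hits %>%
    distinct(genome_id, system_type) %>%
    mutate(present = 1)
  genomes %>%
    select(label = genome_id) %>%
    left_join(
      tidyr::pivot_wider(
        pres,
        id_cols = genome_id, names_from = system_type,
        values_from = present, values_fill = 0
      ),
      by = c("label" = "genome_id")
    ) %>%
    mutate(across(-label, ~ dplyr::coalesce(.x, 0)))
}

#' Phylogenetic-signal screen over system types
#'
#' Fits Pagel's lambda to the presence/absence trait of every system type
#' with at least two presences and two absences among the tree's leaves;
#' other types are reported as skipped with a reason. A `patchy` label
#' marks types whose distribution shows no phylogenetic signal at the
#' chosen p cutoff (closely related strains no more similar than random
#' ones).
#'
#' @param presence wide presence/absence tibble from [presence_matrix()]
#'   (`label` column plus one 0/1 column per type); labels must cover the
#'   tree's leaves.
#' @param tree an [ape::phylo] object.
#' @param p_cutoff significance cutoff on the LR p-value (default 0.05).
#' @param max_frequency optional frequency filter: only screen types
#'   present in at most this fraction of genomes (e.g. 0.05 to focus on
#'   rare systems).
#' @return tibble with one row per type: `system_type`, `n_present`,
#'   `frequency`, `lambda`, `sigma2`, `logLik`, `logLik0`, `p_value`,
#'   `signal`, `patchy`, `skipped` (reason or NA).
#' @export
signal_screen <- function(presence, tree, p_cutoff = 0.05, max_frequency = NULL) {
  check_columns(presence, "label", "presence matrix")
  validate_tree(tree)
  missing_leaves <- setdiff(tree$tip.label, presence$label)
  if (length(missing_leaves) > 0L) {
    abort(sprintf(
      "presence matrix lacks tree leaves: %s",
      paste(head(missing_leaves, 5L), collapse = ", ")
    ))
  }
  presence <- presence[match(tree$tip.label, presence$label), ]
  types <- setdiff(names(presence), "label")
  n <- length(tree$tip.label)
  rows <- purrr::map(types, function(ty) {
    y <- setNames(as.numeric(presence[[ty]]), presence$label)
    n1 <- sum(y == 1)
    n0 <- sum(y == 0)
    base <- tibble(
      system_type = ty, n_present = n1, frequency = n1 / n,
      lambda = NA_real_, sigma2 = NA_real_, logLik = NA_real_,
      logLik0 = NA_real_, p_value = NA_real_, signal = NA, patchy = NA,
      skipped = NA_character_
    )
    if (n1 < 2L || n0 < 2L) {
      base$skipped <- "fewer than 2 presences or 2 absences (trait ~ constant)"
      return(base)
    }
    if (!is.null(max_frequency) && n1 / n > max_frequency) {
      base$skipped <- sprintf("frequency above max_frequency = %g", max_frequency)
      return(base)
    }
    fit <- fit_lambda(y, tree)
    base$lambda <- fit$lambda
    base$sigma2 <- fit$sigma2
    base$logLik <- fit$logLik
    base$logLik0 <- fit$logLik0
    base$p_value <- fit$p_value
    base$signal <- fit$p_value <= p_cutoff
    base$patchy <- !base$signal
    base
  })
  bind_rows(rows)
}
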