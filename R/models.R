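#' Model specifications for incompatibility accumulation
#'
#' Constructs a specification for one of the four accumulation models fitted
#' by the package.  Substitutions are assumed to accrue as a Poisson process
#' at a constant rate along branches; a substitution contributes an observed
#' incompatibility against the recipient lineage with a small probability
#' proportional to its potential-interaction count, so per-branch counts of
#' participating mutations are independent Poisson.  Only rate-times-
#' probability composites are identifiable in this small-probability regime,
#' which fixes the parameter counts:
#'
#' * `linear` (k = 1, `rho`): expected count proportional to branch length —
#'   the null of no epistatic snowball.
#' * `DM` (k = 1, `c`): pairwise incompatibilities; a substitution at depth
#'   `u` carries weight `T + u` (derived partners across the recipient
#'   lineage of depth `T`, plus `u`-proportional exposure to
#'   derived-ancestral pairs with earlier same-lineage substitutions).
#' * `p2p3` (k = 2, `c2`, `c3`): the DM pairwise term plus a three-locus
#'   term weighted by the expected per-focal triple-interaction count.
#' * `paPd` (k = 2, `c_d`, `c_a`): pairwise, but derived-derived and
#'   derived-ancestral incompatibilities arise at different rates.
#'
#' @param name One of `"linear"`, `"DM"`, `"p2p3"`, `"paPd"`.
#' @param params Named nonnegative parameter vector; defaults to unit rates.
#' @return An object of class `model_spec` with fields `name`, `params`, `k`.
#' @examples
#' model_spec("DM", c(c = 2))
#' @export
model_spec <- function(name = c("linear", "DM", "p2p3", "paPd"),
                       params = NULL) {
  name <- match.arg(name)
  expected <- model_param_names(name)
  if (is.null(params)) params <- stats::setNames(rep(1, length(expected)),
                                                 expected)
  if (!setequal(names(params), expected)) {
    stop("model '", name, "' needs parameters ",
         paste(expected, collapse = ", "))
  }
  params <- params[expected]
  if (any(!is.finite(params)) || any(params < 0)) {
    stop("parameters must be finite and nonnegative")
  }
  structure(list(name = name, params = params, k = length(expected)),
            class = "model_spec")
}

model_param_names <- function(name) {
  switch(name,
         linear = "rho",
         DM = "c",
         p2p3 = c("c2", "c3"),
         paPd = c("c_d", "c_a"))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Accumulation model '", x$name, "' (k = ", x$k, "): ",
      paste(names(x$params), "=", signif(x$params, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Depth interval [u0, u1] spanned by each branch on the donor root-to-tip
# path of an ultrametric tree (depth measured from the root of the
# three-taxon tree; T = t_b + t_c).
branch_depth_intervals <- function(tree) {
  stopifnot(inherits(tree, "three_taxon_tree"))
  if (!tree$ultrametric) {
    stop("tree is not ultrametric; apply enforce_clock() first")
  }
  T <- tree$depth_T
  list(b = c(0, tree$t_b), c = c(tree$t_b, T), d = c(tree$t_b, T), T = T)
}

# Pairwise DM integral over a branch: int_u0^u1 (T + u) du
dm_integral <- function(T, u0, u1) T * (u1 - u0) + (u1^2 - u0^2) / 2

#' Expected per-branch counts of incompatibility-participating mutations
#'
#' Computes the model mean vector `(mu_b, mu_c, mu_d)` for an ultrametric
#' three-taxon tree in the small-probability regime.  Writing `T` for the
#' tree depth and `[u0, u1]` for the depth interval a branch spans on the
#' donor root-to-tip path:
#'
#' * linear: `mu = rho * t_x`;
#' * DM: `mu = c * (T * t_x + (u1^2 - u0^2) / 2)`;
#' * paPd: `mu = c_d * T * t_x + c_a * (u1^2 - u0^2) / 2`;
#' * p2p3: `c2 * (DM integral) + c3 * M3_x`, where `M3_x` is the seeded
#'   Monte-Carlo expectation (over unit-rate Poisson substitution histories)
#'   of per-focal three-locus interaction counts summed over focal
#'   substitutions on branch `x` (see [mc_interaction_means()]).
#'
#' @param model A [model_spec()].
#' @param tree An ultrametric [three_taxon_tree()].
#' @param config A [run_config()]; supplies `mc_reps` and the seed for the
#'   `p2p3` Monte-Carlo term.
#' @return Named numeric vector `c(mu_b, mu_c, mu_d)`.
#' @examples
#' tr <- three_taxon_tree(1.251, 0.502, 0.749, 0.749)
#' expected_counts(model_spec("DM", c(c = 1)), tr)
#' @export
expected_counts <- function(model, tree, config = run_config()) {
  stopifnot(inherits(model, "model_spec"))
  iv <- branch_depth_intervals(tree)
  T <- iv$T
  p <- model$params
  lens <- c(b = tree$t_b, c = tree$t_c, d = tree$t_d)
  pair_term <- vapply(c("b", "c", "d"), function(x) {
    dm_integral(T, iv[[x]][1], iv[[x]][2])
  }, numeric(1))
  da_term <- vapply(c("b", "c", "d"), function(x) {
    (iv[[x]][2]^2 - iv[[x]][1]^2) / 2
  }, numeric(1))
  mu <- switch(model$name,
    linear = p[["rho"]] * lens,
    DM = p[["c"]] * pair_term,
    paPd = p[["c_d"]] * T * lens + p[["c_a"]] * da_term,
    p2p3 = {
      m3 <- mc_triple_means(tree, config)
      p[["c2"]] * pair_term + p[["c3"]] * m3
    })
  stats::setNames(as.numeric(mu), c("mu_b", "mu_c", "mu_d"))
}

#' Monte-Carlo expected interaction weights per branch
#'
#' Simulates unit-rate Poisson substitution histories on the donor
#' root-to-tip path (depth `T`) and, independently, the recipient path
#' (also depth `T`), and estimates the expectation of per-focal potential
#' interaction counts summed over focal substitutions falling on the
#' internal (`b`) versus terminal depth interval.  Returns both the pairwise
#' sums (derived-derived plus derived-ancestral; the Monte-Carlo counterpart
#' of the DM closed-form integral) and the three-locus sums used by the
#' `p2p3` model mean.  Seeded and cached per (tree, reps, seed), so repeated
#' model evaluations during optimization reuse one draw.
#'
#' @param tree Ultrametric [three_taxon_tree()].
#' @param config A [run_config()] (uses `mc_reps` and `seed`).
#' @return A list with numeric vectors `pair` and `triple`, each of length 3
#'   (branches `b`, `c`, `d`; the two terminal entries are equal by the
#'   clock assumption).
#' @export
mc_interaction_means <- function(tree, config = run_config()) {
  iv <- branch_depth_intervals(tree)
  T <- iv$T
  t_b <- tree$t_b
  reps <- config$mc_reps
  withr::with_seed(config$seed, {
    K <- stats::rpois(reps, T)        # donor-path substitution counts
    K_sl <- stats::rpois(reps, T)     # recipient-path substitution counts
    total <- sum(K)
    rep_id <- rep.int(seq_len(reps), K)
    u <- stats::runif(total, 0, T)
    # temporal order index i within each history
    ord <- order(rep_id, u)
    u <- u[ord]
    i <- sequence(K[K > 0])
    Kr <- rep.int(K[K > 0], K[K > 0])
    Kslr <- rep.int(K_sl[K > 0], K[K > 0])
    # per-focal pairwise weight: K_other derived partners + (i - 1)
    # derived-ancestral partners
    g <- Kslr + (i - 1)
    # per-focal three-locus weight: sum over same-lineage partners j != i of
    # ddd (= K_other) and dda (= min(i, j) - 1) counts
    f <- (Kr - 1) * Kslr + (i - 1) * (2 * Kr - i - 2) / 2
    # the simulated donor path covers branch b plus ONE terminal branch;
    # by the clock assumption the other terminal has the same expectation
    early <- u <= t_b
    pair_b <- sum(g[early]) / reps
    pair_t <- sum(g[!early]) / reps
    trip_b <- sum(f[early]) / reps
    trip_t <- sum(f[!early]) / reps
    list(pair = c(b = pair_b, c = pair_t, d = pair_t),
         triple = c(b = trip_b, c = trip_t, d = trip_t))
  })
}

# cache MC triple means per (tree geometry, reps, seed)
.mc_cache <- new.env(parent = emptyenv())

mc_triple_means <- function(tree, config) {
  key <- paste(c(signif(c(tree$t_b, tree$depth_T), 12), config$mc_reps,
                 config$seed), collapse = "|")
  hit <- .mc_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- mc_interaction_means(tree, config)$triple
  .mc_cache[[key]] <- val
  val
}

#' Poisson log-likelihood of branch counts under a model
#'
#' Independent-Poisson log-likelihood of observed per-branch mutation counts
#' `(n_b, n_c, n_d)` given the model's expected counts:
#' `sum_x n_x log(mu_x) - mu_x - log(n_x!)`.  A zero mean with a positive
#' observed count yields `-Inf` (with a warning); the `0 * log(0)` limit for
#' empty branches is 0.
#'
#' @param model A [model_spec()].
#' @param counts One-row `branch_counts` (or anything with `n_b`, `n_c`,
#'   `n_d`).
#' @param tree Ultrametric [three_taxon_tree()].
#' @param config A [run_config()].
#' @return Log-likelihood (scalar).
#' @export
loglik <- function(model, counts, tree, config = run_config()) {
  mu <- expected_counts(model, tree, config)
  n <- as.numeric(c(counts$n_b[1], counts$n_c[1], counts$n_d[1]))
  poisson_ll(n, mu)
}

poisson_ll <- function(n, mu) {
  if (any(mu == 0 & n > 0)) {
    warning("expected count of 0 with observed count > 0; returning -Inf")
    return(-Inf)
  }
  terms <- ifelse(n == 0 & mu == 0, 0, stats::dpois(n, mu, log = TRUE))
  sum(terms)
}

# total-Poisson x multinomial decomposition of the same likelihood (equal to
# poisson_ll by the Poisson splitting identity); kept as a numerical
# cross-check
loglik_total_multinomial <- function(n, mu) {
  N <- sum(n)
  if (sum(mu) == 0) return(if (N == 0) 0 else -Inf)
  stats::dpois(N, sum(mu), log = TRUE) +
    stats::dmultinom(n, N, prob = mu / sum(mu), log = TRUE)
}

#' Per-pair-totals likelihood with shared-branch covariance
#'
#' Alternative data reduction: the observable in each cross is the pair
#' total (`n_b + n_c` for the SH pair, `n_b + n_d` for the SP pair); the two
#' totals are correlated through the shared internal branch.  Under the
#' per-branch Poisson model the pair totals follow a common-shock bivariate
#' Poisson whose likelihood marginalizes over the unobserved shared split:
#' `L(X1, X2) = sum_k L_branch(k, X1 - k, X2 - k)`.
#'
#' @param model,tree,config As in [loglik()].
#' @param pair_totals Length-2 vector `c(n_b + n_c, n_b + n_d)`.
#' @return Log-likelihood of the pair totals.
#' @export
loglik_pair_totals <- function(model, pair_totals, tree,
                               config = run_config()) {
  mu <- expected_counts(model, tree, config)
  x1 <- pair_totals[1]; x2 <- pair_totals[2]
  ks <- 0:min(x1, x2)
  lls <- vapply(ks, function(k) {
    poisson_ll(c(k, x1 - k, x2 - k), mu)
  }, numeric(1))
  m <- max(lls)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lls - m)))
}

#' Fit one accumulation model over a tree set
#'
#' Maximizes the per-branch Poisson log-likelihood over the model's
#' nonnegative parameters for each tree in the set (bounded quasi-Newton on
#' log-parameters with seeded random multistarts), then averages the AIC
#' (`2k - 2 logLik`) across trees.  Fitted parameters are reported from the
#' tree with the median AIC.
#'
#' @param name Model name (see [model_spec()]).
#' @param counts One-row `branch_counts`.
#' @param trees A [tree_set()] or single [three_taxon_tree()].
#' @param config A [run_config()]; `config$seed` seeds the multistarts and
#'   any Monte-Carlo model terms.
#' @param n_starts Number of random multistarts per tree.
#' @return An object of class `model_fit`: list with `model` (fitted
#'   [model_spec()]), `loglik`, `aic` (mean over trees), `aic_sd`,
#'   `n_trees`, `per_tree` (data frame of per-tree results).
#' @export
fit_model <- function(name, counts, trees, config = run_config(),
                      n_starts = 5) {
  if (inherits(trees, "three_taxon_tree")) trees <- tree_set(trees)
  stopifnot(inherits(trees, "tree_set"))
  pnames <- model_param_names(name)
  k <- length(pnames)
  n <- c(counts$n_b[1], counts$n_c[1], counts$n_d[1])
  N <- sum(n)
  fits <- vector("list", length(trees$trees))
  for (ti in seq_along(trees$trees)) {
    tree <- trees$trees[[ti]]
    obj <- function(logp) {
      spec <- model_spec(name, stats::setNames(exp(logp), pnames))
      -poisson_ll(n, expected_counts(spec, tree, config))
    }
    # scale-matched starting point: total rate such that sum(mu) ~ N
    base <- model_spec(name)
    mu1 <- expected_counts(base, tree, config)
    s0 <- log(max(N, 0.5) / sum(mu1))
    starts <- list(rep(s0, k))
    jitters <- withr::with_seed(config$seed + ti, {
      lapply(seq_len(max(0, n_starts - 1)),
             function(s) s0 + stats::rnorm(k, 0, 1.5))
    })
    starts <- c(starts, jitters)
    best <- NULL
    for (st in starts) {
      res <- tryCatch(
        stats::optim(st, obj, method = "L-BFGS-B",
                     lower = rep(-30, k), upper = rep(30, k),
                     control = list(factr = 10)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value - 1e-12) best <- res
    }
    if (is.null(best)) {
      warning("optimizer failed on tree ", ti, "; tree skipped")
      next
    }
    fits[[ti]] <- list(par = stats::setNames(exp(best$par), pnames),
                       loglik = -best$value)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("model '", name, "' could not be fitted on any tree")
  lls <- vapply(fits[ok], `[[`, numeric(1), "loglik")
  aics <- 2 * k - 2 * lls
  med_idx <- which(ok)[which.min(abs(aics - stats::median(aics)))]
  per_tree <- data.frame(tree = which(ok), loglik = lls, aic = aics)
  structure(list(model = model_spec(name, fits[[med_idx]]$par),
                 loglik = fits[[med_idx]]$loglik,
                 aic = mean(aics),
                 aic_sd = if (length(aics) > 1) stats::sd(aics) else 0,
                 n_trees = sum(ok),
                 per_tree = per_tree),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Fit of '%s': mean AIC = %.3f (SD %.3f over %d tree%s)\n",
              x$model$name, x$aic, x$aic_sd, x$n_trees,
              if (x$n_trees == 1) "" else "s"))
  cat("  params: ", paste(names(x$model$params), "=",
                          signif(x$model$params, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fit and compare the four accumulation models
#'
#' Fits all four models ([fit_model()]) and selects the one with the
#' smallest mean AIC; ties (within `tol`) go to the model with fewer
#' parameters, then to the fixed order linear, DM, p2p3, paPd.
#'
#' @inheritParams fit_model
#' @param models Candidate model names to fit and compare (default all
#'   four).
#' @param tol AIC tie tolerance.
#' @return A list of class `model_comparison`: `table` (one row per model:
#'   `model`, `k`, `loglik`, `aic`, `aic_sd`, `n_trees`), `fits` (named list
#'   of `model_fit`), `selected` (model name).
#' @examples
#' tr <- three_taxon_tree(1.251, 0.502, 0.749, 0.749)
#' cmp <- compare_models(make_branch_counts(1, 7, 6, "pollen"), tr,
#'                       config = run_config(seed = 1, mc_reps = 5000))
#' cmp$selected
#' @export
compare_models <- function(counts, trees, config = run_config(),
                           models = c("linear", "DM", "p2p3", "paPd"),
                           n_starts = 5, tol = 1e-6) {
  order_names <- intersect(c("linear", "DM", "p2p3", "paPd"), models)
  stopifnot(length(order_names) >= 2)
  fits <- lapply(order_names, fit_model, counts = counts, trees = trees,
                 config = config, n_starts = n_starts)
  names(fits) <- order_names
  tab <- data.frame(
    model = order_names,
    k = vapply(fits, function(f) f$model$k, numeric(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    aic_sd = vapply(fits, `[[`, numeric(1), "aic_sd"),
    n_trees = vapply(fits, `[[`, numeric(1), "n_trees"),
    row.names = NULL)
  best_aic <- min(tab$aic)
  cand <- tab[tab$aic <= best_aic + tol, ]
  cand <- cand[order(cand$k, match(cand$model, order_names)), ]
  structure(list(table = tab, fits = fits, selected = cand$model[1]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Incompatibility accumulation model comparison\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Selected (min mean AIC): ", x$selected, "\n", sep = "")
  invisible(x)
}
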