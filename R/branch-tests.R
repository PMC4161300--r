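#' Null early/late proportions from branch lengths
#'
#' Under the null that isolation-causing mutations fall on branches in
#' linear proportion to branch length, the expected probability of an
#' "early" mutation is `t_b / (t_b + t_c + t_d)`.  Scale-invariant in the
#' tree's time units.
#'
#' @param tree A [three_taxon_tree()].
#' @return A list with `p_early` and `p_late` (`= 1 - p_early`).
#' @examples
#' branch_proportions(three_taxon_tree(1.251, 0.502, 0.749, 0.749))
#' @export
branch_proportions <- function(tree) {
  tot <- tree$t_b + tree$t_c + tree$t_d
  if (tot <= 0) stop("t_b + t_c + t_d must be positive")
  p_early <- tree$t_b / tot
  list(p_early = p_early, p_late = 1 - p_early)
}

#' Chi-square goodness of fit of early/late mutation counts
#'
#' Pearson chi-square test of observed early/late counts against the
#' expectation `(N * p_early, N * p_late)`, with 1 degree of freedom.
#'
#' @param n_early,n_late Observed mutation counts.
#' @param props A list with `p_early`, `p_late` (see
#'   [branch_proportions()]).
#' @return A list with `chi2`, `p_value`, `df = 1`, `expected`.
#' @examples
#' chisq_gof(1, 13, list(p_early = 0.251, p_late = 0.749))
#' @export
chisq_gof <- function(n_early, n_late, props) {
  N <- n_early + n_late
  stopifnot(N >= 1)
  expected <- N * c(props$p_early, props$p_late)
  if (any(expected < 5)) {
    warning("expected count below 5; chi-square approximation is rough")
  }
  chi2 <- sum((c(n_early, n_late) - expected)^2 / expected)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, expected = expected)
}

#' Binomial resampling of the number of late mutations
#'
#' Re-draws the observed total number of mutations as
#' `Binomial(n, p_late)` trials `iters` times (seeded) and reports the
#' fraction of draws in which at least `threshold` mutations land on late
#' branches, alongside the exact binomial tail probability
#' `P(X >= threshold)` as an internal oracle.
#'
#' @param n Total number of observed mutations (trials per draw).
#' @param p_late Probability a mutation falls on a late branch.
#' @param threshold Count whose upper tail is evaluated (`0 <= threshold <=
#'   n`).
#' @param iters Number of simulated draws.
#' @param seed Integer RNG seed.
#' @return A list with `fraction` (simulated), `exact_tail`, `iters`.
#' @examples
#' binomial_tail_sim(14, 0.749, 13, iters = 1000, seed = 1)
#' @export
binomial_tail_sim <- function(n, p_late, threshold, iters = 1000, seed = 1) {
  stopifnot(threshold >= 0, threshold <= n, iters >= 1,
            p_late >= 0, p_late <= 1)
  draws <- withr::with_seed(seed, stats::rbinom(iters, n, p_late))
  list(fraction = mean(draws >= threshold),
       exact_tail = stats::pbinom(threshold - 1, n, p_late,
                                  lower.tail = FALSE),
       iters = as.integer(iters))
}

#' Bootstrap confidence interval for late-mutation effect sizes
#'
#' Resamples the late-arising mutations' effect sizes with replacement
#' (`n_boot` resamples, same size as the input) and returns the percentile
#' 95% confidence interval of the resample mean.  Comparisons operate on
#' effect-size magnitudes `|delta %|`, since effects are reported as
#' magnitudes of fertility reduction; inputs may be signed.
#'
#' @param late_effects Numeric vector (length >= 2) of late-mutation effect
#'   sizes (signed `delta %` or magnitudes).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer RNG seed.
#' @param statistic `"mean"` (default) resamples the mean; `"values"`
#'   resamples individual values (the CI then describes the value
#'   distribution itself).
#' @return A list with `ci_low`, `ci_high`, `boot_stats`, `n_boot`.
#' @export
bootstrap_effect_ci <- function(late_effects, n_boot = 500, seed = 1,
                                statistic = c("mean", "values")) {
  statistic <- match.arg(statistic)
  if (length(late_effects) < 2) stop("need at least 2 late effect sizes")
  x <- abs(late_effects)
  stats_v <- withr::with_seed(seed, {
    if (statistic == "mean") {
      vapply(seq_len(n_boot),
             function(i) mean(sample(x, length(x), replace = TRUE)),
             numeric(1))
    } else {
      sample(x, n_boot, replace = TRUE)
    }
  })
  ci <- stats::quantile(stats_v, c(0.025, 0.975), names = FALSE)
  list(ci_low = ci[1], ci_high = ci[2], boot_stats = stats_v,
       n_boot = as.integer(n_boot))
}

#' Compare the early-mutation effect size with the late bootstrap interval
#'
#' @param early_value Effect size of the early-arising mutation (signed
#'   `delta %` or magnitude; compared on magnitude).
#' @param late_effects Late-mutation effect sizes, as in
#'   [bootstrap_effect_ci()].
#' @param config A [run_config()] supplying `n_boot` and `seed`.
#' @param statistic Passed to [bootstrap_effect_ci()].
#' @return A list of class `effect_size_comparison`: `early_value`
#'   (magnitude), `boot_ci_low`, `boot_ci_high`, `n_boot`, `outside_ci`
#'   (strictly outside; the boundary counts as inside).
#' @examples
#' compare_early_late(-47, c(-81, -62.5, -70, -55, -85, -70, -66))
#' @export
compare_early_late <- function(early_value, late_effects,
                               config = run_config(),
                               statistic = c("mean", "values")) {
  ci <- bootstrap_effect_ci(late_effects, n_boot = config$n_boot,
                            seed = config$seed,
                            statistic = match.arg(statistic))
  ev <- abs(early_value)
  structure(list(early_value = ev,
                 boot_ci_low = ci$ci_low, boot_ci_high = ci$ci_high,
                 n_boot = ci$n_boot,
                 outside_ci = ev < ci$ci_low || ev > ci$ci_high),
            class = "effect_size_comparison")
}

#' @export
print.effect_size_comparison <- function(x, ...) {
  cat(sprintf(
    "Early effect magnitude %.3g vs late bootstrap 95%% CI [%.3g, %.3g]: %s\n",
    x$early_value, x$boot_ci_low, x$boot_ci_high,
    if (x$outside_ci) "outside" else "inside"))
  invisible(x)
}
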