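test_that("expected counts: zero rates, linear proportions, clock guard", {
  tr <- study_tree()
  for (nm in c("linear", "DM", "p2p3", "paPd")) {
    pn <- names(model_spec(nm)$params)
    zero <- model_spec(nm, stats::setNames(rep(0, length(pn)), pn))
    expect_equal(unname(expected_counts(zero, tr,
                                        run_config(mc_reps = 200))),
                 c(0, 0, 0))
  }
  mu <- expected_counts(model_spec("linear", c(rho = 1)), tr)
  expect_equal(unname(mu / sum(mu)), c(0.251, 0.3745, 0.3745))

  skewed <- three_taxon_tree(1, 0.4, 0.5, 0.7)
  expect_error(expected_counts(model_spec("DM"), skewed), "ultrametric")
})

test_that("DM closed form agrees with the Monte-Carlo estimator", {
  tr <- study_tree()
  mc <- mc_interaction_means(tr, run_config(seed = 5, mc_reps = 20000))
  closed <- expected_counts(model_spec("DM", c(c = 1)), tr)
  expect_lt(max(abs(mc$pair - closed) / closed), 0.02)
})

test_that("model means are monotone in parameters and branch lengths", {
  cfg <- run_config(seed = 2, mc_reps = 2000)
  set.seed(42)
  for (rep in 1:20) {
    t_b <- runif(1, 0.1, 1)
    t_c <- runif(1, 0.1, 1)
    tr <- three_taxon_tree(t_b + t_c, t_b, t_c, t_c)
    tr_big <- three_taxon_tree(1.25 * (t_b + t_c), 1.25 * t_b, 1.25 * t_c,
                               1.25 * t_c)
    for (nm in c("linear", "DM", "p2p3", "paPd")) {
      pn <- names(model_spec(nm)$params)
      p1 <- stats::setNames(runif(length(pn), 0.5, 2), pn)
      p2 <- p1 * (1 + runif(length(pn), 0, 1))
      m1 <- expected_counts(model_spec(nm, p1), tr, cfg)
      m2 <- expected_counts(model_spec(nm, p2), tr, cfg)
      expect_true(all(m2 >= m1))
      m3 <- expected_counts(model_spec(nm, p1), tr_big, cfg)
      expect_true(all(m3 >= m1))
    }
  }
})

test_that("DM accumulation snowballs and shifts mass to late branches", {
  # superlinearity in depth: doubling T more than doubles the total
  tr1 <- study_tree()
  tr2 <- three_taxon_tree(2 * 1.251, 2 * 0.502, 2 * 0.749, 2 * 0.749)
  m1 <- sum(expected_counts(model_spec("DM", c(c = 1)), tr1))
  m2 <- sum(expected_counts(model_spec("DM", c(c = 1)), tr2))
  expect_gt(m2, 2 * m1)

  # early fraction under DM < linear for any tree with t_b > 0
  set.seed(7)
  for (rep in 1:10) {
    t_b <- runif(1, 0.05, 1); t_c <- runif(1, 0.05, 1)
    tr <- three_taxon_tree(t_b + t_c, t_b, t_c, t_c)
    mu_dm <- expected_counts(model_spec("DM", c(c = 1)), tr)
    mu_lin <- expected_counts(model_spec("linear", c(rho = 1)), tr)
    expect_lt(mu_dm[1] / sum(mu_dm), mu_lin[1] / sum(mu_lin))
  }
})

test_that("log-likelihood: conventions, decomposition, concavity", {
  tr <- study_tree()
  cnt0 <- make_branch_counts(0, 0, 0)
  zero <- model_spec("linear", c(rho = 0))
  expect_equal(loglik(zero, cnt0, tr), 0)
  expect_warning(
    ll <- loglik(zero, pollen_counts(), tr), "-Inf")
  expect_equal(ll, -Inf)

  # equals the total-Poisson x multinomial decomposition at the linear MLE
  n <- c(1, 7, 6)
  rho_hat <- sum(n) / (tr$t_b + tr$t_c + tr$t_d)
  mod <- model_spec("linear", c(rho = rho_hat))
  ll1 <- loglik(mod, pollen_counts(), tr)
  mu <- expected_counts(mod, tr)
  ll2 <- stats::dpois(sum(n), sum(mu), log = TRUE) +
    stats::dmultinom(n, sum(n), prob = mu / sum(mu), log = TRUE)
  expect_equal(ll1, ll2)

  # perturbing any mu away from n decreases the Poisson log-likelihood
  base <- sum(stats::dpois(n, n, log = TRUE))
  for (i in 1:3) for (f in c(0.7, 1.4)) {
    mu_p <- n; mu_p[i] <- n[i] * f
    expect_lt(sum(stats::dpois(n, mu_p, log = TRUE)), base)
  }
})

test_that("pair-totals likelihood marginalizes the per-branch form", {
  tr <- study_tree()
  mod <- model_spec("DM", c(c = 2))
  x1 <- 5; x2 <- 4
  target <- loglik_pair_totals(mod, c(x1, x2), tr)
  mu <- expected_counts(mod, tr)
  lls <- vapply(0:min(x1, x2), function(k) {
    sum(stats::dpois(c(k, x1 - k, x2 - k), mu, log = TRUE))
  }, numeric(1))
  expect_equal(target, log(sum(exp(lls))))
  # per-branch data are strictly more informative than the pair totals
  expect_lt(loglik(mod, make_branch_counts(2, 3, 2), tr), target)
})

test_that("fit_model recovers parameters and reports AIC invariants", {
  tr <- study_tree()
  truth <- calibrate_params("linear", tr, 1500)
  cnt <- simulate_counts(truth, tr, seed = 31)
  fit <- fit_model("linear", cnt, tr, run_config(seed = 1))
  expect_lt(abs(fit$model$params[["rho"]] - truth$params[["rho"]]) /
              truth$params[["rho"]], 0.05)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  expect_equal(fit$aic_sd, 0)  # single tree
  expect_equal(fit$n_trees, 1)
})

test_that("nested models dominate DM in log-likelihood at the MLE", {
  tr <- study_tree()
  cfg <- run_config(seed = 4, mc_reps = 5000)
  for (cnt in list(pollen_counts(), seed_counts(),
                   make_branch_counts(3, 2, 9))) {
    ll_dm <- fit_model("DM", cnt, tr, cfg)$loglik
    expect_gte(fit_model("p2p3", cnt, tr, cfg)$loglik, ll_dm - 1e-6)
    expect_gte(fit_model("paPd", cnt, tr, cfg)$loglik, ll_dm - 1e-6)
  }
})

test_that("model comparison selects consistently at scale and never picks
           linear on the observed pollen counts", {
  tr <- study_tree()
  cfg <- run_config(seed = 6, mc_reps = 5000)
  cnt_lin <- simulate_counts(calibrate_params("linear", tr, 2000), tr,
                             seed = 8)
  expect_equal(compare_models(cnt_lin, tr, cfg)$selected, "linear")

  cnt_dm <- simulate_counts(calibrate_params("DM", tr, 2000, config = cfg),
                            tr, seed = 9, config = cfg)
  expect_false(compare_models(cnt_dm, tr, cfg)$selected == "linear")

  cmp <- compare_models(pollen_counts(), tr, cfg)
  aic_lin <- cmp$table$aic[cmp$table$model == "linear"]
  expect_gt(aic_lin, min(cmp$table$aic[cmp$table$model != "linear"]))
})

test_that("fits averaged over a tree set report spread, and models
           carry their parameter count", {
  base <- study_tree()
  ts <- gen_tree_set(base, cv = 0.15, n = 8, seed = 12)
  fit <- fit_model("DM", pollen_counts(), ts, run_config(seed = 3))
  expect_equal(fit$n_trees, 8)
  expect_gt(fit$aic_sd, 0)
  expect_equal(model_spec("p2p3")$k, 2)
  expect_equal(model_spec("linear")$k, 1)
  expect_error(model_spec("DM", c(rho = 1)), "needs parameters")
  expect_error(model_spec("DM", c(c = -1)), "nonnegative")
})
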