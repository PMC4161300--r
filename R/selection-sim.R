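#' Simulate branch counts under an accumulation model
#'
#' Draws independent Poisson per-branch counts with means from
#' [expected_counts()].
#'
#' @param model A [model_spec()].
#' @param tree Ultrametric [three_taxon_tree()].
#' @param seed Integer RNG seed.
#' @param config A [run_config()] (Monte-Carlo settings for `p2p3` means).
#' @param trait Trait label attached to the counts.
#' @return A one-row `branch_counts`.
#' @export
simulate_counts <- function(model, tree, seed = 1, config = run_config(),
                            trait = "simulated") {
  mu <- expected_counts(model, tree, config)
  n <- withr::with_seed(seed, stats::rpois(3, mu))
  make_branch_counts(n[1], n[2], n[3], trait)
}

#' Calibrate a model's rate so the expected total matches a target
#'
#' Rescales the overall rate composite so that `mu_b + mu_c + mu_d`
#' equals `target_total` on the given tree.  All model means here are linear
#' in the overall rate, so the calibration is a closed-form rescaling; for
#' two-parameter models the shape ratio (`c3/c2` or `c_a/c_d`) must be
#' supplied and is preserved.
#'
#' @param name Model name.
#' @param tree Ultrametric [three_taxon_tree()].
#' @param target_total Desired expected total count (> 0).
#' @param shape_ratio Ratio `c3/c2` (`p2p3`) or `c_a/c_d` (`paPd`); ignored
#'   for one-parameter models.
#' @param config A [run_config()].
#' @return A calibrated [model_spec()].
#' @examples
#' tr <- three_taxon_tree(1.251, 0.502, 0.749, 0.749)
#' calibrate_params("linear", tr, 14)$params  # rho = 14 / 2
#' @export
calibrate_params <- function(name, tree, target_total, shape_ratio = 1,
                             config = run_config()) {
  if (!is.finite(target_total) || target_total <= 0) {
    stop("target_total must be positive")
  }
  pnames <- model_param_names(name)
  base_params <- if (length(pnames) == 1) {
    stats::setNames(1, pnames)
  } else {
    stats::setNames(c(1, shape_ratio), pnames)
  }
  base <- model_spec(name, base_params)
  tot <- sum(expected_counts(base, tree, config))
  if (tot <= 0) stop("target unattainable: model mean is zero on this tree")
  model_spec(name, base$params * target_total / tot)
}

#' Simulation study of AIC-based model selection
#'
#' For each ground-truth model, repeatedly (i) draws a tree uniformly with
#' replacement from the tree set, (ii) calibrates the truth so its expected
#' total matches `target_total`, (iii) simulates per-branch counts,
#' (iv) runs [compare_models()] and tallies the selected model.  Reports the
#' confusion matrix (truth by selected) and, per truth model, precision
#' (`TP / (TP + FP)`) and recall (`TP / (TP + FN)`) of selecting it.
#'
#' @param truth_models Character vector of ground-truth model names.
#' @param trees A [tree_set()] or single tree.
#' @param n_sims Simulations per truth model.
#' @param target_total Expected total count for calibration (e.g. 14 for a
#'   pollen-scale or 8 for a seed-scale experiment).
#' @param shape_ratios Named list/vector of shape ratios for two-parameter
#'   truth models (default 1).
#' @param config A [run_config()]; `config$seed` makes the whole experiment
#'   reproducible.
#' @param candidate_models Models offered to the AIC selection (default all
#'   four; restricting to the truth set turns the study into a head-to-head
#'   discrimination experiment).
#' @param n_starts Multistarts per model fit.
#' @return A list of class `confusion_summary`: `confusion` (matrix), and a
#'   data frame `summary` with `model`, `precision`, `recall`, `n_sims`;
#'   plus `n_failed` fits.
#' @export
selection_experiment <- function(truth_models, trees, n_sims = 100,
                                 target_total = 14, shape_ratios = NULL,
                                 config = run_config(),
                                 candidate_models = c("linear", "DM",
                                                      "p2p3", "paPd"),
                                 n_starts = 3) {
  if (inherits(trees, "three_taxon_tree")) trees <- tree_set(trees)
  stopifnot(n_sims >= 1)
  all_models <- intersect(c("linear", "DM", "p2p3", "paPd"),
                          candidate_models)
  stopifnot(all(truth_models %in% all_models))
  confusion <- matrix(0L, length(truth_models), length(all_models),
                      dimnames = list(truth = truth_models,
                                      selected = all_models))
  n_failed <- 0L
  sim_id <- 0L
  for (truth in truth_models) {
    ratio <- 1
    if (!is.null(shape_ratios) && !is.null(shape_ratios[[truth]])) {
      ratio <- shape_ratios[[truth]]
    }
    for (s in seq_len(n_sims)) {
      sim_id <- sim_id + 1L
      sim_seed <- (config$seed + 7919L * sim_id) %% .Machine$integer.max
      tree_idx <- withr::with_seed(sim_seed,
                                   sample.int(length(trees$trees), 1))
      tree <- trees$trees[[tree_idx]]
      spec <- calibrate_params(truth, tree, target_total, ratio, config)
      counts <- simulate_counts(spec, tree, seed = sim_seed + 1L,
                                config = config)
      sel <- tryCatch(
        compare_models(counts, tree, config = config, models = all_models,
                       n_starts = n_starts)$selected,
        error = function(e) NA_character_)
      if (is.na(sel)) {
        n_failed <- n_failed + 1L
      } else {
        confusion[truth, sel] <- confusion[truth, sel] + 1L
      }
    }
  }
  summary_df <- data.frame(model = truth_models,
                           precision = NA_real_, recall = NA_real_,
                           n_sims = n_sims)
  for (m in truth_models) {
    tp <- confusion[m, m]
    fp <- sum(confusion[setdiff(truth_models, m), m])
    fn <- sum(confusion[m, setdiff(all_models, m)])
    i <- match(m, summary_df$model)
    summary_df$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    summary_df$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  }
  structure(list(confusion = confusion, summary = summary_df,
                 n_failed = n_failed),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Model-selection simulation study\n")
  print(x$confusion)
  print(x$summary, row.names = FALSE, digits = 3)
  if (x$n_failed > 0) cat(x$n_failed, "simulations had failed fits\n")
  invisible(x)
}
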