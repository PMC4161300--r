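#' Fertility-test scenarios
#'
#' Defines the generating conditions for a synthetic cross-species allelism
#' test: true class means, residual and maternal-family standard deviations,
#' plants per class and families per class.  The named presets encode the
#' least-squares means observed at the three study loci (seeds/fruit for the
#' seed loci, proportion fertile pollen for the pollen locus), with
#' residual noise at a realistic bench scale and small maternal variance
#' (maternal effects were uniformly non-significant in the source
#' experiments).
#'
#' @param preset One of `"sss1.2"`, `"sss2.1"`, `"pf7.2"`, or `"custom"`.
#' @param genotype_means Named vector of true class means (for `"custom"`).
#' @param sd Residual standard deviation.
#' @param maternal_sd Between-family standard deviation.
#' @param n_per_class Plants per genotype class (>= families_per_class).
#' @param families_per_class Maternal families per class.
#' @param trait `"pollen"` or `"seed"`.
#' @return A list of class `fertility_scenario`.
#' @examples
#' fertility_scenario("sss2.1")
#' @export
fertility_scenario <- function(preset = c("custom", "sss1.2", "sss2.1",
                                          "pf7.2"),
                               genotype_means = NULL, sd = NULL,
                               maternal_sd = NULL, n_per_class = 25,
                               families_per_class = 5, trait = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    sss1.2 = list(means = c(SL = 60.83, IL_PP = 10.41, IL_HH = 38.13,
                            IL_HP = 26.66),
                  sd = 8, trait = "seed"),
    sss2.1 = list(means = c(SL = 60.83, IL_PP = 11.08, IL_HH = 64.89,
                            IL_HP = 67.93),
                  sd = 8, trait = "seed"),
    pf7.2 = list(means = c(SL = 0.90, IL_PP = 0.81, IL_HH = 0.76,
                           IL_HP = 0.77, IL_PH = 0.78),
                 sd = 0.05, trait = "pollen"),
    custom = list(means = NULL, sd = NULL, trait = "seed"))
  means <- if (is.null(genotype_means)) defaults$means else genotype_means
  if (is.null(means)) stop("custom scenarios need genotype_means")
  if (is.null(names(means)) || !all(names(means) %in% GENOTYPE_LEVELS)) {
    stop("genotype_means must be named with genotype classes")
  }
  sd <- if (is.null(sd)) defaults$sd else sd
  trait <- if (is.null(trait)) defaults$trait else match.arg(trait,
                                                            c("pollen",
                                                              "seed"))
  if (is.null(maternal_sd)) maternal_sd <- sd / 10
  stopifnot(sd > 0, maternal_sd >= 0,
            n_per_class >= families_per_class, families_per_class >= 1)
  if (trait == "pollen" && any(means < 0 | means > 1)) {
    stop("pollen class means must lie in [0, 1]")
  }
  if (any(means < 0)) stop("class means must be nonnegative")
  structure(list(preset = preset, genotype_means = means, sd = sd,
                 maternal_sd = maternal_sd,
                 n_per_class = as.integer(n_per_class),
                 families_per_class = as.integer(families_per_class),
                 trait = trait),
            class = "fertility_scenario")
}

#' @export
print.fertility_scenario <- function(x, ...) {
  cat("Fertility scenario (", x$preset, ", ", x$trait, "): ",
      paste(names(x$genotype_means), "=", x$genotype_means,
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  sd = %g, maternal sd = %g, n = %d plants / %d families\n",
              x$sd, x$maternal_sd, x$n_per_class, x$families_per_class))
  invisible(x)
}

#' Generate a synthetic fertility table
#'
#' Draws per-plant fertility values as class mean + maternal-family effect
#' (`Normal(0, maternal_sd)`) + residual (`Normal(0, sd)`), with balanced
#' families and values truncated to the trait's domain (pollen to \[0, 1\],
#' seed to `>= 0`).
#'
#' @param scenario A [fertility_scenario()].
#' @param seed Integer RNG seed.
#' @return A fertility `data.frame` in the format of
#'   [read_fertility_table()].
#' @examples
#' head(gen_fertility(fertility_scenario("pf7.2"), seed = 1))
#' @export
gen_fertility <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "fertility_scenario"))
  means <- scenario$genotype_means
  domain_max <- if (scenario$trait == "pollen") 1 else Inf
  if (any(means - 4 * scenario$sd > domain_max) || any(means < 0)) {
    stop("class mean lies far outside the trait domain; truncation would ",
         "distort the scenario")
  }
  nf <- scenario$families_per_class
  npc <- scenario$n_per_class
  fam_sizes <- rep(npc %/% nf, nf) + c(rep(1, npc %% nf),
                                       rep(0, nf - npc %% nf))
  withr::with_seed(seed, {
    rows <- lapply(names(means), function(g) {
      fam_eff <- stats::rnorm(nf, 0, scenario$maternal_sd)
      fam <- rep(seq_len(nf), fam_sizes)
      value <- means[[g]] + fam_eff[fam] + stats::rnorm(npc, 0, scenario$sd)
      value <- pmin(pmax(value, 0), domain_max)
      data.frame(plant_id = paste0(g, "_", seq_len(npc)),
                 genotype = g,
                 maternal_family = paste0(g, ".f", fam),
                 trait = scenario$trait,
                 value = value,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a jittered tree set
#'
#' Produces `n` trees by multiplying each branch length of a base tree by
#' independent lognormal factors with mean 1 and coefficient of variation
#' `cv`, then re-enforcing the clock.  Stands in for a posterior sample of
#' phylogenies.
#'
#' @param base A [three_taxon_tree()].
#' @param cv Coefficient of variation of the branch-length multipliers
#'   (`cv = 0` replicates the base tree).
#' @param n Number of trees.
#' @param seed Integer RNG seed.
#' @return A [tree_set()].
#' @examples
#' gen_tree_set(three_taxon_tree(1.251, 0.502, 0.749, 0.749), cv = 0.1,
#'              n = 5, seed = 1)
#' @export
gen_tree_set <- function(base, cv = 0.1, n = 100, seed = 1) {
  stopifnot(inherits(base, "three_taxon_tree"), cv >= 0, n >= 1)
  if (cv == 0) {
    return(tree_set(rep(list(enforce_clock(base)), n),
                    source_label = "jitter cv=0"))
  }
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2  # lognormal with mean exactly 1
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      f <- stats::rlnorm(4, meanlog, sdlog)
      enforce_clock(three_taxon_tree(base$t_a * f[1], base$t_b * f[2],
                                     base$t_c * f[3], base$t_d * f[4],
                                     taxa = base$taxa))
    })
  })
  tree_set(trees, source_label = sprintf("jitter cv=%g", cv))
}

#' Generate QTL inventories with known ground truth
#'
#' The inverse of [collapse_inventory()]: simulates (or accepts) per-branch
#' mutation counts and emits the per-cross QTL inventory they would produce.
#' A mutation on the shared branch `b` becomes a co-localized pair (one QTL
#' per cross, ground-truth call `homologous`); mutations on `c`/`d` become
#' QTL unique to the SH/SP cross.  With `n_composite > 0`, that many `b`
#' mutations are paired with an extra SP-specific mutation at the same
#' location (ground-truth call `composite_shared_plus_SP`), exercising the
#' composite classification path.  Effect sizes are drawn
#' `Normal(effect_mean, effect_sd)` truncated to be `<= 0`.
#'
#' @param model A [model_spec()] used to simulate counts (ignored when
#'   `forced_counts` is given).
#' @param tree Ultrametric [three_taxon_tree()].
#' @param seed Integer RNG seed.
#' @param trait Trait label for all generated QTL.
#' @param effect_mean,effect_sd Parameters of the effect-size draw (percent).
#' @param forced_counts Optional one-row `branch_counts` to reproduce
#'   exactly.
#' @param n_composite Number of `b` mutations to upgrade to composite pairs.
#' @param config A [run_config()].
#' @return A list of class `inventory_sim`: `inventory` (both crosses, one
#'   data frame), `outcomes` (named ground-truth calls for co-localized
#'   pairs), `truth_counts` (the generating `branch_counts`),
#'   `truth_placements`.
#' @examples
#' sim <- gen_inventory(forced_counts = make_branch_counts(1, 7, 6,
#'                                                         "pollen"),
#'                      seed = 1)
#' table(sim$inventory$cross)
#' @export
gen_inventory <- function(model = model_spec("linear", c(rho = 7)),
                          tree = three_taxon_tree(1.251, 0.502, 0.749,
                                                  0.749),
                          seed = 1, trait = "pollen",
                          effect_mean = -45, effect_sd = 20,
                          forced_counts = NULL, n_composite = 0,
                          config = run_config()) {
  counts <- if (is.null(forced_counts)) {
    simulate_counts(model, tree, seed = seed, config = config, trait = trait)
  } else forced_counts
  n_b <- counts$n_b[1]; n_c <- counts$n_c[1]; n_d <- counts$n_d[1]
  stopifnot(n_composite <= n_b)
  draw_effect <- function(k, rng_offset) {
    if (k == 0) return(numeric(0))
    withr::with_seed(seed + rng_offset, {
      -abs(stats::rnorm(k, effect_mean, effect_sd))
    })
  }
  pref <- substr(trait, 1, 2)
  rows <- list()
  outcomes <- character(0)
  add_row <- function(qtl_id, cross, delta, partner = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      qtl_id = qtl_id, cross = cross, trait = trait,
      chromosome = ((length(rows)) %% 12) + 1L,
      delta_pct = delta, dominance_D = -0.5,
      colocal_partner = partner, pollen_confounded = FALSE,
      stringsAsFactors = FALSE)
  }
  eff_b <- draw_effect(n_b, 1)
  for (i in seq_len(n_b)) {
    id_sh <- sprintf("%s_b%d_SHxSL", pref, i)
    id_sp <- sprintf("%s_b%d_SPxSL", pref, i)
    add_row(id_sh, "SHxSL", eff_b[i], id_sp)
    add_row(id_sp, "SPxSL", eff_b[i], id_sh)
    outcomes[[id_sh]] <- if (i <= n_composite) {
      "composite_shared_plus_SP"
    } else "homologous"
  }
  eff_c <- draw_effect(n_c, 2)
  for (i in seq_len(n_c)) {
    add_row(sprintf("%s_c%d", pref, i), "SHxSL", eff_c[i])
  }
  eff_d <- draw_effect(n_d, 3)
  for (i in seq_len(n_d)) {
    add_row(sprintf("%s_d%d", pref, i), "SPxSL", eff_d[i])
  }
  inventory <- if (length(rows) == 0) {
    validate_qtl_inventory(
      data.frame(qtl_id = character(0), cross = character(0),
                 trait = character(0), chromosome = integer(0),
                 delta_pct = numeric(0), dominance_D = numeric(0),
                 colocal_partner = character(0),
                 pollen_confounded = logical(0)))
  } else validate_qtl_inventory(do.call(rbind, rows))
  truth_counts <- make_branch_counts(n_b, n_c, n_d + n_composite, trait)
  structure(list(inventory = inventory, outcomes = as.list(outcomes),
                 truth_counts = truth_counts,
                 truth_placements = collapse_inventory(inventory,
                                                       as.list(outcomes))),
            class = "inventory_sim")
}
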