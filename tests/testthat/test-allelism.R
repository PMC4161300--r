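test_that("fit_group_stats recovers the letter structure of each scenario", {
  # null case: equal true means -> everyone shares a letter
  sc <- fertility_scenario("custom",
                           genotype_means = c(SL = 50, IL_HH = 50,
                                              IL_PP = 50, IL_HP = 50),
                           sd = 5, trait = "seed", n_per_class = 40)
  fg <- fit_group_stats(gen_fertility(sc, seed = 11), trait = "seed")
  shared <- Reduce(intersect, strsplit(fg$stats$letters, ""))
  expect_gt(length(shared), 0)

  # SP-specific scenario: IL_PP gets its own letter, the rest share one
  sc2 <- fertility_scenario("sss2.1")
  fg2 <- fit_group_stats(gen_fertility(sc2, seed = 7), trait = "seed")
  st <- fg2$stats
  lets <- function(g) strsplit(st$letters[st$genotype == g], "")[[1]]
  expect_length(intersect(lets("IL_PP"), lets("SL")), 0)
  expect_gt(length(intersect(lets("IL_HH"), lets("SL"))), 0)
  expect_gt(length(intersect(lets("IL_HP"), lets("SL"))), 0)
  expect_lt(fg2$anova_p_genotype, 1e-6)

  # two well-separated classes: distinct letters, tiny genotype p
  sc3 <- fertility_scenario("custom",
                            genotype_means = c(SL = 10, IL_PP = 0),
                            sd = 0.1, trait = "seed")
  fg3 <- fit_group_stats(gen_fertility(sc3, seed = 3), trait = "seed")
  expect_length(
    Reduce(intersect, strsplit(fg3$stats$letters, "")), 0)
  expect_lt(fg3$anova_p_genotype, 1e-6)
})

test_that("fit_group_stats rejects degenerate designs", {
  one_class <- data.frame(plant_id = paste0("p", 1:4), genotype = "SL",
                          maternal_family = "f1", trait = "seed",
                          value = c(1, 2, 3, 4))
  expect_error(fit_group_stats(one_class, "seed"), "two genotype")
  tiny <- rbind(one_class,
                data.frame(plant_id = "q1", genotype = "IL_PP",
                           maternal_family = "f2", trait = "seed",
                           value = 1))
  expect_error(fit_group_stats(tiny, "seed"), "fewer than 2")
})

test_that("classify_allelism reproduces the observed calls from letters", {
  expect_equal(classify_allelism(letters_table("pf7.2"))$call, "homologous")
  expect_equal(classify_allelism(letters_table("sss2.1"))$call,
               "lineage_specific_SP")
  expect_equal(classify_allelism(letters_table("sss1.2"))$call,
               "composite_shared_plus_SP")

  flat <- data.frame(genotype = c("SL", "IL_PP", "IL_HH", "IL_HP"),
                     ls_mean = c(60, 59, 61, 60.5), letters = "A")
  expect_equal(classify_allelism(flat)$call, "no_sterility")

  # mirror cases
  sh_spec <- data.frame(genotype = c("SL", "IL_PP", "IL_HH", "IL_HP"),
                        ls_mean = c(60, 62, 12, 59),
                        letters = c("A", "A", "B", "A"))
  expect_equal(classify_allelism(sh_spec)$call, "lineage_specific_SH")
  comp_sh <- data.frame(genotype = c("SL", "IL_PP", "IL_HH", "IL_HP"),
                        ls_mean = c(60, 38, 10, 27),
                        letters = c("A", "B", "C", "B"))
  expect_equal(classify_allelism(comp_sh)$call, "composite_shared_plus_SH")

  expect_error(
    classify_allelism(letters_table("sss1.2")[-2, ]), "IL_PP")

  # trans-het rescued above both sterile homozygotes: no rule fits
  odd <- data.frame(genotype = c("SL", "IL_PP", "IL_HH", "IL_HP"),
                    ls_mean = c(60, 20, 22, 40),
                    letters = c("A", "C", "C", "B"))
  expect_equal(classify_allelism(odd)$call, "indeterminate")
  expect_match(classify_allelism(odd)$evidence, "no complementation rule")
})

test_that("effect_size_delta matches the observed table and is monotone", {
  expect_equal(round(effect_size_delta(60.83, 10.41), 1), -82.9)
  expect_equal(effect_size_delta(42, 42), 0)
  expect_equal(round(effect_size_delta(0.9, 0.78), 1), -13.3)
  expect_error(effect_size_delta(0, 5), "> 0")

  il <- seq(0, 80, by = 5)
  deltas <- vapply(il, function(x) effect_size_delta(60.83, x), numeric(1))
  expect_true(all(diff(deltas) > 0))  # increasing in il_mean
})

test_that("shared and additional effect estimators reproduce the worked
           example and compose sequentially", {
  sh <- estimate_shared_effect(60.83, 38.13, 26.66)
  expect_equal(round(sh$delta_pct), -47)
  expect_equal(round(sh$abs_diff), 28)
  add <- estimate_additional_effect(10.41, sh$pool_mean)
  expect_equal(round(add), -68)

  expect_equal(estimate_shared_effect(100, 100, 100)$delta_pct, 0)
  expect_equal(estimate_shared_effect(50, 30, 20)$delta_pct, -50)
  expect_equal(estimate_shared_effect(50, 30, 20)$abs_diff, 25)
  expect_equal(estimate_additional_effect(10, 40), -75)
  expect_equal(estimate_additional_effect(40, 40), 0)

  # sequential composition: SL * (1 + shared/100) * (1 + additional/100)
  # reproduces the double-mutant mean to machine precision
  sl <- 60.83; il_pp <- 10.41
  expect_equal(sl * (1 + sh$delta_pct / 100) * (1 + add / 100), il_pp)

  # additive-residual variant
  expect_equal(
    estimate_additional_effect(10, 40, composition = "additive",
                               sl_mean = 50), -60)
  expect_error(estimate_additional_effect(10, 0), "> 0")
})

test_that("classification recovers generating scenarios from synthetic
           data", {
  cases <- list(c("sss2.1", "lineage_specific_SP"),
                c("sss1.2", "composite_shared_plus_SP"),
                c("pf7.2", "homologous"))
  for (cs in cases) {
    sc <- fertility_scenario(cs[1])
    hits <- 0
    for (s in 1:20) {
      fg <- fit_group_stats(gen_fertility(sc, seed = s), trait = sc$trait)
      if (classify_allelism(fg)$call == cs[2]) hits <- hits + 1
    }
    expect_gte(hits, 19)
  }
})
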