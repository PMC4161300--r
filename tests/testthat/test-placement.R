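test_that("collapsing the packaged inventory reproduces the study's
           branch counts", {
  inv <- example_input("inventory")
  pl <- collapse_inventory(inv, fixture_allelism_calls())

  bc <- branch_counts(pl)
  pol <- bc[bc$trait == "pollen", ]
  expect_equal(c(pol$n_b, pol$n_c, pol$n_d), c(1, 7, 6))
  expect_equal(pol$n_total, 14)
  expect_equal(pol$n_late, 13)

  sd_ <- bc[bc$trait == "seed", ]
  expect_equal(sd_$n_total, 8)
  expect_equal(sd_$n_early, 1)
  expect_equal(sd_$n_late, 7)

  # whole-genome tallies: 22 distinct mutations, 20 unshared
  expect_equal(nrow(pl), 22)
  expect_equal(sum(pl$epoch == "late"), 20)
  expect_equal(sum(pl$trait == "pollen" & pl$epoch == "late"), 13)
})

test_that("collapse handles empty inventories and demands outcomes", {
  empty <- example_input("inventory")[0, ]
  expect_equal(nrow(collapse_inventory(empty, list())), 0)

  inv <- example_input("inventory")
  calls <- fixture_allelism_calls()
  calls$pf7.2_SHxSL <- NULL
  expect_error(collapse_inventory(inv, calls), "no allelism outcome")
  calls$pf7.2_SHxSL <- "indeterminate"
  expect_error(collapse_inventory(inv, calls), "indeterminate")
})

test_that("lineage-specific pairs keep the non-confounded partner only", {
  inv <- example_input("inventory")
  # sss2.1: SH instance is pollen-confounded -> dropped; flip the flag and
  # the SH QTL must reappear on branch c
  pl <- collapse_inventory(inv, fixture_allelism_calls())
  expect_false("sss2.1_SHxSL" %in% pl$mutation_id)
  inv2 <- inv
  inv2$pollen_confounded[inv2$qtl_id == "sss2.1_SHxSL"] <- FALSE
  pl2 <- collapse_inventory(inv2, fixture_allelism_calls())
  expect_true("sss2.1_SHxSL" %in% pl2$mutation_id)
  expect_equal(pl2$branch[pl2$mutation_id == "sss2.1_SHxSL"], "c")
})

test_that("mutation count obeys the conservation identity on random
           inventories", {
  for (s in 1:25) {
    n_b <- s %% 4
    sim <- gen_inventory(seed = s, trait = "pollen",
                         forced_counts = make_branch_counts(
                           n_b, (s * 3) %% 5, (s * 7) %% 5, "pollen"),
                         n_composite = if (n_b > 0) s %% 2 else 0)
    pl <- sim$truth_placements
    inv <- sim$inventory
    n_unique <- sum(is.na(inv$colocal_partner))
    calls <- unlist(sim$outcomes)
    n_homologous <- sum(calls == "homologous")
    n_composite <- sum(calls == "composite_shared_plus_SP")
    expect_equal(nrow(pl), n_unique + n_homologous + 2 * n_composite)
  }
})

test_that("collapse inverts gen_inventory exactly", {
  for (s in 1:100) {
    sim <- gen_inventory(model_spec("DM", c(c = 3)),
                         tree = study_tree(), seed = s,
                         n_composite = 0)
    got <- branch_counts(collapse_inventory(sim$inventory, sim$outcomes))
    truth <- sim$truth_counts
    if (truth$n_total == 0) {
      expect_equal(nrow(sim$inventory), 0)
    } else {
      expect_equal(got$n_b, truth$n_b)
      expect_equal(got$n_c, truth$n_c)
      expect_equal(got$n_d, truth$n_d)
    }
  }
})

test_that("derived_ancestral_check applies the parsimony rule", {
  extra <- list(SC = c("7@85", "2@10"), SM = c("3@55"))
  expect_equal(derived_ancestral_check(extra, "9@20"), "derived_on_b")
  expect_equal(derived_ancestral_check(extra, "7@85"), "possibly_ancestral")
  expect_warning(out <- derived_ancestral_check(list(), "7@85"),
                 "no additional crosses")
  expect_equal(out, "possibly_ancestral")
})

test_that("extrapolate_counts inflates late branches with half-away
           rounding", {
  out <- extrapolate_counts(pollen_counts(), fraction = 1 / 3)
  expect_equal(c(out$n_b, out$n_c, out$n_d), c(1, 9, 8))
  expect_equal(out$n_total, 18)

  expect_equal(extrapolate_counts(pollen_counts(), fraction = 0),
               pollen_counts())

  out_seed <- extrapolate_counts(seed_counts(), fraction = 1 / 3)
  expect_equal(out_seed$n_late, 9)  # 7 * 4/3 = 9.33 -> 9 across terminals
  expect_equal(out_seed$n_b, 1)
})
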