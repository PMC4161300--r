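test_that("read_tree maps branch lengths to roles and prunes extra taxa", {
  tr <- read_tree("((SH:0.6,SP:0.6):0.4,SL:1.0);")
  expect_equal(tr$t_b, 0.4)
  expect_equal(tr$t_c, 0.6)
  expect_equal(tr$t_d, 0.6)
  expect_equal(tr$t_a, 1.0)
  expect_true(tr$ultrametric)
  expect_equal(tr$depth_T, 1.0)

  # an extra taxon is pruned and the result is identical
  expect_message(
    tr2 <- read_tree("(((SH:0.6,SP:0.6):0.4,SL:1.0):0.2,OUT:1.2);"),
    "pruning")
  expect_equal(tr2[c("t_a", "t_b", "t_c", "t_d")],
               tr[c("t_a", "t_b", "t_c", "t_d")])

  # a tree with t_b / (t_b + t_c + t_d) = 0.251 yields the study's early
  # fraction downstream
  tr3 <- read_tree("((SH:0.749,SP:0.749):0.502,SL:1.251);")
  expect_equal(branch_proportions(tr3)$p_early, 0.251)
})

test_that("read_tree rejects malformed inputs with a named offender", {
  expect_error(read_tree("((SH:0.6,SP:0.6):0.4,XX:1.0);"), "SL")
  expect_error(read_tree("((SL:0.6,SP:0.6):0.4,SH:1.0);"), "topology")
  expect_error(read_tree("((SH,SP),SL);"), "branch length")
})

test_that("tree write/read round-trips all branch lengths exactly", {
  tr <- three_taxon_tree(1.251, 0.502, 0.749, 0.749)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr, path)
  back <- read_tree(path)
  expect_equal(back[c("t_a", "t_b", "t_c", "t_d")],
               tr[c("t_a", "t_b", "t_c", "t_d")])
})

test_that("enforce_clock averages terminals, preserves t_b, is idempotent", {
  tr <- three_taxon_tree(0.9, 0.4, 0.55, 0.65)
  cl <- enforce_clock(tr)
  expect_equal(cl$t_c, 0.6)
  expect_equal(cl$t_d, 0.6)
  expect_equal(cl$t_a, 1.0)
  expect_equal(cl$t_b, tr$t_b)
  expect_true(cl$ultrametric)
  expect_equal(enforce_clock(cl), cl)

  # already-ultrametric trees are unchanged
  ul <- three_taxon_tree(1, 0.4, 0.6, 0.6)
  expect_equal(enforce_clock(ul), ul)
})

test_that("read_tree_set parses multi-tree Newick files", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((SH:0.6,SP:0.6):0.4,SL:1.0);",
               "((SH:0.7,SP:0.7):0.3,SL:1.0);"), path)
  ts <- read_tree_set(path)
  expect_s3_class(ts, "tree_set")
  expect_length(ts$trees, 2)
  expect_equal(ts$trees[[2]]$t_b, 0.3)
})

test_that("fertility tables validate and round-trip", {
  df <- data.frame(plant_id = c("p1", "p2", "p3"),
                   genotype = c("SL", "IL_HH", "IL_PP"),
                   maternal_family = c("f1", "f1", "f2"),
                   trait = "pollen", value = c(0.9, 0.8, 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fertility_table(df, path)
  back <- read_fertility_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$value, df$value)

  bad <- df; bad$value[2] <- 1.2
  expect_error(validate_fertility(bad), "row 2")
  bad <- df; bad$genotype[3] <- "IL_XX"
  expect_error(validate_fertility(bad), "row 3")
  bad <- rbind(df, df[1, ])
  expect_error(validate_fertility(bad), "duplicated")
})

test_that("inventory validation enforces field ranges and symmetric links", {
  inv <- example_input("inventory")
  expect_silent(validate_qtl_inventory(inv))
  bad <- inv; bad$delta_pct[2] <- 5
  expect_error(validate_qtl_inventory(bad), "delta_pct")
  bad <- inv; bad$dominance_D[1] <- -1.5
  expect_error(validate_qtl_inventory(bad), "dominance_D")
  bad <- inv; bad$colocal_partner[1] <- NA
  expect_error(validate_qtl_inventory(bad), "symmetric")
  bad <- inv; bad$colocal_partner[1] <- "nonexistent"
  expect_error(validate_qtl_inventory(bad), "not present")
})

test_that("inventory write/read round-trips fields exactly", {
  inv <- example_input("inventory")
  path <- withr::local_tempfile(fileext = ".csv")
  write_qtl_inventory(inv, path)
  back <- read_qtl_inventory(path)
  expect_equal(back$qtl_id, inv$qtl_id)
  expect_equal(back$delta_pct, inv$delta_pct)
  expect_equal(back$colocal_partner, inv$colocal_partner)
  expect_equal(back$pollen_confounded, inv$pollen_confounded)
})
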