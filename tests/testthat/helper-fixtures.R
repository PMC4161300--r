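# shared fixtures: the clock-enforced study tree (early fraction 0.251) and
# the observed per-trait branch counts
study_tree <- function() three_taxon_tree(1.251, 0.502, 0.749, 0.749)

pollen_counts <- function() make_branch_counts(1, 7, 6, "pollen")
seed_counts <- function() make_branch_counts(1, 3, 4, "seed")

study_props <- function() list(p_early = 0.251, p_late = 0.749)

# letter-display tables for the three observed allelism tests
letters_table <- function(locus) {
  switch(locus,
    pf7.2 = data.frame(
      genotype = c("SL", "IL_PP", "IL_HH", "IL_HP", "IL_PH"),
      ls_mean = c(0.90, 0.81, 0.76, 0.77, 0.78),
      letters = c("A", "B", "B", "B", "B")),
    sss1.2 = data.frame(
      genotype = c("SL", "IL_PP", "IL_HH", "IL_HP"),
      ls_mean = c(60.83, 10.41, 38.13, 26.66),
      letters = c("A", "C", "B", "B")),
    sss2.1 = data.frame(
      genotype = c("SL", "IL_PP", "IL_HH", "IL_HP"),
      ls_mean = c(60.83, 11.08, 64.89, 67.93),
      letters = c("A", "B", "A", "A")))
}

fixture_allelism_calls <- function() {
  list(pf7.2_SHxSL = "homologous",
       sss1.2_SHxSL = "composite_shared_plus_SP",
       sss2.1_SHxSL = "lineage_specific_SP")
}
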