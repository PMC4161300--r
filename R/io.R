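#' Read a per-plant fertility table
#'
#' Reads a comma- or tab-delimited table of per-plant fertility measurements
#' with columns `plant_id`, `genotype`, `maternal_family`, `trait`, `value`.
#' Genotypes are the five classes of a cross-species allelism test: the
#' fertile recurrent parent `SL`, the two homozygous introgression lines
#' `IL_HH` and `IL_PP`, and the reciprocal trans-heterozygotes `IL_HP` and
#' `IL_PH`.  Pollen values are proportions of fertile pollen per flower in
#' \[0, 1\]; seed values are seeds per fruit (nonnegative).
#'
#' @param path Delimited text file with a header row.
#' @return A validated `data.frame` (one row per plant and trait).
#' @export
read_fertility_table <- function(path) {
  df <- read_delim_auto(path)
  validate_fertility(df)
}

#' @rdname read_fertility_table
#' @param df Fertility data frame to validate.
#' @export
validate_fertility <- function(df) {
  need <- c("plant_id", "genotype", "maternal_family", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("fertility table missing columns: ",
                             paste(miss, collapse = ", "))
  df$genotype <- as.character(df$genotype)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  bad <- which(!df$genotype %in% GENOTYPE_LEVELS)
  if (length(bad) > 0) stop("unknown genotype '", df$genotype[bad[1]],
                            "' in row ", bad[1])
  bad <- which(!df$trait %in% c("pollen", "seed"))
  if (length(bad) > 0) stop("unknown trait '", df$trait[bad[1]],
                            "' in row ", bad[1])
  bad <- which(!is.finite(df$value) | df$value < 0 |
                 (df$trait == "pollen" & df$value > 1))
  if (length(bad) > 0) stop("fertility value out of range in row ", bad[1],
                            " (value = ", df$value[bad[1]], ", trait = ",
                            df$trait[bad[1]], ")")
  key <- paste(df$plant_id, df$trait)
  if (anyDuplicated(key)) {
    stop("duplicated (plant_id, trait) in row ", anyDuplicated(key))
  }
  df
}

#' @rdname read_fertility_table
#' @param sep Field separator, `","` or `"\t"`.
#' @export
write_fertility_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

GENOTYPE_LEVELS <- c("SL", "IL_HH", "IL_PP", "IL_HP", "IL_PH")

# delimited reader: sniffs comma vs tab from the header line ('#' = comment)
read_delim_auto <- function(path) {
  header <- grep("^\\s*#", readLines(path, n = 20), value = TRUE,
                 invert = TRUE)[1]
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

#' Read a QTL inventory table
#'
#' A QTL inventory lists one detected sterility QTL per row for the two
#' introgression-line mapping crosses, with columns `qtl_id`, `cross`
#' (`SHxSL` or `SPxSL`), `trait` (`pollen` or `seed`), `chromosome`,
#' `delta_pct` (signed percent change versus the fertile parent; `<= 0` for
#' sterility loci), `dominance_D` (degree of dominance in \[-1, 0\], or `NA`),
#' `colocal_partner` (the `qtl_id` of a physically co-localized QTL in the
#' other cross, or `NA`) and `pollen_confounded` (logical: a seed QTL whose
#' signal was not statistically independent of pollen sterility).
#'
#' @param path Delimited text file with a header row.
#' @return A validated inventory `data.frame`.
#' @export
read_qtl_inventory <- function(path) {
  df <- read_delim_auto(path)
  validate_qtl_inventory(df)
}

#' @rdname read_qtl_inventory
#' @param df Inventory data frame to validate.
#' @export
validate_qtl_inventory <- function(df) {
  need <- c("qtl_id", "cross", "trait", "chromosome", "delta_pct",
            "dominance_D", "colocal_partner", "pollen_confounded")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("inventory missing columns: ",
                             paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df)
  df$cross <- as.character(df$cross)
  df$trait <- as.character(df$trait)
  df$qtl_id <- as.character(df$qtl_id)
  df$colocal_partner <- as.character(df$colocal_partner)
  df$pollen_confounded <- as.logical(df$pollen_confounded)
  df$delta_pct <- as.numeric(df$delta_pct)
  bad <- which(!df$cross %in% c("SHxSL", "SPxSL"))
  if (length(bad) > 0) stop("unknown cross in row ", bad[1])
  bad <- which(!df$trait %in% c("pollen", "seed"))
  if (length(bad) > 0) stop("unknown trait in row ", bad[1])
  bad <- which(!is.na(df$delta_pct) & df$delta_pct > 0)
  if (length(bad) > 0) stop("delta_pct must be <= 0 for sterility loci (row ",
                            bad[1], ")")
  bad <- which(!is.na(df$dominance_D) &
                 (df$dominance_D < -1 | df$dominance_D > 0))
  if (length(bad) > 0) stop("dominance_D must lie in [-1, 0] (row ", bad[1], ")")
  bad <- which(!df$chromosome %in% 1:12)
  if (length(bad) > 0) stop("chromosome must be an integer 1-12 (row ",
                            bad[1], ")")
  # co-localization must be symmetric across the two crosses
  has <- !is.na(df$colocal_partner)
  for (i in which(has)) {
    j <- match(df$colocal_partner[i], df$qtl_id)
    if (is.na(j)) stop("colocal_partner '", df$colocal_partner[i],
                       "' of ", df$qtl_id[i], " not present in inventory")
    if (df$cross[j] == df$cross[i]) {
      stop("colocal_partner of ", df$qtl_id[i], " is in the same cross")
    }
    if (is.na(df$colocal_partner[j]) || df$colocal_partner[j] != df$qtl_id[i]) {
      stop("colocal_partner link of ", df$qtl_id[i], " is not symmetric")
    }
  }
  df
}

#' @rdname read_qtl_inventory
#' @param sep Field separator.
#' @export
write_qtl_inventory <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the seed and iteration counts used by the randomized stages of the
#' pipeline.  Every randomized operation draws from a single RNG stream
#' seeded per invocation, so whole analyses are reproducible bit-for-bit.
#'
#' @param seed Integer RNG seed.
#' @param n_boot Bootstrap replicates for effect-size comparisons.
#' @param n_binom_iter Iterations for binomial resampling.
#' @param mc_reps Monte-Carlo replicates for expected interaction counts.
#' @param small_p_mode Use the small-probability closed forms for model means.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_boot = 500L, n_binom_iter = 1000L,
                       mc_reps = 20000L, small_p_mode = TRUE) {
  stopifnot(n_boot >= 1, n_binom_iter >= 1, mc_reps >= 1)
  structure(list(seed = as.integer(seed), n_boot = as.integer(n_boot),
                 n_binom_iter = as.integer(n_binom_iter),
                 mc_reps = as.integer(mc_reps),
                 small_p_mode = isTRUE(small_p_mode)),
            class = "run_config")
}

#' Packaged example inputs
#'
#' Accessors for the small plain-text inputs shipped with the package: the
#' study-system QTL inventory (structure and totals follow the published
#' mapping results for the two tomato-clade crosses; per-locus effect sizes
#' of cross-unique loci are synthetic stand-ins, see the file's header
#' comment), the genotype-fertility least-squares means from the three
#' allelism tests, and a clock-enforced three-taxon tree whose internal
#' branch accounts for 0.251 of the total donor-side length.
#'
#' @param file One of `"inventory"`, `"genotype_means"`, `"tree"`.
#' @return For `"tree"` a [three_taxon_tree()]; otherwise a `data.frame`.
#' @examples
#' example_input("genotype_means")
#' @export
example_input <- function(file = c("inventory", "genotype_means", "tree")) {
  file <- match.arg(file)
  path <- switch(file,
    inventory = system.file("extdata", "qtl_inventory_synthetic.csv",
                            package = "dmisnowball"),
    genotype_means = system.file("extdata", "allelism_genotype_means.csv",
                                 package = "dmisnowball"),
    tree = system.file("extdata", "tree_three_taxon.nwk",
                       package = "dmisnowball"))
  if (path == "") stop("packaged file not found; is the package installed?")
  switch(file,
         inventory = read_qtl_inventory(path),
         genotype_means = read_delim_auto(path),
         tree = read_tree(path))
}
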