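#' Nested ANOVA and Tukey HSD summary of an allelism test
#'
#' Fits the fertility model for one cross-species complementation test:
#' a fixed-effects nested ANOVA with genotype and maternal family nested
#' within genotype, followed by least-squares means per genotype and
#' Tukey-HSD-adjusted all-pairs contrasts, summarized as a compact letter
#' display (genotypes sharing a letter are statistically indistinguishable
#' at family-wise alpha).
#'
#' @param measurements Fertility data frame (see [read_fertility_table()]).
#' @param trait `"pollen"` or `"seed"`; rows for the other trait are dropped.
#' @param alpha Family-wise error rate for the Tukey letters.
#' @return A list of class `group_stats` with elements
#'   \describe{
#'     \item{stats}{data frame: `genotype`, `ls_mean`, `se`, `n`, `letters`.}
#'     \item{contrasts}{Tukey-adjusted pairwise contrasts (from emmeans).}
#'     \item{anova_p_genotype, anova_p_maternal}{F-test p-values.}
#'     \item{trait, alpha}{inputs, for printing.}
#'   }
#' @examples
#' sc <- fertility_scenario("sss2.1")
#' fg <- fit_group_stats(gen_fertility(sc, seed = 42), trait = "seed")
#' fg$stats
#' @export
fit_group_stats <- function(measurements, trait = c("seed", "pollen"),
                            alpha = 0.05) {
  trait <- match.arg(trait)
  df <- measurements[measurements$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) stop("no measurements for trait '", trait, "'")
  df$genotype <- factor(df$genotype,
                        levels = intersect(GENOTYPE_LEVELS, df$genotype))
  df$maternal_family <- factor(df$maternal_family)
  tab <- table(df$genotype)
  if (length(tab) < 2) stop("need at least two genotype classes")
  if (any(tab < 2)) {
    stop("genotype class with fewer than 2 plants: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  nested <- nlevels(df$maternal_family) > nlevels(df$genotype)
  form <- if (nested) value ~ genotype + genotype:maternal_family
          else value ~ genotype
  fit <- stats::aov(form, data = df)
  atab <- stats::anova(fit)
  p_gen <- atab[["Pr(>F)"]][match("genotype", rownames(atab))]
  p_mat <- if (nested) {
    atab[["Pr(>F)"]][match("genotype:maternal_family", rownames(atab))]
  } else NA_real_
  emm <- suppressMessages(emmeans::emmeans(fit, "genotype"))
  emm_sum <- summary(emm)
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "tukey"))
  sig <- pairwise_sig_matrix(as.character(emm_sum$genotype), prs, alpha)
  letters <- insert_absorb_letters(emm_sum$emmean, sig)
  stats_df <- data.frame(
    genotype = as.character(emm_sum$genotype),
    ls_mean = emm_sum$emmean,
    se = emm_sum$SE,
    n = as.integer(tab[as.character(emm_sum$genotype)]),
    letters = letters,
    stringsAsFactors = FALSE
  )
  ord <- order(match(stats_df$genotype, GENOTYPE_LEVELS))
  structure(list(stats = stats_df[ord, , drop = FALSE],
                 contrasts = prs,
                 anova_p_genotype = p_gen,
                 anova_p_maternal = p_mat,
                 trait = trait, alpha = alpha),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("Allelism-test genotype statistics (", x$trait, ")\n", sep = "")
  print(x$stats, row.names = FALSE)
  cat(sprintf("ANOVA p(genotype) = %.3g; p(maternal family) = %.3g\n",
              x$anova_p_genotype, x$anova_p_maternal))
  invisible(x)
}

# TRUE at [i, j] when the Tukey-adjusted contrast between genotypes i and j
# is significant at alpha
pairwise_sig_matrix <- function(genotypes, contrasts, alpha) {
  k <- length(genotypes)
  sig <- matrix(FALSE, k, k, dimnames = list(genotypes, genotypes))
  parts <- strsplit(as.character(contrasts$contrast), " - ", fixed = TRUE)
  for (r in seq_along(parts)) {
    gi <- parts[[r]][1]
    gj <- parts[[r]][2]
    s <- isTRUE(contrasts$p.value[r] < alpha)
    sig[gi, gj] <- s
    sig[gj, gi] <- s
  }
  sig
}

# Compact letter display by the insert-absorb algorithm: start from one
# letter covering all groups; for each significant pair, duplicate the
# letters containing both and split them; absorb letters that are subsets of
# others.  Groups share a letter iff they are not significantly different.
insert_absorb_letters <- function(means, sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))  # each column = membership vector of one letter
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    ord <- order(-abs(means[pairs[, 1]] - means[pairs[, 2]]))
    pairs <- pairs[ord, , drop = FALSE]
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    new_cols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        new_cols <- c(new_cols, list(c1, c2))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_cols[[a]] <= new_cols[[b]]) &&
            any(new_cols[[a]] != new_cols[[b]])) {
          keep[a] <- FALSE
        }
      }
    }
    # drop exact duplicates
    sig_cols <- new_cols[keep]
    key <- vapply(sig_cols, function(v) paste(as.integer(v), collapse = ""),
                  character(1))
    cols <- sig_cols[!duplicated(key)]
  }
  # order letters so that 'A' tags the highest mean
  first_mean <- vapply(cols, function(col) max(means[col]), numeric(1))
  cols <- cols[order(-first_mean)]
  out <- vapply(seq_len(k), function(i) {
    paste(LETTERS[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  out
}

#' Classify a test of allelism
#'
#' Applies the complementation-test decision rules to the genotype summary of
#' one locus.  Writing `below(x, y)` for "`x` has significantly lower
#' fertility than `y`" (Tukey-adjusted) and `rescued(x)` for "`x` is not
#' significantly below `SL`", the calls are:
#'
#' * `no_sterility`: no introgression class is below `SL`.
#' * `lineage_specific_SP`: `IL_PP` below `SL` and below `IL_HP`, while
#'   `IL_HH`, `IL_HP` (and `IL_PH` if present) are rescued — the SH allele
#'   fully complements, so the sterility mutation is unique to the SP
#'   lineage.  `lineage_specific_SH` is the mirror image.
#' * `composite_shared_plus_SP`: `IL_HH` and `IL_HP` both below `SL` (the
#'   SP allele fails to complement the shared mutation carried by `IL_HH`),
#'   `IL_PP` below `IL_HP` (partial complementation of the extra SP
#'   mutation by the SH allele) and `IL_HH` not below `IL_HP` — a shared
#'   mutation plus at least one additional SP-specific mutation.
#'   `composite_shared_plus_SH` is the mirror image.  When the
#'   trans-heterozygote sits significantly above both homozygotes yet below
#'   `SL`, neither composite signature applies and the call is
#'   `indeterminate`.
#' * `homologous`: every introgression class below `SL` and neither
#'   homozygote below the trans-heterozygote — no complementation; the two
#'   donor alleles are inferred to be the same mutation.
#' * anything else: `indeterminate`, with an evidence string.
#'
#' Rules are direction-aware: a trans-heterozygote significantly *above* `SL`
#' still counts as rescued.  Classification therefore works for incompletely
#' recessive loci, where heterozygote fertility may differ from both
#' homozygote classes.
#'
#' @param stats A `group_stats` object from [fit_group_stats()], or a data
#'   frame with columns `genotype`, `ls_mean`, `letters` (genotypes sharing a
#'   letter are treated as statistically indistinguishable).
#' @param locus Optional locus name carried into the result.
#' @return A list of class `allelism_outcome` with elements `locus`, `call`,
#'   `evidence`, `anova_p_genotype`, `maternal_p`.
#' @examples
#' tab <- data.frame(genotype = c("SL", "IL_PP", "IL_HH", "IL_HP"),
#'                   ls_mean = c(60.83, 11.08, 64.89, 67.93),
#'                   letters = c("A", "B", "A", "A"))
#' classify_allelism(tab, locus = "sss2.1")$call
#' @export
classify_allelism <- function(stats, locus = NA_character_) {
  p_gen <- NA_real_; p_mat <- NA_real_
  if (inherits(stats, "group_stats")) {
    p_gen <- stats$anova_p_genotype
    p_mat <- stats$anova_p_maternal
    stats <- stats$stats
  }
  need <- c("SL", "IL_HH", "IL_PP", "IL_HP")
  miss <- setdiff(need, stats$genotype)
  if (length(miss) > 0) stop("missing required genotype class(es): ",
                             paste(miss, collapse = ", "))
  mean_of <- function(g) stats$ls_mean[match(g, stats$genotype)]
  letters_of <- function(g) {
    strsplit(stats$letters[match(g, stats$genotype)], "")[[1]]
  }
  differs <- function(x, y) {
    length(intersect(letters_of(x), letters_of(y))) == 0
  }
  below <- function(x, y) differs(x, y) && mean_of(x) < mean_of(y)
  has_ph <- "IL_PH" %in% stats$genotype
  rescued <- function(x) !below(x, "SL")

  hets_rescued_sp <- rescued("IL_HP") && (!has_ph || rescued("IL_PH"))
  hets_below_sl <- below("IL_HP", "SL") && (!has_ph || below("IL_PH", "SL"))

  call <- "indeterminate"
  if (rescued("IL_HH") && rescued("IL_PP") && hets_rescued_sp) {
    call <- "no_sterility"
  } else if (below("IL_PP", "SL") && below("IL_PP", "IL_HP") &&
             rescued("IL_HH") && hets_rescued_sp) {
    call <- "lineage_specific_SP"
  } else if (below("IL_HH", "SL") && below("IL_HH", "IL_HP") &&
             rescued("IL_PP") && hets_rescued_sp) {
    call <- "lineage_specific_SH"
  } else if (below("IL_HH", "SL") && below("IL_HP", "SL") &&
             below("IL_PP", "IL_HP") && !below("IL_HH", "IL_HP")) {
    call <- "composite_shared_plus_SP"
  } else if (below("IL_PP", "SL") && below("IL_HP", "SL") &&
             below("IL_HH", "IL_HP") && !below("IL_PP", "IL_HP")) {
    call <- "composite_shared_plus_SH"
  } else if (below("IL_HH", "SL") && below("IL_PP", "SL") && hets_below_sl &&
             !below("IL_PP", "IL_HP") && !below("IL_HH", "IL_HP")) {
    call <- "homologous"
  }
  evidence <- paste0(
    paste0(stats$genotype, "=", signif(stats$ls_mean, 4), " [",
           stats$letters, "]", collapse = "; "),
    if (call == "indeterminate") " -- pattern matches no complementation rule")
  structure(list(locus = locus, call = call, evidence = evidence,
                 anova_p_genotype = p_gen, maternal_p = p_mat),
            class = "allelism_outcome")
}

#' @export
print.allelism_outcome <- function(x, ...) {
  cat("Allelism outcome", if (!is.na(x$locus)) paste0("for ", x$locus),
      ": ", x$call, "\n  ", x$evidence, "\n", sep = "")
  invisible(x)
}

#' Effect size of an introgression relative to the fertile parent
#'
#' The standard per-locus effect size: the signed percentage change of an
#' introgression-line mean relative to the fertile recurrent parent,
#' `100 * (il_mean - sl_mean) / sl_mean`.  Negative values are fertility
#' reductions.
#'
#' @param sl_mean Fertility mean of the recurrent parent (must be positive).
#' @param il_mean Fertility mean of the introgression class.
#' @return Signed percent change.
#' @examples
#' effect_size_delta(60.83, 10.41)  # about -82.9
#' @export
effect_size_delta <- function(sl_mean, il_mean) {
  if (!is.finite(sl_mean) || sl_mean <= 0) stop("sl_mean must be > 0")
  100 * (il_mean - sl_mean) / sl_mean
}

#' Effect of the shared allele at a composite locus
#'
#' At a locus carrying a shared (homologous) mutation plus a lineage-specific
#' one, the classes homozygous for the shared mutation alone are `IL_HH` and
#' the trans-heterozygote `IL_HP`; their pooled mean estimates the fertility
#' under the shared mutation only.  Returns its percent change versus `SL`
#' and the absolute difference in trait units (e.g. seeds per fruit).
#'
#' @param sl_mean,il_hh_mean,il_hp_mean Class fertility means; `sl_mean > 0`.
#' @return A list with `delta_pct`, `abs_diff` and `pool_mean`.
#' @examples
#' estimate_shared_effect(60.83, 38.13, 26.66)  # about -47% / 28 seeds
#' @export
estimate_shared_effect <- function(sl_mean, il_hh_mean, il_hp_mean) {
  if (!is.finite(sl_mean) || sl_mean <= 0) stop("sl_mean must be > 0")
  pool <- (il_hh_mean + il_hp_mean) / 2
  list(delta_pct = 100 * (pool - sl_mean) / sl_mean,
       abs_diff = sl_mean - pool,
       pool_mean = pool)
}

#' Additional effect of the lineage-specific allele at a composite locus
#'
#' The residual fertility reduction attributable to the lineage-specific
#' mutation after the shared one, under sequential (multiplicative)
#' composition: `100 * (il_pp_mean / shared_pool_mean - 1)`.  By
#' construction, applying the shared and then the additional reduction to the
#' `SL` mean reproduces the double-mutant class mean exactly.  Set
#' `composition = "additive"` for the additive-residual variant
#' (`100 * (il_pp_mean - shared_pool_mean) / sl_mean`, which then requires
#' `sl_mean`).
#'
#' @param il_pp_mean Mean of the class carrying both mutations.
#' @param shared_pool_mean Pooled mean under the shared mutation alone
#'   (`pool_mean` from [estimate_shared_effect()]); must be positive.
#' @param composition `"sequential"` (default) or `"additive"`.
#' @param sl_mean Needed only for the additive variant.
#' @return Signed percent change.
#' @examples
#' estimate_additional_effect(10.41, (38.13 + 26.66) / 2)  # about -68
#' @export
estimate_additional_effect <- function(il_pp_mean, shared_pool_mean,
                                       composition = c("sequential",
                                                       "additive"),
                                       sl_mean = NULL) {
  composition <- match.arg(composition)
  if (!is.finite(shared_pool_mean) || shared_pool_mean <= 0) {
    stop("shared_pool_mean must be > 0")
  }
  if (composition == "sequential") {
    100 * (il_pp_mean / shared_pool_mean - 1)
  } else {
    if (is.null(sl_mean)) stop("additive composition requires sl_mean")
    if (sl_mean <= 0) stop("sl_mean must be > 0")
    100 * (il_pp_mean - shared_pool_mean) / sl_mean
  }
}
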