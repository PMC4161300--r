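#' Potential interaction counts for a focal substitution
#'
#' Closed-form counting rules for the number of potential deleterious
#' epistatic interactions (incompatibilities against the other lineage's
#' background) in which a focal derived substitution can participate, under
#' the combinatorial model of incompatibility accumulation.  Substitutions
#' within a lineage are indexed `i = 1, 2, ...` in temporal order.
#'
#' `pairwise_dd()` counts derived-derived pairs: the focal `i`-th derived
#' allele in one lineage can be incompatible with any of the `K_other`
#' derived alleles in the other lineage, independent of `i`.
#'
#' `pairwise_da()` counts derived-ancestral pairs: the `i`-th derived allele
#' arises on a background of `i - 1` earlier same-lineage substitutions and
#' has never been co-tested with the ancestral allele at any of those loci in
#' the other lineage, giving `i - 1` potential interactions.  This is the
#' formal sense in which later-arising mutations are increasingly exposed to
#' interactions involving ancestral alleles.
#'
#' @param i,j Temporal order indices (`>= 1`) of derived alleles within one
#'   lineage; vectorized.
#' @param K_other Number of derived alleles in the other lineage.
#' @return Integer count(s).
#' @examples
#' pairwise_dd(i = 9, K_other = 5)  # 5, independent of i
#' pairwise_da(i = 4)               # 3
#' @export
pairwise_dd <- function(i, K_other) {
  stopifnot(all(i >= 1), all(K_other >= 0))
  rep_len(as.integer(K_other), length(i))
}

#' @rdname pairwise_dd
#' @export
pairwise_da <- function(i) {
  stopifnot(all(i >= 1))
  as.integer(i) - 1L
}

#' @rdname pairwise_dd
#' @details `triple_counts()` counts three-locus interactions involving the
#'   distinct `i`-th and `j`-th derived alleles of one lineage: with a
#'   derived partner in the other lineage there are `K_other`
#'   (derived-derived-derived); with an ancestral partner the third locus
#'   must have been substituted in the focal lineage before both `i` and `j`,
#'   giving `min(i, j) - 1` (derived-derived-ancestral).  The first derived
#'   allele of a lineage (`min = 1`) participates in no such
#'   ancestral-partner triple.
#' @return For `triple_counts()`, a list with components `ddd` and `dda`.
#' @export
triple_counts <- function(i, j, K_other) {
  stopifnot(all(i >= 1), all(j >= 1), all(K_other >= 0))
  if (any(i == j)) stop("i and j must be distinct order indices")
  list(ddd = rep_len(as.integer(K_other), length(i)),
       dda = as.integer(pmin(i, j)) - 1L)
}

#' Enumerate potential interactions over an explicit substitution history
#'
#' Brute-force oracle for the closed forms in [pairwise_dd()],
#' [pairwise_da()] and [triple_counts()].  A substitution history places
#' `K1` derived alleles in lineage I and `K2` in lineage II, each at distinct
#' loci, indexed in temporal order within its lineage.  All allele pairs
#' (arity 2) or trios (arity 3) satisfying each interaction class definition
#' are enumerated explicitly and tallied per focal derived allele (arity 2)
#' or per unordered same-lineage pair of derived alleles (arity 3).
#'
#' Classes: `dd` derived-derived pairs across lineages; `da` pairs of a
#' derived allele with the other lineage's ancestral allele at a locus
#' substituted earlier in the focal lineage; `ddd` two same-lineage derived
#' alleles plus a derived allele in the other lineage; `dda` two same-lineage
#' derived alleles plus the other lineage's ancestral allele at a locus
#' substituted earlier (in the focal lineage) than both.
#'
#' @param K1,K2 Substitution counts in lineages I and II.
#' @param arity 2 or 3.
#' @param classes Subset of `c("dd", "da")` (arity 2) or `c("ddd", "dda")`
#'   (arity 3).
#' @param guard Maximum number of combinations enumerated.
#' @return A data.frame of per-focal counts: columns `lineage`, `i`
#'   (and `j` for trios) plus one column per requested class.
#' @examples
#' enumerate_interactions(3, 2, arity = 2)
#' @export
enumerate_interactions <- function(K1, K2, arity = 2,
                                   classes = if (arity == 2) c("dd", "da")
                                             else c("ddd", "dda"),
                                   guard = 1e7) {
  stopifnot(K1 >= 0, K2 >= 0, arity %in% c(2, 3))
  K <- c(K1, K2)
  if (prod(pmax(K, 1))^(arity - 1) > guard) {
    stop("history too large to enumerate; use the closed forms")
  }
  if (arity == 2) {
    rows <- list()
    for (lin in 1:2) {
      Kf <- K[lin]; Ko <- K[3 - lin]
      if (Kf == 0) next
      for (i in seq_len(Kf)) {
        dd <- 0L; da <- 0L
        # derived-derived: pair focal i with each derived allele in the
        # other lineage
        for (m in seq_len(Ko)) dd <- dd + 1L
        # derived-ancestral: pair focal i with the other lineage's ancestral
        # allele at the locus of each earlier same-lineage substitution k
        for (k in seq_len(Kf)) if (k < i) da <- da + 1L
        rows[[length(rows) + 1]] <- data.frame(lineage = lin, i = i,
                                               dd = dd, da = da)
      }
    }
    out <- if (length(rows) == 0) {
      data.frame(lineage = integer(0), i = integer(0), dd = integer(0),
                 da = integer(0))
    } else do.call(rbind, rows)
    return(out[, c("lineage", "i", intersect(classes, c("dd", "da"))),
               drop = FALSE])
  }
  rows <- list()
  for (lin in 1:2) {
    Kf <- K[lin]; Ko <- K[3 - lin]
    if (Kf < 2) next
    for (i in seq_len(Kf - 1)) for (j in seq((i + 1), Kf)) {
      ddd <- 0L; dda <- 0L
      for (m in seq_len(Ko)) ddd <- ddd + 1L
      # ancestral partner: locus substituted in the focal lineage before
      # both i and j (the other lineage still carries the ancestral allele)
      for (k in seq_len(Kf)) if (k < i && k < j && k != i && k != j) {
        dda <- dda + 1L
      }
      rows[[length(rows) + 1]] <- data.frame(lineage = lin, i = i, j = j,
                                             ddd = ddd, dda = dda)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(lineage = integer(0), i = integer(0), j = integer(0),
               ddd = integer(0), dda = integer(0))
  } else do.call(rbind, rows)
  out[, c("lineage", "i", "j", intersect(classes, c("ddd", "dda"))),
      drop = FALSE]
}
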