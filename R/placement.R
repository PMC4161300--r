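#' Collapse two crosses' QTL inventories into distinct mutations on branches
#'
#' Combines the per-cross QTL inventories with the outcomes of the allelism
#' tests at co-localized loci to produce the list of distinct mutations, each
#' assigned to a branch of the three-taxon tree:
#'
#' * a co-localized pair called `homologous` contributes one mutation on the
#'   shared internal branch `b` ("early");
#' * a `composite_shared_plus_SP` pair contributes one mutation on `b` plus
#'   one SP-specific mutation on terminal branch `d` (mirror for SH / `c`);
#' * a `lineage_specific_SP` pair contributes the SP mutation on `d`; the
#'   co-localized SH instance is dropped when flagged `pollen_confounded`
#'   (its seed signal is a side effect of pollen sterility), otherwise it is
#'   kept as an independent SH mutation on `c` (mirror for SH);
#' * every QTL without a co-localized partner maps to the terminal branch of
#'   its cross (`SHxSL` to `c`, `SPxSL` to `d`).
#'
#' Each QTL is conservatively assumed to be underpinned by a single mutation.
#'
#' @param inventory Inventory data frame (see [read_qtl_inventory()]) holding
#'   both crosses.
#' @param outcomes Named list or character vector of allelism calls, keyed by
#'   `qtl_id` (either member of a co-localized pair works); values may be
#'   `allelism_outcome` objects or call strings.
#' @return A data.frame of class `mutation_placement`: `mutation_id`, `trait`,
#'   `branch` (`b`/`c`/`d`), `epoch` (`early`/`late`), `delta_pct`,
#'   `source_qtls`.
#' @examples
#' inv <- example_input("inventory")
#' calls <- c(pf7.2 = "homologous", sss1.2 = "composite_shared_plus_SP",
#'            sss2.1 = "lineage_specific_SP")
#' collapse_inventory(inv, calls)
#' @export
collapse_inventory <- function(inventory, outcomes) {
  inventory <- validate_qtl_inventory(inventory)
  if (nrow(inventory) == 0) {
    return(empty_placements())
  }
  call_of <- function(id) {
    oc <- outcomes[[id]]
    if (is.null(oc)) return(NA_character_)
    if (inherits(oc, "allelism_outcome")) oc$call else as.character(oc)
  }
  terminal_branch <- c(SHxSL = "c", SPxSL = "d")
  rows <- list()
  add <- function(id, trait, branch, delta, sources) {
    rows[[length(rows) + 1]] <<- data.frame(
      mutation_id = id, trait = trait, branch = branch,
      epoch = if (branch == "b") "early" else "late",
      delta_pct = delta, source_qtls = paste(sources, collapse = "+"),
      stringsAsFactors = FALSE)
  }
  done <- character(0)
  for (i in seq_len(nrow(inventory))) {
    q <- inventory[i, ]
    if (q$qtl_id %in% done) next
    if (is.na(q$colocal_partner)) {
      add(q$qtl_id, q$trait, terminal_branch[[q$cross]], q$delta_pct,
          q$qtl_id)
      done <- c(done, q$qtl_id)
      next
    }
    j <- match(q$colocal_partner, inventory$qtl_id)
    p <- inventory[j, ]
    pair_ids <- c(q$qtl_id, p$qtl_id)
    call <- call_of(q$qtl_id)
    if (is.na(call)) call <- call_of(p$qtl_id)
    if (is.na(call)) {
      stop("co-localized pair ", paste(pair_ids, collapse = "/"),
           " has no allelism outcome")
    }
    sp_q <- if (q$cross == "SPxSL") q else p
    sh_q <- if (q$cross == "SHxSL") q else p
    base <- sub("_(SHxSL|SPxSL)$", "", q$qtl_id)
    switch(call,
      homologous = add(base, q$trait, "b",
                       mean(c(q$delta_pct, p$delta_pct)), pair_ids),
      composite_shared_plus_SP = {
        add(paste0(base, ".shared"), q$trait, "b", sh_q$delta_pct, pair_ids)
        add(paste0(base, ".SP"), q$trait, "d", sp_q$delta_pct, sp_q$qtl_id)
      },
      composite_shared_plus_SH = {
        add(paste0(base, ".shared"), q$trait, "b", sp_q$delta_pct, pair_ids)
        add(paste0(base, ".SH"), q$trait, "c", sh_q$delta_pct, sh_q$qtl_id)
      },
      lineage_specific_SP = {
        add(sp_q$qtl_id, sp_q$trait, "d", sp_q$delta_pct, sp_q$qtl_id)
        if (!isTRUE(sh_q$pollen_confounded)) {
          add(sh_q$qtl_id, sh_q$trait, "c", sh_q$delta_pct, sh_q$qtl_id)
        }
      },
      lineage_specific_SH = {
        add(sh_q$qtl_id, sh_q$trait, "c", sh_q$delta_pct, sh_q$qtl_id)
        if (!isTRUE(sp_q$pollen_confounded)) {
          add(sp_q$qtl_id, sp_q$trait, "d", sp_q$delta_pct, sp_q$qtl_id)
        }
      },
      no_sterility = {
        warning("co-localized pair ", paste(pair_ids, collapse = "/"),
                " called no_sterility; dropped from placements")
      },
      indeterminate = stop("allelism outcome for pair ",
                           paste(pair_ids, collapse = "/"),
                           " is indeterminate; resolve before placement"),
      stop("unknown allelism call '", call, "'")
    )
    done <- c(done, pair_ids)
  }
  out <- if (length(rows) == 0) empty_placements() else do.call(rbind, rows)
  class(out) <- c("mutation_placement", "data.frame")
  out
}

empty_placements <- function() {
  out <- data.frame(mutation_id = character(0), trait = character(0),
                    branch = character(0), epoch = character(0),
                    delta_pct = numeric(0), source_qtls = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_placement", "data.frame")
  out
}

#' Tabulate mutation placements into per-branch counts
#'
#' @param placements A `mutation_placement` data frame from
#'   [collapse_inventory()].
#' @param trait Optional trait filter (`"pollen"` or `"seed"`); default
#'   tabulates each trait present.
#' @return A data.frame of class `branch_counts` with one row per trait and
#'   columns `trait`, `n_b`, `n_c`, `n_d`, `n_total`, `n_early`, `n_late`.
#' @export
branch_counts <- function(placements, trait = NULL) {
  if (!is.null(trait)) {
    placements <- placements[placements$trait %in% trait, , drop = FALSE]
  }
  traits <- unique(placements$trait)
  if (length(traits) == 0) traits <- character(0)
  rows <- lapply(traits, function(tr) {
    br <- placements$branch[placements$trait == tr]
    make_branch_counts(sum(br == "b"), sum(br == "c"), sum(br == "d"), tr)
  })
  out <- if (length(rows) == 0) {
    make_branch_counts(0L, 0L, 0L, character(0))[0, ]
  } else do.call(rbind, rows)
  class(out) <- c("branch_counts", "data.frame")
  out
}

#' @rdname branch_counts
#' @param n_b,n_c,n_d Nonnegative mutation counts on branches `b`, `c`, `d`.
#' @export
make_branch_counts <- function(n_b, n_c, n_d, trait = NA_character_) {
  stopifnot(n_b >= 0, n_c >= 0, n_d >= 0)
  out <- data.frame(trait = trait, n_b = as.integer(n_b),
                    n_c = as.integer(n_c), n_d = as.integer(n_d),
                    stringsAsFactors = FALSE)
  out$n_total <- out$n_b + out$n_c + out$n_d
  out$n_early <- out$n_b
  out$n_late <- out$n_c + out$n_d
  class(out) <- c("branch_counts", "data.frame")
  out
}

#' Parsimony check that a shared mutation is derived on the internal branch
#'
#' A locus shared by the two donor crosses could in principle reflect a
#' derived-ancestral interaction, with the causal substitutions on the
#' recipient's terminal branch.  If additional crosses between the recipient
#' and species from its own side of the root show no QTL at the shared
#' location, parsimony favors a single derived mutation on the internal
#' donor branch `b`.
#'
#' @param extra_crosses Named list: for each additional recipient-sister
#'   species, the set (character vector) of QTL locations detected when
#'   crossed to the recipient.
#' @param shared_locus_location Location label of the shared locus, in the
#'   same coordinate system.
#' @return `"derived_on_b"` or `"possibly_ancestral"`.
#' @examples
#' derived_ancestral_check(list(SC = c("6@40"), SM = character(0)), "7@85")
#' @export
derived_ancestral_check <- function(extra_crosses, shared_locus_location) {
  if (length(extra_crosses) == 0) {
    warning("no additional crosses supplied; cannot exclude a ",
            "derived-ancestral history")
    return("possibly_ancestral")
  }
  hit <- vapply(extra_crosses, function(locs) {
    shared_locus_location %in% locs
  }, logical(1))
  if (any(hit)) "possibly_ancestral" else "derived_on_b"
}

#' Inflate late counts for possibly multi-mutation QTL
#'
#' Cross-unique ("late") QTL may be underpinned by more than one mutation.
#' This applies the extrapolation used in sensitivity analyses: a `fraction`
#' of lineage-specific QTL are assumed to hide a second mutation, so each
#' terminal-branch count is multiplied by `1 + fraction` and rounded to the
#' nearest whole number (ties away from zero).  The early count is unchanged.
#'
#' @param counts A one-row `branch_counts` object (or data frame row).
#' @param fraction Fraction of late QTL assumed to carry two mutations,
#'   in \[0, 1\].
#' @return A `branch_counts` row with inflated `n_c`, `n_d`.
#' @examples
#' extrapolate_counts(make_branch_counts(1, 7, 6, "pollen"))
#' @export
extrapolate_counts <- function(counts, fraction = 1 / 3) {
  stopifnot(fraction >= 0, fraction <= 1)
  out <- lapply(seq_len(nrow(counts)), function(i) {
    make_branch_counts(counts$n_b[i],
                       round_half_away(counts$n_c[i] * (1 + fraction)),
                       round_half_away(counts$n_d[i] * (1 + fraction)),
                       counts$trait[i])
  })
  out <- do.call(rbind, out)
  class(out) <- c("branch_counts", "data.frame")
  out
}

# nearest integer, ties away from zero (round() would go to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
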