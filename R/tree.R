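#' Three-taxon tree
#'
#' Container for the rooted three-taxon tree used throughout the package,
#' with topology `((X, Y), Z)` where `Z` is the recurrent (recipient) species
#' and `X`, `Y` are the two donor species.  Branch roles follow the usual
#' labelling: `a` is the terminal branch to the recipient, `b` the internal
#' stem shared by the two donors ("early"), and `c`, `d` the donor terminal
#' branches ("late").
#'
#' @param t_a,t_b,t_c,t_d Nonnegative branch lengths (substitutions/site or
#'   any consistent time unit).
#' @param taxa Optional character vector of length 3 naming the recipient,
#'   first donor (branch `c`) and second donor (branch `d`) tips.
#' @param tol Relative tolerance used when checking ultrametricity.
#'
#' @return An object of class `three_taxon_tree`: a list with elements
#'   `t_a`, `t_b`, `t_c`, `t_d`, `taxa`, `ultrametric` and, when ultrametric,
#'   `depth_T = t_b + t_c`.
#' @examples
#' three_taxon_tree(t_a = 1, t_b = 0.4, t_c = 0.6, t_d = 0.6)
#' @export
three_taxon_tree <- function(t_a, t_b, t_c, t_d,
                             taxa = c("SL", "SH", "SP"), tol = 1e-6) {
  len <- c(t_a = t_a, t_b = t_b, t_c = t_c, t_d = t_d)
  if (any(!is.finite(len)) || any(len < 0)) {
    stop("branch lengths must be finite and nonnegative")
  }
  scale <- max(len, 1e-12)
  ultra <- abs(t_c - t_d) <= tol * scale &&
    abs(t_a - (t_b + t_c)) <= tol * scale
  out <- list(t_a = t_a, t_b = t_b, t_c = t_c, t_d = t_d,
              taxa = taxa, ultrametric = ultra,
              depth_T = if (ultra) t_b + t_c else NA_real_)
  class(out) <- "three_taxon_tree"
  out
}

#' @export
print.three_taxon_tree <- function(x, ...) {
  cat("Three-taxon tree ((", x$taxa[2], ",", x$taxa[3], "),", x$taxa[1],
      ")\n", sep = "")
  cat(sprintf("  t_a = %.4g  t_b = %.4g  t_c = %.4g  t_d = %.4g\n",
              x$t_a, x$t_b, x$t_c, x$t_d))
  cat(sprintf("  ultrametric: %s", x$ultrametric))
  if (x$ultrametric) cat(sprintf("  (depth T = %.4g)", x$depth_T))
  cat("\n")
  invisible(x)
}

#' Read a three-taxon tree from a Newick file
#'
#' Parses a Newick tree, prunes it to the three named taxa (extra tips are
#' dropped with a message), checks that the induced topology is
#' `((donor1, donor2), recipient)` and maps branch lengths to roles
#' `a`/`b`/`c`/`d`.
#'
#' @param path Path to a Newick file (a text string starting with `(` is also
#'   accepted and parsed directly).
#' @param taxa Character vector of length 3: recipient, donor on branch `c`,
#'   donor on branch `d`.  Matched against tip labels exactly.
#' @return A [three_taxon_tree()].
#' @examples
#' tr <- read_tree("((SH:0.6,SP:0.6):0.4,SL:1.0);")
#' tr$t_b
#' @export
read_tree <- function(path, taxa = c("SL", "SH", "SP")) {
  stopifnot(length(taxa) == 3)
  phy <- if (grepl("^\\s*\\(", path)) {
    ape::read.tree(text = path)
  } else {
    ape::read.tree(path)
  }
  if (is.null(phy)) stop("could not parse Newick input: ", path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  missing <- setdiff(taxa, phy$tip.label)
  if (length(missing) > 0) {
    stop("taxa not found in tree: ", paste(missing, collapse = ", "))
  }
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  extra <- setdiff(phy$tip.label, taxa)
  if (length(extra) > 0) {
    message("pruning ", length(extra), " extra taxa: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")
    phy <- ape::keep.tip(phy, taxa)
  }
  phylo_to_three_taxon(phy, taxa)
}

# Map a pruned 3-tip phylo to branch roles; recipient must be the outgroup.
phylo_to_three_taxon <- function(phy, taxa) {
  recipient <- taxa[1]
  donors <- taxa[2:3]
  ntip <- length(phy$tip.label)
  stopifnot(ntip == 3)
  if (any(is.na(phy$edge.length))) stop("tree has missing branch lengths")
  # the internal (non-root) node must subtend exactly the two donors
  internal <- setdiff(unique(phy$edge[, 1]), phy$edge[phy$edge[, 2] > ntip, 2])
  root <- ape::Ntip(phy) + 1L
  kids_of_root <- phy$edge[phy$edge[, 1] == root, 2]
  tip_id <- function(lab) match(lab, phy$tip.label)
  rec_id <- tip_id(recipient)
  if (!(rec_id %in% kids_of_root)) {
    stop("wrong topology: recipient taxon '", recipient,
         "' is not sister to the (", donors[1], ",", donors[2], ") clade")
  }
  inner <- setdiff(kids_of_root, rec_id)
  if (length(inner) != 1 || inner <= ntip) {
    stop("wrong topology: expected ((", donors[1], ",", donors[2], "),",
         recipient, ")")
  }
  edge_len <- function(child) phy$edge.length[match(child, phy$edge[, 2])]
  t_a <- edge_len(rec_id)
  t_b <- edge_len(inner)
  t_c <- edge_len(tip_id(donors[1]))
  t_d <- edge_len(tip_id(donors[2]))
  three_taxon_tree(t_a, t_b, t_c, t_d, taxa = taxa)
}

#' Write a three-taxon tree to Newick
#'
#' @param tree A [three_taxon_tree()].
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "three_taxon_tree"))
  nwk <- sprintf("((%s:%.10g,%s:%.10g):%.10g,%s:%.10g);",
                 tree$taxa[2], tree$t_c, tree$taxa[3], tree$t_d,
                 tree$t_b, tree$taxa[1], tree$t_a)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Enforce a molecular clock by terminal-branch averaging
#'
#' Makes the tree ultrametric by replacing the two donor terminal branches
#' with their average and setting the recipient terminal branch to the root
#' depth `t_b + (t_c + t_d) / 2`.  The internal branch `t_b` is preserved and
#' the operation is idempotent.  This deliberately simple scheme replaces
#' penalized-likelihood rate smoothing, which is over-parameterized for a
#' three-taxon tree.
#'
#' @param tree A [three_taxon_tree()].
#' @return An ultrametric [three_taxon_tree()].
#' @examples
#' enforce_clock(three_taxon_tree(0.9, 0.4, 0.55, 0.65))
#' @export
enforce_clock <- function(tree) {
  stopifnot(inherits(tree, "three_taxon_tree"))
  tc <- (tree$t_c + tree$t_d) / 2
  three_taxon_tree(t_a = tree$t_b + tc, t_b = tree$t_b, t_c = tc, t_d = tc,
                   taxa = tree$taxa)
}

#' Tree sets
#'
#' A `tree_set` is a non-empty list of [three_taxon_tree()] objects, standing
#' in for a posterior sample of phylogenies over which model fits are
#' averaged.
#'
#' @param trees List of `three_taxon_tree` objects.
#' @param source_label Free-text provenance label.
#' @return An object of class `tree_set`.
#' @export
tree_set <- function(trees, source_label = "unspecified") {
  if (inherits(trees, "three_taxon_tree")) trees <- list(trees)
  stopifnot(length(trees) >= 1,
            all(vapply(trees, inherits, logical(1), "three_taxon_tree")))
  structure(list(trees = trees, source_label = source_label),
            class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat("Tree set (", length(x$trees), " trees; source: ", x$source_label,
      ")\n", sep = "")
  invisible(x)
}

#' @rdname tree_set
#' @param path Path to a (possibly multi-tree) Newick file.
#' @param taxa Taxa passed to [read_tree()].
#' @export
read_tree_set <- function(path, taxa = c("SL", "SH", "SP")) {
  phys <- ape::read.tree(path)
  if (inherits(phys, "phylo")) phys <- list(phys)
  trees <- lapply(phys, function(phy) {
    extra <- setdiff(phy$tip.label, taxa)
    if (length(extra) > 0) phy <- ape::keep.tip(phy, taxa)
    phylo_to_three_taxon(phy, taxa)
  })
  tree_set(trees, source_label = path)
}
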