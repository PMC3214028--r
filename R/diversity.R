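# Faith's phylogenetic diversity on the unrooted barcode tree: the sum of
# branch lengths of the minimal (Steiner) subtree connecting a tip subset.

#' Faith's phylogenetic diversity
#'
#' PD of a tip subset is the total branch length of the minimal
#' connecting subtree spanning the subset on the unrooted tree: an edge
#' contributes iff both sides of its bipartition contain at least one
#' subset tip.  No root edge is included (the tree is unrooted).
#'
#' @param tree a `phylo` with branch lengths
#' @param tip_subset character vector of >= 2 tip labels (PD of a
#'   singleton is undefined without a root)
#' @return an object of class `pd_result`: list with `pd_value`,
#'   `tip_subset`, `fraction_of_species_represented` (percent of the
#'   tree's tips included)
#' @export
faith_pd <- function(tree, tip_subset) {
  tips <- tree$tip.label
  unknown <- setdiff(tip_subset, tips)
  if (length(unknown) > 0L)
    stop("input-error: unknown tip(s): ", paste(unknown, collapse = ", "))
  tip_subset <- unique(tip_subset)
  if (length(tip_subset) < 2L)
    stop("input-error: PD needs at least 2 tips (unrooted tree)")
  if (is.null(tree$edge.length))
    stop("input-error: tree has no branch lengths")
  sides <- .edge_tip_sets(tree)
  # an edge is on the minimal spanning subtree iff removing it separates
  # subset tips: some below it AND some above it
  inside <- vapply(sides, function(s) {
    k <- sum(tip_subset %in% s)
    k > 0L && k < length(tip_subset)
  }, logical(1L))
  pd <- sum(tree$edge.length[inside])
  structure(list(pd_value = pd, tip_subset = tip_subset,
                 fraction_of_species_represented =
                   100 * length(tip_subset) / length(tips)),
            class = "pd_result")
}

#' @export
print.pd_result <- function(x, ...) {
  cat(sprintf("pd_result: PD = %.6g over %d tips (%.1f%% of tree)\n",
              x$pd_value, length(x$tip_subset),
              x$fraction_of_species_represented))
  invisible(x)
}
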