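# Hypothetical-species delimitation: maximal monophyletic groups with zero
# pairwise distance, richness estimation with amplification-error
# correction, and the two accuracy statistics (species discrimination and
# richness estimation accuracy).

# round half away from zero, to integer percent
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer percentage, rounding halves away from zero
#' @param num,den numerator and denominator
#' @return integer percent
#' @export
percent_of <- function(num, den) as.integer(.round_half_up(100 * num / den))

#' Maximal zero-distance monophyletic clusters
#'
#' For each tip, finds the largest monophyletic group (a side of some
#' bipartition of the unrooted tree; singletons and the full tip set
#' count) containing it whose members are pairwise at distance exactly
#' zero.  "Zero" is the identity relation carried by the distance
#' matrix (`zero`): identical retained nucleotide columns and, when
#' present, identical binary indel characters — never a numeric
#' tolerance.  The distinct maximal groups form a partition of the tips.
#'
#' @param tree `phylo` whose tips equal the matrix ids
#' @param dm a `barcode_dist`
#' @return list of character vectors (the clusters), sorted by first
#'   member id
#' @export
zero_distance_clusters <- function(tree, dm) {
  stopifnot(inherits(dm, "barcode_dist"))
  tips <- tree$tip.label
  if (!setequal(tips, dm$sample_ids))
    stop("input-error: tree tips and distance matrix ids differ")
  if (dm$degenerate || any(is.na(dm$d)))
    stop("input-error: undefined (degenerate or saturated) distances")
  n <- length(tips)
  # identity class per tip from the exact-zero relation
  zero <- dm$zero[tips, tips, drop = FALSE]
  cls <- apply(zero, 1L, function(r) which(r)[1L])
  # candidate clades: every bipartition side, its complement, full set
  sides <- .edge_tip_sets(tree)
  cands <- c(sides, lapply(sides, function(s) setdiff(tips, s)), list(tips))
  cands <- unique(lapply(cands, sort))
  cands <- cands[lengths(cands) > 0L]
  zerodiam <- vapply(cands, function(s) length(unique(cls[s])) == 1L,
                     logical(1L))
  zcands <- cands[zerodiam]
  assign_of <- vector("list", n)
  names(assign_of) <- tips
  for (t in tips) {
    holds <- zcands[vapply(zcands, function(s) t %in% s, logical(1L))]
    sz <- lengths(holds)
    best <- holds[sz == max(sz)]
    best <- best[order(vapply(best, paste, "", collapse = "\r"))]
    assign_of[[t]] <- best[[1L]]
  }
  clusters <- unique(assign_of)
  # the maximality argument guarantees a partition; assert it
  all_members <- unlist(clusters)
  if (anyDuplicated(all_members) || !setequal(all_members, tips))
    stop("internal error: clusters do not partition the tips")
  clusters[order(vapply(clusters, `[`, "", 1L))]
}

#' Corrected species richness estimate
#'
#' The richness estimate is the number of maximal zero-distance
#' monophyletic clusters minus the number of known amplification errors
#' (contaminant sequences that would otherwise inflate the estimate).
#'
#' @param partition cluster list from [zero_distance_clusters()]
#' @param n_errors non-negative count of amplification errors, at most
#'   the cluster count
#' @return integer corrected estimate
#' @export
richness_estimate <- function(partition, n_errors = 0L) {
  k <- length(partition)
  if (n_errors < 0L) stop("input-error: n_errors must be >= 0")
  if (n_errors > k)
    stop("input-error: n_errors (", n_errors,
         ") exceeds cluster count (", k, ")")
  as.integer(k - n_errors)
}

#' Species discrimination accuracy
#'
#' A species is distinguished iff the set of its samples is exactly one
#' cluster (no foreign samples, not split).  Discrimination accuracy is
#' the rounded integer percentage of species in the alignment that are
#' distinguished.
#'
#' @param partition cluster list from [zero_distance_clusters()]
#' @param species_labels named character vector: sample id -> true
#'   species, covering every sample in the partition
#' @return list: `species_resolved`, `not_resolved`,
#'   `present_in_alignment`, `discrimination_accuracy` (integer %),
#'   `discrimination_accuracy_exact`, `resolved_species` (names)
#' @export
score_discrimination <- function(partition, species_labels) {
  samples <- unlist(partition)
  missing <- setdiff(samples, names(species_labels))
  if (length(missing) > 0L)
    stop("input-error: samples lacking species label: ",
         paste(missing, collapse = ", "))
  species_labels <- species_labels[samples]
  species <- unique(species_labels)
  keys <- vapply(partition, function(s) paste(sort(s), collapse = "\r"), "")
  resolved <- vapply(species, function(sp) {
    mem <- sort(names(species_labels)[species_labels == sp])
    paste(mem, collapse = "\r") %in% keys
  }, logical(1L))
  n_sp <- length(species)
  n_res <- sum(resolved)
  list(species_resolved = n_res,
       not_resolved = n_sp - n_res,
       present_in_alignment = n_sp,
       discrimination_accuracy = percent_of(n_res, n_sp),
       discrimination_accuracy_exact = 100 * n_res / n_sp,
       resolved_species = species[resolved])
}

#' Species richness estimation accuracy
#'
#' The corrected estimate divided by the number of species truly
#' present in the plot, as a rounded integer percentage.  May exceed
#' 100 when the data over-estimate.
#'
#' @param corrected_estimate error-corrected richness estimate
#' @param present_in_plot true species count in the plot (>= 1)
#' @return integer percent
#' @export
score_estimation <- function(corrected_estimate, present_in_plot) {
  if (present_in_plot < 1L)
    stop("input-error: present_in_plot must be >= 1")
  percent_of(corrected_estimate, present_in_plot)
}

#' Run the full delimitation step on one tree + distance matrix
#'
#' Convenience wrapper producing a `delimitation_result`: the cluster
#' partition, raw and error-corrected richness estimates, and (when
#' species labels are supplied, i.e. known-flora mode) the accuracy
#' summary.  In unknown-flora mode the label-dependent fields are
#' absent, never zero-filled.
#'
#' @param tree `phylo` from [nj_build()]
#' @param dm `barcode_dist` that produced the tree
#' @param n_errors known amplification-error count
#' @param species_labels optional named vector sample id -> species
#' @param present_in_plot optional true plot richness (enables
#'   estimation accuracy)
#' @return a `delimitation_result`
#' @export
delimit <- function(tree, dm, n_errors = 0L, species_labels = NULL,
                    present_in_plot = NULL) {
  clusters <- zero_distance_clusters(tree, dm)
  est <- length(clusters)
  corrected <- richness_estimate(clusters, n_errors)
  res <- list(clusters = clusters,
              richness_estimate = est,
              n_amplification_errors = as.integer(n_errors),
              corrected_estimate = corrected)
  if (!is.null(species_labels)) {
    res <- c(res, score_discrimination(clusters, species_labels))
    if (!is.null(present_in_plot)) {
      res$present_in_plot <- as.integer(present_in_plot)
      res$estimation_accuracy <- score_estimation(corrected, present_in_plot)
      res$estimation_accuracy_exact <- 100 * corrected / present_in_plot
    }
  }
  structure(res, class = "delimitation_result")
}

#' @export
print.delimitation_result <- function(x, ...) {
  cat(sprintf("delimitation_result: %d cluster(s), corrected estimate %d (%d error(s))\n",
              x$richness_estimate, x$corrected_estimate,
              x$n_amplification_errors))
  if (!is.null(x$discrimination_accuracy))
    cat(sprintf("  discrimination: %d/%d resolved (%d%%)\n",
                x$species_resolved, x$present_in_alignment,
                x$discrimination_accuracy))
  if (!is.null(x$estimation_accuracy))
    cat(sprintf("  estimation: %d vs %d in plot (%d%%)\n",
                x$corrected_estimate, x$present_in_plot,
                x$estimation_accuracy))
  invisible(x)
}
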