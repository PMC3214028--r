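# Deterministic Saitou-Nei neighbor joining on a distance matrix, plus
# nonparametric bootstrap supports and the unrooted monophyly test.
# Determinism rules: Q-criterion ties are broken by the lexicographically
# smallest pair of cluster representatives (a cluster is represented by its
# smallest tip id); negative branch lengths are clamped to 0 with the
# deficit moved to the sibling edge created at the same join.

.dist_input <- function(dm) {
  if (inherits(dm, "barcode_dist")) {
    if (dm$degenerate)
      stop("input-error: degenerate alignment, distances undefined")
    if (any(is.na(dm$d))) {
      bad <- which(is.na(dm$d) & upper.tri(dm$d), arr.ind = TRUE)[1L, ]
      stop("input-error: undefined (saturated) distance between '",
           dm$sample_ids[bad[1L]], "' and '", dm$sample_ids[bad[2L]], "'")
    }
    dm$d
  } else {
    D <- as.matrix(dm)
    if (is.null(rownames(D))) stop("input-error: distance matrix needs ids")
    if (anyNA(D)) stop("input-error: undefined distances in matrix")
    D
  }
}

.fmt_bl <- function(x) sprintf("%.12g", x)

#' Build a neighbor-joining tree
#'
#' Saitou-Nei NJ with the Q criterion.  Fully deterministic: ties in Q
#' are broken by the lexicographically smallest pair of cluster
#' representatives, and a negative branch length is clamped to zero with
#' the deficit transferred to its sibling edge (the total joined path
#' length is preserved).
#'
#' Samples at pairwise distance exactly 0 are collapsed to one
#' representative before the joining loop and re-attached afterwards as
#' a zero-branch-length fan (multifurcation).  With zero-length edges
#' the NJ topology is metrically degenerate -- Q ties exactly between
#' joining two identical tips and joining one of them with a neighbour
#' -- so without the collapse an identity class can come out
#' non-monophyletic on numerical noise.  Collapsing guarantees every
#' zero-distance class is a clade, which the delimitation step
#' presupposes.
#'
#' @param dm a `barcode_dist` or a symmetric labelled matrix; at least 3
#'   samples, no undefined entries
#' @return an unrooted `phylo` tree with branch lengths in
#'   substitutions/site
#' @export
nj_build <- function(dm) {
  Dfull <- .dist_input(dm)
  n <- nrow(Dfull)
  if (n < 3L) stop("input-error: need at least 3 samples for NJ")
  # collapse exact-zero identity classes; for a barcode_dist the identity
  # relation additionally includes binary indel characters (finer than
  # d == 0), so indel-distinct samples stay separate backbone tips
  zero_rel <- if (inherits(dm, "barcode_dist"))
    dm$zero[rownames(Dfull), rownames(Dfull), drop = FALSE]
  else Dfull == 0
  ids <- rownames(Dfull)
  ord_ids <- order(ids)
  cls <- rep(NA_integer_, n)
  nc <- 0L
  for (i in ord_ids) {
    if (!is.na(cls[i])) next
    nc <- nc + 1L
    members <- which(zero_rel[i, ])
    if (!all(zero_rel[members, members]))
      stop("input-error: zero-distance relation is not transitive")
    cls[members] <- nc
  }
  reps <- vapply(seq_len(nc), function(k) min(ids[cls == k]), "")
  frag0 <- vapply(seq_len(nc), function(k) {
    mem <- sort(ids[cls == k])
    if (length(mem) == 1L) mem
    else paste0("(", paste0(mem, ":0", collapse = ","), ")")
  }, "")
  if (nc == 1L)
    return(ape::read.tree(text = paste0(frag0, ";")))
  D <- Dfull[match(reps, ids), match(reps, ids), drop = FALSE]
  rownames(D) <- colnames(D) <- reps
  if (nc == 2L) {
    h <- D[1L, 2L] / 2
    return(ape::read.tree(text = paste0(
      "(", frag0[1L], ":", .fmt_bl(h), ",", frag0[2L], ":", .fmt_bl(h),
      ");")))
  }
  rep_lab <- reps                        # cluster representative ids
  frag <- frag0                          # newick fragments
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    # deterministic tie-break on representative id pairs
    key1 <- pmin(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]])
    key2 <- pmax(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newfrag <- paste0("(", frag[i], ":", .fmt_bl(li), ",",
                      frag[j], ":", .fmt_bl(lj), ")")
    newrep <- min(rep_lab[i], rep_lab[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    lab2 <- c(rep_lab[keep], newrep)
    rownames(D2) <- colnames(D2) <- make.unique(lab2)
    D <- D2
    rep_lab <- lab2
    frag <- c(frag[keep], newfrag)
  }
  # closed form for the final three clusters
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- paste0("(", frag[1L], ":", .fmt_bl(la), ",",
                frag[2L], ":", .fmt_bl(lb), ",",
                frag[3L], ":", .fmt_bl(lc), ");")
  ape::read.tree(text = nwk)
}

# tip-label set below each edge (edge index = row of tree$edge)
.edge_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    p <- ord[k, 1L]; ch <- ord[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)),
         function(k) sort(sets[[tree$edge[k, 2L]]]))
}

.split_key <- function(tips) paste(sort(tips), collapse = "\r")

# canonical keys for the nontrivial bipartitions of an unrooted tree:
# each split is represented by the side NOT containing the reference tip
.tree_split_keys <- function(tree) {
  alltips <- sort(tree$tip.label)
  ref <- alltips[1L]
  sides <- .edge_tip_sets(tree)
  keys <- vapply(sides, function(s) {
    if (ref %in% s) s <- setdiff(alltips, s)
    .split_key(s)
  }, "")
  n <- length(tree$tip.label)
  sizes <- lengths(sides)
  unique(keys[sizes > 1L & sizes < n - 1L])   # nontrivial only
}

#' Test monophyly of a tip set on an unrooted tree
#'
#' TRUE iff the subset (or its complement) is exactly one side of some
#' edge of the unrooted tree.  Singletons and the full tip set are
#' always monophyletic.
#'
#' @param tree a `phylo`
#' @param tip_subset non-empty character vector of tip labels
#' @return logical
#' @export
is_clade <- function(tree, tip_subset) {
  if (length(tip_subset) == 0L) stop("input-error: empty tip subset")
  tips <- tree$tip.label
  unknown <- setdiff(tip_subset, tips)
  if (length(unknown) > 0L)
    stop("input-error: unknown tip(s): ", paste(unknown, collapse = ", "))
  tip_subset <- unique(tip_subset)
  k <- length(tip_subset)
  if (k == 1L || k == length(tips)) return(TRUE)
  key <- .split_key(tip_subset)
  ckey <- .split_key(setdiff(tips, tip_subset))
  sides <- vapply(.edge_tip_sets(tree), .split_key, "")
  key %in% sides || ckey %in% sides
}

#' Nonparametric bootstrap supports
#'
#' Resamples alignment columns with replacement, re-runs the full
#' distance + NJ pipeline per replicate, and reports for each internal
#' edge of the reference tree the percentage of replicates containing
#' its bipartition.  Supports are stored as internal `node.label`s
#' (empty at the basal node).  Replicates whose pipeline fails (e.g.
#' saturated distances) count against the support.
#'
#' @param aln the `locus_alignment` that produced `tree`'s distances
#' @param tree reference `phylo` from [nj_build()]
#' @param n_reps number of replicates (>= 1)
#' @param seed integer seed; fixes all replicate column draws
#' @return `tree` with `node.label` supports and attribute
#'   `"support_table"` (data.frame of split, support)
#' @export
bootstrap_supports <- function(aln, tree, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1L) stop("input-error: n_reps must be >= 1")
  cd <- suppressWarnings(complete_deletion(aln))
  if (isTRUE(attr(cd, "degenerate")))
    stop("input-error: degenerate alignment")
  L <- alignment_length(cd)
  m <- alignment_matrix(cd)
  set.seed(as.integer(seed))
  draws <- matrix(sample.int(L, L * n_reps, replace = TRUE), nrow = n_reps)
  want <- .tree_split_keys(tree)
  hits <- setNames(numeric(length(want)), want)
  for (b in seq_len(n_reps)) {
    rep_aln <- .alignment_from_matrix(m[, draws[b, ], drop = FALSE], cd)
    got <- tryCatch(.tree_split_keys(nj_build(distance_matrix(rep_aln))),
                    error = function(e) character(0))
    hits[want %in% got] <- hits[want %in% got] + 1
  }
  supp <- 100 * hits / n_reps
  # attach supports as internal node labels
  ntip <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  sides <- .edge_tip_sets(tree)
  alltips <- sort(tree$tip.label)
  ref <- alltips[1L]
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2L]
    if (ch <= ntip) next
    s <- sides[[k]]
    if (ref %in% s) s <- setdiff(alltips, s)
    key <- .split_key(s)
    if (key %in% names(supp))
      labs[ch - ntip] <- sprintf("%g", round(supp[[key]]))
  }
  tree$node.label <- labs
  attr(tree, "support_table") <-
    data.frame(split = gsub("\r", "|", names(supp)),
               support = unname(supp), stringsAsFactors = FALSE)
  tree
}
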