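# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written with different algorithms/data paths
# than the package internals they check.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(L, pi = rep(0.25, 4)) {
  paste(sample(BASES, L, replace = TRUE, prob = pi), collapse = "")
}

# mutate k sites to a different base, uniformly
mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), k)
  v[idx] <- vapply(v[idx],
                   function(b) sample(setdiff(BASES, b), 1L), "")
  paste(v, collapse = "")
}

# ---- distances -------------------------------------------------------------

# brute-force pooled pair/site tally (oracle for pool_substitution_counts)
oracle_pool_counts <- function(seqs) {
  rows <- strsplit(seqs, "")
  N <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  n <- length(rows)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    for (s in seq_along(rows[[i]])) {
      a <- rows[[i]][s]; b <- rows[[j]][s]
      if (a == b) N[a, a] <- N[a, a] + 1
      else { N[a, b] <- N[a, b] + 1; N[b, a] <- N[b, a] + 1 }
    }
  }
  N
}

# independent scalar TN93 closed form (method-of-moments inversion)
oracle_tn93_closed_form <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  L <- length(a)
  pi <- table(factor(c(a, b), levels = BASES)) / (2 * L)
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  piR <- piA + piG; piY <- piC + piT
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / L
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / L
  Q <- sum(a != b) / L - P1 - P2
  w1 <- 1 - piR * P1 / (2 * piA * piG) - Q / (2 * piR)
  w2 <- 1 - piY * P2 / (2 * piC * piT) - Q / (2 * piY)
  w3 <- 1 - Q / (2 * piR * piY)
  -2 * piA * piG / piR * log(w1) - 2 * piC * piT / piY * log(w2) -
    2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY) * log(w3)
}

# evolve one K2P pair-end: sample child bases given parent, branch length t
# (substitutions/site), transition/transversion rate ratio kappa
k2p_evolve <- function(parent, t, kappa) {
  # rates: transition alpha = kappa*beta, two transversions beta each;
  # normalized total rate alpha + 2 beta = 1
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  ee_b <- exp(-4 * beta * t)
  ee_ab <- exp(-2 * (alpha + beta) * t)
  p_same <- 0.25 + 0.25 * ee_b + 0.5 * ee_ab
  p_ts <- 0.25 + 0.25 * ee_b - 0.5 * ee_ab
  p_tv <- 0.25 - 0.25 * ee_b                      # each of 2 transversions
  TS <- c(A = "G", G = "A", C = "T", T = "C")
  TV <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
             T = c("A", "G"))
  vapply(parent, function(bse) {
    u <- runif(1)
    if (u < p_same) bse
    else if (u < p_same + p_ts) TS[[bse]]
    else TV[[bse]][1L + (u > p_same + p_ts + p_tv)]
  }, "", USE.NAMES = FALSE)
}

# star-topology K2P sample: n sequences at pairwise divergence d
k2p_star <- function(n, L, d, kappa) {
  anc <- sample(BASES, L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i)
    paste(k2p_evolve(anc, d / 2, kappa), collapse = ""), "")
  setNames(seqs, sprintf("s%02d", seq_len(n)))
}

# ---- trees -----------------------------------------------------------------

# components of the tree after deleting edge k: BFS over the remaining
# edges (independent of the package's postorder accumulation)
oracle_edge_side <- function(tree, k) {
  edges <- tree$edge[-k, , drop = FALSE]
  adj <- rbind(edges, edges[, 2:1])
  start <- tree$edge[k, 2L]
  seen <- start
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- adj[adj[, 1L] %in% frontier, 2L]
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(tree$tip.label[seen[seen <= length(tree$tip.label)]])
}

oracle_all_sides <- function(tree) {
  lapply(seq_len(nrow(tree$edge)), function(k) oracle_edge_side(tree, k))
}

# brute-force maximal zero-diameter clade partition
oracle_zero_clusters <- function(tree, dm) {
  tips <- tree$tip.label
  sides <- oracle_all_sides(tree)
  cands <- unique(c(sides, lapply(sides, function(s) sort(setdiff(tips, s))),
                    list(sort(tips))))
  cands <- cands[lengths(cands) > 0L]
  zd <- vapply(cands, function(s) all(dm$zero[s, s]), logical(1L))
  zc <- cands[zd]
  out <- lapply(tips, function(t) {
    h <- zc[vapply(zc, function(s) t %in% s, logical(1L))]
    h[[which.max(lengths(h))]]
  })
  unique(out)
}

# PD oracle: union of edges on all tip-to-tip paths (via ape::nodepath)
oracle_pd <- function(tree, subset) {
  idx <- match(subset, tree$tip.label)
  ekey <- paste(tree$edge[, 1L], tree$edge[, 2L])
  used <- character(0)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i >= j) next
    np <- ape::nodepath(tree, idx[i], idx[j])
    for (k in seq_len(length(np) - 1L)) {
      e <- c(paste(np[k], np[k + 1L]), paste(np[k + 1L], np[k]))
      used <- union(used, e[e %in% ekey])
    }
  }
  sum(tree$edge.length[ekey %in% used])
}

# random test alignment with duplicate groups (for delimitation oracles)
random_cluster_alignment <- function(n_tips, L = 120L) {
  n_classes <- sample(2:max(2L, n_tips - 1L), 1L)
  base <- rand_seq(L)
  class_seqs <- c(base, vapply(seq_len(n_classes - 1L), function(i)
    mutate_seq(base, sample(2:6, 1L)), ""))
  cls <- sort(c(seq_len(n_classes),
                sample(n_classes, n_tips - n_classes, replace = TRUE)))
  seqs <- setNames(class_seqs[cls], sprintf("t%02d", seq_len(n_tips)))
  locus_alignment(seqs, "sim")
}
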