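# Plot-survey simulator with full ground truth.  The generator emulates a
# ~0.1 ha rainforest plot survey: ~100 stems from ~35 species, three
# chloroplast barcode loci with lineage-specific amplification failure,
# occasional contaminant ("amplification error") sequences, star-shaped
# intraspecific variation, and -- at the hypervariable spacer locus only --
# a short reverse-complement inversion polymorphism and indel polymorphism.

#' Survey generator configuration
#'
#' Defaults are sized to the kind of plot the pipeline targets: two
#' official barcode loci plus a hypervariable spacer (550/850/450 bp),
#' ~35 species with geometrically distributed stem counts of mean 3
#' (~100 stems), a Yule species tree rescaled to an expected root-to-tip
#' depth of 0.15 substitutions/site, intraspecific variation at 1% of
#' the interspecific scale, locus-specific amplification failure with a
#' 5-fold lineage effect on the matK-like locus, and 1% contamination.
#'
#' @param n_species number of species in the plot (>= 2)
#' @param stems_mean mean stems per species (geometric, minimum 1)
#' @param loci data.frame with columns locus_id, length, rate,
#'   fail_prob, lineage_fail_mult, hypervariable
#' @param tree_scale expected root-to-tip depth (substitutions/site)
#' @param min_split_depth minimum pairwise interspecific divergence
#'   (substitutions/site): species-tree node heights are floored at
#'   half this value.  The default (0.003) keeps every interspecific
#'   divergence at least 20x the default expected intraspecific
#'   pairwise distance, i.e. species are barcode-resolvable taxa
#' @param birth,death birth-death rates of the species tree
#' @param intraspecific_fraction ratio of within- to between-species
#'   expected divergence (0 = clones); scalar or one value per locus.
#'   Defaults reflect a coding/conserved locus pair with essentially no
#'   intraspecific variation and a hypervariable spacer with rare
#'   intraspecific variants
#' @param contamination_prob per sample-locus probability of an
#'   amplification error (contaminant sequence)
#' @param inversion_prob per-species probability of carrying the
#'   inversion polymorphism at the hypervariable locus
#' @param inversion_len inversion length in bp
#' @param indel_prob per-species probability of a diagnostic indel at
#'   the hypervariable locus
#' @param pi,kappa1,kappa2 TN93 parameters of sequence evolution
#' @param plot_id plot identifier written to the metadata
#' @param seed integer seed fixing the survey byte-for-byte
#' @return a `survey_config` list
#' @export
survey_config <- function(n_species = 35L,
                          stems_mean = 3,
                          loci = data.frame(
                            locus_id = c("rbcLa", "matK", "trnH-psbA"),
                            length = c(550L, 850L, 450L),
                            rate = c(0.8, 1.0, 1.5),
                            fail_prob = c(0.02, 0.25, 0.08),
                            lineage_fail_mult = c(1, 5, 1),
                            hypervariable = c(FALSE, FALSE, TRUE),
                            stringsAsFactors = FALSE),
                          tree_scale = 0.15,
                          min_split_depth = 0.003,
                          birth = 1, death = 0,
                          intraspecific_fraction = c(5e-4, 5e-4, 2e-3),
                          contamination_prob = 0.01,
                          inversion_prob = 0.05,
                          inversion_len = 6L,
                          indel_prob = 0.10,
                          pi = c(A = 0.30, C = 0.19, G = 0.21, T = 0.30),
                          kappa1 = 2, kappa2 = 2,
                          plot_id = "plot1",
                          seed = 1L) {
  stopifnot(n_species >= 2L, stems_mean >= 1,
            all(c(loci$fail_prob, contamination_prob, inversion_prob,
                  indel_prob) >= 0),
            all(c(loci$fail_prob, contamination_prob, inversion_prob,
                  indel_prob) <= 1),
            abs(sum(pi) - 1) < 1e-9)
  structure(as.list(environment()), class = "survey_config")
}

#' Simulate an ultrametric species tree
#'
#' Birth-death tree over the configured species count, rescaled so the
#' root-to-tip depth equals `tree_scale` exactly (hence mean pairwise
#' distance scales linearly with `tree_scale`).
#'
#' @param config a `survey_config`
#' @param seed seed (default `config$seed`)
#' @return ultrametric `phylo` with tips `sp01`, `sp02`, ...
#' @export
simulate_species_tree <- function(config, seed = config$seed) {
  set.seed(as.integer(seed))
  tr <- ape::rphylo(config$n_species, birth = config$birth,
                    death = config$death, fossils = FALSE)
  depth <- max(ape::node.depth.edgelength(tr))
  if (depth > 0) tr$edge.length <- tr$edge.length * config$tree_scale / depth
  # floor node heights so the shallowest split still separates species
  h0 <- config$min_split_depth / 2
  if (h0 > 0) {
    n <- length(tr$tip.label)
    dep <- ape::node.depth.edgelength(tr)
    h <- max(dep) - dep                  # height above the tips
    h[seq_len(n)] <- 0
    idx <- seq(n + 1L, n + tr$Nnode)
    h[idx] <- pmax(h[idx], h0)
    tr$edge.length <- h[tr$edge[, 1L]] - h[tr$edge[, 2L]]
  }
  tr$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
  tr
}

# evolve one sequence one edge under TN93 (encoded bases 1..4)
.evolve_edge <- function(x, t, pi, k1, k2) {
  if (t <= 0) return(x)
  P <- .tn93_P(t, pi, k1, k2)
  out <- x
  for (b in 1:4) {
    idx <- which(x == b)
    if (length(idx))
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
  }
  out
}

# species-level sequences for one locus down the tree
.evolve_locus <- function(tree, L, rate, pi, k1, k2) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  seqs <- vector("list", nn)
  root <- n + 1L
  seqs[[root]] <- sample.int(4L, L, replace = TRUE, prob = pi)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- tree$edge.length[match(paste(ord[, 1], ord[, 2]),
                                 paste(tree$edge[, 1], tree$edge[, 2]))]
  for (k in seq_len(nrow(ord)))
    seqs[[ord[k, 2L]]] <- .evolve_edge(seqs[[ord[k, 1L]]], lens[k] * rate,
                                       pi, k1, k2)
  out <- do.call(rbind, seqs[seq_len(n)])
  rownames(out) <- tree$tip.label
  out
}

#' Evolve per-stem, per-locus sequences
#'
#' Species-level sequences evolve under TN93 down the species tree per
#' locus; each stem is then an independent copy of its species sequence
#' mutated at the intraspecific per-site rate (star-shaped
#' intraspecific variation, no within-species coalescent).  At the
#' hypervariable locus a conserved motif region is planted and, for
#' carrier species, reverse-complemented in a minority of stems; indel
#' polymorphisms replace a short extent with gaps for all stems of a
#' carrier species.
#'
#' @param tree species tree from [simulate_species_tree()]
#' @param config a `survey_config`
#' @param seed seed (default `config$seed + 1`)
#' @return list with `stems` (data.frame sample_id, species),
#'   `stem_seqs` (list per locus of named character vectors),
#'   `inversions` and `indels` truth data.frames
#' @export
evolve_sequences <- function(tree, config, seed = config$seed + 1L) {
  set.seed(as.integer(seed))
  nsp <- config$n_species
  sp <- tree$tip.label
  # stem counts: 1 + geometric with mean stems_mean
  counts <- 1L + rgeom(nsp, prob = 1 / config$stems_mean)
  stems <- data.frame(
    sample_id = sprintf("st%03d", seq_len(sum(counts))),
    species = rep(sp, counts), stringsAsFactors = FALSE)
  p_intra_by_locus <- rep(config$intraspecific_fraction,
                          length.out = nrow(config$loci)) * config$tree_scale
  stem_seqs <- list()
  inversions <- data.frame(locus_id = character(0), species = character(0),
                           sample_id = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
  indels <- data.frame(locus_id = character(0), species = character(0),
                       start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE)
  for (li in seq_len(nrow(config$loci))) {
    locus <- config$loci$locus_id[li]
    L <- config$loci$length[li]
    spseq <- .evolve_locus(tree, L, config$loci$rate[li], config$pi,
                           config$kappa1, config$kappa2)
    x <- spseq[stems$species, , drop = FALSE]
    # star-shaped intraspecific variation
    p_intra <- p_intra_by_locus[li]
    if (p_intra > 0) {
      nmut <- rbinom(nrow(x), L, p_intra)
      for (r in which(nmut > 0)) {
        sites <- sample.int(L, nmut[r])
        shift <- sample.int(3L, nmut[r], replace = TRUE)
        x[r, sites] <- 1L + (x[r, sites] - 1L + shift) %% 4L
      }
    }
    chars <- matrix(.BASES[x], nrow = nrow(x))
    rownames(chars) <- stems$sample_id
    if (config$loci$hypervariable[li]) {
      if (config$inversion_prob > 0 && config$inversion_len >= 4L) {
        # conserved motif region: fixed flanks + non-palindromic core
        core <- strsplit("TTTTAT", "")[[1]]
        if (config$inversion_len != 6L) {
          repeat {
            core <- sample(.BASES, config$inversion_len, replace = TRUE)
            if (paste(core, collapse = "") !=
                reverse_complement(paste(core, collapse = ""))) break
          }
        }
        w0 <- as.integer(floor(L / 2))        # 1-based start of core
        fl <- strsplit("GCAG", "")[[1]]; fr <- strsplit("CTGC", "")[[1]]
        region <- (w0 - 4L):(w0 + length(core) + 3L)
        chars[, region] <- matrix(rep(c(fl, core, fr), each = nrow(chars)),
                                  nrow = nrow(chars))
        carriers <- sp[runif(nsp) < config$inversion_prob]
        for (s in carriers) {
          idx <- which(stems$species == s)
          k <- sample.int(length(idx), 1L)    # a minority of stems
          flip <- idx[sample(length(idx), min(k, max(1L, length(idx) - 1L)))]
          rcc <- rev(.COMPLEMENT[core])
          for (r in flip)
            chars[r, w0:(w0 + length(core) - 1L)] <- rcc
          inversions <- rbind(inversions, data.frame(
            locus_id = locus, species = s,
            sample_id = stems$sample_id[flip],
            start = w0 - 1L, end = w0 - 1L + length(core),
            stringsAsFactors = FALSE))
        }
      }
      if (config$indel_prob > 0) {
        carriers <- sp[runif(nsp) < config$indel_prob]
        for (s in carriers) {
          glen <- sample(3:9, 1L)
          gs <- sample.int(L - glen - 20L, 1L) + 10L   # interior
          chars[stems$species == s, gs:(gs + glen - 1L)] <- "-"
          indels <- rbind(indels, data.frame(
            locus_id = locus, species = s, start = gs - 1L,
            end = gs - 1L + glen, stringsAsFactors = FALSE))
        }
      }
    }
    stem_seqs[[locus]] <- setNames(apply(chars, 1L, paste, collapse = ""),
                                   stems$sample_id)
  }
  list(stems = stems, stem_seqs = stem_seqs,
       inversions = inversions, indels = indels)
}

#' Apply amplification failures and contamination errors
#'
#' Samples a status (`ok`/`fail`/`error`) per stem and locus.  Failure
#' probability is the locus base rate, multiplied by the lineage effect
#' for species inside one randomly chosen clade when the locus has
#' `lineage_fail_mult > 1` (emulating lineage-specific primer failure).
#' Error samples keep a sequence, but it is swapped for the sequence of
#' the most distant species (a contaminant).
#'
#' @param tree species tree
#' @param evolved result of [evolve_sequences()]
#' @param config a `survey_config`
#' @param seed seed (default `config$seed + 2`)
#' @return list with `status` (matrix sample x locus), `stem_seqs`
#'   (contaminants substituted), `errors` truth data.frame,
#'   `lineage_clade` (species in the unlucky clade)
#' @export
apply_failures_and_errors <- function(tree, evolved, config,
                                      seed = config$seed + 2L) {
  set.seed(as.integer(seed))
  stems <- evolved$stems
  nst <- nrow(stems)
  loci <- config$loci
  coph <- ape::cophenetic.phylo(tree)
  # one unlucky clade for lineage-specific failure
  ntip <- length(tree$tip.label)
  nodes <- if (tree$Nnode >= 2L) seq(ntip + 2L, ntip + tree$Nnode)
           else integer(0)
  lineage <- character(0)
  if (any(loci$lineage_fail_mult > 1) && length(nodes) > 0L) {
    # failure-prone lineage: a genus-sized clade, not most of the flora
    sizes <- vapply(nodes, function(nd)
      length(ape::extract.clade(tree, nd)$tip.label), 0L)
    cap <- max(2L, ceiling(ntip / 3))
    ok <- nodes[sizes <= cap]
    if (length(ok) == 0L) ok <- nodes[which.min(sizes)]
    nd <- ok[sample.int(length(ok), 1L)]
    lineage <- ape::extract.clade(tree, nd)$tip.label
  }
  status <- matrix("ok", nst, nrow(loci),
                   dimnames = list(stems$sample_id, loci$locus_id))
  stem_seqs <- evolved$stem_seqs
  errors <- data.frame(sample_id = character(0), locus_id = character(0),
                       true_species = character(0),
                       contaminant_species = character(0),
                       stringsAsFactors = FALSE)
  for (li in seq_len(nrow(loci))) {
    locus <- loci$locus_id[li]
    p <- rep(loci$fail_prob[li], nst)
    p[stems$species %in% lineage] <-
      pmin(1, p[stems$species %in% lineage] * loci$lineage_fail_mult[li])
    failed <- runif(nst) < p
    status[failed, li] <- "fail"
    err <- !failed & runif(nst) < config$contamination_prob
    status[err, li] <- "error"
    for (r in which(err)) {
      sp0 <- stems$species[r]
      donor_sp <- names(which.max(coph[sp0, ]))
      donor_stem <- stems$sample_id[stems$species == donor_sp][1L]
      stem_seqs[[locus]][r] <- stem_seqs[[locus]][[donor_stem]]
      errors <- rbind(errors, data.frame(
        sample_id = stems$sample_id[r], locus_id = locus,
        true_species = sp0, contaminant_species = donor_sp,
        stringsAsFactors = FALSE))
    }
  }
  list(status = status, stem_seqs = stem_seqs, errors = errors,
       lineage_clade = lineage)
}

#' Simulate a complete plot survey
#'
#' Runs tree simulation, sequence evolution and the failure/error
#' process, and assembles the artifacts the pipeline reads: one
#' `locus_alignment` per locus (samples with a sequence, i.e. status
#' `ok` or `error`), a metadata table, and a ground-truth record.
#' Optionally writes FASTA + metadata files.
#'
#' @param config a `survey_config`
#' @param dir optional output directory for FASTA/metadata files
#' @return an object of class `barcode_survey`: list with `config`,
#'   `species_tree`, `alignments`, `metadata`, `truth`
#' @export
simulate_survey <- function(config = survey_config(), dir = NULL) {
  tree <- simulate_species_tree(config)
  ev <- evolve_sequences(tree, config)
  fx <- apply_failures_and_errors(tree, ev, config)
  stems <- ev$stems
  loci <- config$loci$locus_id
  alignments <- list()
  for (locus in loci) {
    keep <- fx$status[, locus] != "fail"
    alignments[[locus]] <- if (any(keep))
      locus_alignment(fx$stem_seqs[[locus]][keep], locus)
    else structure(list(locus_id = locus, sample_ids = character(0),
                        seqs = character(0), binary_chars = NULL,
                        offsets = NULL, col_index = integer(0)),
                   class = "locus_alignment")
  }
  metadata <- data.frame(sample_id = stems$sample_id,
                         plot_id = config$plot_id,
                         species_label = stems$species,
                         stringsAsFactors = FALSE)
  for (locus in loci) metadata[[locus]] <- unname(fx$status[, locus])
  attr(metadata, "loci") <- loci
  n_errors <- vapply(loci, function(l) sum(fx$status[, l] == "error"), 0L)
  truth <- list(species = setNames(stems$species, stems$sample_id),
                status = fx$status,
                inversions = ev$inversions,
                indels = ev$indels,
                errors = fx$errors,
                n_errors = n_errors,
                lineage_clade = fx$lineage_clade,
                true_richness = length(unique(stems$species)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (locus in loci)
      write_fasta(alignments[[locus]],
                  file.path(dir, paste0(gsub("[^A-Za-z0-9]", "_", locus),
                                        ".fasta")))
    write_metadata(metadata, file.path(dir, "metadata.csv"))
    write_newick(tree, file.path(dir, "species_tree.nwk"))
  }
  structure(list(config = config, species_tree = tree,
                 alignments = alignments, metadata = metadata,
                 truth = truth),
            class = "barcode_survey")
}

#' @export
print.barcode_survey <- function(x, ...) {
  cat(sprintf("barcode_survey '%s': %d species, %d stems, %d loci, seed %d\n",
              x$config$plot_id, x$truth$true_richness,
              nrow(x$metadata), length(x$alignments), x$config$seed))
  invisible(x)
}
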