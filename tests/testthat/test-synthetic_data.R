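test_that("surveys are byte-for-byte reproducible for a fixed seed", {
  cfg <- survey_config(n_species = 8L, seed = 5L)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(lapply(s1$alignments, `[[`, "seqs"),
                   lapply(s2$alignments, `[[`, "seqs"))
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(ape::write.tree(s1$species_tree),
                   ape::write.tree(s2$species_tree))
})

test_that("species tree respects size, scale, and the split-depth floor", {
  cfg <- survey_config(n_species = 2L, seed = 2L)
  tr <- simulate_species_tree(cfg)
  expect_equal(length(tr$tip.label), 2L)

  cfg10 <- survey_config(n_species = 10L, seed = 4L)
  tr10 <- simulate_species_tree(cfg10)
  expect_equal(max(ape::node.depth.edgelength(tr10)), cfg10$tree_scale,
               tolerance = 1e-9)
  cc <- ape::cophenetic.phylo(tr10)
  expect_gte(min(cc[upper.tri(cc)]), cfg10$min_split_depth - 1e-12)

  # mean pairwise distance scales linearly with the scale parameter
  mean_d <- function(scale) {
    cfg <- survey_config(n_species = 12L, seed = 6L, tree_scale = scale,
                         min_split_depth = 0)
    mean(ape::cophenetic.phylo(simulate_species_tree(cfg)))
  }
  expect_equal(mean_d(0.3) / mean_d(0.1), 3, tolerance = 1e-9)
})

test_that("intraspecific and interspecific knobs behave at their limits", {
  cfg0 <- survey_config(n_species = 6L, seed = 8L,
                        intraspecific_fraction = 0,
                        inversion_prob = 0, indel_prob = 0)
  tr <- simulate_species_tree(cfg0)
  ev <- evolve_sequences(tr, cfg0)
  for (locus in names(ev$stem_seqs)) {
    per_sp <- split(ev$stem_seqs[[locus]], ev$stems$species)
    for (s in per_sp) expect_length(unique(s), 1L)
  }

  # zero divergence scale: all species identical, estimate collapses to 1
  cfgz <- survey_config(n_species = 5L, seed = 8L, tree_scale = 0,
                        min_split_depth = 0, intraspecific_fraction = 0,
                        contamination_prob = 0, inversion_prob = 0,
                        indel_prob = 0)
  sv <- simulate_survey(cfgz)
  aln <- sv$alignments[["rbcLa"]]
  dm <- distance_matrix(aln)
  cl <- zero_distance_clusters(nj_build(dm), dm)
  expect_length(cl, 1L)
})

test_that("pairwise species divergence matches its expectation", {
  # two species at depth t: expected distance 2 * t * rate
  loci1 <- data.frame(locus_id = "L", length = 20000L, rate = 1,
                      fail_prob = 0, lineage_fail_mult = 1,
                      hypervariable = FALSE, stringsAsFactors = FALSE)
  cfg <- survey_config(n_species = 2L, seed = 10L, loci = loci1,
                       stems_mean = 1, tree_scale = 0.06,
                       min_split_depth = 0, intraspecific_fraction = 0,
                       contamination_prob = 0, inversion_prob = 0,
                       indel_prob = 0)
  sv <- simulate_survey(cfg)
  dm <- distance_matrix(concatenate(c(sv$alignments, sv$alignments)))
  d <- dm$d[1, 2]
  expect_equal(d, 2 * cfg$tree_scale, tolerance = 0.05)
})

test_that("failures and contamination are applied and tallied faithfully", {
  # failure prob 1 at one locus empties it and the intersection
  loci <- survey_config()$loci
  loci$fail_prob <- c(0, 1, 0)
  cfg <- survey_config(n_species = 5L, seed = 12L, loci = loci,
                       contamination_prob = 0)
  sv <- simulate_survey(cfg)
  expect_length(sv$alignments[["matK"]]$sample_ids, 0L)
  expect_equal(sv$truth$n_errors[["matK"]], 0L)

  # planted error count equals the truth tally across seeds
  for (s in 1:20) {
    cfg <- survey_config(n_species = 6L, seed = s,
                         contamination_prob = 0.1)
    sv <- simulate_survey(cfg)
    expect_equal(unname(sv$truth$n_errors),
                 unname(vapply(names(sv$alignments), function(l)
                   sum(sv$metadata[[l]] == "error"), 0L)))
    expect_equal(sum(sv$truth$n_errors), nrow(sv$truth$errors))
  }

  # contamination 0 -> zero errors everywhere
  cfg0 <- survey_config(n_species = 5L, seed = 3L, contamination_prob = 0)
  expect_equal(sum(simulate_survey(cfg0)$truth$n_errors), 0L)
})

test_that("lineage-specific failure hits the unlucky clade hardest", {
  cfg <- survey_config(n_species = 20L, seed = 14L)
  sv <- simulate_survey(cfg)
  clade <- sv$truth$lineage_clade
  if (length(clade) > 0L && length(clade) < 20L) {
    st <- sv$truth$status[, "matK"]
    sp <- sv$truth$species[rownames(sv$truth$status)]
    in_rate <- mean(st[sp %in% clade] == "fail")
    out_rate <- mean(st[!(sp %in% clade)] == "fail")
    expect_gte(in_rate, out_rate)
  }
})

test_that("no-noise surveys are recovered perfectly end to end", {
  loci <- survey_config()$loci
  loci$fail_prob <- c(0, 0, 0)
  cfg <- survey_config(n_species = 12L, seed = 16L, loci = loci,
                       intraspecific_fraction = 0, contamination_prob = 0,
                       inversion_prob = 0, indel_prob = 0)
  sv <- simulate_survey(cfg)
  for (locus in c("rbcLa", "matK")) {
    aln <- sv$alignments[[locus]]
    dm <- distance_matrix(aln)
    tr <- nj_build(dm)
    del <- delimit(tr, dm, n_errors = 0L,
                   species_labels = sv$truth$species,
                   present_in_plot = sv$truth$true_richness)
    expect_equal(del$corrected_estimate, sv$truth$true_richness)
    expect_equal(del$discrimination_accuracy, 100L)
  }
})

test_that("fusing the shallowest species pair loses exactly one cluster", {
  loci <- survey_config()$loci
  loci$fail_prob <- c(0, 0, 0)
  cfg <- survey_config(n_species = 4L, seed = 18L, loci = loci,
                       stems_mean = 1, intraspecific_fraction = 0,
                       contamination_prob = 0, inversion_prob = 0,
                       indel_prob = 0)
  tr <- simulate_species_tree(cfg)
  run_estimate <- function(tree) {
    ev <- evolve_sequences(tree, cfg)
    fx <- apply_failures_and_errors(tree, ev, cfg)
    aln <- locus_alignment(fx$stem_seqs[["rbcLa"]], "rbcLa")
    dm <- distance_matrix(aln)
    del <- delimit(nj_build(dm), dm, n_errors = 0L,
                   species_labels = setNames(ev$stems$species,
                                             ev$stems$sample_id),
                   present_in_plot = 4L)
    del
  }
  base <- run_estimate(tr)
  expect_equal(base$corrected_estimate, 4L)
  # collapse the shallowest split: its two species become identical
  n <- length(tr$tip.label)
  dep <- ape::node.depth.edgelength(tr)
  h <- max(dep) - dep; h[seq_len(n)] <- 0
  shallow <- which.min(h[(n + 2):(n + tr$Nnode)]) + n + 1L
  h[shallow] <- 0
  tr2 <- tr
  tr2$edge.length <- h[tr$edge[, 1]] - h[tr$edge[, 2]]
  fused <- run_estimate(tr2)
  expect_equal(fused$corrected_estimate, 3L)
  expect_equal(fused$estimation_accuracy, 75L)
  expect_equal(fused$discrimination_accuracy, 50L)
})
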