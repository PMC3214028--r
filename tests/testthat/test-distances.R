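test_that("complete deletion keeps only clean A/C/G/T columns", {
  aln <- locus_alignment(c(a = "ACGT", b = "AC-T"), "x")
  cd <- complete_deletion(aln)
  expect_equal(alignment_length(cd), 3L)
  expect_equal(cd$col_index, c(1L, 2L, 4L))

  aln2 <- locus_alignment(c(a = "ACGT", b = "ACNT"), "x")
  expect_equal(complete_deletion(aln2)$col_index, c(1L, 2L, 4L))
  # ambiguity codes other than N are missing data too
  aln3 <- locus_alignment(c(a = "ACRT", b = "ACGT"), "x")
  expect_equal(complete_deletion(aln3)$col_index, c(1L, 2L, 4L))

  aln4 <- locus_alignment(c(a = "A-GT", b = "AC-T", c = "-CGT", d = "ACG-"),
                          "x")
  expect_warning(cd4 <- complete_deletion(aln4), "degenerate")
  expect_equal(alignment_length(cd4), 0L)
  expect_true(attr(cd4, "degenerate"))
})

test_that("pooled counts match the brute-force pair/site oracle", {
  p <- pool_substitution_counts(locus_alignment(c(a = "AAAA", b = "AAAA"),
                                                "x"))
  expect_equal(sum(p$counts) - sum(diag(p$counts)), 0)
  expect_equal(p$freqs[["A"]], 1)

  p2 <- pool_substitution_counts(locus_alignment(c(a = "AAAA", b = "GGGG"),
                                                 "x"))
  expect_equal(p2$counts["A", "G"], 4)
  expect_equal(sum(p2$counts) - p2$counts["A", "G"] - p2$counts["G", "A"], 0)

  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    seqs <- setNames(replicate(n, rand_seq(40)), paste0("s", 1:n))
    got <- pool_substitution_counts(locus_alignment(seqs, "x"))$counts
    expect_equal(unname(got), unname(oracle_pool_counts(seqs)))
  }
  expect_error(pool_substitution_counts(
    locus_alignment(c(a = "ACGT"), "x")), "input-error")
})

test_that("pooled parameter estimation recovers generating models", {
  # identical data: no changes observed, flagged fallback
  pp <- estimate_pooled_params(pool_substitution_counts(
    locus_alignment(c(a = "ACGTACGT", b = "ACGTACGT"), "x")))
  expect_equal(pp$kappa1, 1); expect_equal(pp$kappa2, 1)
  expect_true(pp$kappa1_fallback && pp$kappa2_fallback)

  # JC world: kappas ~ 1; K2P kappa=4 world: kappas ~ 4
  est_kappa <- function(kappa, n_rep = 6L, L = 10000L) {
    vapply(seq_len(n_rep), function(r) {
      seqs <- k2p_star(10L, L, d = 0.2, kappa = kappa)
      pp <- estimate_pooled_params(pool_substitution_counts(
        locus_alignment(seqs, "x")))
      (pp$kappa1 + pp$kappa2) / 2
    }, 0)
  }
  set.seed(31)
  kj <- est_kappa(1)
  expect_lt(abs(mean(kj) - 1), 3 * sd(kj) / sqrt(length(kj)) + 0.02)
  kk <- est_kappa(4)
  expect_lt(abs(mean(kk) - 4), 3 * sd(kk) / sqrt(length(kk)) + 0.08)
})

test_that("pairwise distance agrees with the TN93 closed-form oracle", {
  set.seed(41)
  L <- 600L
  base <- rand_seq(L)
  # JC-proportioned mismatches: 1/6 of changes each AG and CT transitions
  plant <- function(s, n_ts1, n_ts2, n_tv) {
    v <- strsplit(s, "")[[1]]
    iA <- sample(which(v == "A"), n_ts1); v[iA] <- "G"
    iC <- sample(which(v == "C"), n_ts2); v[iC] <- "T"
    iT <- sample(which(v == "T"), n_tv); v[iT] <- "G"
    paste(v, collapse = "")
  }
  params <- list(pi = c(A = .25, C = .25, G = .25, T = .25),
                 kappa1 = 1, kappa2 = 1)
  for (scalef in c(1L, 4L)) {
    other <- plant(base, 2L * scalef, 2L * scalef, 8L * scalef)
    got <- pairwise_distance(base, other, params)
    expect_false(got$saturated)
    expect_equal(got$d, oracle_tn93_closed_form(base, other),
                 tolerance = 0.02)
  }
  # identical rows: exactly zero
  expect_identical(pairwise_distance(base, base, params)$d, 0)
  # complementary rows: saturated, distance undefined
  comp <- reverse_complement(base)
  comp <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")  # complement only
  got <- pairwise_distance(base, comp, params)
  expect_true(got$saturated)
  expect_true(is.na(got$d))
  expect_error(pairwise_distance("", "", params), "input-error")
})

test_that("distance_matrix satisfies its invariants", {
  aln <- locus_alignment(c(a = "ACGTACGT", b = "ACGTACGT"), "x")
  dm <- distance_matrix(aln)
  expect_equal(unname(dm$d), matrix(0, 2, 2))

  set.seed(51)
  base <- rand_seq(400)
  seqs <- c(a = base, b = base, c = mutate_seq(base, 6),
            d = mutate_seq(base, 14), e = mutate_seq(base, 20))
  dm <- distance_matrix(locus_alignment(seqs, "x"))
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 5))
  # d == 0 iff retained rows identical
  expect_identical(unname(dm$d == 0), unname(dm$zero))
  expect_true(dm$zero["a", "b"])
  expect_gt(dm$d["a", "c"], 0)
  # invariant to row order
  dm2 <- distance_matrix(locus_alignment(rev(seqs), "x"))
  expect_equal(dm2$d[names(seqs), names(seqs)], dm$d)
  # invariant to duplicating the column set
  dup <- setNames(paste0(seqs, seqs), names(seqs))
  dm3 <- distance_matrix(locus_alignment(dup, "x"))
  expect_equal(dm3$d, dm$d, tolerance = 1e-6)
})

test_that("distances on a known 4-taxon tree are within 3 SE of truth", {
  # two cherries (a,b) and (c,d): evolve with the independent K2P sampler
  set.seed(61)
  L <- 10000L
  anc <- sample(BASES, L, replace = TRUE)
  n1 <- k2p_evolve(anc, 0.05, 2); n2 <- k2p_evolve(anc, 0.05, 2)
  seqs <- c(a = paste(k2p_evolve(n1, 0.02, 2), collapse = ""),
            b = paste(k2p_evolve(n1, 0.03, 2), collapse = ""),
            c = paste(k2p_evolve(n2, 0.02, 2), collapse = ""),
            d = paste(k2p_evolve(n2, 0.04, 2), collapse = ""))
  true_d <- matrix(c(0, .05, .14, .16,
                     .05, 0, .15, .17,
                     .14, .15, 0, .06,
                     .16, .17, .06, 0), 4, 4,
                   dimnames = list(names(seqs), names(seqs)))
  dm <- distance_matrix(locus_alignment(seqs, "x"))
  for (i in 1:3) for (j in (i + 1):4) {
    d0 <- true_d[i, j]
    p0 <- 3 / 4 * (1 - exp(-4 * d0 / 3))      # JC-scale saturation proxy
    se <- sqrt(p0 * (1 - p0) / L) / (1 - 4 * p0 / 3)
    expect_lt(abs(dm$d[i, j] - d0), 3 * se + 0.003)
  }
})

test_that("pooled TN93 converges to the JC distance under uniform rates", {
  set.seed(71)
  L <- 50000L
  seqs <- k2p_star(2L, L, d = 0.12, kappa = 1)
  dm <- distance_matrix(locus_alignment(seqs, "x"))
  p <- mean(strsplit(seqs[[1]], "")[[1]] != strsplit(seqs[[2]], "")[[1]])
  jc <- -3 / 4 * log(1 - 4 * p / 3)
  se <- sqrt(p * (1 - p) / L) / (1 - 4 * p / 3)
  expect_lt(abs(dm$d[1, 2] - jc), 3 * se)
})

test_that("phylip export writes a square labelled matrix", {
  set.seed(81)
  base <- rand_seq(100)
  dm <- distance_matrix(locus_alignment(
    c(a = base, b = mutate_seq(base, 3), c = mutate_seq(base, 5)), "x"))
  f <- withr::local_tempfile(fileext = ".dist")
  write_phylip_distances(dm, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4L)
})
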