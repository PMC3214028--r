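# Maximum-composite-likelihood distances: TN93 with rate parameters (kappa1 =
# purine transition rate, kappa2 = pyrimidine transition rate, both relative
# to the transversion rate) estimated ONCE from substitution counts pooled
# over all sequence pairs, then applied per pair.  Distances are in expected
# substitutions per site.

.BASES <- c("A", "C", "G", "T")

# integer-encode clean rows: A=1 C=2 G=3 T=4
.encode_rows <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  out <- matrix(match(m, .BASES), nrow = nrow(m))
  rownames(out) <- names(seqs)
  out
}

#' Complete-deletion filtering
#'
#' Removes every alignment column in which any row carries a gap, an `N`,
#' or any ambiguity code: only columns where all rows are unambiguous
#' A/C/G/T are retained.  Original column indices are kept as provenance
#' in `col_index`.  If no column survives, the returned alignment has
#' zero columns and attribute `degenerate = TRUE` (distances undefined).
#'
#' @param aln a `locus_alignment`
#' @return a filtered `locus_alignment`
#' @export
complete_deletion <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  m <- alignment_matrix(aln)
  keep <- colSums(matrix(m %in% .BASES, nrow = nrow(m))) == nrow(m)
  out <- .alignment_from_matrix(m[, keep, drop = FALSE], aln,
                                col_index = aln$col_index[keep])
  if (!any(keep)) {
    warning("degenerate-alignment: no column free of gaps/missing data; ",
            "distances are undefined")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Pool substitution counts over all sequence pairs
#'
#' Tallies, over every unordered pair of rows and every site, the
#' unordered base-pair configuration.  `counts[a,b]` (`a != b`) is the
#' total number of (pair, site) events showing bases `{a,b}`; the
#' diagonal counts identical-base events.  Computed by per-column base
#' tallies, which is algebraically identical to enumerating all pairs.
#'
#' @param aln a `locus_alignment` already passed through
#'   [complete_deletion()] (rows must be pure A/C/G/T)
#' @return list with `counts` (symmetric 4x4), `freqs` (pooled base
#'   frequencies), `n_seq`, `n_sites`
#' @export
pool_substitution_counts <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (length(aln$sample_ids) < 2L)
    stop("input-error: need at least 2 sequences to pool counts")
  if (alignment_length(aln) == 0L)
    stop("input-error: zero-length alignment (degenerate)")
  x <- .encode_rows(aln$seqs)
  if (anyNA(x))
    stop("input-error: alignment must be complete-deletion filtered first")
  # per-site base tallies: ordered pooled count O[a,b] = sum_s n_a n_b - d_ab n_a
  tab <- vapply(1:4, function(b) colSums(x == b), numeric(ncol(x)))
  if (ncol(x) == 1L) tab <- matrix(tab, nrow = 1L)
  O <- crossprod(tab)            # sum_s n_a(s) n_b(s)
  diag(O) <- diag(O) - colSums(tab)
  N <- O
  diag(N) <- diag(N) / 2         # unordered identical events
  dimnames(N) <- list(.BASES, .BASES)
  freqs <- colSums(tab) / sum(tab)
  names(freqs) <- .BASES
  list(counts = N, freqs = freqs,
       n_seq = nrow(x), n_sites = ncol(x))
}

# TN93 transition probability matrix at scaled time t (expected
# substitutions/site) for parameters pi, kappa1 (A<->G), kappa2 (C<->T).
.tn93_P <- function(t, pi, kappa1, kappa2) {
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  beta <- 1 / (2 * (kappa1 * pi["A"] * pi["G"] +
                    kappa2 * pi["C"] * pi["T"] + piR * piY))
  a1 <- kappa1 * beta; a2 <- kappa2 * beta
  e1 <- exp(-beta * t)
  e2 <- exp(-(piR * a1 + piY * beta) * t)
  e3 <- exp(-(piY * a2 + piR * beta) * t)
  P <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  pur <- c("A", "G"); pyr <- c("C", "T")
  for (i in pur) for (j in pur)
    P[i, j] <- pi[j] + pi[j] * piY / piR * e1 +
      ((i == j) * piR - pi[j]) / piR * e2
  for (i in pyr) for (j in pyr)
    P[i, j] <- pi[j] + pi[j] * piR / piY * e1 +
      ((i == j) * piY - pi[j]) / piY * e3
  for (i in pur) for (j in pyr) P[i, j] <- pi[j] * (1 - e1)
  for (i in pyr) for (j in pur) P[i, j] <- pi[j] * (1 - e1)
  P
}

# multinomial log-likelihood of an unordered pair-count matrix N at time t
.tn93_loglik <- function(t, N, pi, kappa1, kappa2) {
  P <- .tn93_P(t, pi, kappa1, kappa2)
  E <- pi * P                    # pr of ordered event (a,b)
  E <- E + t(E); diag(E) <- diag(E) / 2   # pr of unordered event
  use <- upper.tri(N, diag = TRUE) & N > 0
  if (any(E[use] <= 0)) return(-Inf)
  sum(N[use] * log(E[use]))
}

#' Estimate pooled TN93 rate parameters
#'
#' Maximizes the composite (pooled multinomial) likelihood over
#' `kappa1`, `kappa2` and a pooled divergence nuisance parameter.
#' When a change class is unobserved (no purine transitions, no
#' pyrimidine transitions, or no transversions) the affected kappa is
#' unidentifiable and falls back to 1.0 with a flag.
#'
#' @param pooled result of [pool_substitution_counts()]
#' @return list with `pi`, `kappa1`, `kappa2`,
#'   `kappa1_fallback`, `kappa2_fallback`
#' @export
estimate_pooled_params <- function(pooled) {
  N <- pooled$counts
  if (sum(N) == 0) stop("input-error: all-zero count table")
  pi <- pooled$freqs
  ts1 <- N["A", "G"]
  ts2 <- N["C", "T"]
  tv  <- N["A", "C"] + N["A", "T"] + N["G", "C"] + N["G", "T"]
  fb1 <- ts1 == 0 || tv == 0
  fb2 <- ts2 == 0 || tv == 0
  k1 <- 1; k2 <- 1
  if (!(fb1 && fb2)) {
    obj <- function(par) {
      kk1 <- if (fb1) 1 else exp(par[["lk1"]])
      kk2 <- if (fb2) 1 else exp(par[["lk2"]])
      -.tn93_loglik(exp(par[["lt"]]), N, pi, kk1, kk2)
    }
    par0 <- c(lt = log(0.1))
    if (!fb1) par0 <- c(par0, lk1 = 0)
    if (!fb2) par0 <- c(par0, lk2 = 0)
    fit <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (!fb1) k1 <- exp(fit$par[["lk1"]])
    if (!fb2) k2 <- exp(fit$par[["lk2"]])
  }
  list(pi = pi, kappa1 = unname(k1), kappa2 = unname(k2),
       kappa1_fallback = fb1, kappa2_fallback = fb2)
}

# unordered event-count matrix for one pair of encoded rows
.pair_counts <- function(xi, xj) {
  t16 <- tabulate((xi - 1L) * 4L + xj, nbins = 16L)
  Ford <- matrix(t16, 4, 4, byrow = TRUE, dimnames = list(.BASES, .BASES))
  N <- Ford + t(Ford)
  diag(N) <- diag(N) / 2
  N
}

.T_MAX <- 20      # ML search bound; hitting it means saturation

.pair_distance_ml <- function(N, params) {
  if (sum(N) - sum(diag(N)) == 0)
    return(list(d = 0, saturated = FALSE))
  f <- function(t) .tn93_loglik(t, N, params$pi, params$kappa1, params$kappa2)
  opt <- optimize(f, c(1e-9, .T_MAX), maximum = TRUE, tol = 1e-10)
  if (opt$maximum > 0.95 * .T_MAX)
    return(list(d = NA_real_, saturated = TRUE))
  list(d = opt$maximum, saturated = FALSE)
}

#' Pairwise composite-likelihood distance
#'
#' TN93 distance for one pair of clean equal-length rows, maximizing the
#' pair multinomial likelihood over divergence with the SHARED pooled
#' rate parameters held fixed.  Identical rows give exactly 0.  If the
#' likelihood keeps increasing up to the search bound the pair is
#' saturated: the distance is undefined (`NA`) and flagged.
#'
#' @param row_i,row_j equal-length A/C/G/T strings
#' @param pooled_params result of [estimate_pooled_params()]
#' @return list with `d` (substitutions/site or `NA`) and `saturated`
#' @export
pairwise_distance <- function(row_i, row_j, pooled_params) {
  if (nchar(row_i) == 0L || nchar(row_j) == 0L)
    stop("input-error: zero-length rows")
  if (nchar(row_i) != nchar(row_j))
    stop("input-error: rows must have equal length")
  if (identical(row_i, row_j)) return(list(d = 0, saturated = FALSE))
  x <- .encode_rows(setNames(c(row_i, row_j), c("i", "j")))
  if (anyNA(x)) stop("input-error: rows must be unambiguous A/C/G/T")
  .pair_distance_ml(.pair_counts(x[1L, ], x[2L, ]), pooled_params)
}

#' Pairwise distance matrix for an alignment
#'
#' Runs the full distance pipeline: complete deletion, count pooling,
#' pooled TN93 parameter estimation, then per-pair composite-likelihood
#' distances.  `d[i,j]` is exactly 0 if and only if rows `i` and `j` are
#' identical over the retained columns.  `zero[i,j]` additionally
#' requires identical binary indel characters when the alignment carries
#' them; delimitation uses `zero`, not a numeric tolerance.
#'
#' @param aln a `locus_alignment` with at least 2 samples
#' @return an object of class `barcode_dist`: list with `sample_ids`,
#'   `d` (symmetric matrix, `NA` where saturated), `saturated` (logical
#'   matrix), `zero` (logical identity matrix), `pooled_params`,
#'   `n_sites_used`, `degenerate`
#' @export
distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  n <- length(aln$sample_ids)
  if (n < 2L) stop("input-error: need at least 2 sequences")
  cd <- suppressWarnings(complete_deletion(aln))
  ids <- cd$sample_ids
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  degenerate <- isTRUE(attr(cd, "degenerate"))
  # identity over retained columns (+ binary indel characters if present)
  key <- cd$seqs
  if (!is.null(cd$binary_chars))
    key <- paste(key, apply(cd$binary_chars, 1L, paste, collapse = ""))
  zero <- outer(key, key, "==")
  dimnames(zero) <- list(ids, ids)
  params <- NULL
  if (degenerate) {
    warning("degenerate-alignment: distances undefined")
    d[] <- NA_real_; diag(d) <- 0
  } else {
    params <- estimate_pooled_params(pool_substitution_counts(cd))
    # compute each distinct pair of distinct rows once, then expand
    uniq <- unique(cd$seqs)
    map <- match(cd$seqs, uniq)
    xu <- .encode_rows(setNames(uniq, seq_along(uniq)))
    nu <- length(uniq)
    du <- matrix(0, nu, nu); su <- matrix(FALSE, nu, nu)
    if (nu > 1L) for (a in seq_len(nu - 1L)) for (b in (a + 1L):nu) {
      r <- .pair_distance_ml(.pair_counts(xu[a, ], xu[b, ]), params)
      du[a, b] <- du[b, a] <- r$d
      su[a, b] <- su[b, a] <- r$saturated
    }
    d[] <- du[cbind(rep(map, n), rep(map, each = n))]
    sat[] <- su[cbind(rep(map, n), rep(map, each = n))]
    diag(d) <- 0; diag(sat) <- FALSE
  }
  structure(list(sample_ids = ids, d = d, saturated = sat, zero = zero,
                 pooled_params = params,
                 n_sites_used = alignment_length(cd),
                 degenerate = degenerate),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat(sprintf("barcode_dist: %d samples, %d sites used%s\n",
              length(x$sample_ids), x$n_sites_used,
              if (x$degenerate) " (DEGENERATE)" else ""))
  if (any(x$saturated))
    cat(sprintf("  %d saturated pair(s)\n", sum(x$saturated) / 2))
  invisible(x)
}

#' Export a distance matrix in PHYLIP square format
#' @param dm a `barcode_dist`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phylip_distances <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$sample_ids)), con)
  for (i in seq_along(dm$sample_ids))
    writeLines(paste(c(sprintf("%-10s", dm$sample_ids[i]),
                       sprintf("%.8f", dm$d[i, ])), collapse = "  "), con)
  invisible(path)
}
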