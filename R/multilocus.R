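# Multilocus handling: concatenation over the sample intersection, simple
# indel coding (presence/absence gap characters with ? for subsumed gaps),
# and normalization of short reverse-complement inversions of the kind seen
# in the trnH-psbA intergenic spacer.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", "-" = "-", N = "N",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", V = "B", D = "H", H = "D", U = "A")

#' Reverse complement of a nucleotide string
#' @param s IUPAC string
#' @return reverse complement string
#' @export
reverse_complement <- function(s) {
  paste(rev(.COMPLEMENT[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

#' Concatenate locus alignments over their sample intersection
#'
#' Only samples present in EVERY locus alignment are kept: mixing
#' single-locus samples into a concatenated alignment inflates apparent
#' richness, so it is refused by construction.  Rows are joined in the
#' order the alignments are given; per-locus 0-based start offsets are
#' recorded, and binary indel characters of the constituent loci are
#' carried over (restricted to the intersection).
#'
#' @param alignments_by_locus named list of >= 2 `locus_alignment`s
#' @param locus_id id for the result (default: loci joined by `+`)
#' @return a `locus_alignment`; zero samples with a
#'   `degenerate-alignment` warning when the intersection is empty
#' @export
concatenate <- function(alignments_by_locus, locus_id = NULL) {
  if (length(alignments_by_locus) < 2L)
    stop("input-error: need at least 2 locus alignments")
  ids <- lapply(alignments_by_locus, `[[`, "sample_ids")
  common <- Reduce(intersect, ids)
  lnames <- vapply(alignments_by_locus, `[[`, "", "locus_id")
  if (is.null(locus_id)) locus_id <- paste(lnames, collapse = "+")
  if (length(common) == 0L) {
    warning("degenerate-alignment: empty sample intersection across loci")
    return(structure(list(locus_id = locus_id, sample_ids = character(0),
                          seqs = character(0), binary_chars = NULL,
                          offsets = NULL, col_index = integer(0)),
                     class = "locus_alignment"))
  }
  lens <- vapply(alignments_by_locus, alignment_length, 0L)
  offsets <- setNames(cumsum(c(0L, lens[-length(lens)])), lnames)
  seqs <- vapply(common, function(id)
    paste(vapply(alignments_by_locus, function(a) a$seqs[[id]], ""),
          collapse = ""), "")
  bc <- NULL
  for (a in alignments_by_locus) {
    if (is.null(a$binary_chars)) next
    bc <- cbind(bc, a$binary_chars[common, , drop = FALSE])
  }
  locus_alignment(setNames(seqs, common), locus_id,
                  binary_chars = bc, offsets = offsets)
}

# maximal gap runs per row: matrix of (start, end) half-open 0-based
.gap_runs <- function(row) {
  r <- rle(strsplit(row, "")[[1]] == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Simple indel coding
#'
#' One binary presence/absence character per distinct internal gap
#' extent observed in the alignment (the Simmons-Ochoterena scheme).
#' For a descriptor `[start, end)` a sample scores `1` when its row is
#' gap exactly over that extent with non-gap flanks, `?` when its own
#' gap region strictly subsumes the descriptor (the state is
#' unobservable), and `0` otherwise.  Terminal gap runs are treated as
#' missing data: they are not coded, and descriptors overlapping a
#' sample's terminal gap score `?` for that sample.
#'
#' @param aln a `locus_alignment`
#' @return an object of class `indel_characters`: list with
#'   `descriptors` (data.frame start/end, 0-based half-open) and
#'   `states` (character matrix sample x descriptor); and the input
#'   alignment with `binary_chars` attached as attribute `"alignment"`
#' @export
simple_indel_coding <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  L <- alignment_length(aln)
  runs <- lapply(aln$seqs, .gap_runs)
  internal <- lapply(runs, function(r)
    r[r[, "start"] > 0L & r[, "end"] < L, , drop = FALSE])
  desc <- unique(do.call(rbind, internal))
  if (is.null(desc) || nrow(desc) == 0L) {
    out <- list(descriptors = data.frame(start = integer(0), end = integer(0)),
                states = matrix("", nrow = length(aln$sample_ids), ncol = 0L,
                                dimnames = list(aln$sample_ids, NULL)))
    class(out) <- "indel_characters"
    attr(out, "alignment") <- aln
    return(out)
  }
  desc <- desc[order(desc[, "start"], desc[, "end"]), , drop = FALSE]
  states <- matrix("0", nrow = length(aln$sample_ids), ncol = nrow(desc),
                   dimnames = list(aln$sample_ids, NULL))
  for (si in seq_along(aln$sample_ids)) {
    r <- runs[[si]]
    terminal <- r[r[, "start"] == 0L | r[, "end"] == L, , drop = FALSE]
    for (di in seq_len(nrow(desc))) {
      s <- desc[di, "start"]; e <- desc[di, "end"]
      exact <- any(r[, "start"] == s & r[, "end"] == e &
                     r[, "start"] > 0L & r[, "end"] < L)
      subsumed <- any(r[, "start"] <= s & r[, "end"] >= e &
                        (r[, "end"] - r[, "start"]) > (e - s))
      in_terminal <- nrow(terminal) > 0L &&
        any(terminal[, "start"] < e & terminal[, "end"] > s)
      states[si, di] <- if (exact) "1"
                        else if (subsumed || in_terminal) "?"
                        else "0"
    }
  }
  out <- list(descriptors = data.frame(start = desc[, "start"],
                                       end = desc[, "end"]),
              states = states)
  class(out) <- "indel_characters"
  attr(out, "alignment") <- locus_alignment(
    aln$seqs, aln$locus_id, binary_chars = states,
    offsets = aln$offsets, col_index = aln$col_index)
  out
}

#' Alignment with binary indel characters attached
#' @param ic an `indel_characters` object
#' @return the `locus_alignment` carrying `binary_chars`
#' @export
with_indel_chars <- function(ic) attr(ic, "alignment")

#' Detect and normalize short reverse-complement inversions
#'
#' Scans windows of length `max_len` down to `min_len` for positions
#' where a minority of rows carry exactly the reverse complement of the
#' majority consensus window while matching the majority consensus over
#' the flanking regions; such rows are reverse-complemented in place.
#' Palindromic windows (self reverse-complement) are skipped since the
#' two orientations are indistinguishable.  Zero detections is a valid
#' outcome.  This is OFF by default in the pipeline and must be enabled
#' per locus: an inversion is a biological polymorphism, and rewriting
#' it is a deliberate analysis choice.
#'
#' @param aln a `locus_alignment`
#' @param min_len,max_len window length bounds (4 <= min <= max <= 30)
#' @param flank number of flanking columns that must match the majority
#' @return list with `alignment` (normalized) and `report` (data.frame
#'   start, end, length, sample_id; 0-based half-open columns)
#' @export
detect_and_normalize_inversions <- function(aln, min_len = 4L, max_len = 30L,
                                            flank = 4L) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (!(4L <= min_len && min_len <= max_len && max_len <= 30L))
    stop("input-error: need 4 <= min_len <= max_len <= 30")
  m <- alignment_matrix(aln)
  L <- ncol(m); nr <- nrow(m)
  report <- data.frame(start = integer(0), end = integer(0),
                       length = integer(0), sample_id = character(0),
                       stringsAsFactors = FALSE)
  if (nr < 2L || L < min_len)
    return(list(alignment = aln, report = report))
  majority_str <- function(v) names(which.max(table(v)))
  for (len in seq(min_len, min(max_len, L))) {
    for (s in seq_len(L - len + 1L)) {
      win <- apply(m[, s:(s + len - 1L), drop = FALSE], 1L, paste,
                   collapse = "")
      cons <- majority_str(win)
      rc <- reverse_complement(cons)
      if (rc == cons) next                       # palindromic
      hit <- which(win == rc)
      if (length(hit) == 0L || length(hit) >= nr - length(hit)) next
      # flank check against the majority consensus columns
      fl <- max(s - flank, 1L):(s - 1L)
      fr <- (s + len):min(s + len + flank - 1L, L)
      fcols <- c(fl[fl >= 1L & fl < s], fr[fr <= L])
      okflank <- vapply(hit, function(r) {
        all(vapply(fcols, function(cc)
          m[r, cc] == majority_str(m[, cc]), logical(1L)))
      }, logical(1L))
      hit <- hit[okflank]
      if (length(hit) == 0L) next
      for (r in hit) {
        m[r, s:(s + len - 1L)] <- strsplit(cons, "")[[1]]
        report <- rbind(report,
                        data.frame(start = s - 1L, end = s + len - 1L,
                                   length = len,
                                   sample_id = rownames(m)[r],
                                   stringsAsFactors = FALSE))
      }
    }
  }
  list(alignment = .alignment_from_matrix(m, aln, col_index = aln$col_index),
       report = report)
}
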