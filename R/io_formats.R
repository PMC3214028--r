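#' @importFrom stats optim optimize rbinom rgeom runif setNames
#' @importFrom utils read.table write.table
NULL

# IUPAC nucleotide alphabet accepted on input; everything outside A/C/G/T is
# treated as missing downstream (complete deletion).
.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-")

#' Construct a locus alignment
#'
#' The central container of the package: a set of equal-length aligned
#' nucleotide rows over named samples for one barcode locus (or a
#' concatenation of loci).  Optionally carries appended binary indel
#' characters (see [simple_indel_coding()]) and, after concatenation,
#' the per-locus column offsets.
#'
#' @param seqs named character vector of equal-length uppercase IUPAC
#'   strings (`-` for gaps); names are sample ids.
#' @param locus_id single string identifying the locus
#'   (e.g. `"rbcLa"`, `"matK"`, `"trnH-psbA"`, `"concat"`).
#' @param binary_chars optional character matrix of `"0"`/`"1"`/`"?"`
#'   states, one row per sample, from indel coding.
#' @param offsets optional named integer vector of 0-based start columns
#'   per constituent locus (set by [concatenate()]).
#' @param col_index optional integer vector mapping current columns back to
#'   the original alignment columns (set by [complete_deletion()]).
#' @return an object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, locus_id, binary_chars = NULL,
                            offsets = NULL, col_index = NULL) {
  if (length(seqs) == 0L) stop("format-error: alignment has no sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("format-error: all sequences must be named by sample id")
  if (anyDuplicated(ids))
    stop("format-error: duplicate sample id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("alignment-error: rows have unequal lengths (",
         paste(sort(len), collapse = ", "), ")")
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]), .IUPAC)
  if (length(bad) > 0L)
    stop("format-error: non-IUPAC characters in alignment: ",
         paste(bad, collapse = " "))
  if (!is.null(binary_chars)) {
    binary_chars <- as.matrix(binary_chars)
    if (nrow(binary_chars) != length(seqs))
      stop("format-error: binary_chars row count must equal sample count")
    if (!all(binary_chars %in% c("0", "1", "?")))
      stop("format-error: binary_chars states must be 0, 1 or ?")
    rownames(binary_chars) <- ids
  }
  structure(list(locus_id = locus_id, sample_ids = ids, seqs = seqs,
                 binary_chars = binary_chars, offsets = offsets,
                 col_index = if (is.null(col_index)) seq_len(len) else col_index),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus_alignment '%s': %d samples x %d columns",
              x$locus_id, length(x$sample_ids), alignment_length(x)))
  if (!is.null(x$binary_chars))
    cat(sprintf(" (+%d binary indel characters)", ncol(x$binary_chars)))
  cat("\n")
  invisible(x)
}

#' Number of nucleotide columns of an alignment
#' @param aln a `locus_alignment`
#' @return integer column count
#' @export
alignment_length <- function(aln) {
  if (length(aln$seqs) == 0L) 0L else nchar(aln$seqs[[1L]])
}

#' Alignment as a character matrix (one column per site)
#' @param aln a `locus_alignment`
#' @return character matrix, rownames = sample ids
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$sample_ids
  m
}

#' Rebuild an alignment from a character matrix
#' @param m character matrix with sample rownames
#' @param template `locus_alignment` providing locus_id and binary_chars
#' @param col_index provenance column indices for the matrix columns
#' @return a `locus_alignment`
#' @keywords internal
.alignment_from_matrix <- function(m, template, col_index = NULL) {
  seqs <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) seqs <- setNames(rep("", nrow(m)), rownames(m))
  locus_alignment(setNames(seqs, rownames(m)), template$locus_id,
                  binary_chars = template$binary_chars,
                  offsets = template$offsets, col_index = col_index)
}

#' Read one aligned FASTA file
#'
#' Rows are validated to equal length, lowercase is normalized to upper
#' case, and duplicate ids are rejected.
#'
#' @param path path to an aligned FASTA file
#' @param locus_id locus identifier to attach
#' @return a `locus_alignment`
#' @export
read_fasta <- function(path, locus_id) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format-error: empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("format-error: FASTA must start with a '>' header")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)          # id is the first whitespace token
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")), "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("format-error: FASTA record with no sequence")
  locus_alignment(setNames(unname(seqs), ids), locus_id)
}

#' Write an alignment as FASTA
#'
#' @param aln a `locus_alignment`
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in aln$sample_ids) {
    s <- aln$seqs[[id]]
    writeLines(paste0(">", id), con)
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.STATUS_TOKENS <- c("ok", "fail", "error")

#' Read a sample metadata table
#'
#' A delimited table (comma or tab, sniffed from the header line) with
#' columns `sample_id`, `plot_id`, optionally `species_label`, and one
#' status column per locus whose values are `ok`, `fail` or `error`.
#'
#' @param path path to the delimited file
#' @return a data.frame with one row per sample; attribute `"loci"` holds
#'   the status column names.  `species_label` is absent in
#'   unknown-flora mode.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "")
  if (!all(c("sample_id", "plot_id") %in% names(df)))
    stop("format-error: metadata needs sample_id and plot_id columns")
  if (anyNA(df$sample_id) || any(df$sample_id == ""))
    stop("format-error: missing sample_id")
  if (anyDuplicated(df$sample_id))
    stop("format-error: duplicate sample_id in metadata")
  loci <- setdiff(names(df), c("sample_id", "plot_id", "species_label"))
  for (l in loci) {
    bad <- setdiff(unique(df[[l]]), .STATUS_TOKENS)
    if (length(bad) > 0L)
      stop("format-error: unknown status token(s) in column '", l, "': ",
           paste(bad, collapse = ", "))
  }
  attr(df, "loci") <- loci
  df
}

#' Write a sample metadata table
#' @param df metadata data.frame as returned by [read_metadata()]
#' @param path output path
#' @param sep field separator
#' @return `path`, invisibly
#' @export
write_metadata <- function(df, path, sep = ",") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree in newick format
#'
#' Branch lengths are required; bootstrap supports present as
#' `node.label` are written as internal node labels.
#'
#' @param tree a `phylo` object (see [nj_build()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree$edge.length))
    stop("input-error: tree has no branch lengths")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path path to a newick file
#' @return a `phylo` object
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  ape::read.tree(path)
}
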