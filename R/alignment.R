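# Amino-acid alignments with gaps ('-'), masked residues ('X') and
# optional per-column confidence scores.

#' Construct an amino-acid alignment
#'
#' @param seqs Named character vector of aligned residue strings (equal
#'   lengths) over the 20 amino acids plus `-` (gap) and `X` (masked).
#' @param confidence Optional numeric vector of per-column confidence
#'   scores in `[0, 1]`, one per alignment column.
#' @return An object of class `aa_alignment`: a list with `seqs` (a
#'   character matrix, rows = sequences, columns = alignment columns)
#'   and `confidence`.
#' @export
aa_alignment <- function(seqs, confidence = NULL) {
  if (length(seqs) == 0) stop("empty alignment")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("sequences must carry unique non-empty identifiers")
  n <- unique(nchar(seqs))
  if (length(n) != 1) stop("all rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- ids
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET, "-", "X"))
  if (length(bad))
    stop("invalid residue characters: ", paste(bad, collapse = " "))
  if (!is.null(confidence)) {
    if (length(confidence) != n)
      stop("confidence vector must have one entry per column")
    if (any(confidence < 0 | confidence > 1))
      stop("confidence scores must lie in [0, 1]")
  }
  structure(list(seqs = mat, confidence = confidence),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("aa_alignment: %d sequences x %d columns%s\n",
              nrow(x$seqs), ncol(x$seqs),
              if (is.null(x$confidence)) "" else " (with confidence)"))
  invisible(x)
}

#' Number of columns / sequences of an alignment
#' @param aln An `aa_alignment`.
#' @return Integer count.
#' @export
aln_ncol <- function(aln) ncol(aln$seqs)

#' @rdname aln_ncol
#' @export
aln_nseq <- function(aln) nrow(aln$seqs)

#' Collapse alignment rows back to strings
#' @param aln An `aa_alignment`.
#' @return Named character vector.
#' @export
aln_strings <- function(aln) {
  apply(aln$seqs, 1, paste, collapse = "")
}

#' Read an amino-acid FASTA alignment
#'
#' @param path FASTA file; gaps `-`, masked residues `X`.
#' @param confidence_csv Optional CSV with columns `column_index`,
#'   `score` giving per-column confidence values.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, confidence_csv = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")), "")
  names(seqs) <- ids
  conf <- NULL
  if (!is.null(confidence_csv)) {
    tab <- utils::read.csv(confidence_csv)
    conf <- rep(NA_real_, nchar(seqs[[1]]))
    conf[tab$column_index] <- tab$score
    if (anyNA(conf)) stop("confidence CSV does not cover every column")
  }
  aa_alignment(seqs, confidence = conf)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or `aa_alignment`).
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "aa_alignment")) seqs <- aln_strings(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Mask low-confidence alignment columns
#'
#' Replaces every residue in columns whose confidence score is strictly
#' below `threshold` with `X`; gaps are left untouched and all other
#' columns are returned bit-identical. This mirrors the alignment-hygiene
#' step of masking unreliably aligned residues rather than deleting
#' whole columns.
#'
#' @param aln An `aa_alignment` with a confidence vector.
#' @param threshold Confidence cutoff in `[0, 1]`; columns with score
#'   `< threshold` are masked.
#' @return The masked `aa_alignment` (confidence vector preserved).
#' @export
mask_low_confidence <- function(aln, threshold = 0.5) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (is.null(aln$confidence))
    stop("alignment has no column confidence scores")
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  low <- which(aln$confidence < threshold)
  for (j in low) {
    col <- aln$seqs[, j]
    col[col != "-"] <- "X"
    aln$seqs[, j] <- col
  }
  aln
}

#' Strip gap-rich alignment columns
#'
#' Retains exactly the columns whose gap fraction is strictly less than
#' `max_gap_fraction` and reports the mapping from retained to original
#' column indices.
#'
#' @param aln An `aa_alignment`.
#' @param max_gap_fraction Cutoff in `(0, 1]`; a column is dropped when
#'   `gap fraction >= max_gap_fraction`.
#' @return List with `alignment` (stripped `aa_alignment`) and
#'   `column_map` (integer vector: original index of each kept column).
#' @export
strip_gappy_columns <- function(aln, max_gap_fraction = 0.95) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (max_gap_fraction <= 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must lie in (0, 1]")
  gap_frac <- colMeans(aln$seqs == "-")
  keep <- which(gap_frac < max_gap_fraction)
  if (length(keep) == 0) stop("no columns retained")
  out <- aln
  out$seqs <- aln$seqs[, keep, drop = FALSE]
  if (!is.null(aln$confidence)) out$confidence <- aln$confidence[keep]
  list(alignment = out, column_map = keep)
}
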