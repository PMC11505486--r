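#' Construct and validate a codon alignment
#'
#' A codon alignment is a set of in-frame, equal-length nucleotide
#' sequences (one per species) for a single gene. Sequences may contain
#' gaps (`-`) and ambiguous bases (`N`); [filter_alignment()] removes the
#' affected codon columns before dN/dS estimation.
#'
#' @param seqs Named character vector or list of nucleotide strings; names
#'   are species identifiers (exact-match strings, must be unique).
#' @param gene_id Gene identifier.
#' @return An object of class `codon_alignment`: list with `gene_id`,
#'   `seqs` (named character), `length` (nucleotides).
#' @export
codon_alignment <- function(seqs, gene_id = "gene") {
  seqs <- toupper(unlist(seqs))
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyNA(names(seqs))) {
    stop("every sequence must be named by its species", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicated species identifiers: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length; found lengths ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  }
  len <- lens[[1L]]
  if (len %% 3L != 0L) {
    stop("alignment length ", len, " is not a multiple of 3 (broken frame)",
         call. = FALSE)
  }
  ok <- grepl("^[ACGTN-]*$", seqs)
  if (!all(ok)) {
    stop("illegal characters (alphabet is A,C,G,T,N,-) in: ",
         paste(names(seqs)[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(gene_id = gene_id, seqs = seqs, length = unname(len)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment '", x$gene_id, "': ", length(x$seqs),
      " sequences x ", x$length, " nt (", x$length / 3, " codons)\n",
      sep = "")
  invisible(x)
}

#' Read a codon alignment from FASTA
#'
#' @param path Path to a FASTA file of aligned, in-frame coding sequences.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @return A validated [codon_alignment()].
#' @export
read_codon_alignment <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(gene_id)) {
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(set),
                          sub("\\s.*$", "", names(set)))
  codon_alignment(seqs, gene_id = gene_id)
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  set <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Filter an alignment for dN/dS estimation
#'
#' Applies the two pre-estimation filters in order: (1) drop sequences that
#' are too short (fewer gap-free codons than the threshold, measured before
#' any column removal); (2) remove every codon column in which any retained
#' sequence carries a gap or an `N` at any of the codon's three positions.
#' Gap handling is codon-granular so the reading frame is preserved.
#'
#' @param aln A [codon_alignment()].
#' @param min_frac Length threshold as a fraction of the alignment's codon
#'   length (default 0.5); ignored when `min_len` is given.
#' @param min_len Absolute threshold in codons, optional.
#' @return A filtered [codon_alignment()] (gap- and N-free).
#' @export
filter_alignment <- function(aln, min_frac = 0.5, min_len = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  n_codons <- aln$length %/% 3L
  if (is.null(min_len)) min_len <- ceiling(min_frac * n_codons)

  codon_mat <- t(vapply(aln$seqs, .split_codons,
                        character(n_codons)))
  if (n_codons == 1L) {
    codon_mat <- matrix(vapply(aln$seqs, .split_codons, character(1L)),
                        ncol = 1L, dimnames = list(names(aln$seqs), NULL))
  }
  clean <- !grepl("[N-]", codon_mat)
  dim(clean) <- dim(codon_mat)

  keep_seq <- rowSums(clean) >= min_len
  if (!any(keep_seq)) {
    stop(errorCondition(
      paste0("empty alignment: every sequence shorter than ", min_len,
             " gap-free codons"),
      class = c("evorate_empty_alignment", "error")))
  }
  keep_col <- colSums(!clean[keep_seq, , drop = FALSE]) == 0L
  if (!any(keep_col)) {
    stop(errorCondition(
      "empty alignment: every codon column contains a gap or N",
      class = c("evorate_empty_alignment", "error")))
  }
  out <- apply(codon_mat[keep_seq, keep_col, drop = FALSE], 1L, paste,
               collapse = "")
  codon_alignment(stats::setNames(out, names(aln$seqs)[keep_seq]),
                  gene_id = aln$gene_id)
}
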