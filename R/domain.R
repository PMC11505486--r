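#' Six-group physicochemical amino-acid scheme
#'
#' The partition of the 20 standard amino acids used to classify
#' substitutions as radical (between groups) or conservative (within a
#' group): (1) cysteine; (2) serine, threonine, alanine, glycine, proline;
#' (3) aspartate, glutamate, asparagine, glutamine; (4) histidine,
#' arginine, lysine; (5) methionine, isoleucine, leucine, valine;
#' (6) tryptophan, tyrosine, phenylalanine.
#'
#' @return Named list of six character vectors partitioning the 20 amino
#'   acids.
#' @export
aa_groups <- function() {
  list(g1 = "C",
       g2 = c("S", "T", "A", "G", "P"),
       g3 = c("D", "E", "N", "Q"),
       g4 = c("H", "R", "K"),
       g5 = c("M", "I", "L", "V"),
       g6 = c("W", "Y", "F"))
}

.group_lookup <- function(scheme) {
  all_aa <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(all_aa) || !setequal(all_aa, .AA20) ||
      length(scheme) != 6L) {
    stop("scheme must be a disjoint partition of the 20 amino acids into ",
         "six groups", call. = FALSE)
  }
  stats::setNames(rep(names(scheme), lengths(scheme)), all_aa)
}

#' Is a substitution radical under a group scheme?
#'
#' A substitution is radical when the two residues belong to different
#' groups of the scheme; it is symmetric and false for identical residues.
#'
#' @param aa1,aa2 Standard amino acids (one-letter codes; vectorized).
#' @param scheme Group scheme as returned by [aa_groups()].
#' @return Logical vector.
#' @examples
#' is_radical("C", "Y")  # TRUE: cysteine group vs aromatic group
#' is_radical("L", "V")  # FALSE: both aliphatic
#' @export
is_radical <- function(aa1, aa2, scheme = aa_groups()) {
  lookup <- .group_lookup(scheme)
  aa1 <- toupper(aa1); aa2 <- toupper(aa2)
  bad <- setdiff(c(aa1, aa2), names(lookup))
  if (length(bad) > 0L) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(lookup[aa1] != lookup[aa2])
}

.msa_matrix <- function(msa) {
  stopifnot(!is.null(names(msa)))
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows must have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(mat) <- names(msa)
  mat
}

#' Consensus of a protein alignment
#'
#' Per column, the most frequent residue across species, gaps ignored.
#' Ties are broken by alphabetical order of the tied residues and the
#' position is flagged in the `tie_positions` attribute.
#'
#' @param msa Named character vector of equal-length aligned protein
#'   sequences (>= 2 rows).
#' @return Consensus string with attribute `tie_positions` (integer
#'   vector, 1-based).
#' @export
build_consensus <- function(msa) {
  mat <- .msa_matrix(msa)
  if (nrow(mat) < 2L) stop("need at least two rows", call. = FALSE)
  ties <- integer(0)
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) {
      stop("column ", j, " is entirely gaps: no consensus", call. = FALSE)
    }
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) ties <<- c(ties, j)
    sort(top)[1L]
  }, character(1))
  structure(paste(cons, collapse = ""), tie_positions = ties)
}

#' Per-taxon, per-position deviation counts from a consensus
#'
#' For each taxon and each alignment position, counts the species whose
#' residue differs from the consensus residue — all substitutions
#' (`mode = "all"`) or only radical ones under the six-group scheme
#' (`mode = "radical"`). Gaps are never counted as deviations.
#' Conservative positions are positions with zero counted deviations, per
#' taxon and over all taxa.
#'
#' @param msa Named character vector of aligned protein sequences.
#' @param consensus Consensus string (defaults to [build_consensus()] of
#'   `msa`).
#' @param taxon_map Named character vector: species -> taxon; every
#'   alignment row must be assigned.
#' @param mode `"all"` or `"radical"`.
#' @param scheme Group scheme for radical classification.
#' @return Object of class `deviation_table`: list with `consensus`,
#'   `counts` (taxa x positions integer matrix), `conservative` (named
#'   per-taxon counts), `conservative_overall`, `mode`.
#' @export
deviation_counts <- function(msa, consensus = NULL, taxon_map,
                             mode = c("all", "radical"),
                             scheme = aa_groups()) {
  mode <- match.arg(mode)
  mat <- .msa_matrix(msa)
  if (is.null(consensus)) consensus <- build_consensus(msa)
  cons <- strsplit(as.character(consensus), "")[[1L]]
  if (length(cons) != ncol(mat)) {
    stop("consensus length (", length(cons),
         ") does not match alignment width (", ncol(mat), ")",
         call. = FALSE)
  }
  unassigned <- setdiff(rownames(mat), names(taxon_map))
  if (length(unassigned) > 0L) {
    stop("alignment rows without a taxon assignment: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  taxa <- unique(unname(taxon_map[rownames(mat)]))
  lookup <- .group_lookup(scheme)
  counts <- matrix(0L, nrow = length(taxa), ncol = ncol(mat),
                   dimnames = list(taxa, NULL))
  for (tx in taxa) {
    sub <- mat[rownames(mat)[taxon_map[rownames(mat)] == tx], ,
               drop = FALSE]
    for (j in seq_len(ncol(mat))) {
      col <- sub[, j]
      col <- col[col %in% .AA20]          # gaps/X never count as deviations
      dev <- if (mode == "all") {
        col != cons[j]
      } else {
        lookup[col] != lookup[[cons[j]]]
      }
      counts[tx, j] <- sum(dev)
    }
  }
  conservative <- apply(counts, 1L, function(z) sum(z == 0L))
  structure(list(consensus = as.character(consensus), counts = counts,
                 conservative = conservative,
                 conservative_overall = sum(colSums(counts) == 0L),
                 mode = mode),
            class = "deviation_table")
}

#' @export
print.deviation_table <- function(x, ...) {
  cat("Deviation table (", x$mode, " substitutions), ",
      ncol(x$counts), " positions\n", sep = "")
  cat("consensus:", x$consensus, "\n")
  for (tx in rownames(x$counts)) {
    cat(sprintf("  %-20s total %4d, conservative positions %d\n",
                tx, sum(x$counts[tx, ]), x$conservative[[tx]]))
  }
  cat("conservative positions over all taxa:", x$conservative_overall, "\n")
  invisible(x)
}

#' Compare longevity quotients across a residue-defined species split
#'
#' Splits the aligned species at a domain position — either carriers of an
#' exact residue versus all others, or species deviating radically from
#' the consensus versus the rest — and compares the median longevity
#' quotient (LQ) of the two groups.
#'
#' @param msa Named character vector of aligned protein sequences.
#' @param position 1-based position within the domain alignment.
#' @param traits Trait table with an `lq` column; species with missing LQ
#'   are excluded from the medians.
#' @param mode `"exact_residue"` (requires `residue`) or
#'   `"radical_vs_consensus"`.
#' @param residue Residue defining the in-group for `"exact_residue"`.
#' @param consensus Optional consensus string for
#'   `"radical_vs_consensus"`; computed from `msa` when absent.
#' @param scheme Group scheme for radical classification.
#' @return List with `median_lq_in`, `median_lq_out`,
#'   `percent_difference` (`100 * (in - out)/out`), `n_in`, `n_out`.
#' @export
residue_lq_compare <- function(msa, position, traits,
                               mode = c("exact_residue",
                                        "radical_vs_consensus"),
                               residue = NULL, consensus = NULL,
                               scheme = aa_groups()) {
  mode <- match.arg(mode)
  mat <- .msa_matrix(msa)
  if (position < 1L || position > ncol(mat)) {
    stop("position ", position, " outside the domain (1..", ncol(mat), ")",
         call. = FALSE)
  }
  col <- mat[, position]
  in_group <- if (mode == "exact_residue") {
    if (is.null(residue)) {
      stop("`residue` is required for mode = 'exact_residue'",
           call. = FALSE)
    }
    names(col)[col == toupper(residue)]
  } else {
    if (is.null(consensus)) consensus <- build_consensus(msa)
    cons_res <- substr(as.character(consensus), position, position)
    carriers <- names(col)[col %in% .AA20]
    carriers[is_radical(col[carriers], cons_res, scheme)]
  }
  out_group <- setdiff(rownames(mat), in_group)
  if (length(in_group) == 0L || length(out_group) == 0L) {
    stop("empty group: the split must leave species on both sides",
         call. = FALSE)
  }
  lq_of <- stats::setNames(traits$lq, traits$species_id)
  lq_in <- lq_of[in_group]; lq_in <- lq_in[!is.na(lq_in)]
  lq_out <- lq_of[out_group]; lq_out <- lq_out[!is.na(lq_out)]
  if (length(lq_in) == 0L || length(lq_out) == 0L) {
    stop("no LQ values available in one of the groups", call. = FALSE)
  }
  med_in <- stats::median(lq_in)
  med_out <- stats::median(lq_out)
  list(median_lq_in = med_in, median_lq_out = med_out,
       percent_difference = 100 * (med_in - med_out) / med_out,
       n_in = length(in_group), n_out = length(out_group))
}
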