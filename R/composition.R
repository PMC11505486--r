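#' Amino-acid occurrence profile of one protein sequence
#'
#' Percentage of each of the 20 standard amino acids among the counted
#' residues; gaps (`-`) and ambiguity codes (`X`) are excluded from the
#' denominator.
#'
#' @param protein Amino-acid sequence (single string, one-letter codes).
#' @return Named numeric vector of length 20 (percentages summing to 100).
#' @examples
#' composition("ACDE")  # 25% each
#' @export
composition <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  res <- strsplit(toupper(protein), "")[[1L]]
  bad <- setdiff(res, c(.AA20, "-", "X", "*"))
  if (length(bad) > 0L) {
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  res <- res[res %in% .AA20]
  if (length(res) == 0L) {
    stop("empty or all-gap sequence: composition undefined", call. = FALSE)
  }
  counts <- table(factor(res, levels = .AA20))
  stats::setNames(100 * as.numeric(counts) / length(res), .AA20)
}

#' Occurrence profiles for a set of species
#'
#' @param proteins Named character vector of protein sequences (names are
#'   species identifiers) or an `AAStringSet`.
#' @return Matrix species x 20 amino acids of occurrence percentages.
#' @export
composition_profiles <- function(proteins) {
  if (!is.character(proteins)) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  stopifnot(!is.null(names(proteins)))
  t(vapply(proteins, composition, numeric(length(.AA20))))
}

#' Correlate amino-acid occurrence with a species trait
#'
#' For each of the 20 standard amino acids, the Pearson correlation (and
#' two-sided p-value) between its per-species occurrence and the trait:
#' lifespan in years or the common logarithm of body weight. A positive r
#' is read as preference (the trait rises with occurrence), a negative r
#' as avoidance. Amino acids with zero variance across species get `NA`
#' for r and p; other amino acids are unaffected.
#'
#' @param profiles Species x amino-acid occurrence matrix (see
#'   [composition_profiles()]).
#' @param traits Trait table data frame.
#' @param trait `"mrls"` or `"lg_weight"`.
#' @return Data frame with `amino_acid`, `mean_occurrence_pct`, `r`, `p`.
#' @export
correlate_composition <- function(profiles, traits,
                                  trait = c("mrls", "lg_weight")) {
  trait <- match.arg(trait)
  sp <- intersect(rownames(profiles), traits$species_id)
  tr <- traits[match(sp, traits$species_id), ]
  y <- if (trait == "mrls") tr$mrls else log10(tr$weight)
  keep <- !is.na(y)
  sp <- sp[keep]; y <- y[keep]
  if (length(sp) < 3L) {
    stop("fewer than 3 species with both a profile and the trait",
         call. = FALSE)
  }
  prof <- profiles[sp, , drop = FALSE]
  rows <- lapply(colnames(prof), function(aa) {
    occ <- prof[, aa]
    if (stats::var(occ) == 0 || stats::var(y) == 0) {
      return(data.frame(amino_acid = aa,
                        mean_occurrence_pct = mean(occ),
                        r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(occ, y, method = "pearson")
    data.frame(amino_acid = aa, mean_occurrence_pct = mean(occ),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
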