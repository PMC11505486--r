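#' Median pairwise dN/dS of one gene in one focal species
#'
#' The package's genomic characteristic: for a gene and a focal species,
#' the median of the pairwise dN/dS values between the focal species'
#' sequence and each other functional ortholog in the taxon (a star around
#' the focal species). Pairs with undefined omega (dS = 0) or a saturated
#' correction are excluded from the median and counted. The median is the
#' middle order statistic (mean of the two middle values for even counts).
#'
#' @param gene Gene identifier (must match `aln$gene_id` records in `map`).
#' @param focal Focal species identifier.
#' @param aln A filtered, gap-free [codon_alignment()] for the gene.
#' @param map Ortholog map data frame (`gene_id`, `species_id`, `status`,
#'   `sequence_id`).
#' @param taxon Character vector of species identifiers forming the taxon.
#' @return Object of class `gene_species_characteristic`: list with
#'   `gene_id`, `species_id`, `median_omega` (`NA` when undefined),
#'   `n_pairs_used`, `n_pairs_excluded`, `reason` (`NA`, `"pseudogene/lost"`
#'   or `"no_pairs"`).
#' @export
median_omega <- function(gene, focal, aln, map, taxon) {
  stopifnot(inherits(aln, "codon_alignment"))
  gmap <- map[map$gene_id == gene, , drop = FALSE]
  status_of <- stats::setNames(gmap$status, gmap$species_id)
  res <- list(gene_id = gene, species_id = focal,
              median_omega = NA_real_, n_pairs_used = 0L,
              n_pairs_excluded = 0L, reason = NA_character_)
  class(res) <- "gene_species_characteristic"

  if (is.na(status_of[focal]) || status_of[focal] != "functional") {
    res$reason <- "pseudogene/lost"
    return(res)
  }
  others <- setdiff(taxon, focal)
  others <- others[!is.na(status_of[others]) &
                     status_of[others] == "functional" &
                     others %in% names(aln$seqs)]
  if (length(others) == 0L || !(focal %in% names(aln$seqs))) {
    res$reason <- "no_pairs"
    return(res)
  }
  omegas <- vapply(others, function(sp) {
    est <- estimate_pair(aln$seqs[[focal]], aln$seqs[[sp]])
    if (est$saturated) NA_real_ else est$omega
  }, numeric(1))
  used <- omegas[!is.na(omegas)]
  res$n_pairs_used <- length(used)
  res$n_pairs_excluded <- sum(is.na(omegas))
  if (length(used) == 0L) {
    res$reason <- "no_pairs"
    return(res)
  }
  res$median_omega <- stats::median(used)
  res
}

#' @export
print.gene_species_characteristic <- function(x, ...) {
  cat("median(dN/dS) for", x$gene_id, "in", x$species_id, "=",
      if (is.na(x$median_omega)) paste0("undefined (", x$reason, ")")
      else format(x$median_omega),
      sprintf("[%d pairs used, %d excluded]\n",
              x$n_pairs_used, x$n_pairs_excluded))
  invisible(x)
}

#' Median characteristic for every functional species of a taxon
#'
#' @inheritParams median_omega
#' @return Data frame with columns `gene_id`, `species_id`, `median_omega`,
#'   `n_pairs_used`, `n_pairs_excluded`, `reason` — one row per taxon
#'   species.
#' @export
median_omega_all <- function(gene, aln, map, taxon) {
  rows <- lapply(taxon, function(sp) {
    ch <- median_omega(gene, sp, aln, map, taxon)
    data.frame(gene_id = ch$gene_id, species_id = ch$species_id,
               median_omega = ch$median_omega,
               n_pairs_used = ch$n_pairs_used,
               n_pairs_excluded = ch$n_pairs_excluded,
               reason = ch$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Variation interval of the median characteristic
#'
#' @param medians Numeric vector of per-species median omegas for one gene
#'   and taxon (`NA` = undefined records, which are ignored).
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
median_interval <- function(medians) {
  medians <- medians[!is.na(medians)]
  if (length(medians) == 0L) {
    stop("no defined median records: interval undefined", call. = FALSE)
  }
  c(min = min(medians), max = max(medians))
}
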