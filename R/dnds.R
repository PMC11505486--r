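#' Fractional synonymous and nonsynonymous site counts for one codon
#'
#' Counts, in the Nei-Gojobori (1986) fashion, the fraction of each of a
#' codon's three positions at which a random single-nucleotide change would
#' be synonymous. Each of the nine single-nucleotide neighbors contributes
#' 1/3 of a synonymous site if it codes the same amino acid; changes that
#' create a stop codon count as nonsynonymous.
#'
#' @param codon A single sense codon (3-letter DNA string, standard code).
#' @return Named numeric vector `c(S = ..., N = ...)` with `S + N == 3`.
#' @examples
#' count_sites("TTT")  # S = 1/3: only TTT -> TTC is synonymous
#' count_sites("CTG")  # S = 4/3: fourfold-degenerate third position + TTG
#' @export
count_sites <- function(codon) {
  if (length(codon) != 1L || !is.character(codon)) {
    stop("`codon` must be a single 3-letter string", call. = FALSE)
  }
  codon <- toupper(codon)
  if (!.is_sense(codon)) {
    stop("not a sense codon: '", codon,
         "' (stop or ambiguous codons have no site counts)", call. = FALSE)
  }
  c(S = .SITE_TABLE[codon, "S"], N = .SITE_TABLE[codon, "N"])
}

#' Pathway-averaged synonymous/nonsynonymous difference counts
#'
#' For two sense codons differing at `k` positions, averages the number of
#' synonymous and nonsynonymous single-nucleotide steps over all `k!`
#' orderings of the changes. Orderings passing through a stop codon are
#' excluded and the average renormalized over the remaining orderings; in
#' the (degenerate) case where every ordering passes through a stop, all
#' orderings are used with stop-involving steps classed nonsynonymous and
#' the result carries attribute `stop_fallback = TRUE`.
#'
#' @param c1,c2 Sense codons (3-letter DNA strings).
#' @return Named numeric vector `c(Sd = ..., Nd = ...)`; `Sd + Nd` equals the
#'   number of differing positions.
#' @examples
#' count_differences("TTT", "TTC")  # one synonymous step
#' count_differences("TTT", "GTA")  # two orderings averaged: (0.5, 1.5)
#' @export
count_differences <- function(c1, c2) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  for (cod in c(c1, c2)) {
    if (!.is_sense(cod)) {
      stop("not a sense codon: '", cod, "'", call. = FALSE)
    }
  }
  pw <- .pair_pathway(c1, c2)
  structure(c(Sd = pw$Sd, Nd = pw$Nd), stop_fallback = pw$stop_fallback)
}

#' Jukes-Cantor multiple-hit correction
#'
#' Converts an observed proportion of differences per site into an estimated
#' number of substitutions per site: `d = -(3/4) * log(1 - 4p/3)`.
#'
#' @param p Proportion(s) of observed differences, `0 <= p < 3/4`.
#' @return Corrected distance(s), `d >= p`.
#' @export
jukes_cantor <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("`p` must be finite and non-negative", call. = FALSE)
  }
  if (any(p >= 0.75)) {
    stop(errorCondition(
      paste0("proportion p = ", max(p), " >= 3/4: substitution saturation, ",
             "distance undefined"),
      class = c("evorate_saturation_error", "error")))
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS for two aligned coding sequences
#'
#' Implements counting-based dN/dS estimation: fractional site counts are
#' summed per codon and averaged between the two sequences; difference
#' counts are pathway-averaged per codon pair and summed; proportions
#' `pS = Sd/S`, `pN = Nd/N` are Jukes-Cantor corrected into `dS`, `dN`; and
#' `omega = dN/dS` when `dS > 0` (otherwise `NA`, the pair being
#' uninformative about the ratio). A proportion at or beyond the
#' correction's domain boundary (3/4) makes the corresponding distance
#' `Inf` and flags the pair `saturated`; such pairs are excluded from
#' downstream medians but still report a conventional omega (0 when only
#' `dS` saturates, `NA` when both do) instead of raising an error.
#'
#' @param seqA,seqB In-frame, gap-free, equal-length nucleotide strings
#'   (post [filter_alignment()]). Internal stop codons raise an error, since
#'   they signal pseudogenized input.
#' @return An object of class `codon_pair_counts`: a list with elements
#'   `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons`,
#'   `saturated`, `stop_fallback`.
#' @examples
#' p <- estimate_pair("TTTTTC", "TTCTTC")
#' p$Sd  # 1 synonymous difference
#' p$omega  # 0: no nonsynonymous change, positive dS
#' @export
estimate_pair <- function(seqA, seqB) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) != nchar(seqB)) {
    stop("sequences differ in length (", nchar(seqA), " vs ", nchar(seqB),
         ")", call. = FALSE)
  }
  codA <- .split_codons(seqA)
  codB <- .split_codons(seqB)
  if (length(codA) == 0L) stop("zero codons to compare", call. = FALSE)
  bad <- c(codA, codB)[!(c(codA, codB) %in% names(.GENETIC_CODE))]
  if (length(bad) > 0L) {
    stop("non-ACGT codon(s) in input (gaps/N must be filtered first): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  stops <- c(codA, codB)[c(codA, codB) %in% .STOP_CODONS]
  if (length(stops) > 0L) {
    stop(errorCondition(
      "internal stop codon in sequence: pseudogenized input",
      class = c("evorate_stop_codon_error", "error")))
  }

  S <- sum(.SITE_TABLE[codA, "S"] + .SITE_TABLE[codB, "S"]) / 2
  N <- sum(.SITE_TABLE[codA, "N"] + .SITE_TABLE[codB, "N"]) / 2

  pm <- .path_matrices()
  ia <- match(codA, .SENSE_CODONS)
  ib <- match(codB, .SENSE_CODONS)
  idx <- cbind(ia, ib)
  Sd <- sum(pm$SD[idx])
  Nd <- sum(pm$ND[idx])
  stop_fb <- any(vapply(which(codA != codB), function(i) {
    isTRUE(attr(count_differences(codA[i], codB[i]), "stop_fallback"))
  }, logical(1)))

  pS <- Sd / S
  pN <- Nd / N
  saturated <- pS >= 0.75 || pN >= 0.75
  dS <- if (pS >= 0.75) Inf else jukes_cantor(pS)
  dN <- if (pN >= 0.75) Inf else jukes_cantor(pN)
  omega <- if (dS > 0) dN / dS else NA_real_
  if (is.nan(omega)) omega <- NA_real_

  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 n_codons = length(codA), saturated = saturated,
                 stop_fallback = stop_fb),
            class = "codon_pair_counts")
}

#' @export
print.codon_pair_counts <- function(x, ...) {
  cat("Codon pair counts over", x$n_codons, "codons\n")
  cat(sprintf("  sites        S = %.3f, N = %.3f\n", x$S, x$N))
  cat(sprintf("  differences  Sd = %.3f, Nd = %.3f\n", x$Sd, x$Nd))
  if (x$saturated) {
    cat("  saturated pair: distances undefined\n")
  } else {
    cat(sprintf("  distances    dS = %.5f, dN = %.5f\n", x$dS, x$dN))
    cat("  omega (dN/dS):",
        if (is.na(x$omega)) "undefined (dS = 0)" else format(x$omega), "\n")
  }
  invisible(x)
}

#' All-pairs dN/dS table for one codon alignment
#'
#' Runs [estimate_pair()] over every unordered pair of sequences in a
#' (filtered, gap-free) codon alignment.
#'
#' @param aln A [codon_alignment()].
#' @return A data frame with one row per unordered species pair and columns
#'   `speciesA`, `speciesB`, `S`, `N`, `Sd`, `Nd`, `dN`, `dS`, `omega`,
#'   `saturated` (`omega` is `NA` where undefined).
#' @export
pairwise_dnds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  sp <- names(aln$seqs)
  if (length(sp) < 2L) stop("need at least two sequences", call. = FALSE)
  combs <- utils::combn(sp, 2L)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1L, k]; b <- combs[2L, k]
    est <- estimate_pair(aln$seqs[[a]], aln$seqs[[b]])
    data.frame(speciesA = a, speciesB = b,
               S = est$S, N = est$N, Sd = est$Sd, Nd = est$Nd,
               dN = est$dN, dS = est$dS, omega = est$omega,
               saturated = est$saturated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
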