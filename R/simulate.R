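#' Simulation parameters for the codon substitution simulator
#'
#' @param omega_true Target dN/dS ratio (>= 0): acceptance probability of a
#'   proposed nonsynonymous change.
#' @param kappa Transition/transversion rate ratio (>= 0) used to weight
#'   proposals (counting-based estimation deliberately ignores it, which is
#'   the realistic mismatch the recovery tests quantify).
#' @param t Expected number of substitution proposals per codon site.
#' @param n_codons Sequence length in codons.
#' @param seed Integer seed; fixes the full output.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(omega_true, kappa = 2, t = 0.3, n_codons = 500,
                       seed = 1L) {
  stopifnot(length(omega_true) == 1L, omega_true >= 0,
            length(kappa) == 1L, kappa >= 0,
            length(t) == 1L, t >= 0,
            length(n_codons) == 1L, n_codons >= 1)
  structure(list(omega_true = omega_true, kappa = kappa, t = t,
                 n_codons = as.integer(n_codons), seed = as.integer(seed)),
            class = "sim_params")
}

# Evolve a codon vector in place for a Poisson(t * n_codons) number of
# proposal events; uses the caller's RNG stream.
.evolve_codons <- function(codons, omega, kappa, t) {
  n <- length(codons)
  n_events <- stats::rpois(1L, t * n)
  if (n_events == 0L) return(codons)
  targets <- sample.int(n, n_events, replace = TRUE)
  positions <- sample.int(3L, n_events, replace = TRUE)
  for (e in seq_len(n_events)) {
    cod <- codons[[targets[e]]]
    pos <- positions[e]
    cur <- substr(cod, pos, pos)
    alts <- setdiff(.NUC, cur)
    w <- ifelse(.is_transition(rep(cur, 3L), alts), kappa, 1)
    if (all(w == 0)) next
    nuc <- sample(alts, 1L, prob = w)
    prop <- cod
    substr(prop, pos, pos) <- nuc
    aa_new <- .GENETIC_CODE[[prop]]
    if (aa_new == "*") next                     # never fix a stop codon
    if (aa_new == .GENETIC_CODE[[cod]]) {
      codons[[targets[e]]] <- prop              # synonymous: always accepted
    } else if (stats::runif(1L) < omega) {
      codons[[targets[e]]] <- prop              # nonsynonymous: prob omega
    }
  }
  codons
}

#' Simulate a diverged pair of coding sequences
#'
#' Draws an ancestral sequence uniformly over the 61 sense codons and
#' evolves a derived copy by repeated single-nucleotide proposals: a random
#' codon and codon position are picked, the replacement nucleotide is drawn
#' with transitions weighted `kappa` against transversions, and the change
#' is accepted with probability 1 if synonymous, `omega_true` if
#' nonsynonymous, and 0 if it would create a stop codon. The number of
#' proposal events is Poisson with mean `t * n_codons`. Deterministic given
#' the seed.
#'
#' @param params A [sim_params()] object.
#' @return List with `ancestral` and `derived` nucleotide strings.
#' @examples
#' sim <- simulate_pair(sim_params(omega_true = 0, t = 0.5, n_codons = 50))
#' estimate_pair(sim$ancestral, sim$derived)$Nd  # 0 under omega_true = 0
#' @export
simulate_pair <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  anc <- sample(.SENSE_CODONS, params$n_codons, replace = TRUE)
  der <- .evolve_codons(anc, params$omega_true, params$kappa, params$t)
  list(ancestral = paste(anc, collapse = ""),
       derived = paste(der, collapse = ""))
}
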