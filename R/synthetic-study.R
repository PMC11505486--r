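# Seeded generators for complete synthetic studies: ortholog sequence
# sets diverged under per-species omega, trait tables with a planted
# linear trait-vs-median relationship, planted-deviation domain
# alignments, and composition profiles with planted trait correlations.

# Average amino-acid background composition (percent) used when building
# synthetic proteins; approximate vertebrate proteome frequencies.
.BASE_AA_PCT <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6,
                  H = 2.6, I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6,
                  P = 6.3, Q = 4.8, R = 5.6, S = 8.3, T = 5.4, V = 6.0,
                  W = 1.2, Y = 2.7)

#' Configuration of a synthetic study
#'
#' Bundles every tunable of the synthetic-study generators. The defaults
#' mirror the kind of signal the pipeline is designed to detect: a gene
#' whose per-species evolutionary rate is coupled to the traits (median
#' characteristic spanning `omega_range`), a planted linear lifespan model
#' `mrls = 439 * median - 36` with noise calibrated to a population
#' correlation of 0.76 at the default range, a log-weight model
#' `lg(weight) = 25 * median - 1` (r = 0.67), and a +17% planted
#' longevity-quotient contrast for a carrier set. All values are
#' configuration, not constants.
#'
#' @param n_species Number of species in the study.
#' @param n_codons Codon length of each simulated gene.
#' @param genes Named list: gene id -> list with `omega_mode`
#'   (`"constant"` or `"trait_coupled"`) and either `omega` (constant) or
#'   `omega_range` (coupled).
#' @param kappa,t Simulator transition/transversion ratio and expected
#'   proposals per codon per branch.
#' @param pseudogene_fraction,lost_fraction Fractions of species marked
#'   pseudogene (internal stop planted) or lost (absent) for each gene.
#' @param mrls_model,lgw_model Lists `(slope, intercept, r)` for the
#'   planted lifespan (years) and log10-weight (grams) models; noise is
#'   derived from the target correlation `r` over `omega_range`.
#' @param lq_model List `(baseline_median, percent_difference, sdlog)`
#'   for the longevity-quotient generator.
#' @param seed Integer seed fixing the whole study.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_species = 20,
                         n_codons = 300,
                         genes = list(
                           geneA = list(omega_mode = "trait_coupled",
                                        omega_range = c(0.074, 0.178)),
                           geneB = list(omega_mode = "constant",
                                        omega = 0.05)),
                         kappa = 2, t = 0.3,
                         pseudogene_fraction = 0,
                         lost_fraction = 0,
                         mrls_model = list(slope = 439, intercept = -36,
                                           r = 0.76),
                         lgw_model = list(slope = 25, intercept = -1,
                                          r = 0.67),
                         lq_model = list(baseline_median = 1,
                                         percent_difference = 17,
                                         sdlog = 0.3),
                         seed = 1L) {
  stopifnot(n_species >= 2, n_codons >= 1,
            pseudogene_fraction >= 0, lost_fraction >= 0,
            pseudogene_fraction + lost_fraction < 1)
  structure(list(n_species = as.integer(n_species),
                 n_codons = as.integer(n_codons), genes = genes,
                 kappa = kappa, t = t,
                 pseudogene_fraction = pseudogene_fraction,
                 lost_fraction = lost_fraction,
                 mrls_model = mrls_model, lgw_model = lgw_model,
                 lq_model = lq_model, seed = as.integer(seed)),
            class = "study_config")
}

#' Generate ortholog sequence sets and their status map
#'
#' For each configured gene, draws one ancestral sequence and evolves an
#' independent branch to every species with the species' own omega: for
#' `trait_coupled` genes the omegas are evenly spaced over `omega_range`
#' (so downstream median characteristics are monotone in the planted
#' rate); for `constant` genes every branch uses the same omega. A
#' configurable fraction of species is marked pseudogene (an internal stop
#' codon is planted in the emitted sequence) or lost (no sequence).
#'
#' @param config A [study_config()].
#' @return List with `alignments` (named list of [codon_alignment()], one
#'   per gene, functional + pseudogene sequences), `ortholog_map` (data
#'   frame), `true_omegas` (named list per gene of the per-species branch
#'   omegas), `species` (identifiers).
#' @export
generate_ortholog_set <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  n <- config$n_species
  species <- sprintf("sp%03d", seq_len(n))
  n_pseudo <- ceiling(config$pseudogene_fraction * n)
  n_lost <- floor(config$lost_fraction * n)
  status <- rep("functional", n)
  if (n_pseudo + n_lost > 0) {
    flagged <- sample(species, n_pseudo + n_lost)
    status[species %in% flagged[seq_len(n_pseudo)]] <- "pseudogene"
    if (n_lost > 0) {
      status[species %in% flagged[n_pseudo + seq_len(n_lost)]] <- "lost"
    }
  }
  names(status) <- species

  alignments <- list()
  true_omegas <- list()
  map_rows <- list()
  for (gene in names(config$genes)) {
    gcfg <- config$genes[[gene]]
    omegas <- if (identical(gcfg$omega_mode, "constant")) {
      rep(gcfg$omega, n)
    } else {
      seq(gcfg$omega_range[1L], gcfg$omega_range[2L], length.out = n)
    }
    names(omegas) <- species
    anc <- sample(.SENSE_CODONS, config$n_codons, replace = TRUE)
    seqs <- character(0)
    for (sp in species) {
      if (status[[sp]] == "lost") next
      der <- .evolve_codons(anc, omegas[[sp]], config$kappa, config$t)
      if (status[[sp]] == "pseudogene") {
        # plant an internal stop at a middle codon
        der[[max(2L, length(der) %/% 2L)]] <- "TAA"
      }
      seqs[[sp]] <- paste(der, collapse = "")
    }
    alignments[[gene]] <- codon_alignment(seqs, gene_id = gene)
    true_omegas[[gene]] <- omegas
    map_rows[[gene]] <- data.frame(
      gene_id = gene, species_id = species, status = unname(status),
      sequence_id = ifelse(status == "lost", "",
                           paste0(gene, "_", species)),
      stringsAsFactors = FALSE)
  }
  list(alignments = alignments,
       ortholog_map = do.call(rbind, unname(map_rows)),
       true_omegas = true_omegas, species = species)
}

#' Generate a trait table from planted linear models
#'
#' Plants `mrls = a * median + b + e` (years) and
#' `lg(weight) = a' * median + b' + e'` (log10 grams), with independent
#' Gaussian noise on the modeled scale; noise levels are derived from the
#' models' target population correlations via [noise_sd_for_r()] using the
#' spread of the supplied medians. Longevity quotients are drawn
#' log-normally around `baseline_median`, with `carriers` shifted
#' multiplicatively by `1 + percent_difference/100`. By default the raw
#' linear model is kept even where it dips below zero at the low end of
#' the median range (as a fitted line on real data does); set `floor` to
#' clamp traits at a positive value instead.
#'
#' @param medians Named numeric vector: species -> median characteristic
#'   (`NA` entries produce missing traits).
#' @param config A [study_config()] supplying the trait models.
#' @param carriers Species whose LQ is shifted (default none).
#' @param floor Optional positive clamp for generated mrls/weights.
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return Trait table data frame (`species_id`, `mrls`, `weight`, `lq`,
#'   `taxon`).
#' @export
generate_traits <- function(medians, config, carriers = character(0),
                            floor = NULL, seed = NULL) {
  stopifnot(inherits(config, "study_config"), !is.null(names(medians)))
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  sd_x <- stats::sd(medians, na.rm = TRUE)
  mm <- config$mrls_model
  wm <- config$lgw_model
  mrls_sd <- if (is.null(mm$noise_sd)) {
    if (is.na(sd_x) || sd_x == 0) 0 else noise_sd_for_r(mm$slope, sd_x, mm$r)
  } else mm$noise_sd
  lgw_sd <- if (is.null(wm$noise_sd)) {
    if (is.na(sd_x) || sd_x == 0) 0 else noise_sd_for_r(wm$slope, sd_x, wm$r)
  } else wm$noise_sd
  n <- length(medians)
  mrls <- mm$slope * medians + mm$intercept + stats::rnorm(n, 0, mrls_sd)
  lgw <- wm$slope * medians + wm$intercept + stats::rnorm(n, 0, lgw_sd)
  if (!is.null(floor)) {
    mrls <- pmax(mrls, floor)
    lgw <- pmax(lgw, log10(floor))
  }
  lqm <- config$lq_model
  lq <- lqm$baseline_median * exp(stats::rnorm(n, 0, lqm$sdlog))
  shift <- names(medians) %in% carriers
  lq[shift] <- lq[shift] * (1 + lqm$percent_difference / 100)
  data.frame(species_id = names(medians),
             mrls = unname(mrls),
             weight = unname(10^lgw),
             lq = unname(lq),
             taxon = "synthetic_taxon",
             stringsAsFactors = FALSE)
}

#' Generate a domain alignment realizing a planted deviation plan
#'
#' Builds a consensus of the requested length, assigns species to taxa,
#' and plants deviations exactly as specified: for each plan row, `n`
#' species of the taxon receive, at the given position, a residue from a
#' different physicochemical group (`radical = TRUE`) or a different
#' residue from the consensus residue's own group (`radical = FALSE`).
#' Positions without plan rows match the consensus in every species, so
#' [deviation_counts()] recovers the plan exactly.
#'
#' @param taxa Named integer vector: taxon -> number of species.
#' @param n_positions Domain length (default 54 columns).
#' @param plan Data frame with columns `position`, `taxon`, `n`,
#'   `radical`; empty by default.
#' @param scheme Group scheme.
#' @param seed Integer seed.
#' @return List with `msa` (named character), `taxon_map` (named
#'   character: species -> taxon), `consensus`, `plan`, and `deviants`
#'   (named list position -> deviant species).
#' @export
generate_domain_alignment <- function(taxa = c(taxonA = 10, taxonB = 10),
                                      n_positions = 54,
                                      plan = NULL, scheme = aa_groups(),
                                      seed = 1L) {
  set.seed(seed)
  if (is.null(plan)) {
    plan <- data.frame(position = integer(0), taxon = character(0),
                       n = integer(0), radical = logical(0))
  }
  stopifnot(all(c("position", "taxon", "n", "radical") %in% names(plan)))
  if (any(!plan$taxon %in% names(taxa))) {
    stop("plan references unknown taxa", call. = FALSE)
  }
  if (any(plan$n > taxa[plan$taxon])) {
    stop("plan requests more deviants than the taxon has species",
         call. = FALSE)
  }
  if (any(plan$position < 1 | plan$position > n_positions)) {
    stop("plan positions outside the domain", call. = FALSE)
  }
  lookup <- .group_lookup(scheme)
  multi <- names(lookup)[lookup %in% names(which(table(lookup) > 1))]
  consensus <- sample(.AA20, n_positions, replace = TRUE)
  # positions carrying a within-group (non-radical) plan need a consensus
  # residue whose group has an alternative member
  for (p in unique(plan$position[!plan$radical])) {
    if (!(consensus[p] %in% multi)) consensus[p] <- sample(multi, 1L)
  }
  species <- sprintf("%s_sp%02d", rep(names(taxa), taxa),
                     unlist(lapply(taxa, seq_len)))
  taxon_map <- stats::setNames(rep(names(taxa), taxa), species)
  rows <- matrix(rep(consensus, each = length(species)),
                 nrow = length(species),
                 dimnames = list(species, NULL))
  deviants <- list()
  for (k in seq_len(nrow(plan))) {
    p <- plan$position[k]; tx <- plan$taxon[k]
    members <- species[taxon_map == tx]
    chosen <- sample(members, plan$n[k])
    cons_aa <- consensus[p]
    pool <- if (plan$radical[k]) {
      names(lookup)[lookup != lookup[[cons_aa]]]
    } else {
      setdiff(names(lookup)[lookup == lookup[[cons_aa]]], cons_aa)
    }
    rows[chosen, p] <- sample(pool, length(chosen), replace = TRUE)
    deviants[[as.character(p)]] <- union(deviants[[as.character(p)]],
                                         chosen)
  }
  msa <- stats::setNames(apply(rows, 1L, paste, collapse = ""), species)
  list(msa = msa, taxon_map = taxon_map,
       consensus = paste(consensus, collapse = ""), plan = plan,
       deviants = deviants)
}

#' Generate protein sequences with planted composition-trait correlations
#'
#' Draws a lifespan per species, then builds each species' protein so that
#' the occurrence of selected amino acids correlates with lifespan at the
#' planted population level (default: leucine r = +0.62, proline
#' r = -0.7). Occurrences are realized as residue counts by
#' largest-remainder rounding, so the emitted sequences carry the planted
#' signal up to rounding noise.
#'
#' @param n_species Number of species.
#' @param planted_r Named numeric vector amino acid -> target population
#'   correlation with lifespan.
#' @param occ_sd Standard deviation (percentage points) of each planted
#'   amino acid's occurrence across species.
#' @param n_residues Protein length.
#' @param mrls_range Lifespans are drawn uniformly over this range
#'   (years).
#' @param seed Integer seed.
#' @return List with `proteins` (named character), `traits` (data frame
#'   with `species_id`, `mrls`, `weight`, `lq`).
#' @export
generate_composition_study <- function(n_species = 49,
                                       planted_r = c(L = 0.62, P = -0.7),
                                       occ_sd = 0.6,
                                       n_residues = 434,
                                       mrls_range = c(2, 70),
                                       seed = 1L) {
  set.seed(seed)
  species <- sprintf("sp%03d", seq_len(n_species))
  mrls <- stats::runif(n_species, mrls_range[1L], mrls_range[2L])
  z <- as.numeric(scale(mrls))
  pct <- matrix(rep(.BASE_AA_PCT, each = n_species), nrow = n_species,
                dimnames = list(species, names(.BASE_AA_PCT)))
  for (aa in names(planted_r)) {
    r <- planted_r[[aa]]
    noise <- stats::rnorm(n_species)
    occ <- .BASE_AA_PCT[[aa]] + occ_sd * (r * z + sqrt(1 - r^2) * noise)
    pct[, aa] <- pmax(occ, 0.05)
  }
  free <- setdiff(colnames(pct), names(planted_r))
  # rescale the unplanted amino acids so each species sums to 100
  for (i in seq_len(n_species)) {
    rem <- 100 - sum(pct[i, names(planted_r)])
    pct[i, free] <- pct[i, free] * rem / sum(pct[i, free])
  }
  proteins <- vapply(seq_len(n_species), function(i) {
    counts <- .largest_remainder(pct[i, ] * n_residues / 100, n_residues)
    paste(sample(rep(colnames(pct), counts)), collapse = "")
  }, character(1))
  names(proteins) <- species
  traits <- data.frame(species_id = species, mrls = mrls,
                       weight = NA_real_, lq = NA_real_,
                       stringsAsFactors = FALSE)
  list(proteins = proteins, traits = traits)
}

# Round non-negative reals to integers summing to `total`, assigning the
# leftover units to the largest fractional parts (ties by order).
.largest_remainder <- function(x, total) {
  base <- floor(x)
  left <- total - sum(base)
  if (left > 0) {
    frac <- x - base
    up <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[up] <- base[up] + 1
  }
  as.integer(base)
}
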