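#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir Output directory (created if absent); inputs are written
#'   under `out_dir/inputs` and reports under `out_dir/reports`.
#' @param study A [study_config()] describing the synthetic study; ignored
#'   when `inputs` points at existing files.
#' @param inputs Optional named list of pre-existing input paths
#'   (`alignments` — named FASTA paths per gene, `ortholog_map`, `traits`)
#'   to ingest instead of simulating. All referenced files must exist; the
#'   check runs before any computation.
#' @param taxa Named list of species sets (taxon definitions). Default: a
#'   single taxon holding every study species.
#' @param alpha Significance threshold for [classify_selection_signal()].
#' @param min_frac Short-sequence threshold passed to
#'   [filter_alignment()].
#' @param domain List describing the domain analysis: arguments for
#'   [generate_domain_alignment()] plus `position` and `residue` of
#'   interest.
#' @param seed Master seed; every stage derives its randomness from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            study = study_config(),
                            inputs = NULL,
                            taxa = NULL,
                            alpha = 1e-3,
                            min_frac = 0.5,
                            domain = list(taxa = c(taxonA = 10,
                                                   taxonB = 10),
                                          n_positions = 54,
                                          plan = NULL,
                                          position = 19,
                                          residue = "N"),
                            seed = 1L) {
  structure(list(out_dir = out_dir, study = study, inputs = inputs,
                 taxa = taxa, alpha = alpha, min_frac = min_frac,
                 domain = domain, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest -> filter -> pairwise dN/dS -> median
#' characteristic -> trait association (both traits) -> amino-acid
#' composition -> domain consensus/deviation/LQ analysis, writing every
#' input and report as plain TSV/FASTA plus a JSON manifest (seed, package
#' version, input digests). Given one seed the run is fully deterministic:
#' two runs produce byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory results (`associations`,
#'   `medians`, `composition`, `deviation_all`, `deviation_radical`,
#'   `lq_comparison`, `manifest`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs, use.names = FALSE)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop("pipeline pre-flight: missing input file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  in_dir <- file.path(config$out_dir, "inputs")
  rep_dir <- file.path(config$out_dir, "reports")
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- stage: simulate or ingest ------------------------------------
  config$study$seed <- config$seed
  dom_cfg <- config$domain
  dom <- .stage("simulate_domain", generate_domain_alignment(
    taxa = dom_cfg$taxa, n_positions = dom_cfg$n_positions,
    plan = dom_cfg$plan, seed = config$seed + 2L))

  if (is.null(config$inputs)) {
    study <- .stage("simulate", generate_ortholog_set(config$study))
    aln_paths <- character(0)
    for (gene in names(study$alignments)) {
      p <- file.path(in_dir, paste0(gene, ".fasta"))
      write_codon_alignment(study$alignments[[gene]], p)
      aln_paths[[gene]] <- p
    }
    map_path <- file.path(in_dir, "ortholog_map.tsv")
    write_ortholog_map(study$ortholog_map, map_path)
  } else {
    aln_paths <- unlist(config$inputs$alignments)
    map_path <- config$inputs$ortholog_map
  }

  # ---- stage: ingest + filter + dnds + medians ----------------------
  map <- .stage("ingest", read_ortholog_map(map_path))
  taxa <- config$taxa
  medians <- list()
  pair_tables <- list()
  filtered <- list()
  for (gene in names(aln_paths)) {
    aln <- .stage("ingest", read_codon_alignment(aln_paths[[gene]],
                                                 gene_id = gene))
    fun_sp <- map$species_id[map$gene_id == gene &
                               map$status == "functional"]
    fun_sp <- intersect(names(aln$seqs), fun_sp)
    faln <- .stage("filter", filter_alignment(
      codon_alignment(aln$seqs[fun_sp], gene_id = gene),
      min_frac = config$min_frac))
    filtered[[gene]] <- faln
    if (is.null(taxa)) taxa <- list(all = map$species_id[
      map$gene_id == gene])
    pt <- .stage("dnds", pairwise_dnds(faln))
    pair_tables[[gene]] <- pt
    .write_delim_auto(pt, file.path(rep_dir, paste0("dnds_", gene,
                                                    ".tsv")))
    med <- .stage("median", do.call(rbind, lapply(names(taxa),
      function(tx) {
        d <- median_omega_all(gene, faln, map, taxa[[tx]])
        d$taxon <- tx
        d
      })))
    medians[[gene]] <- med
    .write_delim_auto(med, file.path(rep_dir, paste0("median_", gene,
                                                     ".tsv")))
  }

  # ---- stage: traits ------------------------------------------------
  if (is.null(config$inputs)) {
    coupled <- names(config$study$genes)[vapply(config$study$genes,
      function(g) identical(g$omega_mode, "trait_coupled"), logical(1))]
    base_gene <- if (length(coupled) > 0L) coupled[[1L]] else
      names(aln_paths)[[1L]]
    med_vec <- stats::setNames(medians[[base_gene]]$median_omega,
                               medians[[base_gene]]$species_id)
    med_vec <- med_vec[!duplicated(names(med_vec))]
    # file-backed trait tables must satisfy the positivity invariant, so
    # the pipeline clamps the planted models at a token 0.1 years / 0.1 g
    traits <- .stage("traits", generate_traits(med_vec, config$study,
                                               floor = 0.1))
    traits_path <- file.path(in_dir, "traits.tsv")
    write_trait_table(traits, traits_path)
  } else {
    traits_path <- config$inputs$traits
  }
  traits <- .stage("ingest", read_trait_table(traits_path))

  # ---- stage: associations ------------------------------------------
  assoc <- list()
  for (gene in names(medians)) {
    for (tr in c("mrls", "lg_weight")) {
      res <- .stage("associate", tryCatch(
        fit_association(medians[[gene]], traits, trait = tr,
                        gene_id = gene),
        error = function(e) NULL))
      if (!is.null(res)) {
        row <- as.data.frame(res)
        row$signal <- classify_selection_signal(res, config$alpha)
        assoc[[paste(gene, tr)]] <- row
      }
    }
  }
  assoc_df <- do.call(rbind, assoc)
  rownames(assoc_df) <- NULL
  .write_delim_auto(assoc_df, file.path(rep_dir, "associations.tsv"))

  # ---- stage: composition -------------------------------------------
  first_gene <- names(aln_paths)[[1L]]
  faln <- filtered[[first_gene]]
  proteins <- vapply(faln$seqs, function(s) {
    paste(.GENETIC_CODE[.split_codons(s)], collapse = "")
  }, character(1))
  profiles <- .stage("aacomp", composition_profiles(proteins))
  comp <- .stage("aacomp", correlate_composition(profiles, traits,
                                                 trait = "mrls"))
  .write_delim_auto(comp, file.path(rep_dir, "composition.tsv"))

  # ---- stage: domain -------------------------------------------------
  dom_traits <- .stage("domain", {
    lqm <- config$study$lq_model
    set.seed(config$seed + 3L)
    sp <- names(dom$taxon_map)
    lq <- lqm$baseline_median * exp(stats::rnorm(length(sp), 0,
                                                 lqm$sdlog))
    carriers <- dom$deviants[[as.character(dom_cfg$position)]]
    lq[sp %in% carriers] <- lq[sp %in% carriers] *
      (1 + lqm$percent_difference / 100)
    data.frame(species_id = sp, mrls = NA_real_, weight = NA_real_,
               lq = lq, stringsAsFactors = FALSE)
  })
  cons <- build_consensus(dom$msa)
  dev_all <- deviation_counts(dom$msa, cons, dom$taxon_map, mode = "all")
  dev_rad <- deviation_counts(dom$msa, cons, dom$taxon_map,
                              mode = "radical")
  for (nm in c("all", "radical")) {
    dt <- if (nm == "all") dev_all else dev_rad
    out <- data.frame(taxon = rownames(dt$counts), dt$counts,
                      conservative = dt$conservative,
                      stringsAsFactors = FALSE)
    names(out) <- c("taxon", paste0("pos", seq_len(ncol(dt$counts))),
                    "conservative")
    .write_delim_auto(out, file.path(rep_dir,
                                     paste0("domain_deviation_", nm,
                                            ".tsv")))
  }
  lq_cmp <- if (length(dom$deviants) > 0L) {
    .stage("domain", residue_lq_compare(
      dom$msa, dom_cfg$position, dom_traits,
      mode = "radical_vs_consensus", consensus = cons))
  } else NULL
  if (!is.null(lq_cmp)) {
    .write_delim_auto(as.data.frame(lq_cmp),
                      file.path(rep_dir, "lq_comparison.tsv"))
  }

  # ---- manifest ------------------------------------------------------
  input_files <- sort(list.files(in_dir, full.names = TRUE))
  manifest <- list(
    package = "evorate",
    version = as.character(utils::packageVersion("evorate")),
    seed = config$seed,
    inputs = lapply(stats::setNames(input_files, basename(input_files)),
                    function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(associations = assoc_df, medians = medians,
                 composition = comp, deviation_all = dev_all,
                 deviation_radical = dev_rad, lq_comparison = lq_cmp,
                 manifest = manifest,
                 paths = list(inputs = in_dir, reports = rep_dir)))
}
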