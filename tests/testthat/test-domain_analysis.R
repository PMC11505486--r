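test_that("the six-group scheme partitions the 20 amino acids", {
  groups <- aa_groups()
  expect_length(groups, 6)
  expect_setequal(unlist(groups), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(anyDuplicated(unlist(groups)), 0)
})

test_that("radical substitutions cross group boundaries", {
  expect_true(is_radical("C", "Y"))   # cysteine vs aromatic
  expect_true(is_radical("R", "W"))   # basic vs aromatic
  expect_false(is_radical("L", "V"))  # both aliphatic
  expect_false(is_radical("N", "N"))
  expect_error(is_radical("B", "A"), "non-standard")

  # full brute-force oracle over all 190 unordered pairs + symmetry
  groups <- aa_groups()
  group_of <- function(aa) names(groups)[vapply(groups, function(g)
    aa %in% g, logical(1))]
  aas <- sort(unlist(groups))
  for (i in seq_along(aas)) {
    for (j in seq_along(aas)) {
      expected <- !identical(group_of(aas[i]), group_of(aas[j]))
      expect_identical(is_radical(aas[i], aas[j]), expected)
      expect_identical(is_radical(aas[i], aas[j]),
                       is_radical(aas[j], aas[i]))
    }
  }
})

test_that("consensus takes the plurality residue, ties alphabetical", {
  msa <- c(a = "NNA", b = "NSA", c = "SSA")
  cons <- build_consensus(msa)
  expect_equal(as.character(cons), "NSA")

  tie <- build_consensus(c(a = "NA", b = "SA"))
  expect_equal(as.character(tie), "NA")
  expect_equal(attr(tie, "tie_positions"), 1L)

  # gaps are ignored; an all-gap column has no consensus
  gappy <- build_consensus(c(a = "-A", b = "SA", c = "SA"))
  expect_equal(as.character(gappy), "SA")
  expect_error(build_consensus(c(a = "-A", b = "-A")), "entirely gaps")

  wide <- build_consensus(setNames(rep(paste(rep("A", 54), collapse = ""),
                                       3), c("a", "b", "c")))
  expect_equal(nchar(as.character(wide)), 54)
})

test_that("deviation counts follow the mode and never count gaps", {
  msa <- c(a = "NAA", b = "NAA", c = "SAA")
  tmap <- c(a = "tx1", b = "tx1", c = "tx1")
  all_dev <- deviation_counts(msa, "NAA", tmap, mode = "all")
  expect_equal(unname(all_dev$counts["tx1", ]), c(1, 0, 0))
  expect_equal(unname(all_dev$conservative["tx1"]), 2)

  # N (amide group) vs S (small group) is a radical deviation too
  rad <- deviation_counts(msa, "NAA", tmap, mode = "radical")
  expect_equal(unname(rad$counts["tx1", ]), c(1, 0, 0))

  # a within-group deviation (L vs V) disappears in radical mode
  msa2 <- c(a = "LAA", b = "LAA", c = "VAA")
  expect_equal(unname(deviation_counts(msa2, "LAA", tmap,
                                       "all")$counts[1, 1]), 1)
  expect_equal(unname(deviation_counts(msa2, "LAA", tmap,
                                       "radical")$counts[1, 1]), 0)

  # gapped residues are not deviations
  msa3 <- c(a = "NAA", b = "-AA", c = "NAA")
  expect_equal(unname(deviation_counts(msa3, "NAA", tmap,
                                       "all")$counts[1, 1]), 0)

  expect_error(deviation_counts(msa, "NAA", c(a = "tx1", b = "tx1"),
                                "all"), "without a taxon")
})

test_that("radical counts never exceed all-substitution counts", {
  gen <- generate_domain_alignment(
    taxa = c(tA = 8, tB = 6), n_positions = 20,
    plan = data.frame(position = c(3, 3, 11, 17),
                      taxon = c("tA", "tB", "tA", "tB"),
                      n = c(4, 2, 5, 6),
                      radical = c(TRUE, FALSE, FALSE, TRUE)),
    seed = 12)
  alln <- deviation_counts(gen$msa, gen$consensus, gen$taxon_map, "all")
  radn <- deviation_counts(gen$msa, gen$consensus, gen$taxon_map,
                           "radical")
  expect_true(all(radn$counts <= alln$counts))
  # replacing every row by the consensus zeroes all deviations
  flat <- setNames(rep(gen$consensus, length(gen$msa)), names(gen$msa))
  refit <- deviation_counts(flat, NULL, gen$taxon_map, "all")
  expect_equal(as.character(build_consensus(flat)), gen$consensus)
  expect_true(all(refit$counts == 0))
  expect_equal(refit$conservative_overall, 20)
})

test_that("planted deviation plans are recovered exactly", {
  plan <- data.frame(position = c(19, 19, 5),
                     taxon = c("tA", "tB", "tA"),
                     n = c(5, 3, 2),
                     radical = c(TRUE, TRUE, FALSE))
  gen <- generate_domain_alignment(taxa = c(tA = 10, tB = 12),
                                   n_positions = 54, plan = plan,
                                   seed = 99)
  expect_equal(nchar(gen$msa[[1]]), 54)
  rad <- deviation_counts(gen$msa, gen$consensus, gen$taxon_map,
                          "radical")
  expect_equal(unname(rad$counts["tA", 19]), 5)
  expect_equal(unname(rad$counts["tB", 19]), 3)
  expect_equal(unname(rad$counts["tA", 5]), 0)   # within-group plant
  alln <- deviation_counts(gen$msa, gen$consensus, gen$taxon_map, "all")
  expect_equal(unname(alln$counts["tA", 5]), 2)
  expect_equal(sum(alln$counts[, -c(5, 19)]), 0)

  expect_error(generate_domain_alignment(
    taxa = c(tA = 3), n_positions = 10,
    plan = data.frame(position = 1, taxon = "tA", n = 5,
                      radical = TRUE)), "more deviants")
})

test_that("LQ group comparisons report median contrasts", {
  msa <- c(a = "NA", b = "NA", c = "NA", d = "SA", e = "SA", f = "SA")
  traits <- data.frame(species_id = letters[1:6],
                       mrls = NA_real_, weight = NA_real_,
                       lq = c(1.2, 1.3, 1.1, 1.0, 0.9, 1.1))
  cmp <- residue_lq_compare(msa, 1, traits, mode = "exact_residue",
                            residue = "N")
  expect_equal(cmp$median_lq_in, 1.2)
  expect_equal(cmp$median_lq_out, 1.0)
  expect_equal(cmp$percent_difference, 20)
  expect_equal(cmp$n_in, 3)

  # identical groups differ by 0%
  traits$lq <- rep(1, 6)
  cmp0 <- residue_lq_compare(msa, 1, traits, mode = "exact_residue",
                             residue = "N")
  expect_equal(cmp0$percent_difference, 0)

  expect_error(residue_lq_compare(msa, 9, traits, "exact_residue",
                                  residue = "N"), "outside the domain")
  expect_error(residue_lq_compare(msa, 2, traits, "exact_residue",
                                  residue = "W"), "empty group")
})

test_that("a planted LQ contrast is recovered by the radical split", {
  diffs <- vapply(1:60, function(s) {
    plan <- data.frame(position = 19, taxon = "tA", n = 12,
                       radical = TRUE)
    gen <- generate_domain_alignment(taxa = c(tA = 30), n_positions = 54,
                                     plan = plan, seed = s)
    carriers <- gen$deviants[["19"]]
    set.seed(s + 5000)
    lq <- exp(rnorm(30, 0, 0.3))
    names(lq) <- names(gen$msa)
    lq[carriers] <- lq[carriers] * 1.17
    traits <- data.frame(species_id = names(lq), mrls = NA_real_,
                         weight = NA_real_, lq = unname(lq))
    residue_lq_compare(gen$msa, 19, traits,
                       mode = "radical_vs_consensus")$percent_difference
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 17), 5)
})
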