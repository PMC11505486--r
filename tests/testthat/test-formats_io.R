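test_that("codon alignments validate frame, length, and alphabet", {
  aln <- codon_alignment(c(a = "TTTAAACCC", b = "TTCAAACCC"))
  expect_s3_class(aln, "codon_alignment")
  expect_equal(aln$length, 9)
  expect_equal(length(aln$seqs), 2)

  expect_error(codon_alignment(c(a = "TTTAAACCC", b = "TTCAAACCCGGG")),
               "equal length")
  expect_error(codon_alignment(c(a = "TTTA", b = "TTCA")), "multiple of 3")
  expect_error(codon_alignment(c(a = "TTXAAA", b = "TTCAAA")),
               "illegal characters")
  expect_error(codon_alignment(c(a = "TTTAAA", a = "TTCAAA")),
               "duplicated species")
})

test_that("FASTA round-trip reproduces the alignment exactly", {
  aln <- toy_alignment()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(aln, path)
  back <- read_codon_alignment(path, gene_id = "toy")
  expect_identical(back, aln)
  expect_error(read_codon_alignment(file.path(tempdir(), "nope.fa")),
               "no such file")
})

test_that("gap columns are removed codon-granularly, order preserved", {
  aln <- toy_alignment()
  filt <- filter_alignment(aln)
  # sp3 has a gapped codon 3: that codon column goes, others stay
  expect_equal(filt$length, 9)
  expect_identical(names(filt$seqs), c("sp1", "sp2", "sp3"))
  expect_identical(unname(filt$seqs[["sp1"]]), "TTTCTGGGG")
  expect_identical(unname(filt$seqs[["sp3"]]), "TTTCTGGGG")

  # gap-free alignment comes back unchanged
  clean <- codon_alignment(c(x = "TTTAAA", y = "TTCAAA"))
  expect_identical(filter_alignment(clean), clean)

  # an N codon column is removed like a gap column
  withn <- codon_alignment(c(x = "TTTANACCC", y = "TTCAAACCC"))
  fn <- filter_alignment(withn)
  expect_equal(fn$length, 6)
  expect_identical(unname(fn$seqs[["x"]]), "TTTCCC")
})

test_that("short sequences are dropped first, then columns re-filtered", {
  # sp3 has only 1 gap-free codon of 4; with min_len = 2 it is dropped and
  # its gap columns no longer force removal
  aln <- codon_alignment(c(
    sp1 = "TTTCTGAAAGGG",
    sp2 = "TTCCTGAAAGGG",
    sp3 = "TTT---------"))
  filt <- filter_alignment(aln, min_len = 2)
  expect_identical(names(filt$seqs), c("sp1", "sp2"))
  expect_equal(filt$length, 12)

  # without the drop the gapped columns would have been removed
  all_kept <- filter_alignment(aln, min_len = 1)
  expect_equal(all_kept$length, 3)

  expect_error(filter_alignment(aln, min_len = 10),
               class = "evorate_empty_alignment")
})

test_that("filtering is idempotent and keeps relative order", {
  set.seed(42)
  for (rep in 1:20) {
    n_sp <- sample(3:6, 1)
    n_cod <- sample(5:12, 1)
    seqs <- vapply(seq_len(n_sp), function(i) {
      codons <- sample(SENSE_ORACLE, n_cod, replace = TRUE)
      gap_at <- which(runif(n_cod) < 0.15)
      codons[gap_at] <- "---"
      paste(codons, collapse = "")
    }, character(1))
    names(seqs) <- paste0("sp", seq_len(n_sp))
    aln <- codon_alignment(seqs)
    once <- tryCatch(filter_alignment(aln), error = function(e) NULL)
    if (is.null(once)) next
    expect_identical(filter_alignment(once), once)
    expect_true(all(names(once$seqs) == names(seqs)[names(seqs) %in%
                                                      names(once$seqs)]))
  }
})

test_that("trait tables read missing markers and reject bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species_id\tmrls\tweight\tlq",
               "Homo_sapiens\t—\t—\t—",
               "Mus_musculus\t4\t20\t0.5"), path)
  tr <- read_trait_table(path)
  expect_true(all(is.na(tr[tr$species_id == "Homo_sapiens",
                           c("mrls", "weight", "lq")])))
  expect_equal(tr$mrls[tr$species_id == "Mus_musculus"], 4)

  writeLines(c("species_id\tmrls\tweight\tlq",
               "a\t1\t2\t0.5", "a\t2\t3\t0.6"), path)
  expect_error(read_trait_table(path), "duplicated species")

  writeLines(c("species_id\tmrls\tweight\tlq",
               "a\tfast\t2\t0.5"), path)
  expect_error(read_trait_table(path), "non-numeric")

  writeLines(c("species_id\tmrls", "a\t1"), path)
  expect_error(read_trait_table(path), "missing required column")
})

test_that("trait and ortholog tables round-trip through TSV", {
  tr <- toy_traits()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_trait_table(tr, p1)
  back <- read_trait_table(p1)
  expect_equal(back, tr)

  map <- data.frame(gene_id = "g", species_id = c("a", "b", "c"),
                    status = c("functional", "pseudogene", "lost"),
                    sequence_id = c("g_a", "g_b", NA),
                    stringsAsFactors = FALSE)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_map(map, p2)
  back <- read_ortholog_map(p2)
  expect_equal(back$status, map$status)

  # functional without sequence_id violates the invariant
  bad <- map; bad$sequence_id[1] <- NA
  expect_error(validate_ortholog_map(bad), "sequence_id")
  bad2 <- rbind(map, map[1, ])
  expect_error(validate_ortholog_map(bad2), "duplicated")
  bad3 <- map; bad3$status[2] <- "maybe"
  expect_error(validate_ortholog_map(bad3), "unknown ortholog status")
})

test_that("association reports have the eight table columns", {
  res <- structure(list(gene_id = "g", trait = "mrls", n = 49, r = 0.76,
                        p = 3e-10, a = 439, b = -36,
                        median_min = 0.074, median_max = 0.178),
                   class = "association_result")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_report(list(res), path)
  df <- read.delim(path)
  expect_identical(names(df), c("gene", "n", "r", "p", "slope",
                                "intercept", "median_min", "median_max"))
  expect_equal(nrow(df), 1)
})
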