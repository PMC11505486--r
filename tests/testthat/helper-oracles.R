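# Independent brute-force oracles and fixture builders used across tests.
# These re-derive expected values from first principles (standard genetic
# code via Biostrings) without touching the package's counting code paths.

GC_ORACLE <- Biostrings::GENETIC_CODE
SENSE_ORACLE <- names(GC_ORACLE)[GC_ORACLE != "*"]
NUC_ORACLE <- c("A", "C", "G", "T")

# brute-force fractional site counts: enumerate the 9 neighbors directly
oracle_sites <- function(codon) {
  syn <- 0
  for (pos in 1:3) {
    for (nuc in setdiff(NUC_ORACLE, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- nuc
      if (GC_ORACLE[[nb]] != "*" && GC_ORACLE[[nb]] == GC_ORACLE[[codon]]) {
        syn <- syn + 1
      }
    }
  }
  c(S = syn / 3, N = 3 - syn / 3)
}

# exhaustive pathway enumeration for a codon pair, written iteratively
# over explicit position orderings (distinct from the package's recursion)
oracle_diffs <- function(c1, c2) {
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  k <- length(pos)
  if (k == 0) return(c(Sd = 0, Nd = 0))
  ords <- switch(as.character(k),
                 "1" = list(pos),
                 "2" = list(pos, rev(pos)),
                 "3" = {
                   m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
                   lapply(seq_len(6), function(i) pos[m[i, ]])
                 })
  syn_counts <- numeric(0)
  fallback_counts <- numeric(0)
  for (ord in ords) {
    cur <- s1
    syn <- 0
    through_stop <- FALSE
    step_from <- paste(cur, collapse = "")
    for (p in ord) {
      cur[p] <- s2[p]
      step_to <- paste(cur, collapse = "")
      if (GC_ORACLE[[step_to]] == "*" && step_to != c2) {
        through_stop <- TRUE
      }
      if (GC_ORACLE[[step_from]] != "*" && GC_ORACLE[[step_to]] != "*" &&
          GC_ORACLE[[step_from]] == GC_ORACLE[[step_to]]) {
        syn <- syn + 1
      }
      step_from <- step_to
    }
    fallback_counts <- c(fallback_counts, syn)
    if (!through_stop) syn_counts <- c(syn_counts, syn)
  }
  use <- if (length(syn_counts) > 0) syn_counts else fallback_counts
  c(Sd = mean(use), Nd = k - mean(use))
}

# closed-form least squares from sums of squares (independent of lm)
oracle_lsq <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  a <- sxy / sxx
  b <- mean(y) - a * mean(x)
  c(a = a, b = b)
}

# random gap-free codon sequence over sense codons
random_codon_seq <- function(n_codons) {
  paste(sample(SENSE_ORACLE, n_codons, replace = TRUE), collapse = "")
}

# small aligned fixture with controllable gap placement
toy_alignment <- function() {
  codon_alignment(c(
    sp1 = "TTTCTGAAAGGG",
    sp2 = "TTCCTGAAAGGG",
    sp3 = "TTTCTG---GGG"), gene_id = "toy")
}

toy_traits <- function() {
  data.frame(
    species_id = c("sp1", "sp2", "sp3", "sp4", "sp5"),
    mrls = c(10, 20, 30, 40, NA),
    weight = c(100, 1000, 10000, NA, 2),
    lq = c(0.8, 1.0, 1.2, 1.4, 0.9),
    stringsAsFactors = FALSE)
}
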