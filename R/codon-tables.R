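# Standard genetic code and precomputed codon tables.
# All dN/dS counting below works off these; built once at install time.

.NUC <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

.GENETIC_CODE <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.SENSE_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]

.AA20 <- sort(unique(.GENETIC_CODE[.SENSE_CODONS]))

# translate one or more codons; stops come back as "*"
.codon_aa <- function(codon) unname(.GENETIC_CODE[codon])

.is_sense <- function(codon) codon %in% .SENSE_CODONS

.is_transition <- function(from, to) {
  (from %in% .PURINES) == (to %in% .PURINES) & from != to
}

# the nine single-nucleotide neighbors of a codon, stops included
.codon_neighbors <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    cur <- substr(codon, pos, pos)
    for (nuc in setdiff(.NUC, cur)) {
      nb <- codon
      substr(nb, pos, pos) <- nuc
      out <- c(out, nb)
    }
  }
  out
}

# Fractional synonymous/nonsynonymous site counts per sense codon
# (mutations to stop codons count as nonsynonymous).
.SITE_TABLE <- {
  m <- matrix(NA_real_, nrow = length(.SENSE_CODONS), ncol = 2,
              dimnames = list(.SENSE_CODONS, c("S", "N")))
  for (cod in .SENSE_CODONS) {
    nbs <- .codon_neighbors(cod)
    syn <- sum(.GENETIC_CODE[nbs] != "*" &
                 .GENETIC_CODE[nbs] == .GENETIC_CODE[[cod]])
    m[cod, "S"] <- syn / 3
    m[cod, "N"] <- 3 - syn / 3
  }
  m
}

# package-local cache for the 61 x 61 pathway-averaged difference matrices
.evorate_cache <- new.env(parent = emptyenv())

# Enumerate all orderings of the differing positions between two sense
# codons; classify each single-nucleotide step as synonymous or
# nonsynonymous. Orderings whose intermediate codons are stops are dropped
# and the average renormalized; if every ordering hits a stop, all orderings
# are kept with stop-involving steps classed nonsynonymous and the result is
# flagged.
.pair_pathway <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) {
    return(list(Sd = 0, Nd = 0, stop_fallback = FALSE))
  }
  orderings <- .permutations(pos)
  paths <- lapply(orderings, function(ord) {
    chain <- c1
    cur <- c1
    for (p in ord) {
      substr(cur, p, p) <- substr(c2, p, p)
      chain <- c(chain, cur)
    }
    chain
  })
  valid <- vapply(paths, function(chain) {
    k <- length(chain)
    if (k <= 2L) TRUE else all(.GENETIC_CODE[chain[2:(k - 1L)]] != "*")
  }, logical(1))
  fallback <- !any(valid)
  use <- if (fallback) paths else paths[valid]
  sd_per <- vapply(use, function(chain) {
    aas <- .GENETIC_CODE[chain]
    # a step is synonymous only between two sense codons coding the same aa
    sum(aas[-length(aas)] == aas[-1] & aas[-1] != "*")
  }, numeric(1))
  Sd <- mean(sd_per)
  list(Sd = Sd, Nd = k - Sd, stop_fallback = fallback)
}

.permutations <- function(x) {
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Lazily build and cache the full 61 x 61 Sd/Nd matrices.
.path_matrices <- function() {
  if (!is.null(.evorate_cache$SD)) {
    return(list(SD = .evorate_cache$SD, ND = .evorate_cache$ND))
  }
  n <- length(.SENSE_CODONS)
  SD <- matrix(0, n, n, dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
  ND <- SD
  for (i in seq_len(n)) {
    for (j in i:n) {
      pw <- .pair_pathway(.SENSE_CODONS[i], .SENSE_CODONS[j])
      SD[i, j] <- SD[j, i] <- pw$Sd
      ND[i, j] <- ND[j, i] <- pw$Nd
    }
  }
  .evorate_cache$SD <- SD
  .evorate_cache$ND <- ND
  list(SD = SD, ND = ND)
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
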