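---
title: "Methods: rate-trait association with evorate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate-trait association with evorate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evorate)
```

## The question the package addresses

Comparative genomics often asks whether the evolutionary fate of a gene —
how fast it accumulates substitutions, up to pseudogenization or outright
loss — tracks a life-history trait of the species carrying it. `evorate`
implements one concrete form of that question for protein-coding genes in
a clade: summarize each species' gene by the **median of its pairwise
dN/dS** against every other functional ortholog in the taxon, then ask
whether that per-species characteristic predicts the species' maximal
reported lifespan (MRLS, years), the common logarithm of its adult body
weight (grams), or its longevity quotient (LQ, observed lifespan relative
to the allometric expectation for the body mass). Protein-level analyses
complement the rate characteristic: per-amino-acid occurrence
correlations with the same traits, and a domain-alignment analysis that
classifies deviations from the consensus as conservative or radical under
a six-group physicochemical partition.

## Pairwise dN/dS by counting

The estimator is the classical Nei–Gojobori (1986) counting method with
Jukes–Cantor correction, chosen deliberately over likelihood codon models:
every intermediate quantity is a finite sum that can be verified against
brute-force enumeration, which suits a pipeline whose statistic is a
median *rank* across species rather than a branch-length estimate.

For each sense codon, each of its nine single-nucleotide neighbors
contributes 1/3 of a synonymous site if it codes the same amino acid;
neighbors that are stop codons count as nonsynonymous, so `S + N = 3`
exactly per codon. For a codon pair differing at *k* positions, the
synonymous/nonsynonymous split of the *k* changes is averaged over all
*k*! orderings of single steps; orderings that pass through a stop codon
are excluded and the average renormalized (in the degenerate case where
every ordering hits a stop, all orderings are kept with stop steps
classed nonsynonymous, and the result is flagged). Site totals are
averaged between the two sequences, proportions `pS = Sd/S`, `pN = Nd/N`
are corrected by `d = -(3/4) log(1 - 4p/3)`, and `omega = dN/dS` when
`dS > 0`.

Numerical conventions, all surfaced rather than silent:

* `dS = 0` (e.g. identical sequences) leaves omega undefined (`NA`); such
  pairs are excluded from medians and counted in `n_pairs_excluded`.
* a proportion at or beyond 3/4 saturates the correction; the distance
  becomes `Inf`, the pair is flagged `saturated` and excluded from
  medians. When only the synonymous side saturates, the conventional
  omega is 0 (finite `dN` over an effectively unbounded `dS`) — visible
  on two-codon toys — but the pair is still excluded downstream.
* internal stop codons raise an error: they signal pseudogenized input
  that the ortholog map should have routed away from estimation.

```{r}
estimate_pair("TTTTTC", "TTCTTC")
```

## The median characteristic

For a gene and a focal species, the characteristic is the median of the
pairwise omegas between the focal sequence and each other *functional*
ortholog of the taxon (a star around the focal species, matching one
point per species in a scatter plot). Pseudogene and lost species
contribute no characteristic and never perturb other species' values —
an invariant the tests exercise directly. The median is the middle order
statistic, averaging the two central values for even counts; the
per-gene summary interval is simply the min and max of the defined
per-species medians.

## Trait association

The association stage is ordinary least squares of trait on median, with
the Pearson correlation tested two-sided via the t distribution on
`n - 2` degrees of freedom (`stats::lm` / `stats::cor.test`). Body
weight enters as `log10(grams)`, the log-linear form of an exponential
weight-rate relationship. Species missing either the median or the trait
are dropped per trait — not listwise — so `n` can differ between the
lifespan and weight rows of the same gene. The significance threshold
for calling a gene "associated" is configuration (`alpha`, default
`10^-3`), applied boundary-inclusive. No multiple-testing correction is
applied across genes or traits; the per-test p-values are reported raw.

Two caveats are intrinsic to the method and documented rather than
patched: species are phylogenetically non-independent, and ordinary
regression ignores that (no PGLS here, by design — the package
reproduces the plain-regression methodology); and a fitted line with a
strongly negative intercept can predict negative lifespans at the low
end of the median range, which is a property of the linear summary, not
of the data.

## Composition and domain analyses

Occurrence is the percentage of each of the 20 standard amino acids in a
species' protein, computed over unaligned full sequences; gaps and `X`
are excluded from the denominator, so profiles sum to 100% exactly. Each
amino acid is then correlated (Pearson, two-sided) with MRLS or log
weight across species; positive r is read as preference, negative as
avoidance. Amino acids with zero variance get `NA` rather than
contaminating the rest.

The domain stage builds a per-column plurality consensus (gaps ignored,
ties broken alphabetically and flagged), counts per-taxon deviations
from the consensus at each position — all substitutions, or only
*radical* ones, i.e. substitutions crossing the six-group partition
(C | STAGP | DENQ | HRK | MILV | WYF) — and reports per-taxon
conservative-position totals. Gapped residues are counted neither as
deviations nor toward the taxon denominator. A residue-at-position split
(exact residue, or radical-vs-consensus) compares median LQ between
carriers and non-carriers as `100 * (median_in - median_out) /
median_out`.

## What the synthetic generators emulate

The package ships generators instead of genome downloads; their defaults
are the study conditions under which everything is tested.

* **Sequences.** `simulate_pair()` draws a uniform sense-codon ancestor
  and applies single-nucleotide proposals (`t` expected proposals per
  codon, Poisson-distributed; transitions weighted `kappa`), accepting
  synonymous changes always, nonsynonymous ones with probability
  `omega_true`, stops never. `generate_ortholog_set()` evolves one
  branch per species from a shared ancestor, with per-species omegas
  either constant or spanning a range (the trait-coupled plant);
  pseudogene species get an internal stop planted mid-sequence.
* **Traits.** `generate_traits()` plants `mrls = 439 x - 36` and
  `lg(weight) = 25 x - 1` on the realized medians with Gaussian noise
  calibrated (via `noise_sd_for_r()`) to population correlations of
  0.76 and 0.67 — a strong, realistic rate-longevity signal at `n = 49`
  species. The raw linear model is kept by default (no truncation), so
  noise-free plants are recovered exactly; a positive `floor` is
  available where a file-backed table must satisfy the positivity
  invariant, at the cost of attenuating the low end.
* **Composition.** `generate_composition_study()` plants leucine
  preference (population r = +0.62) and proline avoidance (r = -0.7)
  against lifespans drawn uniformly on 2–70 years, realizing target
  percentages as residue counts by largest-remainder rounding over
  434-residue proteins.
* **Domain.** `generate_domain_alignment()` emits a 54-column consensus
  alignment with a planted per-position, per-taxon deviation plan
  (radical or within-group), recovered exactly by `deviation_counts()`;
  the longevity-quotient plant multiplies carrier LQs by 1.17 over a
  log-normal baseline (sdlog 0.3), mirroring a +17% median contrast in
  a 56-versus-90 species split.

What the generators do **not** emulate: phylogenetic tree structure
(branches are independent, so species points really are exchangeable —
unlike real clades), indels, codon-usage bias, rate variation among
sites, and correlated trait evolution. Passing recovery tests therefore
demonstrates the correctness and calibration of the estimators under
their own assumptions, not robustness to the phylogenetic
non-independence of real comparative data.

## Known estimator bias under transition/transversion asymmetry

Counting-based dN/dS with equal-weight site counts is known to
underestimate omega when transitions outpace transversions: transitions
are disproportionately synonymous at two-fold degenerate sites, so the
observed synonymous proportion is inflated relative to the equal-weight
site count. Under this package's simulator the expectation of
estimated/true omega is about 0.94 at `kappa = 1` and about 0.84 at
`kappa = 2` (derivable in closed form from the per-codon proposal
probabilities). The estimate remains strictly monotone in the true
omega, which is what the downstream median-rank statistic relies on;
users who need unbiased point estimates under strong
transition/transversion asymmetry should use a maximum-likelihood codon
model, which is out of scope here.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes chosen
to keep Monte-Carlo error well inside the stated tolerances: 50
replicates of 2000 codons for omega recovery, 200 replicates at 49
species for regression and composition recovery, 1000 replicates for
type-I calibration, and 100 replicates of a 146-species domain panel
for the LQ contrast. All randomness flows from explicit integer seeds;
generators call `set.seed()` internally so identical configurations are
byte-identical across runs, which the pipeline's manifest (seed plus
input digests) makes auditable. Alignment filtering is codon-granular
(a gap or `N` anywhere in a codon column removes the whole column) with
the short-sequence threshold expressed as a fraction of the alignment
length (default 0.5) — the relative form keeps repeated filtering
idempotent.
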