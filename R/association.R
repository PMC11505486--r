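#' Regress a species trait on the median dN/dS characteristic
#'
#' Ordinary least-squares of trait on median: `y = a * x + b` with
#' `x = median_omega` and `y` either the maximal reported lifespan in years
#' (`trait = "mrls"`) or the common logarithm of adult body weight in grams
#' (`trait = "lg_weight"` — the log-linear form of an exponential
#' weight-vs-median relationship). The Pearson correlation `r` is tested
#' two-sided against the null of no linear relationship (t distribution,
#' n - 2 df). Species lacking either a defined median or the trait are
#' dropped per trait, and `n` reflects the drop.
#'
#' @param chars Data frame with `species_id` and `median_omega` columns
#'   (see [median_omega_all()]); rows with `NA` median are dropped.
#' @param traits Trait table data frame (see [read_trait_table()]).
#' @param trait `"mrls"` or `"lg_weight"`.
#' @param gene_id Gene label carried into the result.
#' @return Object of class `association_result`: list with `gene_id`,
#'   `trait`, `n`, `r`, `p`, `a` (slope), `b` (intercept), `median_min`,
#'   `median_max`.
#' @export
fit_association <- function(chars, traits, trait = c("mrls", "lg_weight"),
                            gene_id = NULL) {
  trait <- match.arg(trait)
  if (is.null(gene_id)) {
    gene_id <- if (!is.null(chars$gene_id)) chars$gene_id[[1L]] else "gene"
  }
  m <- merge(chars[, c("species_id", "median_omega")],
             traits, by = "species_id")
  x <- m$median_omega
  y <- if (trait == "mrls") m$mrls else log10(m$weight)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    stop("fewer than 3 species with both a defined median and the trait (",
         n, ")", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in ", if (stats::var(x) == 0) "median" else trait,
         ": correlation undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(gene_id = gene_id, trait = trait, n = n,
                 r = unname(ct$estimate), p = ct$p.value,
                 a = unname(stats::coef(fit)[["x"]]),
                 b = unname(stats::coef(fit)[["(Intercept)"]]),
                 median_min = min(x), median_max = max(x)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s ~ median(dN/dS), trait = %s\n", x$gene_id, x$trait))
  cat(sprintf("  n = %d, r = %.3f, p = %.3g\n", x$n, x$r, x$p))
  cat(sprintf("  y = %.4g x + %.4g;  median in [%.4g, %.4g]\n",
              x$a, x$b, x$median_min, x$median_max))
  invisible(x)
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(gene = x$gene_id, trait = x$trait, n = x$n, r = x$r, p = x$p,
             slope = x$a, intercept = x$b,
             median_min = x$median_min, median_max = x$median_max,
             stringsAsFactors = FALSE)
}

#' Classify an association as a selection signal
#'
#' @param result An `association_result`.
#' @param alpha Significance threshold (default `1e-3`); `p <= alpha`
#'   (boundary inclusive) is classified as associated.
#' @return `"associated"` or `"not_associated"`.
#' @export
classify_selection_signal <- function(result, alpha = 1e-3) {
  stopifnot(inherits(result, "association_result"), alpha > 0)
  if (result$p <= alpha) "associated" else "not_associated"
}

#' Noise level that yields a target population correlation
#'
#' For the planted linear trait model `y = a x + b + e`, returns the
#' Gaussian noise standard deviation such that the population Pearson
#' correlation between x and y equals `r`, given the standard deviation of
#' x: `sd = |a| * sd_x * sqrt(1/r^2 - 1)`.
#'
#' @param slope Planted slope `a`.
#' @param sd_x Standard deviation of the predictor (for x uniform on
#'   `[lo, hi]`, `sd_x = (hi - lo)/sqrt(12)`).
#' @param r Target population correlation (0 < |r| <= 1).
#' @return Noise standard deviation on the trait scale.
#' @export
noise_sd_for_r <- function(slope, sd_x, r) {
  stopifnot(abs(r) > 0, abs(r) <= 1, sd_x > 0)
  abs(slope) * sd_x * sqrt(1 / r^2 - 1)
}
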