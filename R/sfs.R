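#' Folded site-frequency spectra
#'
#' A folded site-frequency spectrum (SFS) describes the distribution of minor
#' allele frequency (MAF) across variable loci; it is the weight used when
#' averaging discovery probabilities over loci.  Three forms are supported:
#'
#' * `sfs_neutral()` — the standard neutral infinitely-many-sites model with
#'   constant population size.  Folding the unfolded spectrum (density
#'   proportional to 1/p) gives density proportional to
#'   \eqn{1/p + 1/(1-p) = 1/[p(1-p)]} on \eqn{(0, 1/2]}.
#' * `sfs_finite(N)` — the same model in a population of `N` diploids: a
#'   discrete spectrum on the grid \eqn{p_i = i/(2N)}, \eqn{i = 1..N}, with
#'   weights \eqn{1/[p_i(1-p_i)]}.
#' * `sfs_custom(maf, weight)` — any user-supplied folded spectrum, e.g. a
#'   growth-skewed one; weights need not be normalized.
#'
#' All uses are ratios of integrals (or sums), so none of the spectra need
#' be normalized.
#'
#' @param N Diploid population size (finite spectrum).
#' @param maf,weight Support points in (0, 0.5] and non-negative weights
#'   (custom spectrum; at least two points).
#' @return An object of class `folded_sfs`.
#' @examples
#' sfs_neutral()
#' sfs_finite(100)
#' sfs_custom(c(0.01, 0.05, 0.2), c(10, 3, 1))
#' @export
sfs_neutral <- function() {
  structure(list(kind = "neutral_constant"), class = "folded_sfs")
}

#' @rdname sfs_neutral
#' @export
sfs_finite <- function(N) {
  if (!is.finite(N) || N < 1 || N != round(N))
    stop("N must be a positive integer")
  p <- seq_len(N) / (2 * N)
  structure(list(kind = "finite_2N", N = N, maf = p, weight = 1 / (p * (1 - p))),
            class = "folded_sfs")
}

#' @rdname sfs_neutral
#' @export
sfs_custom <- function(maf, weight) {
  if (length(maf) != length(weight)) stop("maf and weight lengths differ")
  if (length(maf) < 2) stop("a custom spectrum needs at least 2 support points")
  if (any(maf <= 0 | maf > 0.5)) stop("custom SFS support must lie in (0, 0.5]")
  if (any(weight < 0) || all(weight == 0)) stop("weights must be non-negative, not all zero")
  if (anyDuplicated(maf)) stop("duplicated MAF support points")
  o <- order(maf)
  structure(list(kind = "custom", maf = maf[o], weight = weight[o]),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat("Folded site-frequency spectrum:", x$kind)
  if (x$kind == "finite_2N") cat(" (N =", x$N, "diploids)")
  if (x$kind == "custom") cat(" (", length(x$maf), "support points )")
  cat("\n")
  invisible(x)
}

is_continuous_sfs <- function(sfs) identical(sfs$kind, "neutral_constant")

# density of the continuous neutral folded SFS (unnormalized)
neutral_density <- function(p) 1 / (p * (1 - p))

# \int_a^b dp / [p(1-p)] = logit(b) - logit(a), exact
neutral_mass <- function(a, b) {
  stats::qlogis(b) - stats::qlogis(a)
}
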