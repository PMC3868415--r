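#' Two-locus haplotype frequencies
#'
#' Construct a validated set of gamete (haplotype) frequencies for a pair of
#' biallelic loci with alleles A/a and B/b.  All linkage-disequilibrium
#' statistics in this package are gametic: they are computed from these four
#' frequencies, never from diploid genotype counts.
#'
#' Frequencies must be non-negative and sum to 1.  Sums within `1e-9` of 1 are
#' renormalized with a warning; larger discrepancies are rejected.
#'
#' @param p_AB,p_Ab,p_aB,p_ab Frequencies of the four gametes.
#' @return An object of class `two_locus_haplotypes`: a named numeric vector
#'   with components `p_AB`, `p_Ab`, `p_aB`, `p_ab`.
#' @examples
#' h <- two_locus_haplotypes(1/4, 1/4, 0, 1/2)
#' r_squared(h)
#' @export
two_locus_haplotypes <- function(p_AB, p_Ab, p_aB, p_ab) {
  h <- c(p_AB = p_AB, p_Ab = p_Ab, p_aB = p_aB, p_ab = p_ab)
  if (any(!is.finite(h)) || any(h < 0))
    stop("haplotype frequencies must be finite and non-negative")
  s <- sum(h)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("haplotype frequencies sum to %.12g, not 1", s))
  if (s != 1) {
    # warn only for discrepancies beyond accumulated rounding
    if (abs(s - 1) > 1e-12)
      warning("renormalizing haplotype frequencies (sum differed from 1 by ",
              format(abs(s - 1)), ")")
    h <- h / s
  }
  structure(h, class = "two_locus_haplotypes")
}

#' Two-locus haplotypes from marginal allele frequencies
#'
#' Build the 2x2 gamete table from the marginal frequencies of alleles A and B
#' and the frequency of the AB gamete.  `p_AB` must respect the Frechet
#' bounds `max(0, p_A + p_B - 1) <= p_AB <= min(p_A, p_B)`; violations are
#' rejected with the offending bound.
#'
#' @param p_A,p_B Marginal allele frequencies, each in (0, 1).
#' @param p_AB Frequency of the AB gamete.
#' @return A `two_locus_haplotypes` object.
#' @export
haplotypes_from_margins <- function(p_A, p_B, p_AB) {
  if (p_A <= 0 || p_A >= 1 || p_B <= 0 || p_B >= 1)
    stop("marginal frequencies must lie strictly in (0, 1)")
  lo <- max(0, p_A + p_B - 1)
  hi <- min(p_A, p_B)
  if (p_AB < lo - 1e-12)
    stop(sprintf("p_AB = %g violates the lower Frechet bound max(0, p_A + p_B - 1) = %g",
                 p_AB, lo))
  if (p_AB > hi + 1e-12)
    stop(sprintf("p_AB = %g violates the upper Frechet bound min(p_A, p_B) = %g",
                 p_AB, hi))
  p_AB <- min(max(p_AB, lo), hi)
  two_locus_haplotypes(p_AB, p_A - p_AB, p_B - p_AB, 1 - p_A - p_B + p_AB)
}

marginals <- function(h) {
  c(p_A = unname(h[["p_AB"]] + h[["p_Ab"]]),
    p_B = unname(h[["p_AB"]] + h[["p_aB"]]))
}

check_polymorphic <- function(h) {
  m <- marginals(h)
  if (m[["p_A"]] <= 0 || m[["p_A"]] >= 1)
    stop("locus A is monomorphic (p_A = ", m[["p_A"]], ")")
  if (m[["p_B"]] <= 0 || m[["p_B"]] >= 1)
    stop("locus B is monomorphic (p_B = ", m[["p_B"]], ")")
  m
}

#' Linkage disequilibrium coefficient D
#'
#' The classical gametic disequilibrium coefficient
#' \eqn{D = p_{AB} - p_A p_B}, bounded by \eqn{[-1/4, 1/4]}.
#'
#' @param h A [two_locus_haplotypes] object.
#' @return The coefficient D.
#' @export
d_coefficient <- function(h) {
  m <- check_polymorphic(h)
  unname(h[["p_AB"]] - m[["p_A"]] * m[["p_B"]])
}

#' Correlation between allele indicators at two loci
#'
#' \eqn{r = D / \sqrt{p_A p_a p_B p_b}}: the Pearson correlation of the
#' indicator variables of alleles A and B on a random gamete.  `r_squared()`
#' is its square, the LD measure that governs indirect association power.
#'
#' @param h A [two_locus_haplotypes] object; both loci must be polymorphic.
#' @return `ld_r`: the signed correlation r in \eqn{[-1, 1]}.
#'   `r_squared`: \eqn{r^2 \in [0, 1]}.
#' @examples
#' h <- two_locus_haplotypes(1/4, 1/4, 0, 1/2)
#' r_squared(h)  # 1/3
#' @export
ld_r <- function(h) {
  m <- check_polymorphic(h)
  D <- h[["p_AB"]] - m[["p_A"]] * m[["p_B"]]
  unname(D / sqrt(m[["p_A"]] * (1 - m[["p_A"]]) * m[["p_B"]] * (1 - m[["p_B"]])))
}

#' @rdname ld_r
#' @export
r_squared <- function(h) {
  r <- ld_r(h)
  min(r * r, 1)
}

#' Canonical minor-allele frequency pair
#'
#' Reduce a pair of allele frequencies to the canonical form used by the
#' frequency-dependent bound on \eqn{r^2}: fold each frequency to the minor
#' allele (\eqn{p \le 1/2}) and order the loci so that \eqn{p_A \ge p_B}.
#' The returned object records whether either allele was swapped and whether
#' the loci were exchanged.
#'
#' @param p_A,p_B Allele frequencies in (0, 1).
#' @return An `allele_freq_pair`: list with `p_A`, `p_B` (canonical),
#'   `swapped_A`, `swapped_B`, `loci_exchanged`.
#' @export
allele_freq_pair <- function(p_A, p_B) {
  for (p in c(p_A, p_B))
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop("allele frequencies must lie strictly in (0, 1), got ", p)
  sA <- p_A > 0.5; sB <- p_B > 0.5
  a <- if (sA) 1 - p_A else p_A
  b <- if (sB) 1 - p_B else p_B
  ex <- a < b
  structure(list(p_A = if (ex) b else a, p_B = if (ex) a else b,
                 swapped_A = sA, swapped_B = sB, loci_exchanged = ex),
            class = "allele_freq_pair")
}

#' Maximum attainable r-squared given allele frequencies
#'
#' The largest \eqn{r^2} achievable by any feasible gamete table with the
#' given marginal allele frequencies.  After canonicalization to minor-allele
#' frequencies with \eqn{p_A \ge p_B}, the bound is
#' \deqn{r^2_{max} = \frac{(1 - p_A)\, p_B}{p_A (1 - p_B)},}
#' attained at the coupling Frechet boundary \eqn{p_{AB} = p_B}.  It equals 1
#' if and only if the two minor-allele frequencies are equal.
#'
#' @param f An [allele_freq_pair], or a numeric `p_A` (with `p_B` given) that
#'   will be canonicalized.
#' @param p_B Second allele frequency when `f` is numeric.
#' @return The maximum of \eqn{r^2}, in (0, 1].
#' @examples
#' max_r_squared(1/3, 1/51)  # 1/25
#' max_r_squared(1/3, 1/5)   # 1/2
#' @export
max_r_squared <- function(f, p_B = NULL) {
  if (!inherits(f, "allele_freq_pair")) f <- allele_freq_pair(f, p_B)
  pA <- f$p_A; pB <- f$p_B
  (1 - pA) * pB / (pA * (1 - pB))
}

#' Observed r-squared relative to its frequency-dependent maximum
#'
#' \eqn{r^2 / r^2_{max}}: the fraction of the attainable disequilibrium that
#' a pair of loci actually displays.  Two pairs with very different raw
#' \eqn{r^2} can be at comparable fractions of their respective maxima, so
#' the raw magnitude alone can misrepresent the strength of LD.
#'
#' @param h A [two_locus_haplotypes] object.
#' @return `r^2 / r^2_max`, in \eqn{[0, 1]}.
#' @seealso [r2_relative()] for the same ratio from summary numbers.
#' @export
relative_r_squared <- function(h) {
  m <- check_polymorphic(h)
  r_squared(h) / max_r_squared(allele_freq_pair(m[["p_A"]], m[["p_B"]]))
}

#' @describeIn relative_r_squared The ratio computed from marginal allele
#'   frequencies and an externally observed `r2` value.
#' @param p_A,p_B Marginal allele frequencies.
#' @param r2 Observed \eqn{r^2} for the pair.
#' @export
r2_relative <- function(p_A, p_B, r2) {
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  mx <- max_r_squared(p_A, p_B)
  if (r2 > mx + 1e-9)
    stop(sprintf("observed r2 = %g exceeds the frequency-dependent maximum %g", r2, mx))
  r2 / mx
}
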