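#' Variant-discovery sample design
#'
#' A discovery design is a triple: `n_people` diploid individuals
#' (`m = 2 n` chromosomes), a threshold `k` requiring each allele at a site
#' to be seen at least `k` times before the site is accepted as a common
#' variant, and the target minor-allele-frequency cutoff `c` defining which
#' loci one wishes to catalog.
#'
#' @param n_people Number of diploid individuals sampled, at least 1.
#' @param k Minimum observed copies of each allele, `1 <= k <= n_people`.
#' @param c MAF cutoff in (0, 0.5].
#' @return An object of class `sample_design`.
#' @examples
#' sample_design(250, 30, 0.05)
#' @export
sample_design <- function(n_people, k, c) {
  if (!is.finite(n_people) || n_people < 1 || n_people != round(n_people))
    stop("n_people must be a positive integer")
  if (!is.finite(k) || k < 1 || k != round(k))
    stop("k must be a positive integer")
  if (k > n_people)
    stop(sprintf("k = %d exceeds n_people = %d", as.integer(k), as.integer(n_people)))
  if (!is.finite(c) || c <= 0 || c > 0.5)
    stop("MAF cutoff c must lie in (0, 0.5]")
  structure(list(n_people = as.integer(n_people), k = as.integer(k), c = c),
            class = "sample_design")
}

#' Probability a polymorphism is detected at all
#'
#' The probability that both allelic types at a locus with minor allele
#' frequency `p` appear at least once among `2 n` sampled chromosomes:
#' \deqn{1 - (1-p)^{2n} - p^{2n}.}
#' Evaluated in log space so that large `n` does not underflow.
#'
#' @param p Minor allele frequency, in (0, 0.5].  Vectorized.
#' @param n_people Number of diploid individuals.
#' @return Probability in \eqn{[0, 1)}.
#' @examples
#' detect_prob(0.05, 100)  # > 0.9999
#' @export
detect_prob <- function(p, n_people) {
  if (any(!is.finite(p) | p <= 0 | p > 0.5))
    stop("minor allele frequency p must lie in (0, 0.5]")
  if (n_people < 1) stop("n_people must be at least 1")
  m <- 2 * n_people
  1 - exp(m * log1p(-p)) - exp(m * log(p))
}

#' Probability each allele is seen at least k times
#'
#' For the number of minor-allele copies \eqn{X \sim Bin(2n, p)}, the
#' probability that both alleles appear at least `k` times is
#' \eqn{P(k \le X \le 2n - k)}, computed via binomial distribution-function
#' differences (regularized incomplete beta underneath, so no term-by-term
#' summation and no overflow for large `n`).  At `k = 1` this reduces to
#' [detect_prob()].
#'
#' @param p Minor allele frequency in (0, 0.5].  Vectorized over `p`.
#' @param n_people Number of diploid individuals.
#' @param k Threshold, `1 <= k <= n_people`.
#' @return Probability in \eqn{[0, 1]}, non-increasing in `k`.
#' @export
detect_prob_k <- function(p, n_people, k) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p must lie in [0, 1]")
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (k > n_people)
    stop(sprintf("k = %d exceeds n_people = %d", as.integer(k), as.integer(n_people)))
  m <- 2 * n_people
  p <- pmin(p, 1 - p)  # allele-label symmetry, exact by construction
  pmax(0, stats::pbinom(m - k, m, p) - stats::pbinom(k - 1, m, p))
}

# integral of detect_prob_k(p) * f(p) over [lo, hi] for a continuous SFS.
# The integrand behaves like C(2n,k) p^{k-1} as p -> 0: finite (2n) at k = 1,
# zero for k >= 2, so the endpoint is supplied analytically and adaptive
# quadrature sees a bounded function.
pk_sfs_integral <- function(n_people, k, lo, hi, rel.tol = 1e-8) {
  m <- 2 * n_people
  fun <- function(p) {
    out <- numeric(length(p))
    z <- p <= 0
    out[z] <- if (k == 1) m else 0
    pp <- p[!z]
    out[!z] <- detect_prob_k(pp, n_people, k) * neutral_density(pp)
    out
  }
  pieces <- if (lo < 1e-3 && hi > 1e-3) c(lo, 1e-3, hi) else c(lo, hi)
  total <- 0
  for (i in seq_len(length(pieces) - 1)) {
    res <- tryCatch(
      stats::integrate(fun, pieces[i], pieces[i + 1], rel.tol = rel.tol,
                       subdivisions = 400L),
      error = function(e) stop("quadrature failure on [", pieces[i], ", ",
                               pieces[i + 1], "]: ", conditionMessage(e)))
    total <- total + res$value
  }
  total
}

# weighted mean of detect_prob_k over a discrete SFS restricted to [lo, hi]
pk_sfs_sum <- function(n_people, k, sfs, lo, hi) {
  sel <- sfs$maf >= lo & sfs$maf <= hi
  if (!any(sel)) stop("SFS has no support in [", lo, ", ", hi, "]")
  w <- sfs$weight[sel]
  p <- sfs$maf[sel]
  c(num = sum(detect_prob_k(p, n_people, k) * w), den = sum(w))
}

#' Sensitivity of a discovery design
#'
#' The probability that a locus passes the `k`-copies-of-each-allele filter
#' given that its true MAF is at least `c`, averaged over the folded SFS:
#' \deqn{\mathrm{sens} = \frac{\int_c^{1/2} P_k(p) f(p)\,dp}
#'                            {\int_c^{1/2} f(p)\,dp},}
#' with \eqn{P_k} from [detect_prob_k()] and `f` the SFS density.  Discrete
#' spectra replace the integrals by the analogous sums.
#'
#' @param d A [sample_design()].
#' @param sfs A folded SFS ([sfs_neutral()] by default).
#' @param rel.tol Relative quadrature tolerance (continuous spectra).
#' @return Probability in \eqn{[0, 1]}.
#' @examples
#' sensitivity(sample_design(250, 30, 0.05))  # about 0.934
#' @export
sensitivity <- function(d, sfs = sfs_neutral(), rel.tol = 1e-8) {
  stopifnot(inherits(d, "sample_design"), inherits(sfs, "folded_sfs"))
  if (d$c >= 0.5 && is_continuous_sfs(sfs))
    stop("degenerate support: c must be < 0.5 for a continuous spectrum")
  if (is_continuous_sfs(sfs)) {
    num <- pk_sfs_integral(d$n_people, d$k, d$c, 0.5, rel.tol)
    num / neutral_mass(d$c, 0.5)
  } else {
    s <- pk_sfs_sum(d$n_people, d$k, sfs, d$c, 0.5)
    unname(s["num"] / s["den"])
  }
}

#' Positive predictive value of a discovery design
#'
#' The probability that a locus passing the filter truly has MAF at least
#' `c`:
#' \deqn{\mathrm{PPV} = \frac{\int_c^{1/2} P_k(p) f(p)\,dp}
#'                           {\int_0^{1/2} P_k(p) f(p)\,dp}.}
#' The denominator integral is improper at 0 for the neutral spectrum
#' (density \eqn{1/[p(1-p)]}), but the product \eqn{P_k(p) f(p)} behaves like
#' \eqn{p^{k-1}} there and converges for all `k >= 1`; the endpoint is
#' handled analytically before quadrature.
#'
#' @inheritParams sensitivity
#' @return Probability in \eqn{[0, 1]}.
#' @examples
#' 1 - ppv(sample_design(250, 30, 0.05))  # about 0.007
#' @export
ppv <- function(d, sfs = sfs_neutral(), rel.tol = 1e-8) {
  stopifnot(inherits(d, "sample_design"), inherits(sfs, "folded_sfs"))
  if (is_continuous_sfs(sfs)) {
    num <- pk_sfs_integral(d$n_people, d$k, d$c, 0.5, rel.tol)
    den <- pk_sfs_integral(d$n_people, d$k, 0, d$c, rel.tol) + num
    num / den
  } else {
    num <- pk_sfs_sum(d$n_people, d$k, sfs, d$c, 0.5)
    den <- pk_sfs_sum(d$n_people, d$k, sfs, 0, 0.5)
    unname(num["num"] / den["num"])
  }
}

#' Sensitivity/PPV trade-off across thresholds
#'
#' Computes sensitivity and PPV for every threshold `k = 1..n_people` at a
#' fixed cutoff `c`, tracing the operating curve of the discovery filter.
#' Sensitivity is non-increasing and PPV non-decreasing in `k`.
#'
#' @param n_people Number of diploid individuals.
#' @param c MAF cutoff in (0, 0.5].
#' @param sfs Folded SFS.
#' @param k_max Largest threshold to tabulate (default `n_people`).
#' @return A data frame with columns `k`, `sensitivity`, `ppv`.
#' @export
roc_sweep <- function(n_people, c, sfs = sfs_neutral(), k_max = n_people) {
  k_max <- min(k_max, n_people)
  ks <- seq_len(k_max)
  sens <- vapply(ks, function(k) sensitivity(sample_design(n_people, k, c), sfs),
                 numeric(1))
  pp <- vapply(ks, function(k) ppv(sample_design(n_people, k, c), sfs), numeric(1))
  data.frame(k = ks, sensitivity = sens, ppv = pp)
}

#' Smallest design meeting sensitivity and PPV targets
#'
#' Searches over sample sizes `n = 1..n_max` and thresholds `k = 1..n` for
#' the smallest `n` (then the smallest `k`) whose design achieves both
#' `min_sensitivity` and `min_ppv` at cutoff `c`.  Exploits monotonicity in
#' `k`: sensitivity falls and PPV rises with `k`, so for each `n` the
#' feasible thresholds are a contiguous band.
#'
#' @param min_sensitivity,min_ppv Targets in (0, 1).
#' @param c MAF cutoff.
#' @param sfs Folded SFS.
#' @param n_max Upper bound on the sample-size search.
#' @return A list with `feasible`; if feasible, `n_people`, `k`, and the
#'   achieved `sensitivity` and `ppv`; otherwise `best`, the closest design
#'   found.
#' @export
plan_design <- function(min_sensitivity, min_ppv, c, sfs = sfs_neutral(),
                        n_max = 500) {
  if (min_sensitivity <= 0 || min_sensitivity >= 1 ||
      min_ppv <= 0 || min_ppv >= 1)
    stop("targets must lie strictly in (0, 1)")
  best <- NULL
  for (n in seq_len(n_max)) {
    # smallest k with ppv >= min_ppv (ppv non-decreasing in k): binary search
    lo <- 1L; hi <- as.integer(n)
    if (ppv(sample_design(n, hi, c), sfs) < min_ppv) next
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (ppv(sample_design(n, mid, c), sfs) >= min_ppv) hi <- mid else lo <- mid + 1L
    }
    k <- lo
    s <- sensitivity(sample_design(n, k, c), sfs)
    pv <- ppv(sample_design(n, k, c), sfs)
    if (is.null(best) || s > best$sensitivity)
      best <- list(n_people = n, k = k, sensitivity = s, ppv = pv)
    if (s >= min_sensitivity)
      return(list(feasible = TRUE, n_people = n, k = k,
                  sensitivity = s, ppv = pv))
  }
  list(feasible = FALSE, best = best)
}
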