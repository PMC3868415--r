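#' Power of the allelic case-control chi-square test
#'
#' Power of the 1-df Pearson chi-square test comparing allele frequencies
#' between `n_case` cases and `n_control` controls (2n alleles per group of
#' n diploid individuals; alleles, not genotypes, are tested).
#'
#' Methods:
#' * `"exact"` — enumerates the joint distribution of the two binomial
#'   allele counts and sums the rejection probability directly (replicates
#'   with a zero table margin, where the statistic is undefined, are
#'   conditioned out, matching how the package's simulators count them).
#'   This is the power of the test actually performed, to numerical
#'   precision.
#' * `"normal"` — two-proportion normal approximation with the null
#'   (pooled) variance on the critical value and the alternative variance
#'   on the distribution of the difference; accurate for large samples.
#' * `"chisq_ncp"` — the classical noncentral chi-square approximation with
#'   noncentrality
#'   \eqn{\lambda = (q_{case} - q_{control})^2 /
#'   \{\bar q (1-\bar q) [1/(2 n_{case}) + 1/(2 n_{control})]\}},
#'   \eqn{\bar q} the pooled frequency.  Kept for reference; its bias
#'   (order 0.01 in mid-power regions) is visible against simulation.
#' * `"auto"` (default) — `"exact"` when both groups have at most 8000
#'   alleles, else `"normal"`.
#'
#' When `q_case == q_control` the function returns `alpha` exactly, by
#' convention, under every method.
#'
#' @param q_case,q_control Allele frequencies in cases and controls, each in
#'   (0, 1).
#' @param n_case,n_control Numbers of diploid individuals per group.
#' @param alpha Test size in (0, 1).
#' @param method `"auto"`, `"exact"`, `"normal"` or `"chisq_ncp"`.
#' @return Power in \eqn{[\alpha, 1)}.
#' @examples
#' allelic_power(0.55, 0.50, 1000, 1000)
#' @export
allelic_power <- function(q_case, q_control, n_case, n_control = n_case,
                          alpha = 0.05,
                          method = c("auto", "exact", "normal", "chisq_ncp")) {
  method <- match.arg(method)
  for (q in c(q_case, q_control))
    if (!is.finite(q) || q <= 0 || q >= 1)
      stop("allele frequencies must lie strictly in (0, 1)")
  if (n_case < 1 || n_control < 1) stop("group sizes must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (q_case == q_control) return(alpha)
  m1 <- 2 * n_case; m2 <- 2 * n_control
  if (method == "auto") method <- if (max(m1, m2) <= 8000) "exact" else "normal"
  switch(method,
    exact = power_exact_2x2(q_case, q_control, m1, m2, alpha),
    normal = {
      qbar <- (m1 * q_case + m2 * q_control) / (m1 + m2)
      s0 <- sqrt(qbar * (1 - qbar) * (1 / m1 + 1 / m2))
      s1 <- sqrt(q_case * (1 - q_case) / m1 + q_control * (1 - q_control) / m2)
      z <- stats::qnorm(1 - alpha / 2)
      d <- q_case - q_control
      stats::pnorm((d - z * s0) / s1) + stats::pnorm((-d - z * s0) / s1)
    },
    chisq_ncp = {
      qbar <- (m1 * q_case + m2 * q_control) / (m1 + m2)
      lambda <- (q_case - q_control)^2 /
        (qbar * (1 - qbar) * (1 / m1 + 1 / m2))
      stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1, ncp = lambda,
                    lower.tail = FALSE)
    })
}

# exact rejection probability of the uncorrected 1-df Pearson test:
# sum P(X1 = i) P(X2 = j) over the rejection region, restricted to the
# 1e-14 probability windows of each binomial (the neglected tail mass is
# below 1e-12 in total)
power_exact_2x2 <- function(q1, q2, m1, m2, alpha) {
  N <- m1 + m2
  crit <- stats::qchisq(1 - alpha, df = 1)
  is <- stats::qbinom(1e-14, m1, q1):stats::qbinom(1 - 1e-14, m1, q1)
  js <- stats::qbinom(1e-14, m2, q2):stats::qbinom(1 - 1e-14, m2, q2)
  b1 <- stats::dbinom(is, m1, q1)
  b2 <- stats::dbinom(js, m2, q2)
  rej <- 0; def <- 0
  for (a in seq_along(is)) {
    i <- is[a]
    c1 <- i + js
    ok <- c1 > 0 & c1 < N
    if (!any(ok)) next
    det <- i * (m2 - js[ok]) - js[ok] * (m1 - i)
    stat <- N * det^2 / (m1 * m2 * c1[ok] * (N - c1[ok]))
    rej <- rej + b1[a] * sum(b2[ok][stat > crit])
    def <- def + b1[a] * sum(b2[ok])
  }
  rej / def
}

#' Per-group sample size achieving a target power
#'
#' Smallest equal case/control group size whose [allelic_power()] reaches
#' `target_power`, found by geometric bracketing followed by integer
#' bisection (power is monotone increasing in n).
#'
#' @inheritParams allelic_power
#' @param target_power Desired power, in (`alpha`, 1).
#' @return Integer per-group n; `allelic_power` at `n - 1` is below target.
#' @export
required_n <- function(q_case, q_control, alpha = 0.05, target_power = 0.8) {
  if (q_case == q_control)
    stop("q_case equals q_control: no finite sample size attains power above alpha")
  if (target_power <= alpha || target_power >= 1)
    stop("target_power must lie in (alpha, 1)")
  pw <- function(n) allelic_power(q_case, q_control, n, n, alpha)
  hi <- 1
  while (pw(hi) < target_power) {
    hi <- hi * 2
    if (hi > 2^40) stop("sample-size search did not converge")
  }
  lo <- max(1, hi %/% 2)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid + 1
  }
  as.integer(hi)
}

#' Sample-size inflation factor for an indirect (marker) test
#'
#' If a causal locus is in LD at level \eqn{r^2 = d} with a marker that is
#' conditionally independent of the phenotype given the causal locus, the
#' allelic test at the marker with sample size \eqn{n/d} has approximately
#' the power of the test at the causal locus with sample size n.  The
#' inflation factor is therefore \eqn{1/r^2}.
#'
#' @param r2 LD between marker and causal locus, in (0, 1].
#' @return `1 / r2`.
#' @export
inflation_factor <- function(r2) {
  if (!is.finite(r2) || r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  if (r2 == 0)
    stop("r2 = 0: the marker carries no information about the causal locus")
  1 / r2
}

#' Penetrance model at a single causal locus
#'
#' Disease probability `f1` for gametes carrying `risk_allele` at `locus`
#' and `f0` otherwise.  This is the single-causal-locus regime in which
#' marker–phenotype dependence flows entirely through the causal locus and
#' the 1/r² inflation factor applies.
#'
#' @param locus Causal locus name.
#' @param risk_allele Risk allele label at that locus.
#' @param f1,f0 Penetrances in \eqn{[0, 1]}, not identical, not both 0 or 1.
#' @return An object of class `penetrance_model`.
#' @export
penetrance_model <- function(locus, risk_allele, f1, f0) {
  for (f in c(f1, f0))
    if (!is.finite(f) || f < 0 || f > 1) stop("penetrances must lie in [0, 1]")
  if (f1 == 0 && f0 == 0) stop("both penetrances zero: disease never occurs")
  if (f1 == 1 && f0 == 1) stop("both penetrances one: disease always occurs")
  structure(list(locus = locus, risk_allele = risk_allele, f1 = f1, f0 = f0),
            class = "penetrance_model")
}

# disease probability per haplotype row
disease_probs <- function(t, pm) {
  if (inherits(pm, "penetrance_model")) {
    if (!pm$locus %in% loci_names(t)) stop("unknown causal locus: ", pm$locus)
    ifelse(t[[pm$locus]] == pm$risk_allele, pm$f1, pm$f0)
  } else if (is.function(pm)) {
    d <- pm(t)
    if (length(d) != nrow(t) || any(!is.finite(d)) || any(d < 0 | d > 1))
      stop("disease rule must return one probability in [0,1] per haplotype")
    d
  } else stop("pm must be a penetrance_model or a disease-rule function")
}

#' Case and control allele frequencies at a marker
#'
#' Exact retrospective (case-control) allele frequencies at `marker` by
#' Bayes inversion over the haplotype distribution:
#' \eqn{q_{case} = P(\mathrm{allele} \mid D)},
#' \eqn{q_{control} = P(\mathrm{allele} \mid \bar D)}, with the disease
#' probability of each haplotype given by a [penetrance_model()] or by an
#' arbitrary disease rule `function(table) -> P(D | haplotype)` (covering
#' multi-locus and epistatic disease models).
#'
#' @param t A [haplotype_table()].
#' @param pm A [penetrance_model()] or a disease-rule function.
#' @param marker Marker locus name.
#' @param allele Marker allele (default: lexicographically larger label).
#' @return List with `q_case`, `q_control`, `prevalence`, `marker`, `allele`.
#' @examples
#' mod <- risk_protective_model(1/2, 0, 1/4, 1/4)
#' rule <- function(t) as.numeric(t$R == "1" & t$P == "0")  # disease iff phenotype +1
#' marker_case_control_freqs(mod$table, rule, "M")$q_case   # 1
#' @export
marker_case_control_freqs <- function(t, pm, marker, allele = NULL) {
  stopifnot(inherits(t, "haplotype_table"))
  if (!marker %in% loci_names(t)) stop("unknown marker locus: ", marker)
  if (is.null(allele)) allele <- max(unique(t[[marker]][t$freq > 0]))
  d <- disease_probs(t, pm)
  prev <- sum(t$freq * d)
  if (prev <= 0 || prev >= 1)
    stop("degenerate ascertainment: population disease probability is ", prev)
  x <- as.numeric(t[[marker]] == allele)
  list(q_case = sum(t$freq * d * x) / prev,
       q_control = sum(t$freq * (1 - d) * x) / (1 - prev),
       prevalence = prev, marker = marker, allele = allele)
}

#' Exact check of the 1/r-squared inflation factor
#'
#' For a haplotype table with a single causal locus under a
#' [penetrance_model()], computes the per-group sample size required for the
#' allelic test at the causal locus and at the marker, their ratio, and the
#' predicted inflation factor \eqn{1/r^2}.  The ratio approaches
#' \eqn{1/r^2} in the small-effect limit; the function reports both so the
#' discrepancy at larger effects is visible.
#'
#' Multi-locus phenotype maps are refused: with more than one causal locus
#' the marker is not conditionally independent of the phenotype given any
#' single causal locus, and the inflation factor can fail arbitrarily
#' (use [marker_case_control_freqs()] with a disease rule to study those
#' cases exactly).
#'
#' @param t A [haplotype_table()].
#' @param pm A [penetrance_model()] (single causal locus).
#' @param marker Marker locus name.
#' @param alpha Test size.
#' @param target_power Target power for both sample sizes.
#' @return List with `n_causal`, `n_marker`, `ratio`, `r2`,
#'   `inflation_factor`.
#' @export
inflation_check <- function(t, pm, marker, alpha = 0.05, target_power = 0.8) {
  if (!inherits(pm, "penetrance_model"))
    stop("inflation_check requires a single-causal-locus penetrance model; ",
         "for multi-causal or epistatic disease rules the 1/r2 factor does ",
         "not hold - use marker_case_control_freqs() directly")
  causal <- pm$locus
  qc <- marker_case_control_freqs(t, pm, causal, pm$risk_allele)
  qm <- marker_case_control_freqs(t, pm, marker)
  n_causal <- required_n(qc$q_case, qc$q_control, alpha, target_power)
  r2 <- pairwise_r2(t, marker, causal)
  if (qm$q_case == qm$q_control)
    return(list(n_causal = n_causal, n_marker = Inf, ratio = Inf,
                r2 = r2, inflation_factor = inflation_factor(r2)))
  n_marker <- required_n(qm$q_case, qm$q_control, alpha, target_power)
  list(n_causal = n_causal, n_marker = n_marker,
       ratio = n_marker / n_causal, r2 = r2,
       inflation_factor = inflation_factor(r2))
}

#' Probability of a false positive replicating across independent studies
#'
#' Under the null hypothesis, `n_studies` independent tests each of size
#' `alpha` all reject with probability `alpha^n_studies` — e.g. three
#' independent studies at 0.05 jointly reject with probability 0.000125.
#' The result assumes the studies are genuinely independent; replicable
#' spurious associations (population-level confounding) violate it.
#'
#' @param alpha Per-study test size in (0, 1).
#' @param n_studies Number of independent studies, at least 1.
#' @return List with `probability` and the stated `assumption`.
#' @export
joint_false_positive <- function(alpha, n_studies) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_studies < 1 || n_studies != round(n_studies))
    stop("n_studies must be a positive integer")
  list(probability = alpha^n_studies,
       assumption = "studies are independent under the null")
}
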