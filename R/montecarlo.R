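#' Simulation configuration
#'
#' Bundles the knobs of every simulator in the package: number of replicates,
#' root seed (all stochastic output is bit-reproducible given the seed),
#' group sizes, test size and the sampling mode for alleles.
#' `sampling = "allele"` draws 2n alleles per group directly from the group
#' allele frequency; `"hw_genotype"` draws a Binom(2, q) genotype for each of
#' the n individuals and sums the alleles (identical in distribution under
#' Hardy-Weinberg, kept as a literal mechanism).
#'
#' @param reps Number of replicates, at least 1.
#' @param seed Integer root seed.
#' @param n_case,n_control Diploid group sizes.
#' @param alpha Test size in (0, 1).
#' @param sampling `"allele"` or `"hw_genotype"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(reps, seed, n_case = 500, n_control = n_case,
                       alpha = 0.05, sampling = c("allele", "hw_genotype")) {
  sampling <- match.arg(sampling)
  if (reps < 1 || reps != round(reps)) stop("reps must be a positive integer")
  if (!is.finite(seed)) stop("seed must be a finite integer")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_case < 1 || n_control < 1) stop("group sizes must be at least 1")
  structure(list(reps = as.integer(reps), seed = as.integer(seed),
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 alpha = alpha, sampling = sampling),
            class = "sim_config")
}

# resolve any supported source to exact (q_case, q_control)
source_freqs <- function(source) {
  if (inherits(source, "structured_population")) {
    case_control_freqs(source)
  } else if (is.list(source) && !is.null(source$table) && !is.null(source$rule)) {
    f <- marker_case_control_freqs(source$table, source$rule, source$marker)
    list(q_case = f$q_case, q_control = f$q_control)
  } else if (is.list(source) && !is.null(source$q_case)) {
    source
  } else stop("unsupported simulation source")
}

draw_counts <- function(reps, n_people, q, sampling) {
  if (sampling == "allele") {
    stats::rbinom(reps, 2 * n_people, q)
  } else {
    # per-individual HWE genotypes, summed; matrix kept small by chunking
    counts <- integer(reps)
    chunk <- max(1L, floor(2e7 / n_people))
    i <- 1L
    while (i <= reps) {
      j <- min(reps, i + chunk - 1L)
      g <- matrix(stats::rbinom((j - i + 1L) * n_people, 2, q),
                  nrow = j - i + 1L)
      counts[i:j] <- as.integer(rowSums(g))
      i <- j + 1L
    }
    counts
  }
}

#' Sample a case-control allele-count table
#'
#' Draws one 2x2 table of case/control allele counts from a simulation
#' source: a [structured_population()], a haplotype model given as
#' `list(table =, rule =, marker =)` (rule as in
#' [marker_case_control_freqs()]), or a bare `list(q_case =, q_control =)`.
#'
#' @param source Simulation source (see Details).
#' @param cfg A [sim_config()]; only the first replicate's worth of draws is
#'   used.
#' @return 2x2 matrix, rows `case`/`control`, columns `allele`/`other`.
#' @export
sample_panel <- function(source, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  f <- source_freqs(source)
  check_nondegenerate(f)
  set.seed(cfg$seed)
  a_case <- draw_counts(1L, cfg$n_case, f$q_case, cfg$sampling)
  a_ctrl <- draw_counts(1L, cfg$n_control, f$q_control, cfg$sampling)
  m <- rbind(case = c(a_case, 2 * cfg$n_case - a_case),
             control = c(a_ctrl, 2 * cfg$n_control - a_ctrl))
  colnames(m) <- c("allele", "other")
  m
}

check_nondegenerate <- function(f) {
  if (f$q_case <= 0 || f$q_case >= 1 || f$q_control <= 0 || f$q_control >= 1)
    stop("degenerate conditional allele frequencies: q_case = ", f$q_case,
         ", q_control = ", f$q_control)
}

#' Pearson chi-square test on a 2x2 table
#'
#' The 1-df Pearson statistic without continuity correction and its
#' upper-tail p-value.  All four margins must be positive; a zero margin
#' leaves the statistic undefined (callers that simulate should count such
#' replicates separately rather than coercing them).
#'
#' @param table 2x2 numeric matrix of counts.
#' @return List with `statistic` and `p_value`.
#' @examples
#' chisq_2x2(rbind(c(30, 70), c(10, 90)))$statistic  # 12.5
#' @export
chisq_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2) || any(table < 0))
    stop("table must be a non-negative 2x2 matrix")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0))
    stop("undefined test: a margin of the 2x2 table is zero")
  e <- outer(rs, cs) / n
  stat <- sum((table - e)^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# vectorized 1-df chi-square p-values for reps tables given allele counts
chisq_vec <- function(a_case, m_case, a_ctrl, m_ctrl) {
  n <- m_case + m_ctrl
  c1 <- a_case + a_ctrl
  ok <- c1 > 0 & c1 < n
  stat <- rep(NA_real_, length(a_case))
  # Pearson statistic for 2x2 via the determinant form
  det <- a_case * (m_ctrl - a_ctrl) - a_ctrl * (m_case - a_case)
  stat[ok] <- (n[ok] * det[ok]^2) /
    (m_case[ok] * m_ctrl[ok] * c1[ok] * (n[ok] - c1[ok]))
  stat
}

#' Empirical rejection rate of the allelic test
#'
#' Simulates `cfg$reps` case-control panels from `source`, applies the
#' allelic chi-square test at `cfg$alpha`, and returns the rejection rate
#' with its binomial Monte-Carlo standard error.  Replicates in which a
#' margin is zero (the test is undefined) are excluded from the rate and
#' reported in `n_degenerate`.
#'
#' @inheritParams sample_panel
#' @return List with `rate`, `se`, `n_tested`, `n_degenerate`, `seed`.
#' @export
empirical_rejection_rate <- function(source, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  f <- source_freqs(source)
  check_nondegenerate(f)
  set.seed(cfg$seed)
  m_case <- rep(2 * cfg$n_case, cfg$reps)
  m_ctrl <- rep(2 * cfg$n_control, cfg$reps)
  a_case <- draw_counts(cfg$reps, cfg$n_case, f$q_case, cfg$sampling)
  a_ctrl <- draw_counts(cfg$reps, cfg$n_control, f$q_control, cfg$sampling)
  stat <- chisq_vec(a_case, m_case, a_ctrl, m_ctrl)
  ok <- !is.na(stat)
  crit <- stats::qchisq(1 - cfg$alpha, df = 1)
  rate <- mean(stat[ok] > crit)
  list(rate = rate, se = sqrt(rate * (1 - rate) / sum(ok)),
       n_tested = sum(ok), n_degenerate = sum(!ok), seed = cfg$seed)
}

#' Sample minor allele frequencies from a folded SFS
#'
#' For the continuous neutral spectrum the cumulative distribution of
#' \eqn{1/[p(1-p)]} on \eqn{(\epsilon, 1/2]} is linear in
#' \eqn{\mathrm{logit}(p)}, so inverse-CDF sampling is exact:
#' \eqn{p = \mathrm{logit}^{-1}[(1-u)\,\mathrm{logit}(\epsilon)]} for
#' \eqn{u \sim U(0,1)}.  Discrete spectra are sampled by their weights.
#'
#' @param sfs A folded SFS.
#' @param n Number of draws.
#' @param eps Lower truncation for the continuous spectrum (default `1e-4`;
#'   the density is integrable but steep near 0).
#' @return Numeric vector of MAFs in (0, 0.5].
#' @export
sample_sfs <- function(sfs, n, eps = 1e-4) {
  stopifnot(inherits(sfs, "folded_sfs"))
  if (is_continuous_sfs(sfs)) {
    u <- stats::runif(n)
    stats::plogis((1 - u) * stats::qlogis(eps))
  } else {
    sample(sfs$maf, n, replace = TRUE, prob = sfs$weight)
  }
}

#' Monte-Carlo estimate of discovery sensitivity and PPV
#'
#' Simulation oracle for [sensitivity()] and [ppv()]: draws loci with MAF
#' from the folded SFS, samples minor-allele counts Binom(2n, p), applies
#' the k-copies filter, and estimates both conditional probabilities with
#' binomial standard errors.
#'
#' @param d A [sample_design()].
#' @param sfs A folded SFS.
#' @param cfg A [sim_config()] (reps and seed are used).
#' @param eps Lower truncation passed to [sample_sfs()].
#' @return List with `sensitivity`, `sensitivity_se`, `ppv`, `ppv_se`,
#'   `n_common`, `n_detected`, `seed`.
#' @export
empirical_discovery <- function(d, sfs = sfs_neutral(), cfg, eps = 1e-4) {
  stopifnot(inherits(d, "sample_design"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- sample_sfs(sfs, cfg$reps, eps)
  m <- 2 * d$n_people
  x <- stats::rbinom(cfg$reps, m, p)
  detected <- x >= d$k & x <= m - d$k
  common <- p >= d$c
  n_common <- sum(common)
  n_detected <- sum(detected)
  sens <- if (n_common > 0) mean(detected[common]) else NA_real_
  pv <- if (n_detected > 0) mean(common[detected]) else NA_real_
  list(sensitivity = sens,
       sensitivity_se = if (n_common > 0) sqrt(sens * (1 - sens) / n_common) else NA_real_,
       ppv = pv,
       ppv_se = if (n_detected > 0) sqrt(pv * (1 - pv) / n_detected) else NA_real_,
       n_common = n_common, n_detected = n_detected, seed = cfg$seed)
}
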