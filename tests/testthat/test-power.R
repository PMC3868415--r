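test_that("allelic power is alpha under the null and monotone in n", {
  expect_equal(allelic_power(0.3, 0.3, 500, 500, alpha = 0.05), 0.05)
  expect_equal(allelic_power(0.3, 0.3, 500, 500, alpha = 0.01), 0.01)
  pw <- vapply(c(100, 200, 400, 800, 1600),
               function(n) allelic_power(0.55, 0.5, n, n), numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(allelic_power(0, 0.5, 100), "strictly in")
  expect_error(allelic_power(0.5, 1, 100), "strictly in")
})

test_that("analytic power matches the empirical rejection rate", {
  # 2x2 grid of (effect size, sample size), simulation oracle at 1e5 reps
  grid <- expand.grid(q1 = c(0.55, 0.60), n = c(250, 1000))
  for (i in seq_len(nrow(grid))) {
    q1 <- grid$q1[i]; n <- grid$n[i]
    est <- empirical_rejection_rate(
      list(q_case = q1, q_control = 0.5),
      sim_config(1e5, seed = 100 + i, n_case = n, n_control = n))
    ana <- allelic_power(q1, 0.5, n, n)
    expect_lt(abs(ana - est$rate), 3 * max(est$se, 1e-4))
  }
})

test_that("required sample size is the exact integer threshold", {
  n <- required_n(0.55, 0.50, alpha = 0.05, target_power = 0.8)
  expect_gte(allelic_power(0.55, 0.50, n, n), 0.8)
  if (n > 1) expect_lt(allelic_power(0.55, 0.50, n - 1, n - 1), 0.8)
  # a target barely above alpha needs almost nothing
  expect_equal(required_n(0.9, 0.1, 0.05, 0.051), 1L)
  expect_error(required_n(0.5, 0.5), "no finite sample size")
  expect_error(required_n(0.55, 0.5, 0.05, 0.04), "target_power")
})

test_that("halving the noncentrality doubles the required n in the small-effect limit", {
  n1 <- required_n(0.505, 0.5, 0.05, 0.8)
  n2 <- required_n(0.51, 0.5, 0.05, 0.8)   # doubled gap -> ~4x fewer
  expect_equal(n1 / n2, 4, tolerance = 0.02)
})

test_that("inflation factor is 1/r2 with an informative zero error", {
  expect_equal(inflation_factor(1), 1)
  expect_equal(inflation_factor(0.5), 2)
  expect_equal(inflation_factor(1/3), 3)
  expect_error(inflation_factor(0), "no information")
  expect_error(inflation_factor(1.2), "lie in")
})

test_that("marker case/control frequencies follow Bayes inversion exactly", {
  # at the causal locus itself the penetrance-model inversion is closed-form
  tab <- haplotype_table(data.frame(R = c("1", "0")), c(0.3, 0.7))
  pm <- penetrance_model("R", "1", f1 = 0.2, f0 = 0.1)
  f <- marker_case_control_freqs(tab, pm, "R", "1")
  prev <- 0.3 * 0.2 + 0.7 * 0.1
  expect_equal(f$prevalence, prev)
  expect_equal(f$q_case, 0.3 * 0.2 / prev)
  expect_equal(f$q_control, 0.3 * 0.8 / (1 - prev))

  # perfect LD: marker frequencies equal causal frequencies
  t2 <- haplotype_table(data.frame(M = c("1", "0"), R = c("1", "0")),
                        c(0.3, 0.7))
  f2 <- marker_case_control_freqs(t2, pm, "M", "1")
  expect_equal(f2$q_case, f$q_case)
  expect_equal(f2$q_control, f$q_control)
})

test_that("binary disease coding of the signed phenotype retains association", {
  # cases = phenotype +1, controls = everyone else: the marker still splits
  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  rule <- function(t) as.numeric(t$R == "1" & t$P == "0")
  f <- marker_case_control_freqs(rp$table, rule, "M", "1")
  expect_equal(f$q_case, 1)
  expect_equal(f$q_control, 1/3)
  expect_false(isTRUE(all.equal(f$q_case, f$q_control)))
  # whereas the symmetric +1 / -1 contrast is exactly degenerate
  qp <- conditional_marginal(rp$table, rp$map, "M", "1", function(phi) phi > 0)
  qm <- conditional_marginal(rp$table, rp$map, "M", "1", function(phi) phi < 0)
  expect_equal(qp, qm)
  expect_error(required_n(qp, qm), "no finite sample size")
})

test_that("degenerate ascertainment is refused", {
  tab <- haplotype_table(data.frame(R = c("1", "0")), c(0.3, 0.7))
  expect_error(marker_case_control_freqs(
    tab, penetrance_model("R", "1", 0, 0.0), "R"), "penetrances zero")
  expect_error(marker_case_control_freqs(
    tab, function(t) rep(1, 2), "R"), "degenerate ascertainment")
})

test_that("the 1/r2 inflation holds within 10% for small effects", {
  # two-locus table with r2 = 1/2 and a small penetrance contrast
  pAB <- 0.25 + 0.25 / sqrt(2)
  t <- haplotype_table(data.frame(M = c("1", "1", "0", "0"),
                                  R = c("1", "0", "1", "0")),
                       c(pAB, 0.5 - pAB, 0.5 - pAB, pAB))
  expect_equal(pairwise_r2(t, "M", "R"), 0.5, tolerance = 1e-12)
  chk <- inflation_check(t, penetrance_model("R", "1", 0.11, 0.10), "M")
  expect_equal(chk$inflation_factor, 2)
  expect_gt(chk$ratio, 1.8)
  expect_lt(chk$ratio, 2.2)
  # r2 = 1 means no inflation at all
  t1 <- haplotype_table(data.frame(M = c("1", "0"), R = c("1", "0")),
                        c(0.3, 0.7))
  chk1 <- inflation_check(t1, penetrance_model("R", "1", 0.11, 0.10), "M")
  expect_equal(chk1$ratio, 1)
})

test_that("inflation ratio approaches 1/r2 monotonically as the effect shrinks", {
  pAB <- 0.25 + 0.25 / sqrt(2)
  t <- haplotype_table(data.frame(M = c("1", "1", "0", "0"),
                                  R = c("1", "0", "1", "0")),
                       c(pAB, 0.5 - pAB, 0.5 - pAB, pAB))
  gaps <- c(0.08, 0.04, 0.02, 0.01)
  devs <- vapply(gaps, function(g) {
    chk <- inflation_check(t, penetrance_model("R", "1", 0.1 + g, 0.1), "M")
    abs(chk$ratio - chk$inflation_factor)
  }, numeric(1))
  expect_lt(devs[length(devs)], 0.1 * 2)  # within 10% of 1/r2 = 2
  # deviations shrink with the effect (up to integer rounding of n)
  expect_lt(devs[length(devs)], devs[1] + 0.01)
  expect_true(all(devs <= devs[1] + 0.02 * 2))
})

test_that("multi-causal phenotype maps are refused by the inflation check", {
  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  rule <- function(t) as.numeric(t$R == "1" & t$P == "0")
  expect_error(inflation_check(rp$table, rule, "M"),
               "marker_case_control_freqs")
})

test_that("joint false-positive probability multiplies across studies", {
  expect_equal(joint_false_positive(0.05, 3)$probability, 0.000125)
  expect_equal(joint_false_positive(0.05, 1)$probability, 0.05)
  expect_equal(joint_false_positive(0.05, 2)$probability, 0.0025)
  expect_match(joint_false_positive(0.05, 2)$assumption, "independent")
  expect_error(joint_false_positive(1.5, 2), "alpha")
  expect_error(joint_false_positive(0.05, 0), "positive integer")
})
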