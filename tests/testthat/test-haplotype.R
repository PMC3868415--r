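test_that("haplotype tables validate frequencies and distinctness", {
  expect_error(haplotype_table(data.frame(M = c("0", "0")), c(0.5, 0.5)),
               "duplicated")
  expect_error(haplotype_table(data.frame(M = c("0", "1")), c(0.5, 0.4)),
               "sum")
  expect_error(haplotype_table(data.frame(M = c("0", "1")), c(-0.1, 1.1)),
               "non-negative")
  t1 <- haplotype_table(data.frame(M = "0"), 1)
  expect_equal(marginal_freq(t1, "M", "0"), 1)
})

test_that("marginal frequencies follow the builder constructions", {
  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  expect_equal(marginal_freq(rp$table, "M", "1"), 1/2)  # v + w + x
  expect_equal(marginal_freq(rp$table, "R", "1"), 1/4)
  sm <- shared_marker_model(0.1)
  expect_equal(marginal_freq(sm$table, "M", "1"), 0.2)  # 2y
  expect_error(marginal_freq(sm$table, "Z", "1"), "unknown locus")
  expect_error(marginal_freq(sm$table, "M", "9"), "not present")
})

test_that("pairwise LD marginalizes correctly to the two-locus engine", {
  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  expect_equal(pairwise_r2(rp$table, "M", "R"), 1/3)
  expect_equal(pairwise_r2(rp$table, "M", "M"), 1)
  ep <- epistasis_model()
  expect_equal(pairwise_r2(ep$table, "A", "B"), 0)  # independent margins
  # monomorphic locus refused: x = 0 removes the protective allele
  rp0 <- risk_protective_model(1/2, 1/4, 1/4, 0)
  expect_error(pairwise_r2(rp0$table, "M", "P"), "not biallelic")
})

test_that("phenotype moments are exact for the signed risk/protective model", {
  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  mm <- phenotype_moments(rp$table, rp$map)
  expect_equal(unname(mm["mean"]), 0)        # +1 w.p. 1/4, -1 w.p. 1/4
  expect_equal(unname(mm["variance"]), 1/2)
  # constant phenotype -> zero variance, correlation undefined
  cmap <- phenotype_map(values = rep(2, 4))
  expect_equal(unname(phenotype_moments(rp$table, cmap)["variance"]), 0)
  expect_error(locus_phenotype_corr2(rp$table, cmap, "M"), "variance is zero")
  # haploid mean of the shared-marker phenotype is 2y
  sm <- shared_marker_model(0.15)
  expect_equal(unname(phenotype_moments(sm$table, sm$map)["mean"]), 0.3)
})

test_that("diploid random-union doubles moments and preserves correlation", {
  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  dip <- phenotype_map(effects = rp$map$effects, ploidy = "diploid_additive")
  expect_equal(phenotype_moments(rp$table, dip),
               2 * phenotype_moments(rp$table, rp$map))
  expect_equal(locus_phenotype_corr2(rp$table, dip, "R"),
               locus_phenotype_corr2(rp$table, rp$map, "R"))
  expect_error(phenotype_map(values = 1:4, ploidy = "diploid_additive"),
               "additive")
})

test_that("risk/protective model reproduces the attenuation worked example", {
  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  expect_equal(locus_phenotype_corr2(rp$table, rp$map, "R"), 2/3)
  expect_equal(locus_phenotype_corr2(rp$table, rp$map, "M"), 0)
  expect_equal(locus_phenotype_corr(rp$table, rp$map, "M", "1"), 0)
})

test_that("without a protective haplotype the marker attenuates by exactly r2", {
  # x = 0: conditional independence holds, corr2(M, phi) = r2(M, R) * corr2(R, phi)
  set.seed(13)
  for (i in 1:25) {
    f <- as.numeric(rmultinom(1, 100, runif(3))) / 100
    if (any(f == 0)) next
    mod <- risk_protective_model(f[1], f[2], f[3], 0)
    lhs <- locus_phenotype_corr2(mod$table, mod$map, "M")
    rhs <- pairwise_r2(mod$table, "M", "R") *
      locus_phenotype_corr2(mod$table, mod$map, "R")
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("x > w reverses the sign of the marker-phenotype correlation", {
  lo <- risk_protective_model(0.4, 0.1, 0.3, 0.2)  # x < w: positive
  hi <- risk_protective_model(0.4, 0.1, 0.2, 0.3)  # x > w: negative
  expect_gt(locus_phenotype_corr(lo$table, lo$map, "M", "1"), 0)
  expect_lt(locus_phenotype_corr(hi$table, hi$map, "M", "1"), 0)
  expect_error(risk_protective_model(0.5, 0.5, 0.5, 0.5), "equal 1")
  expect_error(risk_protective_model(-0.1, 0.5, 0.3, 0.3), "non-negative")
})

test_that("shared-marker model: perfect marker, attenuated causal loci", {
  for (y in c(0.05, 0.2, 0.4)) {
    sm <- shared_marker_model(y)
    expect_equal(locus_phenotype_corr2(sm$table, sm$map, "M"), 1)
    # closed form validated against enumeration: (1 - 2y) / (2 (1 - y))
    cf <- (1 - 2 * y) / (2 * (1 - y))
    expect_equal(locus_phenotype_corr2(sm$table, sm$map, "R1"), cf,
                 tolerance = 1e-12)
    expect_equal(locus_phenotype_corr2(sm$table, sm$map, "R2"), cf,
                 tolerance = 1e-12)
    expect_lt(cf, 1)
  }
  expect_equal(locus_phenotype_corr2(shared_marker_model(0.2)$table,
                                     shared_marker_model(0.2)$map, "R1"),
               0.375)
  expect_error(shared_marker_model(0.5), "\\(0, 1/2\\)")
})

test_that("epistasis model: causal loci uncorrelated, marker perfect", {
  ep <- epistasis_model()
  expect_equal(locus_phenotype_corr2(ep$table, ep$map, "A"), 0)
  expect_equal(locus_phenotype_corr2(ep$table, ep$map, "B"), 0)
  expect_equal(locus_phenotype_corr2(ep$table, ep$map, "C"), 1)
})

test_that("corr2 agrees with an independent pseudo-sample enumeration oracle", {
  mods <- list(risk_protective_model(1/2, 0, 1/4, 1/4),
               shared_marker_model(0.2), epistasis_model())
  loci <- list(c("M", "R"), c("M", "R1"), c("A", "C"))
  for (j in seq_along(mods)) {
    for (loc in loci[[j]]) {
      got <- locus_phenotype_corr2(mods[[j]]$table, mods[[j]]$map, loc)
      want <- oracle_corr2(mods[[j]]$table, mods[[j]]$map, loc)
      if (is.na(want)) want <- 0  # sd zero => uncorrelated indicator
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
  # random tables with random additive phenotypes
  set.seed(29)
  tried <- 0
  while (tried < 30) {
    t <- random_haplotype_table()
    biall <- Filter(function(l) length(unique(t[[l]])) == 2, names(t)[1:3])
    if (!length(biall)) next
    map <- phenotype_map(effects = stats::setNames(
      lapply(names(t)[1:3], function(l) c("1" = round(runif(1, -2, 2), 2))),
      names(t)[1:3]))
    phiv <- phenotype_values(t, map)
    if (stats::sd(phiv) == 0) next
    for (loc in biall) {
      got <- locus_phenotype_corr2(t, map, loc)
      want <- oracle_corr2(t, map, loc)
      expect_equal(got, want, tolerance = 1e-9)
    }
    tried <- tried + 1
  }
})

test_that("conditional marginals recover case/control contrasts exactly", {
  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  # P(M1 | phi = +1) = 1: only the M1R1P0 haplotype has phi = +1
  expect_equal(conditional_marginal(rp$table, rp$map, "M", "1",
                                    function(phi) phi > 0), 1)
  # P(M1 | phi = -1) = 1 as well: the protective haplotype also carries M1
  expect_equal(conditional_marginal(rp$table, rp$map, "M", "1",
                                    function(phi) phi < 0), 1)
  expect_error(conditional_marginal(rp$table, rp$map, "M", "1",
                                    function(phi) phi > 5),
               "probability zero")
})

test_that("oracle: phenotype variance of random additive maps matches moments", {
  set.seed(31)
  for (i in 1:20) {
    t <- random_haplotype_table()
    map <- phenotype_map(effects = stats::setNames(
      lapply(names(t)[1:3], function(l) c("1" = round(runif(1, -1, 1), 2))),
      names(t)[1:3]))
    counts <- round(t$freq * 200)
    phi <- rep(phenotype_values(t, map), counts)
    mm <- phenotype_moments(t, map)
    expect_equal(unname(mm["mean"]), mean(phi), tolerance = 1e-9)
    expect_equal(unname(mm["variance"]),
                 mean((phi - mean(phi))^2), tolerance = 1e-9)
  }
})
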