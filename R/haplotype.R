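#' Multi-locus haplotype tables
#'
#' An exact, enumerable representation of a population of haplotypes: one row
#' per distinct haplotype, one column per locus (allele labels as character
#' strings) plus a `freq` column.  All downstream quantities — marginal
#' allele frequencies, pairwise LD, phenotype moments and locus–phenotype
#' correlations — are computed by exact enumeration over this table, which
#' is what makes the counterexample models in this package closed-form
#' rather than simulated.
#'
#' @param alleles A data frame of allele labels, one column per locus, rows
#'   distinct.
#' @param freq Numeric vector of haplotype frequencies, non-negative, summing
#'   to 1 (tolerance `1e-9`, renormalized with a warning if within it).
#' @return An object of class `haplotype_table` (a data frame).
#' @examples
#' t <- haplotype_table(data.frame(M = c("1", "1", "0"), R = c("1", "0", "0")),
#'                      freq = c(0.1, 0.2, 0.7))
#' marginal_freq(t, "M", "1")
#' @export
haplotype_table <- function(alleles, freq) {
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  if (ncol(alleles) < 1) stop("need at least one locus")
  if (nrow(alleles) != length(freq)) stop("freq length must match haplotype rows")
  alleles[] <- lapply(alleles, as.character)
  if (anyDuplicated(alleles)) stop("duplicated haplotype rows")
  if (any(!is.finite(freq)) || any(freq < 0)) stop("frequencies must be non-negative")
  s <- sum(freq)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("haplotype frequencies sum to %.12g, not 1", s))
  if (s != 1) {
    if (abs(s - 1) > 1e-12) warning("renormalizing haplotype frequencies")
    freq <- freq / s
  }
  out <- cbind(alleles, freq = freq)
  class(out) <- c("haplotype_table", "data.frame")
  out
}

loci_names <- function(t) setdiff(names(t), "freq")

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table over loci:", paste(loci_names(x), collapse = ", "), "\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Marginal allele frequency at one locus
#'
#' @param t A [haplotype_table()].
#' @param locus Locus (column) name.
#' @param allele Allele label at that locus.
#' @return Total frequency of haplotypes carrying `allele` at `locus`.
#' @export
marginal_freq <- function(t, locus, allele) {
  stopifnot(inherits(t, "haplotype_table"))
  if (!locus %in% loci_names(t)) stop("unknown locus: ", locus)
  if (!allele %in% t[[locus]])
    stop("allele ", allele, " not present at locus ", locus)
  sum(t$freq[t[[locus]] == allele])
}

# collapse two loci of a table to a two_locus_haplotypes object; the "A"/"B"
# alleles are the lexicographically larger labels at each locus
collapse_pair <- function(t, locusA, locusB) {
  for (l in c(locusA, locusB)) {
    if (!l %in% loci_names(t)) stop("unknown locus: ", l)
    present <- unique(t[[l]][t$freq > 0])
    if (length(present) != 2)
      stop("locus ", l, " is not biallelic among haplotypes with positive frequency")
  }
  aA <- max(unique(t[[locusA]][t$freq > 0]))
  aB <- max(unique(t[[locusB]][t$freq > 0]))
  iA <- t[[locusA]] == aA
  iB <- t[[locusB]] == aB
  two_locus_haplotypes(sum(t$freq[iA & iB]),  sum(t$freq[iA & !iB]),
                       sum(t$freq[!iA & iB]), sum(t$freq[!iA & !iB]))
}

#' Pairwise LD between two loci of a haplotype table
#'
#' Marginalizes the table to the 2x2 gamete frequencies of the two loci and
#' applies [r_squared()].  A locus paired with itself returns 1.
#'
#' @param t A [haplotype_table()]; both loci must be biallelic.
#' @param locusA,locusB Locus names.
#' @return \eqn{r^2 \in [0, 1]}.
#' @export
pairwise_r2 <- function(t, locusA, locusB) {
  stopifnot(inherits(t, "haplotype_table"))
  if (identical(locusA, locusB)) {
    if (!locusA %in% loci_names(t)) stop("unknown locus: ", locusA)
    return(1)
  }
  r_squared(collapse_pair(t, locusA, locusB))
}

#' Phenotype maps over haplotypes
#'
#' A phenotype map assigns a (deterministic) phenotype value to every
#' haplotype.  Two modes:
#'
#' * `additive`: `effects` is a named list, one element per affected locus,
#'   each a named numeric vector of per-allele effects; the phenotype of a
#'   haplotype is the sum of the effects of its alleles (alleles without an
#'   entry contribute 0).
#' * `explicit`: `values` gives the phenotype of each haplotype row of the
#'   table it will be applied to.
#'
#' `ploidy = "diploid_additive"` models a genotype as the random union of two
#' independent gametes with summed effects (Hardy–Weinberg); it is only
#' available for additive maps.
#'
#' @param effects Named list of per-locus allele-effect vectors (additive
#'   mode).
#' @param values Numeric phenotype per haplotype row (explicit mode).
#' @param ploidy `"haploid"` (default) or `"diploid_additive"`.
#' @return An object of class `phenotype_map`.
#' @export
phenotype_map <- function(effects = NULL, values = NULL, ploidy = "haploid") {
  ploidy <- match.arg(ploidy, c("haploid", "diploid_additive"))
  if (is.null(effects) == is.null(values))
    stop("give exactly one of `effects` (additive) or `values` (explicit)")
  if (!is.null(values) && ploidy == "diploid_additive")
    stop("diploid_additive requires an additive map")
  if (!is.null(effects)) {
    if (is.null(names(effects)) || any(names(effects) == ""))
      stop("effects must be a named list (one element per locus)")
    for (e in effects)
      if (any(!is.finite(e)) || is.null(names(e)))
        stop("each effect vector must be finite and allele-named")
    mode <- "additive"
  } else {
    if (any(!is.finite(values))) stop("explicit phenotype values must be finite")
    mode <- "explicit"
  }
  structure(list(mode = mode, effects = effects, values = values,
                 ploidy = ploidy), class = "phenotype_map")
}

#' Phenotype value of each haplotype
#'
#' @param t A [haplotype_table()].
#' @param m A [phenotype_map()].
#' @return Numeric vector, one phenotype per haplotype row (per-gamete
#'   contribution for diploid maps).
#' @export
phenotype_values <- function(t, m) {
  stopifnot(inherits(t, "haplotype_table"), inherits(m, "phenotype_map"))
  if (m$mode == "explicit") {
    if (length(m$values) != nrow(t))
      stop("explicit map covers ", length(m$values),
           " haplotypes but the table has ", nrow(t))
    return(m$values)
  }
  unknown <- setdiff(names(m$effects), loci_names(t))
  if (length(unknown))
    stop("effects reference unknown loci: ", paste(unknown, collapse = ", "))
  phi <- numeric(nrow(t))
  for (loc in names(m$effects)) {
    e <- m$effects[[loc]]
    idx <- match(t[[loc]], names(e))
    phi <- phi + ifelse(is.na(idx), 0, e[idx])
  }
  phi
}

#' Exact phenotype mean and variance
#'
#' Moments of the phenotype under the haplotype distribution.  For haploid
#' maps these are the weighted moments of the per-haplotype values.  Under
#' `diploid_additive` the phenotype is the sum of two independent gamete
#' contributions, so the mean doubles and the variance doubles.
#'
#' @inheritParams phenotype_values
#' @return Named vector `c(mean, variance)`.
#' @export
phenotype_moments <- function(t, m) {
  phi <- phenotype_values(t, m)
  mu <- sum(t$freq * phi)
  v <- sum(t$freq * (phi - mu)^2)
  if (m$ploidy == "diploid_additive") { mu <- 2 * mu; v <- 2 * v }
  c(mean = mu, variance = v)
}

#' Squared correlation between a locus and the phenotype
#'
#' The squared Pearson correlation between the indicator of one allele at
#' `locus` and the phenotype, computed by exact enumeration over the
#' haplotype distribution.  The value does not depend on which of the two
#' alleles carries the indicator (the complement flips the sign of the
#' correlation, not its square).  Under `diploid_additive` both the allele
#' count and the phenotype are sums over two independent gametes, so
#' covariance and both variances double and the correlation is unchanged.
#'
#' @inheritParams phenotype_values
#' @param locus Locus name; must be biallelic.
#' @return \eqn{corr^2(X_{locus}, \phi) \in [0, 1]}.
#' @examples
#' mod <- epistasis_model()
#' locus_phenotype_corr2(mod$table, mod$map, "A")  # 0
#' locus_phenotype_corr2(mod$table, mod$map, "C")  # 1
#' @export
locus_phenotype_corr2 <- function(t, m, locus) {
  stopifnot(inherits(t, "haplotype_table"))
  if (!locus %in% loci_names(t)) stop("unknown locus: ", locus)
  present <- unique(t[[locus]][t$freq > 0])
  if (length(present) != 2) stop("locus ", locus, " is not biallelic")
  phi <- phenotype_values(t, m)
  mu_phi <- sum(t$freq * phi)
  v_phi <- sum(t$freq * (phi - mu_phi)^2)
  if (v_phi <= 0) stop("phenotype variance is zero; correlation undefined")
  x <- as.numeric(t[[locus]] == max(present))
  mu_x <- sum(t$freq * x)
  v_x <- sum(t$freq * (x - mu_x)^2)
  cv <- sum(t$freq * (x - mu_x) * (phi - mu_phi))
  min(cv^2 / (v_x * v_phi), 1)
}

#' Signed locus–phenotype correlation
#'
#' As [locus_phenotype_corr2()] but returning the signed correlation of the
#' indicator of a stated allele, so that sign reversals (e.g. when a linked
#' protective haplotype outweighs the risk haplotype) are visible.
#'
#' @inheritParams locus_phenotype_corr2
#' @param allele Allele whose indicator is correlated with the phenotype.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
locus_phenotype_corr <- function(t, m, locus, allele) {
  if (!allele %in% t[[locus]])
    stop("allele ", allele, " not present at locus ", locus)
  phi <- phenotype_values(t, m)
  mu_phi <- sum(t$freq * phi)
  v_phi <- sum(t$freq * (phi - mu_phi)^2)
  if (v_phi <= 0) stop("phenotype variance is zero; correlation undefined")
  x <- as.numeric(t[[locus]] == allele)
  mu_x <- sum(t$freq * x)
  v_x <- sum(t$freq * (x - mu_x)^2)
  if (v_x <= 0) stop("locus ", locus, " is monomorphic")
  sum(t$freq * (x - mu_x) * (phi - mu_phi)) / sqrt(v_x * v_phi)
}

#' Conditional marginal allele frequency given a phenotype condition
#'
#' `P(allele at locus | condition(phenotype))` by exact enumeration: useful
#' for forming case/control allele frequencies under arbitrary phenotype
#' contrasts (e.g. cases = phenotype +1 versus controls = phenotype -1).
#'
#' @inheritParams locus_phenotype_corr2
#' @param allele Allele of interest.
#' @param condition Predicate on phenotype values (vectorized).
#' @return Conditional probability.
#' @export
conditional_marginal <- function(t, m, locus, allele, condition) {
  phi <- phenotype_values(t, m)
  keep <- condition(phi)
  denom <- sum(t$freq[keep])
  if (denom <= 0) stop("the phenotype condition has probability zero")
  sum(t$freq[keep & t[[locus]] == allele]) / denom
}

#' Marker linked to one risk and one protective locus
#'
#' A three-locus haploid model: marker M, risk locus R (allele R=1 adds +1
#' to the phenotype) and protective locus P (allele P=1 subtracts 1).  Only
#' four haplotypes exist — the risk allele never occurs on the marker-0
#' background, and the protective allele co-occurs only with marker allele 1:
#'
#' \tabular{lllll}{
#'   M \tab R \tab P \tab freq \cr
#'   0 \tab 0 \tab 0 \tab u \cr
#'   1 \tab 0 \tab 0 \tab v \cr
#'   1 \tab 1 \tab 0 \tab w \cr
#'   1 \tab 0 \tab 1 \tab x
#' }
#'
#' With `x = 0` this is the plain marker/risk configuration in which the
#' 1/r² sample-size inflation factor holds exactly.  With `x > 0` the
#' marker's residual variance is correlated with the phenotype through P and
#' the factor fails: at `x = w` the marker is uncorrelated with the
#' phenotype despite substantial LD with R, and for `x > w` the sign of the
#' marker–phenotype relationship reverses.
#'
#' @param u,v,w,x Haplotype frequencies, non-negative, summing to 1.
#' @return List with elements `table` ([haplotype_table()]) and `map`
#'   ([phenotype_map()], haploid additive).
#' @examples
#' mod <- risk_protective_model(1/2, 0, 1/4, 1/4)
#' pairwise_r2(mod$table, "M", "R")                # 1/3
#' locus_phenotype_corr2(mod$table, mod$map, "R")  # 2/3
#' @export
risk_protective_model <- function(u, v, w, x) {
  fr <- c(u, v, w, x)
  if (any(!is.finite(fr)) || any(fr < 0)) stop("u, v, w, x must be non-negative")
  if (abs(sum(fr) - 1) > 1e-9) stop("u + v + w + x must equal 1")
  tab <- haplotype_table(
    data.frame(M = c("0", "1", "1", "1"),
               R = c("0", "0", "1", "0"),
               P = c("0", "0", "0", "1")),
    freq = fr)
  map <- phenotype_map(effects = list(R = c("1" = 1), P = c("1" = -1)))
  list(table = tab, map = map)
}

#' Marker tagging two alternative risk loci (multiplicity of causes)
#'
#' Three haplotypes over a marker M and two risk loci: each copy of the
#' marker allele M=1 (total frequency `2y`) carries exactly one of the two
#' risk alleles, each risk allele having frequency `y`.  The phenotype is
#' the number of risk alleles carried, so the marker is perfectly associated
#' with the phenotype (\eqn{r^2 = 1}) while each causal locus has the
#' strictly smaller squared correlation \eqn{(1-2y)/[2(1-y)]}.
#'
#' @param y Risk-allele frequency, in (0, 1/2).
#' @return List with `table` and `map` as in [risk_protective_model()].
#' @export
shared_marker_model <- function(y) {
  if (!is.finite(y) || y <= 0 || y >= 0.5) stop("y must lie in (0, 1/2)")
  tab <- haplotype_table(
    data.frame(M = c("1", "1", "0"),
               R1 = c("1", "0", "0"),
               R2 = c("0", "1", "0")),
    freq = c(y, y, 1 - 2 * y))
  map <- phenotype_map(effects = list(R1 = c("1" = 1), R2 = c("1" = 1)))
  list(table = tab, map = map)
}

#' Epistatic disease with an uncorrelated pair of causal loci
#'
#' The haploid epistasis model: two causal loci A/a and B/b with the four
#' haplotypes AB, Ab, aB, ab at frequency 1/4 each, and disease if and only
#' if the genotype is AB or ab.  A non-causal marker allele C rides exactly
#' on the AB and ab haplotypes.  Each causal locus is then uncorrelated with
#' disease (\eqn{r^2 = 0}) while the marker is perfectly associated
#' (\eqn{r^2 = 1}).  The B/b locus may equally be read as a binary
#' environmental exposure.
#'
#' @return List with `table` and `map` (explicit disease indicator, haploid).
#' @export
epistasis_model <- function() {
  tab <- haplotype_table(
    data.frame(A = c("A", "A", "a", "a"),
               B = c("B", "b", "B", "b"),
               C = c("C", "c", "c", "C")),
    freq = rep(1/4, 4))
  map <- phenotype_map(values = c(1, 0, 0, 1))
  list(table = tab, map = map)
}
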