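# Random-instance generators shared by property-style tests.

# random two-locus gamete table with both loci polymorphic
random_two_locus <- function() {
  repeat {
    f <- as.numeric(stats::rmultinom(1, 1000, stats::runif(4))) / 1000
    h <- try(two_locus_haplotypes(f[1], f[2], f[3], f[4]), silent = TRUE)
    if (inherits(h, "try-error")) next
    m <- h[["p_AB"]] + h[["p_Ab"]]
    mB <- h[["p_AB"]] + h[["p_aB"]]
    if (m > 0 && m < 1 && mB > 0 && mB < 1) return(h)
  }
}

# brute-force maximum of r^2 over a grid of feasible p_AB given margins
brute_max_r2 <- function(p_A, p_B, grid = 1e4) {
  lo <- max(0, p_A + p_B - 1)
  hi <- min(p_A, p_B)
  pAB <- seq(lo, hi, length.out = grid)
  D <- pAB - p_A * p_B
  max(D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B)))
}

# random multi-locus haplotype table (biallelic loci, alleles "0"/"1")
random_haplotype_table <- function(n_loci = 3, max_haps = 6) {
  repeat {
    n_h <- sample(2:max_haps, 1)
    al <- as.data.frame(matrix(sample(c("0", "1"), n_h * n_loci, replace = TRUE),
                               nrow = n_h))
    names(al) <- paste0("L", seq_len(n_loci))
    if (anyDuplicated(al)) next
    f <- as.numeric(stats::rmultinom(1, 200, stats::runif(n_h))) / 200
    if (any(f == 0)) next
    return(haplotype_table(al, f))
  }
}

# weighted-enumeration oracle for the squared locus-phenotype correlation,
# written independently of locus_phenotype_corr2 (expands the distribution
# into a finite pseudo-sample and uses stats::cor)
oracle_corr2 <- function(t, map, locus, denom = 10000L) {
  counts <- round(t$freq * denom)
  x <- rep(as.numeric(t[[locus]] == max(unique(t[[locus]][t$freq > 0]))), counts)
  phi <- rep(phenotype_values(t, map), counts)
  stats::cor(x, phi)^2
}

random_structured_population <- function(I = sample(2:6, 1)) {
  g <- stats::runif(I)
  structured_population(g / sum(g), stats::runif(I, 0.01, 0.5), stats::runif(I))
}
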