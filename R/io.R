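#' Read a haplotype table from TSV
#'
#' Tab-delimited, header required, `#` comment lines allowed: one column per
#' locus plus a `freq` column (and optionally a `phenotype` column, returned
#' as an explicit [phenotype_map()]).  Frequencies are validated exactly as
#' in [haplotype_table()].
#'
#' @param path File path.
#' @return A [haplotype_table()]; if the file has a `phenotype` column, the
#'   map is attached as attribute `"phenotype_map"`.
#' @export
read_haplotype_table <- function(path) {
  df <- read_tsv_checked(path)
  if (!"freq" %in% names(df)) stop("missing required column `freq` in ", path)
  freq <- suppressWarnings(as.numeric(df$freq))
  if (any(is.na(freq))) {
    bad <- which(is.na(freq))[1]
    stop("non-numeric freq on data line ", bad, " of ", path)
  }
  phen <- NULL
  if ("phenotype" %in% names(df)) {
    phen <- suppressWarnings(as.numeric(df$phenotype))
    if (any(is.na(phen))) stop("non-numeric phenotype column in ", path)
  }
  loci <- setdiff(names(df), c("freq", "phenotype"))
  if (!length(loci)) stop("no locus columns in ", path)
  t <- haplotype_table(df[loci], freq)
  if (!is.null(phen)) attr(t, "phenotype_map") <- phenotype_map(values = phen)
  t
}

#' Write a haplotype table to TSV
#'
#' @param t A [haplotype_table()].
#' @param path Output path.
#' @param map Optional explicit [phenotype_map()] written as a `phenotype`
#'   column.
#' @export
write_haplotype_table <- function(t, path, map = NULL) {
  stopifnot(inherits(t, "haplotype_table"))
  df <- as.data.frame(t)
  if (!is.null(map)) df$phenotype <- phenotype_values(t, map)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a structured population from TSV
#'
#' Schema: columns `subpop`, `gamma`, `prevalence`, `allele_freq`; header
#' required; `#` comments allowed.
#'
#' @param path File path.
#' @return A [structured_population()].
#' @export
read_structured_population <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("subpop", "gamma", "prevalence", "allele_freq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
  num <- lapply(df[c("gamma", "prevalence", "allele_freq")], function(x)
    suppressWarnings(as.numeric(x)))
  if (any(vapply(num, anyNA, logical(1))))
    stop("non-numeric values in ", path)
  structured_population(num$gamma, num$prevalence, num$allele_freq)
}

#' @noRd
write_structured_population <- function(s, path) {
  df <- data.frame(subpop = seq_along(s$gamma), gamma = s$gamma,
                   prevalence = s$p, allele_freq = s$q)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a custom folded SFS from TSV
#'
#' Schema: columns `maf`, `weight`; header required.
#'
#' @param path File path.
#' @return An [sfs_custom()] spectrum.
#' @export
read_sfs_table <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("maf", "weight") %in% names(df)))
    stop("custom SFS file needs columns `maf` and `weight`: ", path)
  sfs_custom(as.numeric(df$maf), as.numeric(df$weight))
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", colClasses = "character",
                      check.names = FALSE),
    error = function(e) stop("malformed TSV ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0) stop("empty table: ", path)
  df
}

#' Generate the package's reference and randomized fixtures
#'
#' Writes, deterministically under `seed`:
#' * the four stratification scenarios (`strata_A.tsv` ... `strata_D.tsv`);
#' * the counterexample haplotype models (`risk_protective.tsv`,
#'   `shared_marker.tsv`, `epistasis.tsv`, with phenotype columns);
#' * a small custom SFS (`sfs_custom.tsv`);
#' * randomized two-locus haplotype tables and structured populations with
#'   their ground truth (r-squared; covariance, with unconfounded instances
#'   built by projecting the allele frequencies onto the gamma-weighted
#'   orthogonal complement of the prevalences, so their covariance is 0 by
#'   construction).
#'
#' A manifest (JSON) recording every file and its ground truth is written to
#' `manifest.json` and returned invisibly.
#'
#' @param seed Integer seed.
#' @param out_dir Writable output directory (created if needed).
#' @param n_random Number of randomized instances of each kind.
#' @return The manifest list, invisibly.
#' @export
generate_fixtures <- function(seed, out_dir, n_random = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  manifest <- list(seed = seed, files = list())
  add <- function(name, truth) manifest$files[[name]] <<- truth

  for (sc in c("A", "B", "C", "D")) {
    s <- strat_scenario(sc)
    f <- file.path(out_dir, paste0("strata_", sc, ".tsv"))
    write_structured_population(s, f)
    add(basename(f), list(scenario = sc,
                          covariance = confounding_covariance(s),
                          confounded = is_confounded(s)))
  }

  rp <- risk_protective_model(1/2, 0, 1/4, 1/4)
  write_haplotype_table(rp$table, file.path(out_dir, "risk_protective.tsv"), rp$map)
  add("risk_protective.tsv", list(r2_MR = pairwise_r2(rp$table, "M", "R")))
  sm <- shared_marker_model(0.2)
  write_haplotype_table(sm$table, file.path(out_dir, "shared_marker.tsv"), sm$map)
  add("shared_marker.tsv",
      list(marker_corr2 = locus_phenotype_corr2(sm$table, sm$map, "M")))
  ep <- epistasis_model()
  write_haplotype_table(ep$table, file.path(out_dir, "epistasis.tsv"), ep$map)
  add("epistasis.tsv",
      list(marker_corr2 = locus_phenotype_corr2(ep$table, ep$map, "C")))

  maf <- c(0.005, 0.01, 0.05, 0.1, 0.25, 0.5)
  w <- 1 / (maf * (1 - maf))
  utils::write.table(data.frame(maf = maf, weight = w),
                     file.path(out_dir, "sfs_custom.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add("sfs_custom.tsv", list(points = length(maf)))

  for (i in seq_len(n_random)) {
    # random valid two-locus table via margins + feasible p_AB
    pA <- stats::runif(1, 0.05, 0.95)
    pB <- stats::runif(1, 0.05, 0.95)
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    h <- haplotypes_from_margins(pA, pB, stats::runif(1, lo, hi))
    f <- file.path(out_dir, sprintf("random_pair_%02d.tsv", i))
    tab <- haplotype_table(data.frame(A = c("1", "1", "0", "0"),
                                      B = c("1", "0", "1", "0")),
                           freq = as.numeric(h))
    write_haplotype_table(tab, f)
    add(basename(f), list(r2 = r_squared(h)))

    # random confounded population; prevalences kept well spread so the
    # orthogonal projection below is numerically stable
    I <- sample(2:4, 1)
    g <- stats::runif(I); g <- g / sum(g)
    repeat {
      pv <- stats::runif(I, 0.01, 0.3)
      if (sum(g * (pv - sum(g * pv))^2) > 1e-3) break
    }
    s <- structured_population(g, pv, stats::runif(I))
    f <- file.path(out_dir, sprintf("random_pop_%02d.tsv", i))
    write_structured_population(s, f)
    add(basename(f), list(covariance = confounding_covariance(s)))

    # unconfounded population: project q onto the gamma-orthogonal
    # complement of p, then shift into [0, 1]
    # complement of p (affine rescaling preserves zero covariance)
    q0 <- stats::runif(I)
    pbar <- sum(g * s$p)
    beta <- sum(g * q0 * (s$p - pbar)) / sum(g * (s$p - pbar)^2)
    q <- q0 - beta * (s$p - pbar)
    rng <- max(q) - min(q)
    q <- if (rng > 0) 0.1 + 0.8 * (q - min(q)) / rng else rep(0.5, I)
    s2 <- structured_population(g, s$p, q)
    f <- file.path(out_dir, sprintf("random_pop_null_%02d.tsv", i))
    write_structured_population(s2, f)
    add(basename(f), list(covariance = confounding_covariance(s2)))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
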