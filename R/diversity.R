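# Group-wise diversity summaries on the haploid Y: segregating sites,
# Watterson's theta per site, mean pairwise differences, unique haplotype
# counts, and molecular-clock node dating with Poisson uncertainty.

#' Watterson's theta per site
#'
#' theta_W = S / (a * L) with a = sum_{i=1}^{n-1} 1/i, S the number of
#' segregating sites among n sequences over L surveyed base pairs.
#'
#' @param S segregating-site count (>= 0).
#' @param n number of sequences (>= 2).
#' @param L surveyed length in bp (> 0).
#' @return theta per site.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("watterson_theta requires n >= 2 sequences")
  if (L <= 0) stop("L must be positive")
  if (S < 0) stop("S must be non-negative")
  a <- sum(1 / seq_len(n - 1))
  S / (a * L)
}

#' Mean pairwise differences with dispersion
#'
#' For every unordered sample pair, counts differing sites over the
#' pairwise-complete (both non-missing) positions, then returns the mean
#' and the sample standard deviation over pairs. Pairwise-complete
#' comparison is used because target-enriched and whole-genome samples
#' have heterogeneous missingness.
#'
#' @param x a `polarized_matrix`, or a plain 0/1/NA matrix (rows samples).
#' @param dispersion `"sd"` (default, sample standard deviation over
#'   pairs) or `"var"`.
#' @return list: `mean`, `dispersion`, `which_dispersion`, `n_pairs`,
#'   `pairwise` (the per-pair distances).
#' @export
pairwise_differences <- function(x, dispersion = c("sd", "var")) {
  dispersion <- match.arg(dispersion)
  st <- if (inherits(x, "polarized_matrix")) x$states else as.matrix(x)
  n <- nrow(st)
  if (n < 2) stop("pairwise_differences requires >= 2 samples")
  d <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      ok <- !is.na(st[i, ]) & !is.na(st[j, ])
      d[k] <- sum(st[i, ok] != st[j, ok])
    }
  }
  disp <- if (length(d) > 1) {
    if (dispersion == "sd") stats::sd(d) else stats::var(d)
  } else 0
  list(mean = mean(d), dispersion = disp, which_dispersion = dispersion,
       n_pairs = length(d), pairwise = d)
}

segregating_sites <- function(st) {
  n1 <- colSums(st == 1L, na.rm = TRUE)
  n0 <- colSums(st == 0L, na.rm = TRUE)
  sum(n1 > 0 & n0 > 0)
}

#' Group-wise diversity summary table
#'
#' One row per group (plus optional exclusion rows such as a region without
#' a named haplogroup, and a Total row over all samples): sample count,
#' major-haplogroup count, unique haplotypes, segregating sites, mean
#' pairwise differences (+/- SD) and Watterson's theta per site.
#'
#' @param x a `polarized_matrix`.
#' @param groups named character vector: sample -> group; must cover all
#'   samples.
#' @param assignments optional named character vector: sample -> haplogroup
#'   label (used for the mjHG count and for exclusions).
#' @param exclusions optional named list: entry name = excluded haplogroup
#'   label, value = character vector of groups to which the exclusion row
#'   applies (or `"*"` for all groups carrying that label). Each produces
#'   an extra `"<group> wo <label>"` row.
#' @param L surveyed length in bp used for theta (default 5,063,000, the
#'   single-copy Y target size).
#' @param total add a Total row (default TRUE).
#' @return data.frame of class `diversity_summary`.
#' @export
region_summary <- function(x, groups, assignments = NULL,
                           exclusions = list(), L = 5063000, total = TRUE) {
  stopifnot(inherits(x, "polarized_matrix"))
  uncovered <- setdiff(x$samples, names(groups))
  if (length(uncovered))
    stop("groups must cover all samples; missing: ",
         paste(uncovered, collapse = ", "))
  one <- function(label, samples) {
    n <- length(samples)
    sub <- subset_matrix(x, samples = samples)
    S <- segregating_sites(sub$states)
    hts <- haplotype_strings(sub)$n_distinct
    mj <- if (!is.null(assignments))
      length(unique(assignments[samples])) else NA_integer_
    if (n >= 2) {
      pw <- pairwise_differences(sub)
      theta <- watterson_theta(S, n, L)
      data.frame(group = label, n = n, mjHGs = mj, unique_HTs = hts,
                 S = S, pi_mean = pw$mean, pi_sd = pw$dispersion,
                 theta_W = theta, L = L, stringsAsFactors = FALSE)
    } else {
      data.frame(group = label, n = n, mjHGs = mj, unique_HTs = hts,
                 S = S, pi_mean = NA_real_, pi_sd = NA_real_,
                 theta_W = NA_real_, L = L, stringsAsFactors = FALSE)
    }
  }
  glev <- unique(groups[x$samples])
  rows <- lapply(glev, function(g) one(g, x$samples[groups[x$samples] == g]))
  for (lab in names(exclusions)) {
    if (is.null(assignments))
      stop("exclusions require assignments")
    if (!lab %in% assignments)
      stop("exclusion haplogroup absent from assignments: ", lab)
    gsel <- exclusions[[lab]]
    if (identical(gsel, "*"))
      gsel <- unique(groups[names(assignments)[assignments == lab]])
    for (g in gsel) {
      smp <- x$samples[groups[x$samples] == g]
      smp <- smp[assignments[smp] != lab]
      rows <- c(rows, list(one(paste0(g, " wo ", lab), smp)))
    }
  }
  if (total) rows <- c(rows, list(one("Total", x$samples)))
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_summary", class(out))
  out
}

#' Molecular-clock configuration
#'
#' @param mu mutation rate per site per year (default 1.69e-9, the
#'   published horse MSY clock).
#' @param L surveyed length in bp (default 5,063,000).
#' @return list of class `clock_config`.
#' @export
clock_config <- function(mu = 1.69e-9, L = 5063000) {
  if (mu <= 0 || L <= 0) stop("mu and L must be positive")
  structure(list(mu = mu, L = L), class = "clock_config")
}

#' Date a node from its mutation count
#'
#' Age = k / (mu * L) years for k mutations accumulated on the lineage; the
#' 95% interval comes from the exact Poisson confidence interval on k,
#' divided by mu * L.
#'
#' @param mutation_count non-negative integer k.
#' @param clock a [clock_config()].
#' @return list: `age_years`, `ci_lower`, `ci_upper` (95%).
#' @export
node_age <- function(mutation_count, clock = clock_config()) {
  if (mutation_count < 0) stop("mutation_count must be >= 0")
  rate <- clock$mu * clock$L
  ci <- stats::poisson.test(mutation_count)$conf.int
  list(age_years = mutation_count / rate,
       ci_lower = ci[1] / rate,
       ci_upper = ci[2] / rate)
}

#' Write the diversity summary TSV
#'
#' @param summary a `diversity_summary` from [region_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
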