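#' Allele frequencies at one locus
#'
#' Counting estimator: each typed sample contributes two allele
#' observations, so the frequency of allele a is (count of a) / (2 x
#' typed samples). Unobserved alleles are absent from the result.
#'
#' @param genotypes Genotype table (`sample,locus,allele1,allele2`).
#' @param locus_name Locus to tabulate.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
allele_frequencies <- function(genotypes, locus_name) {
  genotypes <- check_genotype_table(genotypes)
  g <- genotypes[genotypes$locus == locus_name, , drop = FALSE]
  if (nrow(g) == 0L) stop("locus not present in genotype table: ", locus_name)
  tab <- table(c(g$allele1, g$allele2))
  f <- as.numeric(tab) / (2 * nrow(g))
  stats::setNames(f, names(tab))
}

#' Effective number of alleles (Ae)
#'
#' `Ae = 1 / sum(p_i^2)`: the number of equally frequent alleles that
#' would give the same expected homozygosity. Lies in `[1, A]` for a
#' locus with A alleles, with equality at A iff frequencies are uniform.
#'
#' @param freqs Named numeric vector of allele frequencies. Frequencies
#'   are renormalized to sum to 1 (printed tables are rounded).
#' @return Ae, a scalar >= 1.
#' @export
effective_alleles <- function(freqs) {
  freqs <- check_freqs(freqs)
  1 / sum(freqs^2)
}

#' Expected heterozygosity under Hardy-Weinberg proportions
#'
#' @inheritParams effective_alleles
#' @return `1 - sum(p_i^2)`.
#' @export
expected_heterozygosity <- function(freqs) {
  freqs <- check_freqs(freqs)
  1 - sum(freqs^2)
}

#' Observed heterozygosity (Ho)
#'
#' Fraction of typed samples whose two alleles differ.
#'
#' @inheritParams allele_frequencies
#' @return Ho in `[0, 1]`.
#' @export
observed_heterozygosity <- function(genotypes, locus_name) {
  genotypes <- check_genotype_table(genotypes)
  g <- genotypes[genotypes$locus == locus_name, , drop = FALSE]
  if (nrow(g) == 0L) stop("locus not present in genotype table: ", locus_name)
  mean(g$allele1 != g$allele2)
}

#' Power of discrimination (PD)
#'
#' `PD = 1 - sum(g_j^2)` over genotype frequencies: the probability that
#' two random individuals differ in genotype. In `"observed"` mode the
#' genotype frequencies are tabulated from a genotype table; in
#' `"hwe_expected"` mode they are derived from allele frequencies under
#' Hardy-Weinberg proportions (p_i^2 and 2 p_i p_j), for which the
#' closed form `1 - 2 (sum p^2)^2 + sum p^4` is used.
#'
#' @param x A genotype table (observed mode) or a named frequency vector
#'   (hwe_expected mode).
#' @param locus_name Locus name (observed mode only).
#' @param mode `"observed"` or `"hwe_expected"`.
#' @return PD in `[0, 1)`.
#' @export
power_of_discrimination <- function(x, locus_name = NULL,
                                    mode = c("observed", "hwe_expected")) {
  mode <- match.arg(mode)
  if (mode == "observed") {
    if (!is.data.frame(x))
      stop("observed mode requires a genotype table")
    x <- check_genotype_table(x)
    g <- x[x$locus == locus_name, , drop = FALSE]
    if (nrow(g) == 0L) stop("locus not present in genotype table: ", locus_name)
    gf <- as.numeric(table(paste(g$allele1, g$allele2, sep = "/"))) / nrow(g)
    1 - sum(gf^2)
  } else {
    p <- check_freqs(x)
    s2 <- sum(p^2)
    # 1 - sum_j g_j^2 with g = {p_i^2} u {2 p_i p_j, i<j}
    1 - (2 * s2^2 - sum(p^4))
  }
}

#' Probability of exclusion (PE) from observed heterozygosity
#'
#' Trio exclusion power by the heterozygosity-based formula used in the
#' Powerstats worksheet: with `h` the observed heterozygosity and
#' `H = 1 - h`, `PE = h^2 * (1 - 2 * h * H^2)`. Monotone increasing on
#' `[0, 1]` with PE(0) = 0 and PE(1) = 1.
#'
#' @param ho Observed heterozygosity, in `[0, 1]` (vectorized).
#' @return PE in `[0, 1]`.
#' @examples
#' power_of_exclusion(c(0.79, 0.58))  # ~0.58, ~0.27
#' @export
power_of_exclusion <- function(ho) {
  if (!is.numeric(ho) || any(ho < 0 | ho > 1))
    stop("ho must be in [0, 1]")
  ho^2 * (1 - 2 * ho * (1 - ho)^2)
}

#' Combine per-locus powers across a panel
#'
#' `combined = 1 - prod(1 - v_i)`, with the complement `prod(1 - v_i)`
#' accumulated in log space so that magnitudes like 1e-26 survive;
#' panel-wide powers are conventionally reported as `1 - complement`.
#'
#' @param values Numeric vector of per-locus powers, each in `[0, 1)`.
#' @return List with `combined` and `complement`
#'   (`combined == 1 - complement`).
#' @export
combined_power <- function(values) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("values must be a non-empty numeric vector")
  if (any(values < 0 | values >= 1))
    stop("per-locus powers must lie in [0, 1)")
  complement <- exp(sum(log1p(-values)))
  list(combined = 1 - complement, complement = complement)
}

#' Per-locus forensic parameter report
#'
#' One row per locus with allele count, Ae, Ho, PD and PE, plus the
#' combined powers CPD and CPE as attributes (`cpd`, `cpe`, each a
#' `combined_power()` list). PD uses observed-genotype mode when a
#' genotype table is supplied and Hardy-Weinberg-expected mode when only
#' frequencies are available; PE comes from Ho (observed) or from
#' expected heterozygosity (frequency-only mode), and the mode used is
#' recorded in the `mode` column.
#'
#' @param x A genotype table or a frequency set (named list of named
#'   frequency vectors, see [read_frequency_table()]).
#' @return Data frame, one row per locus.
#' @export
forensics_report <- function(x) {
  if (is.data.frame(x)) {
    x <- check_genotype_table(x)
    loci <- unique(x$locus)
    rows <- lapply(loci, function(l) {
      f <- allele_frequencies(x, l)
      ho <- observed_heterozygosity(x, l)
      data.frame(locus = l, n_alleles = length(f),
                 ae = effective_alleles(f), ho = ho,
                 pd = power_of_discrimination(x, l, mode = "observed"),
                 pe = power_of_exclusion(ho), mode = "observed")
    })
  } else {
    stopifnot(is.list(x))
    rows <- lapply(names(x), function(l) {
      f <- check_freqs(x[[l]])
      he <- expected_heterozygosity(f)
      data.frame(locus = l, n_alleles = length(f),
                 ae = effective_alleles(f), ho = he,
                 pd = power_of_discrimination(f, mode = "hwe_expected"),
                 pe = power_of_exclusion(he), mode = "hwe_expected")
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cpd") <- combined_power(out$pd)
  attr(out, "cpe") <- combined_power(out$pe)
  out
}

# Internal: validate a named allele-frequency vector and renormalize it.
check_freqs <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) == 0L)
    stop("frequency set must be a non-empty numeric vector")
  if (is.null(names(freqs)) || any(!nzchar(names(freqs))))
    stop("frequencies must be named by allele")
  if (any(freqs <= 0) || any(freqs > 1))
    stop("frequencies must lie in (0, 1]")
  freqs / sum(freqs)
}
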