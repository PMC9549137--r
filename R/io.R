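#' Read an allele-frequency table
#'
#' The file is comma-separated with header
#' `locus,allele,frequency[,population]`. Printed frequency tables are
#' rounded (typically 2 dp) and rarely sum to exactly 1 per locus, so
#' each locus is renormalized by its column sum; any adjustment larger
#' than `1e-9` is reported via `message()`. The renormalized values are
#' the ones used everywhere downstream (forensic parameters, simulation
#' and likelihood ratios share one frequency object).
#'
#' @param path File path.
#' @param population If the file carries a `population` column, which
#'   population to load; default the first one present.
#' @param quiet Suppress renormalization messages.
#' @return A named list of named numeric frequency vectors (one per
#'   locus), class `mh_freqs`, with attributes `population` and
#'   `renorm` (per-locus raw column sums).
#' @export
read_frequency_table <- function(path, population = NULL, quiet = FALSE) {
  df <- utils::read.csv(path, colClasses = c(frequency = "numeric"))
  need <- c("locus", "allele", "frequency")
  if (!all(need %in% names(df)))
    stop("frequency file must have columns: ", paste(need, collapse = ","))
  if (nrow(df) == 0L) stop("empty frequency table: ", path)
  if ("population" %in% names(df)) {
    if (is.null(population)) population <- df$population[1L]
    df <- df[df$population == population, , drop = FALSE]
    if (nrow(df) == 0L) stop("population not present: ", population)
  } else if (is.null(population)) population <- "default"
  as_freq_set(df, population = population, quiet = quiet)
}

#' Build a frequency set from a long data frame
#'
#' @param df Data frame with columns `locus`, `allele`, `frequency`.
#' @inheritParams read_frequency_table
#' @export
as_freq_set <- function(df, population = "default", quiet = FALSE) {
  if (anyDuplicated(df[c("locus", "allele")]))
    stop("duplicate (locus, allele) rows in frequency table")
  if (any(df$frequency <= 0 | df$frequency > 1))
    stop("frequencies must lie in (0, 1]")
  if (any(!nzchar(df$allele))) stop("empty allele labels")
  loci <- unique(df$locus)
  renorm <- numeric(0)
  fs <- lapply(loci, function(l) {
    d <- df[df$locus == l, , drop = FALSE]
    f <- stats::setNames(d$frequency, d$allele)
    renorm[[l]] <<- sum(f)
    f / sum(f)
  })
  names(fs) <- loci
  off <- abs(renorm - 1) > 1e-9
  if (any(off) && !quiet)
    message(sprintf(
      "renormalized %d/%d loci (raw sums %.2f-%.2f) for population '%s'",
      sum(off), length(loci), min(renorm), max(renorm), population))
  structure(fs, class = "mh_freqs", population = population, renorm = renorm)
}

#' @export
print.mh_freqs <- function(x, ...) {
  cat(sprintf("<mh_freqs> %d loci, %d alleles, population '%s'\n",
              length(x), sum(lengths(x)), attr(x, "population")))
  invisible(x)
}

#' Packaged fixtures: the 36-locus panel and the 29-locus frequency table
#'
#' `mh36_panel()` returns the 36-locus panel definition (names, GRCh37
#' SNP coordinates, rsIDs, extents). `mh29_frequencies()` returns the
#' allele-frequency table of the 29 loci that passed equilibrium testing,
#' estimated from 96 unrelated Shandong Han individuals (renormalized
#' from the printed 2-dp values). `mh29_forensics()` returns the
#' published per-locus forensic parameters (PD, PE, Ho, Ae) for the same
#' 29 loci, as printed.
#'
#' @return See above; `mh29_frequencies()` is an `mh_freqs` object, the
#'   others are an `mh_panel` and a data frame.
#' @export
mh36_panel <- function() {
  read_panel(system.file("extdata", "mh36_panel.csv", package = "microkin",
                         mustWork = TRUE), label = "mh36")
}

#' @rdname mh36_panel
#' @inheritParams read_frequency_table
#' @export
mh29_frequencies <- function(quiet = TRUE) {
  read_frequency_table(
    system.file("extdata", "mh29_frequencies.csv", package = "microkin",
                mustWork = TRUE), quiet = quiet)
}

#' @rdname mh36_panel
#' @export
mh29_forensics <- function() {
  utils::read.csv(system.file("extdata", "mh29_forensics.csv",
                              package = "microkin", mustWork = TRUE))
}

#' Effective-allele matrix across populations
#'
#' Computes Ae per (locus, population) cell from a long frequency table
#' with a `population` column, together with per-population combined
#' powers (CPD/CPE complements) under Hardy-Weinberg-expected genotype
#' frequencies. Missing (locus, population) combinations are `NA`, never
#' imputed.
#'
#' @param df Long data frame `locus,allele,frequency,population`.
#' @param loci Optional character vector restricting/ordering the rows.
#' @return Matrix of Ae values (loci x populations) with attribute
#'   `combined`: a data frame of per-population CPD/CPE complements.
#' @export
population_ae_matrix <- function(df, loci = NULL) {
  stopifnot(all(c("locus", "allele", "frequency", "population") %in% names(df)))
  pops <- unique(df$population)
  if (is.null(loci)) loci <- unique(df$locus)
  m <- matrix(NA_real_, length(loci), length(pops),
              dimnames = list(loci, pops))
  comb <- data.frame(population = pops, cpd_complement = NA_real_,
                     cpe_complement = NA_real_)
  for (j in seq_along(pops)) {
    fs <- as_freq_set(df[df$population == pops[j], , drop = FALSE],
                      population = pops[j], quiet = TRUE)
    common <- intersect(loci, names(fs))
    m[common, j] <- vapply(fs[common], effective_alleles, 0)
    pd <- vapply(fs[common], function(f)
      power_of_discrimination(f, mode = "hwe_expected"), 0)
    pe <- vapply(fs[common], function(f)
      power_of_exclusion(expected_heterozygosity(f)), 0)
    comb$cpd_complement[j] <- combined_power(pd)$complement
    comb$cpe_complement[j] <- combined_power(pe)$complement
  }
  attr(m, "combined") <- comb
  m
}
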