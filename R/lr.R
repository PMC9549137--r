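# Kinship likelihood ratios.
#
# All indices compare the probability of an unordered genotype pair
# under two hypotheses. Sibling-class indices use the IBD-coefficient
# mixture P(g2 | g1, k) = k0 P(g2) + k1 P(g2 | one allele IBD) +
# k2 [g2 == g1]; the paternity index uses mutation-adjusted transmission
# T(a -> b) = 1 - mu if a == b, else mu * m(a, b), so an isolated
# Mendelian mismatch yields a small finite LR instead of an exclusion
# when mu > 0. Mutation enters only the parent-child numerator: at
# microhaplotype rates (1e-8) its effect on sibling likelihoods is below
# floating-point visibility and k-coefficient likelihoods have no
# natural single-meiosis factorization.

# index -> IBD triples of the Hp and Hd hypotheses
lr_hypotheses <- function(index_name) {
  switch(index_name,
         PI   = list(hp = "parent_child", hd = "unrelated"),
         FSI  = list(hp = "full_sibling", hd = "unrelated"),
         HSI  = list(hp = "half_sibling", hd = "unrelated"),
         FCI  = list(hp = "first_cousin", hd = "unrelated"),
         FHSI = list(hp = "full_sibling", hd = "half_sibling"),
         stop("unknown index: ", index_name,
              " (expected PI, FSI, HSI, FCI or FHSI)"))
}

#' Conditional genotype probability given IBD coefficients
#'
#' `P(g2 | g1, k) = k0 P(g2) + k1 P(g2 | one allele IBD with g1) + k2
#' [g2 == g1]`, where the one-IBD term transmits one of g1's alleles
#' (probability 1/2 each) and completes g2 with a population allele.
#' Sums to 1 over all g2. Heterozygote population probabilities are `2
#' p q`; genotype equality is set equality.
#'
#' @param g2,g1 Character vectors of length 2 (unordered genotypes).
#' @param k Numeric IBD triple (k0, k1, k2) summing to 1, e.g. from
#'   [relationship_model()].
#' @param freqs Named numeric vector of allele frequencies; every allele
#'   of g1 and g2 must be present (no silent flooring).
#' @return Probability.
#' @export
conditional_genotype_prob <- function(g2, g1, k, freqs) {
  stopifnot(length(g2) == 2L, length(g1) == 2L, length(k) == 3L,
            abs(sum(k) - 1) < 1e-9)
  freqs <- check_freqs(freqs)
  if (!all(c(g1, g2) %in% names(freqs)))
    stop("allele absent from frequency set: ",
         paste(setdiff(c(g1, g2), names(freqs)), collapse = ", "))
  x <- g2[1L]; y <- g2[2L]
  pg2 <- if (x == y) freqs[[x]]^2 else 2 * freqs[[x]] * freqs[[y]]
  one_ibd <- mean(vapply(g1, function(t) {
    if (x == y) (t == x) * freqs[[x]]
    else (t == x) * freqs[[y]] + (t == y) * freqs[[x]]
  }, 0))
  ident <- as.numeric(setequal(g1, g2) &&
                        (sum(g1 == g1[1L]) == sum(g2 == g2[1L])))
  unname(k[1L] * pg2 + k[2L] * one_ibd + k[3L] * ident)
}

#' Single-locus log10 likelihood ratio
#'
#' PI, FSI, HSI and FCI compare the stated relationship against
#' unrelated; FHSI compares full-sibling against half-sibling. For PI
#' the numerator uses mutation-adjusted transmission (member 1 is taken
#' as the parent; with the symmetric equal-probability model the
#' direction is immaterial). A Mendelian exclusion with `mu = 0` gives
#' `-Inf`, which is retained (it supports Hd at any threshold).
#'
#' @param pair List with elements `g1` and `g2`, each a length-2
#'   character genotype, or a `genotype_pair` from [simulate_pair()]
#'   restricted to one locus via `locus`.
#' @param index_name One of `"PI"`, `"FSI"`, `"HSI"`, `"FCI"`,
#'   `"FHSI"`.
#' @param freqs Named numeric vector of allele frequencies at the locus.
#' @param mutation A [mutation_model()] (used by PI only).
#' @return log10 LR (possibly `-Inf`).
#' @export
lr_index <- function(pair, index_name, freqs,
                     mutation = mutation_model("none")) {
  hyp <- lr_hypotheses(index_name)
  freqs <- check_freqs(freqs)
  g1 <- pair$g1; g2 <- pair$g2
  stopifnot(length(g1) == 2L, length(g2) == 2L)
  num <- pair_prob(g1, g2, hyp$hp, freqs, mutation)
  den <- pair_prob(g1, g2, hyp$hd, freqs, mutation)
  log10(num) - log10(den)
}

# P(unordered pair (g1, g2) | relationship) = P(g1) P(g2 | g1, rel)
pair_prob <- function(g1, g2, label, freqs, mutation) {
  pg1 <- if (g1[1L] == g1[2L]) freqs[[g1[1L]]]^2
         else 2 * freqs[[g1[1L]]] * freqs[[g1[2L]]]
  cond <- if (label == "parent_child" && mutation$rate > 0) {
    tm <- transition_matrix(sort(names(freqs)), mutation)
    pc_conditional(g2, g1, freqs, tm)
  } else {
    conditional_genotype_prob(g2, g1, relationship_model(label)$k, freqs)
  }
  pg1 * cond
}

# P(child g2 | parent g1) with transmission matrix tm (alleles x alleles)
pc_conditional <- function(g2, g1, freqs, tm) {
  x <- g2[1L]; y <- g2[2L]
  mean(vapply(g1, function(t) {
    if (x == y) tm[t, x] * freqs[[x]]
    else tm[t, x] * freqs[[y]] + tm[t, y] * freqs[[x]]
  }, 0))
}

#' Mutation-adjusted allele transmission matrix
#'
#' `T[a, b] = P(transmitted allele b | parental allele a)`: `1 - mu` on
#' the diagonal and `mu * m(a, b)` off it, where `m` is the mutation
#' model's target law (uniform over the other alleles for
#' `equal_probability`; reflected-geometric steps on the repeat ladder
#' for `extended_stepwise`). Rows sum to 1.
#'
#' @param alleles Character vector of the locus' alleles.
#' @param mutation A [mutation_model()].
#' @return Square matrix with `alleles` dimnames.
#' @export
transition_matrix <- function(alleles, mutation) {
  A <- length(alleles)
  tm <- diag(A)
  dimnames(tm) <- list(alleles, alleles)
  mu <- mutation$rate
  if (mu == 0 || mutation$kind == "none") return(tm)
  if (A < 2L)
    stop("mutation with a single-allele universe has no target allele")
  if (mutation$kind == "equal_probability") {
    tm[] <- mu / (A - 1)
    diag(tm) <- 1 - mu
  } else {
    reps <- suppressWarnings(as.numeric(alleles))
    if (anyNA(reps))
      stop("stepwise mutation requires alleles that parse as repeat numbers")
    ord <- order(reps)
    # fold the two-sided geometric step law off the ladder boundaries;
    # truncate once the tail is negligible
    pgeom_s <- function(s) mutation$step_geometric_p *
      (1 - mutation$step_geometric_p)^(s - 1)
    smax <- ceiling(log(1e-15) / log1p(-mutation$step_geometric_p)) + 1L
    step_tm <- matrix(0, A, A)
    for (i in seq_len(A)) {
      for (s in seq_len(smax)) {
        for (d in c(-1L, 1L)) {
          j <- reflect_index(i + d * s, A)
          step_tm[i, j] <- step_tm[i, j] + 0.5 * pgeom_s(s)
        }
      }
    }
    step_tm <- step_tm / rowSums(step_tm)   # renormalize the truncation
    # step_tm is indexed by ladder rank; map back to allele order
    tm_all <- matrix(0, A, A)
    tm_all[ord, ord] <- step_tm
    tm <- (1 - mu) * diag(A) + mu * tm_all
    dimnames(tm) <- list(alleles, alleles)
  }
  tm
}

#' Panel log10 likelihood ratio for a genotype pair
#'
#' Sum of per-locus log10 LRs under the linkage-equilibrium assumption;
#' `-Inf` at any locus propagates.
#'
#' @param pair A `genotype_pair` (see [simulate_pair()]) or a list with
#'   `genotypes_a` and `genotypes_b` named by locus.
#' @param index_name Index name (see [lr_index()]).
#' @param panel_freqs Frequency set covering every locus of the pair.
#' @param mutation A [mutation_model()].
#' @return log10 LR for the whole panel.
#' @export
panel_log10_lr <- function(pair, index_name, panel_freqs,
                           mutation = mutation_model("none")) {
  loci <- names(pair$genotypes_a)
  if (!setequal(loci, names(pair$genotypes_b)))
    stop("pair members typed at different loci")
  missing <- setdiff(loci, names(panel_freqs))
  if (length(missing) > 0L)
    stop("no frequencies for loci: ", paste(missing, collapse = ", "))
  sum(vapply(loci, function(l)
    lr_index(list(g1 = pair$genotypes_a[[l]], g2 = pair$genotypes_b[[l]]),
             index_name, panel_freqs[[l]], mutation), 0))
}

#' Panel log10 LRs for a simulated cohort
#'
#' Vectorized evaluation over an `mh_pairs` cohort: per locus, a lookup
#' table of log10 LRs over all ordered genotype pairs is built once and
#' applied to the whole cohort.
#'
#' @param pairs An `mh_pairs` cohort from [simulate_study()].
#' @inheritParams panel_log10_lr
#' @return Numeric vector of length `n_pairs` (entries may be `-Inf`).
#' @export
study_log10_lr <- function(pairs, index_name, panel_freqs,
                           mutation = mutation_model("none")) {
  stopifnot(inherits(pairs, "mh_pairs"))
  missing <- setdiff(names(pairs$loci), names(panel_freqs))
  if (length(missing) > 0L)
    stop("no frequencies for loci: ", paste(missing, collapse = ", "))
  total <- numeric(pairs$n_pairs)
  for (l in names(pairs$loci)) {
    s <- pairs$loci[[l]]
    lut <- lr_lookup(check_freqs(panel_freqs[[l]]), s$alleles, index_name,
                     mutation)
    A <- length(s$alleles)
    gi <- lut$gidx[cbind(s$m[, 1], s$m[, 2])]
    gj <- lut$gidx[cbind(s$m[, 3], s$m[, 4])]
    total <- total + lut$log10lr[cbind(gi, gj)]
  }
  total
}

# Build the G x G log10 LR lookup for one locus. Genotypes are the
# unordered pairs (i <= j) of the lexicographically sorted alleles.
lr_lookup <- function(freqs, alleles, index_name, mutation) {
  stopifnot(setequal(names(freqs), alleles))
  p <- freqs[alleles]
  A <- length(p)
  comb <- which(upper.tri(matrix(0, A, A), diag = TRUE), arr.ind = TRUE)
  comb <- comb[order(comb[, 1], comb[, 2]), , drop = FALSE]
  G <- nrow(comb)
  gidx <- matrix(NA_integer_, A, A)
  gidx[comb] <- seq_len(G)
  gidx[comb[, c(2, 1)]] <- seq_len(G)
  pg <- ifelse(comb[, 1] == comb[, 2], p[comb[, 1]]^2,
               2 * p[comb[, 1]] * p[comb[, 2]])
  # F[t, g] = P(g | transmitted allele t, mate allele from population)
  Fmat <- function(tm) {
    f <- matrix(0, A, G)
    for (g in seq_len(G)) {
      x <- comb[g, 1]; y <- comb[g, 2]
      f[, g] <- if (x == y) tm[, x] * p[x] else tm[, x] * p[y] + tm[, y] * p[x]
    }
    f
  }
  cond_from <- function(f)  # P(g2 | g1, one transmission) over G x G
    0.5 * (f[comb[, 1], , drop = FALSE] + f[comb[, 2], , drop = FALSE])
  ident <- diag(G)
  cond_for <- function(label) {
    if (label == "parent_child" && mutation$rate > 0)
      return(cond_from(Fmat(transition_matrix(alleles, mutation))))
    k <- relationship_model(label)$k
    k[1] * matrix(pg, G, G, byrow = TRUE) + k[2] * cond_from(Fmat(diag(A))) +
      k[3] * ident
  }
  hyp <- lr_hypotheses(index_name)
  num <- cond_for(hyp$hp)
  den <- cond_for(hyp$hd)
  list(gidx = gidx, log10lr = log10(num) - log10(den))
}
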