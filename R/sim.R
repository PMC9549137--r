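# Mendelian pair simulator.
#
# Pairs are generated pedigree-faithfully: founders are drawn under
# Hardy-Weinberg proportions from the supplied allele frequencies and
# every simulated transmission (meiosis) carries an independent mutation
# event, rather than perturbing finished genotypes. Loci are simulated
# independently (linkage equilibrium).

#' IBD-sharing relationship models
#'
#' Returns the IBD-sharing coefficients (k0, k1, k2) — the probabilities
#' that the pair shares 0, 1 or 2 alleles identical by descent at a
#' locus — for the five supported relationships: unrelated (1,0,0),
#' parent-child (0,1,0), full-sibling (1/4,1/2,1/4), half-sibling
#' (1/2,1/2,0), first-cousin (3/4,1/4,0).
#'
#' @param label One of `"unrelated"`, `"parent_child"`,
#'   `"full_sibling"`, `"half_sibling"`, `"first_cousin"`.
#' @return List with `label` and numeric `k` (length 3, sums to 1).
#' @export
relationship_model <- function(label = c("unrelated", "parent_child",
                                         "full_sibling", "half_sibling",
                                         "first_cousin")) {
  label <- match.arg(label)
  k <- switch(label,
              unrelated    = c(1, 0, 0),
              parent_child = c(0, 1, 0),
              full_sibling = c(0.25, 0.5, 0.25),
              half_sibling = c(0.5, 0.5, 0),
              first_cousin = c(0.75, 0.25, 0))
  list(label = label, k = stats::setNames(k, c("k0", "k1", "k2")))
}

#' Per-meiosis mutation models
#'
#' `"equal_probability"` (microhaplotypes): with probability `rate` the
#' transmitted allele becomes any *other* allele of the locus, each with
#' probability `rate / (A - 1)`. `"extended_stepwise"` (STRs): with
#' probability `rate` the repeat number moves by `s >= 1` steps, `s`
#' geometric with parameter `step_geometric_p` (so `step_geometric_p =
#' 1` is the pure single-step model), direction up/down equally likely,
#' reflected off the ends of the observed allele ladder. `"none"` is a
#' zero-rate model.
#'
#' @param kind Model kind.
#' @param rate Per-meiosis, per-locus mutation probability. Defaults:
#'   1e-8 for `equal_probability`, 1e-3 for `extended_stepwise`, 0 for
#'   `none`.
#' @param step_geometric_p Geometric step-size parameter in (0, 1].
#' @return List of class `mutation_model`.
#' @export
mutation_model <- function(kind = c("equal_probability",
                                    "extended_stepwise", "none"),
                           rate = NULL, step_geometric_p = 0.9) {
  kind <- match.arg(kind)
  if (is.null(rate))
    rate <- switch(kind, equal_probability = 1e-8,
                   extended_stepwise = 1e-3, none = 0)
  if (rate < 0 || rate >= 1) stop("mutation rate must lie in [0, 1)")
  if (kind == "none" && rate != 0) stop("kind 'none' requires rate 0")
  if (rate == 0) kind <- "none"
  if (step_geometric_p <= 0 || step_geometric_p > 1)
    stop("step_geometric_p must lie in (0, 1]")
  structure(list(kind = kind, rate = rate,
                 step_geometric_p = step_geometric_p),
            class = "mutation_model")
}

#' Draw unrelated individuals under Hardy-Weinberg proportions
#'
#' @param freqs Named numeric vector of allele frequencies at one locus.
#' @param n Number of individuals.
#' @return n x 2 character matrix of allele pairs, each row in
#'   lexicographic order.
#' @export
simulate_individual <- function(freqs, n = 1L) {
  freqs <- check_freqs(freqs)
  a <- sort(names(freqs))
  p <- freqs[a]
  i1 <- sample.int(length(p), n, replace = TRUE, prob = p)
  i2 <- sample.int(length(p), n, replace = TRUE, prob = p)
  cbind(a[pmin(i1, i2)], a[pmax(i1, i2)])
}

#' Transmit one parental allele through a meiosis
#'
#' Picks one of the two parental alleles uniformly and applies the
#' mutation model: with probability `mutation$rate` the allele is
#' replaced per the model's law (see [mutation_model()]).
#'
#' @param parent_genotype Character vector of length 2.
#' @param mutation A [mutation_model()].
#' @param allele_universe Character vector of all alleles at the locus
#'   (the mutation target space; for the stepwise model these must parse
#'   as repeat numbers).
#' @param n Number of independent transmissions to draw.
#' @return Character vector of n transmitted alleles.
#' @export
transmit_allele <- function(parent_genotype, mutation, allele_universe,
                            n = 1L) {
  stopifnot(length(parent_genotype) == 2L,
            inherits(mutation, "mutation_model"))
  universe <- sort(allele_universe)
  idx <- match(parent_genotype, universe)
  if (anyNA(idx)) stop("parental allele absent from allele universe")
  pick <- ifelse(stats::runif(n) < 0.5, idx[1L], idx[2L])
  universe[mutate_indices(pick, length(universe), mutation, universe)]
}

# vectorized mutation on integer allele indices (indices refer to the
# lexicographically sorted universe; the stepwise ladder is sorted by
# numeric repeat count)
mutate_indices <- function(v, n_alleles, mutation, universe = NULL) {
  if (mutation$kind == "none" || mutation$rate == 0) return(v)
  hit <- which(stats::runif(length(v)) < mutation$rate)
  if (length(hit) == 0L) return(v)
  if (n_alleles < 2L)
    stop("mutation with a single-allele universe has no target allele")
  if (mutation$kind == "equal_probability") {
    off <- sample.int(n_alleles - 1L, length(hit), replace = TRUE)
    v[hit] <- ((v[hit] - 1L + off) %% n_alleles) + 1L
  } else {  # extended_stepwise on the repeat-number ladder
    reps <- suppressWarnings(as.numeric(universe))
    if (anyNA(reps))
      stop("stepwise mutation requires alleles that parse as repeat numbers")
    ladder <- order(reps)                    # ladder position -> allele index
    rank_of <- match(seq_len(n_alleles), ladder)
    s <- stats::rgeom(length(hit), prob = mutation$step_geometric_p) + 1L
    dir <- ifelse(stats::runif(length(hit)) < 0.5, -1L, 1L)
    pos <- rank_of[v[hit]] + dir * s
    pos <- reflect_index(pos, n_alleles)
    v[hit] <- ladder[pos]
  }
  v
}

# reflect positions off the boundaries of 1..n (repeat as needed for
# multi-bounce steps)
reflect_index <- function(pos, n) {
  if (n == 1L) return(rep(1L, length(pos)))
  repeat {
    below <- pos < 1L
    above <- pos > n
    if (!any(below) && !any(above)) return(pos)
    pos[below] <- 2L - pos[below]
    pos[above] <- 2L * n - pos[above]
  }
}

#' Simulate one genotype pair under a relationship hypothesis
#'
#' Uses the current RNG state; see [simulate_study()] for seeded
#' cohorts. The pedigree structures are: parent-child — one founder
#' parent, the child receives one transmitted (possibly mutated)
#' parental allele plus one population allele; full siblings — two
#' founder parents, each child receives one transmitted allele from
#' each; half siblings — one shared founder parent plus an independent
#' population allele per child; first cousins — full-sibling parents
#' (children of two shared founder grandparents) married to independent
#' founders; unrelated — independent founder draws.
#'
#' @param relationship A [relationship_model()] or its label.
#' @param panel_freqs An `mh_freqs` frequency set (or named list of
#'   named frequency vectors), one entry per locus.
#' @param mutation A [mutation_model()].
#' @return List of class `genotype_pair` with `genotypes_a`,
#'   `genotypes_b` (named lists of length-2 character vectors) and
#'   `relationship`.
#' @export
simulate_pair <- function(relationship, panel_freqs,
                          mutation = mutation_model("none")) {
  if (is.character(relationship))
    relationship <- relationship_model(relationship)
  sim <- lapply(panel_freqs, function(f)
    sim_pairs_locus(check_freqs(f), 1L, relationship$label, mutation))
  a <- lapply(sim, function(s) s$alleles[s$m[1L, 1:2]])
  b <- lapply(sim, function(s) s$alleles[s$m[1L, 3:4]])
  structure(list(genotypes_a = a, genotypes_b = b,
                 relationship = relationship$label),
            class = "genotype_pair")
}

#' Simulate a cohort of genotype pairs
#'
#' Vectorized, seeded simulation of `n_pairs` pairs under one
#' relationship across all panel loci (independent loci).
#'
#' @inheritParams simulate_pair
#' @param n_pairs Number of pairs.
#' @param seed Integer seed; cohorts are reproducible given the seed.
#' @return Object of class `mh_pairs`: per-locus allele labels and an
#'   `n_pairs` x 4 integer matrix (member 1 alleles, member 2 alleles,
#'   each genotype in canonical order). Convert with
#'   `as.data.frame()` for the long `replicate,locus,...` layout.
#' @export
simulate_study <- function(relationship, panel_freqs,
                           mutation = mutation_model("none"),
                           n_pairs = 1e5, seed = 1L) {
  if (is.character(relationship))
    relationship <- relationship_model(relationship)
  stopifnot(n_pairs >= 1)
  set.seed(as.integer(seed))
  loci <- lapply(panel_freqs, function(f)
    sim_pairs_locus(check_freqs(f), as.integer(n_pairs),
                    relationship$label, mutation))
  structure(list(loci = loci, relationship = relationship$label,
                 n_pairs = as.integer(n_pairs), mutation = mutation,
                 seed = as.integer(seed)),
            class = "mh_pairs")
}

#' @export
print.mh_pairs <- function(x, ...) {
  cat(sprintf("<mh_pairs> %d %s pairs at %d loci (mutation %s, rate %g, seed %d)\n",
              x$n_pairs, x$relationship, length(x$loci),
              x$mutation$kind, x$mutation$rate, x$seed))
  invisible(x)
}

# one locus, n pairs; returns list(alleles = sorted labels,
# m = n x 4 integer matrix of allele indices, canonical within member)
sim_pairs_locus <- function(freqs, n, label, mutation) {
  alleles <- sort(names(freqs))
  p <- freqs[alleles]
  A <- length(p)
  pop <- function() sample.int(A, n, replace = TRUE, prob = p)
  pick <- function(x1, x2) ifelse(stats::runif(n) < 0.5, x1, x2)
  meiosis <- function(x1, x2)
    mutate_indices(pick(x1, x2), A, mutation, alleles)
  g <- switch(
    label,
    unrelated = list(a = cbind(pop(), pop()), b = cbind(pop(), pop())),
    parent_child = {
      par <- cbind(pop(), pop())
      list(a = par, b = cbind(meiosis(par[, 1], par[, 2]), pop()))
    },
    full_sibling = {
      fa <- cbind(pop(), pop()); mo <- cbind(pop(), pop())
      list(a = cbind(meiosis(fa[, 1], fa[, 2]), meiosis(mo[, 1], mo[, 2])),
           b = cbind(meiosis(fa[, 1], fa[, 2]), meiosis(mo[, 1], mo[, 2])))
    },
    half_sibling = {
      sh <- cbind(pop(), pop())
      list(a = cbind(meiosis(sh[, 1], sh[, 2]), pop()),
           b = cbind(meiosis(sh[, 1], sh[, 2]), pop()))
    },
    first_cousin = {
      gp <- cbind(pop(), pop()); gm <- cbind(pop(), pop())
      p1 <- cbind(meiosis(gp[, 1], gp[, 2]), meiosis(gm[, 1], gm[, 2]))
      p2 <- cbind(meiosis(gp[, 1], gp[, 2]), meiosis(gm[, 1], gm[, 2]))
      list(a = cbind(meiosis(p1[, 1], p1[, 2]), pop()),
           b = cbind(meiosis(p2[, 1], p2[, 2]), pop()))
    },
    stop("unknown relationship: ", label))
  m <- cbind(pmin(g$a[, 1], g$a[, 2]), pmax(g$a[, 1], g$a[, 2]),
             pmin(g$b[, 1], g$b[, 2]), pmax(g$b[, 1], g$b[, 2]))
  list(alleles = alleles, m = m)
}

#' @export
as.data.frame.mh_pairs <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$loci), function(l) {
    s <- x$loci[[l]]
    data.frame(replicate = seq_len(nrow(s$m)), locus = l,
               a1_member1 = s$alleles[s$m[, 1]],
               a2_member1 = s$alleles[s$m[, 2]],
               a1_member2 = s$alleles[s$m[, 3]],
               a2_member2 = s$alleles[s$m[, 4]])
  }))
  out <- out[order(out$replicate, out$locus), ]
  rownames(out) <- NULL
  out
}

#' Write / read a simulated pair file
#'
#' Comma-separated with header
#' `replicate,locus,a1_member1,a2_member1,a1_member2,a2_member2`.
#'
#' @param pairs An `mh_pairs` object (or its data-frame form).
#' @param path File path.
#' @export
write_pairs <- function(pairs, path) {
  if (inherits(pairs, "mh_pairs")) pairs <- as.data.frame(pairs)
  utils::write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  utils::read.csv(path, colClasses = c(replicate = "integer"))
}
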