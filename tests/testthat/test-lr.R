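test_that("conditional genotype probabilities honour the IBD mixture", {
  p <- toy_freqs(c(a = 0.5, b = 0.5))
  # unrelated: marginal genotype probability whatever g1 is
  expect_equal(conditional_genotype_prob(c("a", "b"), c("a", "a"),
                                         c(1, 0, 0), p), 0.5)
  expect_equal(conditional_genotype_prob(c("a", "a"), c("b", "b"),
                                         c(1, 0, 0), p), 0.25)
  # two IBD alleles: identity indicator
  expect_equal(conditional_genotype_prob(c("a", "b"), c("a", "b"),
                                         c(0, 0, 1), p), 1)
  expect_equal(conditional_genotype_prob(c("a", "a"), c("a", "b"),
                                         c(0, 0, 1), p), 0)
  # one transmitted allele from g1 = aa plus a population allele
  expect_equal(conditional_genotype_prob(c("a", "a"), c("a", "a"),
                                         c(0, 1, 0), p), 0.5)
  expect_equal(conditional_genotype_prob(c("a", "b"), c("a", "a"),
                                         c(0, 1, 0), p), 0.5)
  expect_equal(conditional_genotype_prob(c("b", "b"), c("a", "a"),
                                         c(0, 1, 0), p), 0)
  expect_error(conditional_genotype_prob(c("a", "z"), c("a", "a"),
                                         c(0, 1, 0), p), "absent")
})

test_that("conditional probabilities sum to one over all g2", {
  set.seed(14)
  for (rep in 1:5) {
    p <- runif(sample(2:5, 1))
    p <- setNames(p / sum(p), paste0("a", seq_along(p)))
    gts <- all_genotypes(names(p))
    for (k in list(c(1, 0, 0), c(0, 1, 0), c(0.25, 0.5, 0.25),
                   c(0.5, 0.5, 0))) {
      g1 <- gts[[sample(length(gts), 1)]]
      tot <- sum(vapply(gts, conditional_genotype_prob, 0, g1 = g1,
                        k = k, freqs = p))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("single-locus indices reproduce hand-enumerated values", {
  p <- c(a = 0.5, b = 0.5)
  mu0 <- mutation_model("none")
  # PI(aa, ab) = 1/(2 p_a) = 1
  expect_equal(lr_index(list(g1 = c("a", "a"), g2 = c("a", "b")), "PI",
                        p, mu0), 0)
  # Mendelian exclusion without mutation
  expect_equal(lr_index(list(g1 = c("a", "a"), g2 = c("b", "b")), "PI",
                        p, mu0), -Inf)
  # FSI(aa, aa) = 1/4 + 1/2 * P1/Pg + 1/4 / Pg = 2.25 at p = 0.5
  expect_equal(lr_index(list(g1 = c("a", "a"), g2 = c("a", "a")), "FSI",
                        p, mu0), log10(2.25))
})

test_that("mutation-adjusted PI is finite at exclusions and converges to the classical value", {
  p <- c(a = 0.6, b = 0.3, c = 0.1)
  mu <- mutation_model("equal_probability", rate = 1e-8)
  excl <- lr_index(list(g1 = c("a", "a"), g2 = c("b", "b")), "PI", p, mu)
  expect_true(is.finite(excl))
  expect_lt(excl, -6)  # strongly favours exclusion, but finite
  for (pair in list(list(g1 = c("a", "b"), g2 = c("a", "c")),
                    list(g1 = c("a", "a"), g2 = c("a", "b")))) {
    classical <- lr_index(pair, "PI", p, mutation_model("none"))
    adjusted <- lr_index(pair, "PI", p, mu)
    expect_equal(adjusted, classical, tolerance = 1e-6)
  }
})

test_that("PI with mutation matches the transmission-matrix enumeration oracle", {
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  mu <- mutation_model("equal_probability", rate = 0.01)
  tm <- transition_matrix(names(p), mu)
  expect_equal(unname(rowSums(tm)), rep(1, 3), tolerance = 1e-12)
  oracle <- pair_dist_pc(p, tm)
  gts <- oracle$genotypes
  for (i in seq_along(gts)) for (j in seq_along(gts)) {
    got <- lr_index(list(g1 = gts[[i]], g2 = gts[[j]]), "PI", p, mu)
    pg1 <- geno_prob(gts[[i]], p); pg2 <- geno_prob(gts[[j]], p)
    expect_equal(got, log10(oracle$prob[i, j] / (pg1 * pg2)),
                 tolerance = 1e-10)
  }
})

test_that("stepwise transmission matrices are valid and step-shaped", {
  mu <- mutation_model("extended_stepwise", rate = 1e-3,
                       step_geometric_p = 0.9)
  tm <- transition_matrix(as.character(8:13), mu)
  expect_equal(unname(rowSums(tm)), rep(1, 6), tolerance = 1e-12)
  # boundary reflection can return a multi-step mutation to its origin,
  # so the diagonal is >= 1 - mu (equal at the ladder ends)
  expect_true(all(diag(tm) >= 1 - 1e-3))
  expect_equal(tm["8", "8"], 1 - 1e-3)
  expect_lt(max(diag(tm)), 1 - 1e-3 + 1e-3 * 0.1)
  # single steps dominate multi-steps
  expect_gt(tm["10", "11"], tm["10", "12"])
  expect_gt(tm["10", "9"], tm["10", "8"])
})

test_that("the fundamental LR identities hold by exhaustive enumeration", {
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  mu0 <- mutation_model("none")
  for (index in c("PI", "FSI", "HSI", "FCI", "FHSI")) {
    hyp <- switch(index, PI = "parent_child", FSI = "full_sibling",
                  HSI = "half_sibling", FCI = "first_cousin",
                  FHSI = "full_sibling")
    hd <- if (index == "FHSI") "half_sibling" else "unrelated"
    dist_hp <- pair_dist(p, relationship_model(hyp)$k)
    dist_hd <- pair_dist(p, relationship_model(hd)$k)
    gts <- dist_hp$genotypes
    lr <- matrix(0, length(gts), length(gts))
    for (i in seq_along(gts)) for (j in seq_along(gts))
      lr[i, j] <- 10^lr_index(list(g1 = gts[[i]], g2 = gts[[j]]), index,
                              p, mu0)
    expect_equal(sum(dist_hp$prob), 1, tolerance = 1e-12)
    expect_equal(sum(dist_hd$prob), 1, tolerance = 1e-12)
    # E[LR | Hd] = 1
    expect_equal(sum(dist_hd$prob * lr), 1, tolerance = 1e-9)
    # E[LR | Hd] weighting by Hp mass: sum P(pair|Hp) = sum LR * P(Hd)
    expect_equal(sum(dist_hp$prob), sum(lr * dist_hd$prob),
                 tolerance = 1e-9)
  }
})

test_that("FHSI equals FSI minus HSI in log10, and panel LRs add", {
  p1 <- c(a = 0.5, b = 0.3, c = 0.2)
  p2 <- c(x = 0.7, y = 0.3)
  freqs <- list(L1 = p1, L2 = p2)
  mu0 <- mutation_model("none")
  set.seed(9)
  for (rep in 1:20) {
    pair <- simulate_pair("full_sibling", freqs, mu0)
    fsi <- panel_log10_lr(pair, "FSI", freqs, mu0)
    hsi <- panel_log10_lr(pair, "HSI", freqs, mu0)
    fhsi <- panel_log10_lr(pair, "FHSI", freqs, mu0)
    expect_equal(fhsi, fsi - hsi, tolerance = 1e-10)
    per_locus <- sum(vapply(c("L1", "L2"), function(l)
      lr_index(list(g1 = pair$genotypes_a[[l]],
                    g2 = pair$genotypes_b[[l]]), "FSI", freqs[[l]], mu0),
      0))
    expect_equal(fsi, per_locus, tolerance = 1e-12)
  }
  expect_error(panel_log10_lr(
    list(genotypes_a = list(L9 = c("a", "a")),
         genotypes_b = list(L9 = c("a", "a"))), "FSI", freqs), "L9")
})

test_that("vectorized cohort LRs equal the per-pair computation", {
  freqs <- list(L1 = c(a = 0.5, b = 0.3, c = 0.2),
                L2 = c(x = 0.7, y = 0.3))
  mu <- mutation_model("equal_probability", rate = 1e-8)
  for (rel in c("parent_child", "full_sibling", "unrelated")) {
    st <- simulate_study(rel, freqs, mu, n_pairs = 40, seed = 13)
    for (index in c("PI", "FSI", "HSI", "FHSI")) {
      fast <- study_log10_lr(st, index, freqs, mu)
      df <- as.data.frame(st)
      slow <- vapply(seq_len(st$n_pairs), function(r) {
        d <- df[df$replicate == r, ]
        pair <- list(
          genotypes_a = setNames(lapply(seq_len(nrow(d)), function(i)
            c(d$a1_member1[i], d$a2_member1[i])), d$locus),
          genotypes_b = setNames(lapply(seq_len(nrow(d)), function(i)
            c(d$a1_member2[i], d$a2_member2[i])), d$locus))
        panel_log10_lr(pair, index, freqs, mu)
      }, 0)
      expect_equal(fast, slow, tolerance = 1e-10)
    }
  }
})
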