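test_that("relationship models carry the standard IBD coefficients", {
  expect_equal(unname(relationship_model("unrelated")$k), c(1, 0, 0))
  expect_equal(unname(relationship_model("parent_child")$k), c(0, 1, 0))
  expect_equal(unname(relationship_model("full_sibling")$k),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(relationship_model("half_sibling")$k), c(0.5, 0.5, 0))
  expect_equal(unname(relationship_model("first_cousin")$k),
               c(0.75, 0.25, 0))
  expect_error(relationship_model("cousin"))
})

test_that("mutation model validates its parameters", {
  expect_equal(mutation_model("equal_probability")$rate, 1e-8)
  expect_equal(mutation_model("extended_stepwise")$rate, 1e-3)
  expect_equal(mutation_model("none")$rate, 0)
  expect_error(mutation_model("equal_probability", rate = 1), "rate")
  expect_error(mutation_model("none", rate = 0.1), "rate 0")
  # a zero rate collapses to 'none' whatever the kind
  expect_equal(mutation_model("equal_probability", rate = 0)$kind, "none")
})

test_that("founder draws are Hardy-Weinberg: heterozygote fraction", {
  set.seed(21)
  ind <- simulate_individual(c(a = 0.5, b = 0.5), n = 10000)
  het <- mean(ind[, 1] != ind[, 2])
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))
  expect_equal(unique(simulate_individual(c(z = 1), n = 50)[, 1]), "z")
  expect_true(all(ind[, 1] <= ind[, 2]))
})

test_that("transmission picks parental alleles uniformly, mutating per model", {
  mu0 <- mutation_model("none")
  set.seed(5)
  t0 <- transmit_allele(c("a", "b"), mu0, c("a", "b", "c"), n = 20000)
  expect_lt(abs(mean(t0 == "a") - 0.5), 3 * sqrt(0.25 / 20000))
  expect_true(all(t0 %in% c("a", "b")))

  # equal-probability at inflated rate: P(keep) = 1 - mu,
  # each other allele mu / (A - 1)
  mu5 <- mutation_model("equal_probability", rate = 0.5)
  t1 <- transmit_allele(c("a", "a"), mu5, c("a", "b", "c", "d"), n = 100000)
  pr <- prop.table(table(t1))
  expect_lt(abs(pr[["a"]] - 0.5), 3 * sqrt(0.25 / 100000))
  for (al in c("b", "c", "d"))
    expect_lt(abs(pr[[al]] - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / 100000))

  expect_error(transmit_allele(c("a", "a"), mu5, "a", n = 10), "target")
})

test_that("degenerate stepwise mutation moves exactly one step", {
  mu <- mutation_model("extended_stepwise", rate = 1 - 1e-12,
                       step_geometric_p = 1)
  set.seed(6)
  got <- transmit_allele(c("12", "12"), mu, as.character(10:14), n = 5000)
  expect_true(all(got %in% c("11", "13")))
  # boundary allele reflects back inward
  got_edge <- transmit_allele(c("10", "10"), mu, as.character(10:14),
                              n = 2000)
  expect_true(all(got_edge == "11"))
})

test_that("parent-child pairs always share an allele when mu = 0", {
  f <- list(L1 = c(a = 0.4, b = 0.35, c = 0.25),
            L2 = c(x = 0.6, y = 0.4))
  st <- simulate_study("parent_child", f, mutation_model("none"),
                       n_pairs = 5000, seed = 3)
  for (l in names(st$loci)) {
    m <- st$loci[[l]]$m
    share <- m[, 1] == m[, 3] | m[, 1] == m[, 4] |
      m[, 2] == m[, 3] | m[, 2] == m[, 4]
    expect_true(all(share))
  }
})

test_that("full-sibling IBD-state proportions match (1/4, 1/2, 1/4)", {
  # a near-infinite-allele locus makes identity-by-state track
  # identity-by-descent (coincidence probability 1e-4)
  A <- 10000
  f <- list(L = setNames(rep(1 / A, A), sprintf("a%05d", 1:A)))
  st <- simulate_study("full_sibling", f, mutation_model("none"),
                       n_pairs = 30000, seed = 17)
  m <- st$loci$L$m
  shared <- (m[, 1] == m[, 3]) + (m[, 2] == m[, 4])
  # members are canonically sorted, so count matches pairwise
  shared_any <- rowSums(cbind(m[, 1] == m[, 3], m[, 1] == m[, 4],
                              m[, 2] == m[, 3], m[, 2] == m[, 4]))
  ibd <- pmin(shared_any, 2)
  prop <- tabulate(ibd + 1, 3) / nrow(m)
  expect_lt(abs(prop[1] - 0.25), 3 * sqrt(0.25 * 0.75 / 30000) + 2e-3)
  expect_lt(abs(prop[2] - 0.50), 3 * sqrt(0.25 / 30000) + 2e-3)
  expect_lt(abs(prop[3] - 0.25), 3 * sqrt(0.25 * 0.75 / 30000) + 2e-3)
})

test_that("unrelated members recover the input frequencies independently", {
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  st <- simulate_study("unrelated", list(L = p), mutation_model("none"),
                       n_pairs = 25000, seed = 23)
  m <- st$loci$L$m
  al <- st$loci$L$alleles
  for (member in list(m[, 1:2], m[, 3:4])) {
    f <- tabulate(as.vector(member), length(al)) / (2 * nrow(m))
    se <- sqrt(p[al] * (1 - p[al]) / (2 * nrow(m)))
    expect_true(all(abs(f - p[al]) < 3 * se))
  }
  # per-locus independence across members: sharing indicator close to
  # its product expectation
  share1 <- m[, 1] == m[, 3]
  expect_lt(abs(cor(as.integer(m[, 1]), as.integer(m[, 3]))), 0.02)
})

test_that("inflated mutation rates produce parent-child exclusions at ~mu", {
  p <- c(a = 0.25, b = 0.25, c = 0.25, d = 0.25)
  mu <- 0.01
  st <- simulate_study("parent_child", list(L = p),
                       mutation_model("equal_probability", rate = mu),
                       n_pairs = 200000, seed = 29)
  m <- st$loci$L$m
  share <- m[, 1] == m[, 3] | m[, 1] == m[, 4] |
    m[, 2] == m[, 3] | m[, 2] == m[, 4]
  excl <- mean(!share)
  # exclusion requires a mutation (prob mu) that is also detectable
  # (child's other allele must miss both parental alleles); bound by mu
  expect_gt(excl, 0)
  expect_lt(excl, mu)
  expect_gt(excl, mu * 0.2)
})

test_that("cohorts are reproducible and stream to the pair-file layout", {
  f <- list(L1 = c(a = 0.6, b = 0.4), L2 = c(x = 0.5, y = 0.5))
  s1 <- simulate_study("full_sibling", f, mutation_model("none"),
                       n_pairs = 50, seed = 77)
  s2 <- simulate_study("full_sibling", f, mutation_model("none"),
                       n_pairs = 50, seed = 77)
  expect_identical(s1$loci, s2$loci)
  df <- as.data.frame(s1)
  expect_equal(names(df), c("replicate", "locus", "a1_member1",
                            "a2_member1", "a1_member2", "a2_member2"))
  expect_equal(nrow(df), 100)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_pairs(s1, tmp)
  expect_equal(read_pairs(tmp), df)
  one <- simulate_study("unrelated", f, n_pairs = 1, seed = 1)
  expect_equal(nrow(as.data.frame(one)), 2)
})

test_that("single pairs mirror the cohort construction", {
  f <- list(L1 = c(a = 0.6, b = 0.4))
  set.seed(123)
  pr <- simulate_pair("parent_child", f)
  expect_s3_class(pr, "genotype_pair")
  expect_true(any(pr$genotypes_b$L1 %in% pr$genotypes_a$L1))
})
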