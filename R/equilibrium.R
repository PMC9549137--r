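# Hardy-Weinberg and linkage-equilibrium testing.
#
# The HWE exact test conditions on the observed allele counts: under
# Hardy-Weinberg sampling, every assignment of the 2n allele copies to
# the 2n ordered genotype slots is equally likely, so a random-swap
# Markov chain over slot assignments (accept every move) has exactly the
# conditional distribution of genotype tables as its stationary law.
# The p-value is the probability mass of tables whose conditional
# probability does not exceed that of the observed table.

#' Hardy-Weinberg exact test by Markov-chain Monte Carlo
#'
#' @param x Either a genotype table (`sample,locus,allele1,allele2`), in
#'   which case `locus_name` selects the locus, or an n x 2 character
#'   matrix of per-sample allele pairs.
#' @param locus_name Locus to test when `x` is a genotype table.
#' @param n_steps Number of Markov-chain steps after burn-in.
#' @param n_burnin Burn-in steps discarded before tallying.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return List of class `hwe_result`: `locus_name`, `p_value`,
#'   `n_steps`, `n_burnin`, `seed`.
#' @export
hwe_exact_test <- function(x, locus_name = NULL, n_steps = 1e6,
                           n_burnin = 1e5, seed = 1L) {
  al <- genotype_allele_matrix(x, locus_name)
  locus_name <- attr(al, "locus_name")
  lev <- sort(unique(as.vector(al)))
  res <- structure(list(locus_name = locus_name, p_value = 1.0,
                        n_steps = as.integer(n_steps),
                        n_burnin = as.integer(n_burnin),
                        seed = as.integer(seed)),
                   class = "hwe_result")
  if (length(lev) < 2L) {
    warning("monomorphic locus ", locus_name, ": p-value is 1")
    return(res)
  }
  slots <- as.integer(factor(as.vector(t(al)), levels = lev))
  res$p_value <- hwe_mcmc(slots, length(lev), n_steps, n_burnin, seed)
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE exact test (MCMC) %s: p = %.4g (%d steps, %d burn-in, seed %d)\n",
              x$locus_name, x$p_value, x$n_steps, x$n_burnin, x$seed))
  invisible(x)
}

# core chain; slots = 2n integer allele codes, individual k owns slots
# 2k-1, 2k.  log-probability of a table (up to a constant):
#   H * log 2 - sum_{i<=j} log(n_ij!)
hwe_mcmc <- function(slots, n_alleles, n_steps, n_burnin, seed) {
  set.seed(as.integer(seed))
  n2 <- length(slots)
  cnt <- matrix(0L, n_alleles, n_alleles)   # upper-triangle genotype counts
  for (k in seq_len(n2 / 2L)) {
    i <- slots[2L * k - 1L]; j <- slots[2L * k]
    a <- min(i, j); b <- max(i, j)
    cnt[a, b] <- cnt[a, b] + 1L
  }
  logp <- log(2) * sum(cnt[upper.tri(cnt)]) - sum(lgamma(cnt + 1))
  logp_obs <- logp
  total <- n_burnin + n_steps
  hits <- 0L
  u <- matrix(sample.int(n2, 2L * total, replace = TRUE), ncol = 2L)
  for (s in seq_len(total)) {
    p <- u[s, 1L]; q <- u[s, 2L]
    ip <- (p + 1L) %/% 2L; iq <- (q + 1L) %/% 2L
    if (ip != iq && slots[p] != slots[q]) {
      # remove the two individuals' genotypes, swap, re-add
      g <- c(2L * ip - 1L, 2L * ip, 2L * iq - 1L, 2L * iq)
      old1 <- sort(slots[g[1:2]]); old2 <- sort(slots[g[3:4]])
      tmp <- slots[p]; slots[p] <- slots[q]; slots[q] <- tmp
      new1 <- sort(slots[g[1:2]]); new2 <- sort(slots[g[3:4]])
      for (gg in list(old1, old2)) {
        c0 <- cnt[gg[1L], gg[2L]]
        logp <- logp + log(c0) - (if (gg[1L] != gg[2L]) log(2) else 0)
        cnt[gg[1L], gg[2L]] <- c0 - 1L
      }
      for (gg in list(new1, new2)) {
        c0 <- cnt[gg[1L], gg[2L]] + 1L
        logp <- logp - log(c0) + (if (gg[1L] != gg[2L]) log(2) else 0)
        cnt[gg[1L], gg[2L]] <- c0
      }
    }
    if (s > n_burnin && logp <= logp_obs + 1e-9) hits <- hits + 1L
  }
  hits / n_steps
}

# coerce input to an n x 2 allele matrix
genotype_allele_matrix <- function(x, locus_name = NULL) {
  if (is.data.frame(x)) {
    x <- check_genotype_table(x)
    if (is.null(locus_name)) {
      locus_name <- unique(x$locus)
      if (length(locus_name) > 1L)
        stop("genotype table has several loci; supply locus_name")
    }
    g <- x[x$locus == locus_name, , drop = FALSE]
    if (nrow(g) == 0L) stop("locus not present: ", locus_name)
    m <- cbind(g$allele1, g$allele2)
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 2L) stop("allele matrix must have two columns")
    if (is.null(locus_name)) locus_name <- "locus"
  }
  if (nrow(m) < 2L) stop("need at least two typed samples")
  structure(m, locus_name = locus_name)
}

#' Maximum-likelihood two-locus haplotype frequencies by EM
#'
#' Gametic phase is unobserved in unphased genotype data: a sample that
#' is heterozygous at both loci is compatible with two haplotype
#' configurations. The EM algorithm starts from a uniform distribution
#' over all haplotypes compatible with the data and iterates expected
#' phase counts until the log-likelihood gain drops below `tol` or
#' `max_iter` is reached. The log-likelihood is non-decreasing across
#' iterations. When double heterozygotes are present the likelihood can
#' have symmetric optima; the solution returned is the one reached from
#' the deterministic uniform start, and the condition is flagged via the
#' `ambiguous_phase` attribute.
#'
#' @param geno Data frame with columns `a1`, `a2` (alleles at locus 1)
#'   and `b1`, `b2` (alleles at locus 2), one row per sample.
#' @param max_iter Maximum EM iterations.
#' @param tol Log-likelihood convergence tolerance.
#' @return Named numeric vector of haplotype frequencies (names
#'   `"<allele1>-<allele2>"`, summing to 1) with attributes `loglik`,
#'   `iterations`, `converged`, `ambiguous_phase`.
#' @export
em_haplotype_frequencies <- function(geno, max_iter = 1000L, tol = 1e-8) {
  cls <- two_locus_classes(geno)
  em <- em_run(cls, max_iter = max_iter, tol = tol)
  structure(em$freqs, loglik = em$loglik, iterations = em$iter,
            converged = em$converged,
            ambiguous_phase = any(vapply(cls$configs, length, 0L) > 1L))
}

# Aggregate two-locus genotype rows into unique classes with weights and
# enumerate the compatible unordered haplotype-pair configurations.
two_locus_classes <- function(geno) {
  need <- c("a1", "a2", "b1", "b2")
  if (!is.data.frame(geno) || !all(need %in% names(geno)))
    stop("geno must be a data frame with columns a1,a2,b1,b2")
  if (nrow(geno) == 0L) stop("empty two-locus genotype input")
  a1 <- pmin(geno$a1, geno$a2); a2 <- pmax(geno$a1, geno$a2)
  b1 <- pmin(geno$b1, geno$b2); b2 <- pmax(geno$b1, geno$b2)
  key <- paste(a1, a2, b1, b2, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  hap <- function(a, b) paste(a, b, sep = "-")
  configs <- lapply(parts, function(p) {
    c1 <- c(hap(p[1L], p[3L]), hap(p[2L], p[4L]))
    c2 <- c(hap(p[1L], p[4L]), hap(p[2L], p[3L]))
    cfgs <- list(sort(c1))
    if (!identical(sort(c1), sort(c2))) cfgs <- c(cfgs, list(sort(c2)))
    cfgs
  })
  haps <- sort(unique(unlist(configs)))
  list(w = as.numeric(tab), configs = configs, haps = haps,
       a = cbind(a1, a2), b = cbind(b1, b2), key = names(tab))
}

# EM core on aggregated classes; returns frequencies over cls$haps
em_run <- function(cls, max_iter = 1000L, tol = 1e-8, freqs = NULL) {
  H <- length(cls$haps)
  if (is.null(freqs)) freqs <- stats::setNames(rep(1 / H, H), cls$haps)
  cfg_prob <- function(f) lapply(cls$configs, function(cfgs)
    vapply(cfgs, function(h) {
      p <- f[[h[1L]]] * f[[h[2L]]]
      if (h[1L] != h[2L]) 2 * p else p
    }, 0))
  ll <- function(pr) sum(cls$w * log(vapply(pr, sum, 0)))
  pr <- cfg_prob(freqs)
  loglik <- ll(pr)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E: expected haplotype counts; M: renormalize
    cnt <- stats::setNames(numeric(H), cls$haps)
    for (i in seq_along(cls$configs)) {
      wts <- pr[[i]] / sum(pr[[i]])
      cfgs <- cls$configs[[i]]
      for (j in seq_along(cfgs)) {
        cnt[cfgs[[j]][1L]] <- cnt[cfgs[[j]][1L]] + cls$w[i] * wts[j]
        cnt[cfgs[[j]][2L]] <- cnt[cfgs[[j]][2L]] + cls$w[i] * wts[j]
      }
    }
    freqs <- cnt / sum(cnt)
    pr <- cfg_prob(freqs)
    new_ll <- ll(pr)
    if (new_ll - loglik < tol) { loglik <- max(new_ll, loglik); converged <- TRUE; break }
    loglik <- new_ll
  }
  list(freqs = freqs, loglik = loglik, iter = iter, converged = converged)
}

# log-likelihood of the data under given haplotype frequencies (zero
# frequency for haplotypes absent from `freqs`)
two_locus_loglik <- function(cls, freqs) {
  pr <- vapply(seq_along(cls$configs), function(i)
    sum(vapply(cls$configs[[i]], function(h) {
      f1 <- if (h[1L] %in% names(freqs)) freqs[[h[1L]]] else 0
      f2 <- if (h[2L] %in% names(freqs)) freqs[[h[2L]]] else 0
      p <- f1 * f2
      if (h[1L] != h[2L]) 2 * p else p
    }, 0)), 0)
  sum(cls$w * log(pr))
}

#' Likelihood-ratio permutation test for linkage disequilibrium
#'
#' The observed statistic is `2 * (logL_EM - logL_LE)` where `logL_EM`
#' is the maximized log-likelihood with free haplotype frequencies (EM,
#' see [em_haplotype_frequencies()]) and `logL_LE` constrains every
#' haplotype frequency to the product of its single-locus allele
#' frequencies (linkage equilibrium). The null distribution is built by
#' permuting the second locus' genotypes across samples (breaking any
#' association while preserving both marginals) and re-running EM on
#' each permuted data set. The p-value uses the add-one estimator
#' `(1 + #{permuted >= observed}) / (1 + n_permutations)`.
#'
#' @inheritParams em_haplotype_frequencies
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed; deterministic given the seed.
#' @param locus_pair Length-2 character vector naming the loci (for the
#'   report only).
#' @return List of class `ld_result`: `locus_pair`, `lr_statistic`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
ld_permutation_test <- function(geno, n_permutations = 1e4, seed = 1L,
                                locus_pair = c("locus1", "locus2"),
                                max_iter = 1000L, tol = 1e-8) {
  res <- structure(list(locus_pair = locus_pair, lr_statistic = 0,
                        p_value = 1.0,
                        n_permutations = as.integer(n_permutations),
                        seed = as.integer(seed)),
                   class = "ld_result")
  if (nrow(geno) < 2L) stop("need at least two samples")
  if (length(unique(c(geno$a1, geno$a2))) < 2L ||
      length(unique(c(geno$b1, geno$b2))) < 2L) {
    warning("monomorphic locus in pair (", paste(locus_pair, collapse = ", "),
            "): p-value is 1")
    return(res)
  }
  stat <- function(g) {
    cls <- two_locus_classes(g)
    pa <- prop.table(table(c(g$a1, g$a2)))
    pb <- prop.table(table(c(g$b1, g$b2)))
    le <- outer(as.numeric(pa), as.numeric(pb))
    dimnames(le) <- list(names(pa), names(pb))
    f_le <- stats::setNames(as.vector(le),
                            outer(rownames(le), colnames(le),
                                  function(a, b) paste(a, b, sep = "-")))
    ll_em <- em_run(cls, max_iter = max_iter, tol = tol)$loglik
    max(0, 2 * (ll_em - two_locus_loglik(cls, f_le)))
  }
  obs <- stat(geno)
  set.seed(as.integer(seed))
  n <- nrow(geno)
  exceed <- 0L
  for (r in seq_len(n_permutations)) {
    idx <- sample.int(n)
    g <- data.frame(a1 = geno$a1, a2 = geno$a2,
                    b1 = geno$b1[idx], b2 = geno$b2[idx])
    if (stat(g) >= obs - 1e-12) exceed <- exceed + 1L
  }
  res$lr_statistic <- obs
  res$p_value <- (1 + exceed) / (1 + n_permutations)
  res
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD permutation test %s-%s: LR = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$locus_pair[1L], x$locus_pair[2L], x$lr_statistic, x$p_value,
              x$n_permutations, x$seed))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests, >= 1.
#' @return `alpha / m` at full precision (rounding is a display matter).
#' @examples
#' bonferroni_threshold(0.05, 36)   # 0.05/36  = 0.0014 (4 dp)
#' bonferroni_threshold(0.05, 406)  # 0.05/406 = 0.0001 (4 dp)
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be a positive integer")
  alpha / m
}

#' Two-stage equilibrium scan over a genotype table
#'
#' Stage 1 runs the Hardy-Weinberg exact test on every locus with a
#' Bonferroni threshold of `alpha / (number of loci)`. Stage 2 runs the
#' linkage-disequilibrium permutation test on all pairs of loci that
#' passed stage 1, with a Bonferroni threshold of `alpha / (number of
#' pairs)`. Per-test seeds are spawned from `seed` by a fixed linear
#' scheme so each result is reproducible independently of execution
#' order.
#'
#' @param genotypes Genotype table (`sample,locus,allele1,allele2`).
#' @param alpha Family-wise error rate before correction.
#' @param hwe_steps,hwe_burnin Markov-chain lengths for stage 1.
#' @param ld_permutations Permutations for stage 2.
#' @param seed Root seed.
#' @return List with data frames `hwe` (locus, p_value, significant) and
#'   `ld` (locus1, locus2, lr_statistic, p_value, significant), plus the
#'   thresholds used.
#' @export
equilibrium_scan <- function(genotypes, alpha = 0.05, hwe_steps = 1e5,
                             hwe_burnin = 1e4, ld_permutations = 200L,
                             seed = 1L) {
  genotypes <- check_genotype_table(genotypes)
  loci <- unique(genotypes$locus)
  thr_hwe <- bonferroni_threshold(alpha, length(loci))
  hwe <- do.call(rbind, lapply(seq_along(loci), function(i) {
    r <- hwe_exact_test(genotypes, loci[i], n_steps = hwe_steps,
                        n_burnin = hwe_burnin, seed = spawn_seed(seed, i))
    data.frame(locus = loci[i], p_value = r$p_value,
               significant = r$p_value < thr_hwe)
  }))
  pass <- hwe$locus[!hwe$significant]
  ld <- NULL
  thr_ld <- NA_real_
  if (length(pass) >= 2L) {
    prs <- utils::combn(pass, 2L)
    thr_ld <- bonferroni_threshold(alpha, ncol(prs))
    ld <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      g1 <- genotypes[genotypes$locus == prs[1L, j], , drop = FALSE]
      g2 <- genotypes[genotypes$locus == prs[2L, j], , drop = FALSE]
      common <- intersect(g1$sample, g2$sample)
      geno <- data.frame(
        a1 = g1$allele1[match(common, g1$sample)],
        a2 = g1$allele2[match(common, g1$sample)],
        b1 = g2$allele1[match(common, g2$sample)],
        b2 = g2$allele2[match(common, g2$sample)])
      r <- ld_permutation_test(geno, n_permutations = ld_permutations,
                               seed = spawn_seed(seed, 1000L + j),
                               locus_pair = prs[, j])
      data.frame(locus1 = prs[1L, j], locus2 = prs[2L, j],
                 lr_statistic = r$lr_statistic, p_value = r$p_value,
                 significant = r$p_value < thr_ld)
    }))
  }
  list(hwe = hwe, ld = ld, hwe_threshold = thr_hwe, ld_threshold = thr_ld,
       seed = as.integer(seed))
}

# fixed child-seed spawning: Lehmer step modulo the Mersenne prime 2^31-1
spawn_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i) %% 2147483647)
}
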