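# Independent brute-force oracles used to pin expected values.
# Everything here is deliberately naive (enumeration, no shortcuts) and
# shares no code with the implementation under test.

# ---- Hardy-Weinberg: exact conditional p-value by table enumeration ----

# All genotype tables (upper-triangle count matrices) with the given
# allele-count margins, with their conditional probabilities
# P(table) proportional to 2^H / prod(n_ij!).
enumerate_hwe_tables <- function(allele_counts) {
  A <- length(allele_counts)
  cells <- which(upper.tri(matrix(0, A, A), diag = TRUE), arr.ind = TRUE)
  out <- list()
  recurse <- function(k, remaining, counts) {
    if (k > nrow(cells)) {
      if (all(remaining == 0)) out[[length(out) + 1L]] <<- counts
      return(invisible())
    }
    i <- cells[k, 1]; j <- cells[k, 2]
    cap <- if (i == j) remaining[i] %/% 2 else min(remaining[i], remaining[j])
    for (n_ij in 0:cap) {
      rem <- remaining
      if (i == j) {
        rem[i] <- rem[i] - 2L * n_ij
      } else {
        rem[i] <- rem[i] - n_ij
        rem[j] <- rem[j] - n_ij
      }
      counts[k] <- n_ij
      recurse(k + 1L, rem, counts)
    }
  }
  recurse(1L, allele_counts, integer(nrow(cells)))
  logw <- vapply(out, function(cnt) {
    het <- sum(cnt[cells[, 1] != cells[, 2]])
    het * log(2) - sum(lgamma(cnt + 1))
  }, 0)
  w <- exp(logw - max(logw))
  list(cells = cells, tables = out, prob = w / sum(w))
}

# exact p-value for an observed n x 2 allele matrix
hwe_exact_enumeration <- function(alleles) {
  lev <- sort(unique(as.vector(alleles)))
  i <- match(alleles[, 1], lev)
  j <- match(alleles[, 2], lev)
  counts <- tabulate(c(i, j), nbins = length(lev))
  enum <- enumerate_hwe_tables(counts)
  obs <- integer(nrow(enum$cells))
  for (r in seq_along(i)) {
    a <- min(i[r], j[r]); b <- max(i[r], j[r])
    k <- which(enum$cells[, 1] == a & enum$cells[, 2] == b)
    obs[k] <- obs[k] + 1L
  }
  p_obs <- enum$prob[vapply(enum$tables, identical, TRUE, obs)]
  sum(enum$prob[enum$prob <= p_obs + 1e-12])
}

# ---- two-locus EM: brute force over phase assignments ----

# For data where at most a few samples are ambiguous: try every phase
# assignment, estimate haplotype frequencies by counting, and keep the
# assignment whose frequencies maximize the observed-data likelihood.
phase_enum_ml <- function(geno) {
  n <- nrow(geno)
  configs <- lapply(seq_len(n), function(r) {
    a <- sort(c(geno$a1[r], geno$a2[r]))
    b <- sort(c(geno$b1[r], geno$b2[r]))
    c1 <- sort(c(paste(a[1], b[1], sep = "-"), paste(a[2], b[2], sep = "-")))
    c2 <- sort(c(paste(a[1], b[2], sep = "-"), paste(a[2], b[1], sep = "-")))
    unique(list(c1, c2))
  })
  grid <- expand.grid(lapply(configs, seq_along))
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    haps <- unlist(lapply(seq_len(n), function(r)
      configs[[r]][[grid[g, r]]]))
    f <- table(haps) / (2 * n)
    ll <- sum(vapply(seq_len(n), function(r) {
      log(sum(vapply(configs[[r]], function(h) {
        p <- prod(vapply(h, function(x)
          if (x %in% names(f)) as.numeric(f[[x]]) else 0, 0))
        if (h[1] != h[2]) 2 * p else p
      }, 0)))
    }, 0))
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, freqs = f)
  }
  best
}

# ---- kinship LRs: exhaustive genotype-pair enumeration ----

# unordered genotypes of an allele set
all_genotypes <- function(alleles) {
  alleles <- sort(alleles)
  out <- list()
  for (i in seq_along(alleles))
    for (j in i:length(alleles))
      out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
  out
}

geno_prob <- function(g, p) {
  if (g[1] == g[2]) p[[g[1]]]^2 else 2 * p[[g[1]]] * p[[g[2]]]
}

# P(g2 | g1, one shared parental transmission), naive enumeration over
# which allele of g1 is transmitted and which population allele mates
one_ibd_prob <- function(g2, g1, p) {
  tot <- 0
  for (t in g1) {
    for (mate in names(p)) {
      child <- sort(c(t, mate))
      if (identical(child, sort(g2)))
        tot <- tot + 0.5 * p[[mate]]
    }
  }
  tot
}

# joint distribution of ordered pairs (g1, g2) under a k-triple
pair_dist <- function(p, k) {
  gts <- all_genotypes(names(p))
  probs <- matrix(0, length(gts), length(gts))
  for (i in seq_along(gts)) for (j in seq_along(gts)) {
    g1 <- gts[[i]]; g2 <- gts[[j]]
    cond <- k[1] * geno_prob(g2, p) + k[2] * one_ibd_prob(g2, g1, p) +
      k[3] * as.numeric(identical(sort(g1), sort(g2)))
    probs[i, j] <- geno_prob(g1, p) * cond
  }
  list(genotypes = gts, prob = probs)
}

# parent-child pair distribution with a mutation transition matrix
pair_dist_pc <- function(p, tm) {
  gts <- all_genotypes(names(p))
  probs <- matrix(0, length(gts), length(gts))
  for (i in seq_along(gts)) for (j in seq_along(gts)) {
    g1 <- gts[[i]]; g2 <- gts[[j]]
    cond <- 0
    for (t in g1) for (b in colnames(tm)) for (mate in names(p)) {
      child <- sort(c(b, mate))
      if (identical(child, sort(g2)))
        cond <- cond + 0.5 * tm[t, b] * p[[mate]]
    }
    probs[i, j] <- geno_prob(g1, p) * cond
  }
  list(genotypes = gts, prob = probs)
}

# ---- misc fixtures ----

toy_freqs <- function(p = c(a = 0.5, b = 0.3, c = 0.2)) p

# write a minimal phased VCF for given per-sample haplotype strings
write_toy_vcf <- function(path, chrom, positions, ref, alt, haps1, haps2,
                          samples = paste0("S", seq_along(haps1)),
                          phased = TRUE) {
  sep <- if (phased) "|" else "/"
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_along(positions), function(k) {
    gts <- vapply(seq_along(samples), function(s) {
      g1 <- if (substr(haps1[s], k, k) == ref[k]) 0L else 1L
      g2 <- if (substr(haps2[s], k, k) == ref[k]) 0L else 1L
      paste0(g1, sep, g2)
    }, "")
    paste(c(chrom, positions[k], ".", ref[k], alt[k], ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  path
}
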