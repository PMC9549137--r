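#' Classify a log10 LR against a threshold pair
#'
#' Strict inequalities throughout: `log10 LR > t1` supports Hp, `log10
#' LR < t2` supports Hd, anything in between — including values exactly
#' equal to a threshold — is uncertain. `-Inf` supports Hd, `+Inf`
#' supports Hp.
#'
#' @param log10_lr Numeric vector (may contain `-Inf`/`+Inf`).
#' @param t1 Upper threshold.
#' @param t2 Lower threshold, `t2 <= t1`.
#' @return Factor with levels `support_hp`, `uncertain`, `support_hd`.
#' @export
classify <- function(log10_lr, t1, t2) {
  if (t1 < t2) stop("t1 must be >= t2")
  out <- rep("uncertain", length(log10_lr))
  out[log10_lr > t1] <- "support_hp"
  out[log10_lr < t2] <- "support_hd"
  factor(out, levels = c("support_hp", "uncertain", "support_hd"))
}

#' Decision metrics at one threshold pair
#'
#' Tallies the six classifications (relatives / non-relatives judged
#' related / unrelated / uncertain) and derives: sensitivity = relatives
#' correctly judged related / relatives; specificity = non-relatives
#' correctly judged unrelated / non-relatives; PPV = relatives judged
#' related / all judged related; NPV = non-relatives judged unrelated /
#' all judged unrelated; error rate = (relatives judged unrelated +
#' non-relatives judged related) / total; effectiveness = (relatives
#' judged related + non-relatives judged unrelated) / total. PPV/NPV
#' are `NA` when their denominator is zero.
#'
#' @param hp_lrs,hd_lrs log10 LR samples simulated under Hp and Hd.
#' @inheritParams classify
#' @return One-row data frame with thresholds, the six counts and the
#'   six metrics (class `threshold_metrics`).
#' @export
threshold_metrics <- function(hp_lrs, hd_lrs, t1, t2) {
  if (length(hp_lrs) == 0L || length(hd_lrs) == 0L)
    stop("both LR samples must be non-empty")
  ch <- table(classify(hp_lrs, t1, t2))
  cd <- table(classify(hd_lrs, t1, t2))
  n_hp <- length(hp_lrs); n_hd <- length(hd_lrs)
  rr <- as.integer(ch[["support_hp"]]); ru <- as.integer(ch[["support_hd"]])
  ur <- as.integer(cd[["support_hp"]]); uu <- as.integer(cd[["support_hd"]])
  out <- data.frame(
    t1 = t1, t2 = t2,
    hp_judged_hp = rr, hp_uncertain = as.integer(ch[["uncertain"]]),
    hp_judged_hd = ru,
    hd_judged_hp = ur, hd_uncertain = as.integer(cd[["uncertain"]]),
    hd_judged_hd = uu,
    sensitivity = rr / n_hp,
    specificity = uu / n_hd,
    ppv = if (rr + ur > 0L) rr / (rr + ur) else NA_real_,
    npv = if (uu + ru > 0L) uu / (uu + ru) else NA_real_,
    error_rate = (ru + ur) / (n_hp + n_hd),
    effectiveness = (rr + uu) / (n_hp + n_hd))
  class(out) <- c("threshold_metrics", "data.frame")
  out
}

#' Uncovered rates (UCR)
#'
#' The fraction of Hp-simulated log10 LRs strictly larger than the
#' maximum Hd-simulated log10 LR, and the fraction of Hd-simulated
#' values strictly smaller than the minimum Hp-simulated value. These
#' depend on sample extrema and are highly variable between simulation
#' runs; they summarise distributional overlap, not error rates.
#'
#' @inheritParams threshold_metrics
#' @return List of class `ucr_result`: `max_hd_log10lr`,
#'   `min_hp_log10lr`, `ucr_hp`, `ucr_hd`.
#' @export
ucr <- function(hp_lrs, hd_lrs) {
  if (length(hp_lrs) == 0L || length(hd_lrs) == 0L)
    stop("both LR samples must be non-empty")
  max_hd <- max(hd_lrs)
  min_hp <- min(hp_lrs)
  structure(list(max_hd_log10lr = max_hd, min_hp_log10lr = min_hp,
                 ucr_hp = mean(hp_lrs > max_hd),
                 ucr_hd = mean(hd_lrs < min_hp)),
            class = "ucr_result")
}

#' @export
print.ucr_result <- function(x, ...) {
  cat(sprintf("max(Hd) = %.2f  UCR(Hp > max Hd) = %.2f%%\n",
              x$max_hd_log10lr, 100 * x$ucr_hp))
  cat(sprintf("min(Hp) = %.2f  UCR(Hd < min Hp) = %.2f%%\n",
              x$min_hp_log10lr, 100 * x$ucr_hd))
  invisible(x)
}

#' End-to-end system-power study for one Hp-vs-Hd comparison
#'
#' Simulates an Hp cohort and an Hd cohort, computes the matching panel
#' log10 LR index (PI for parent-child vs unrelated, FSI for
#' full-sibling vs unrelated, HSI for half-sibling vs unrelated, FCI
#' for first-cousin vs unrelated, FHSI for full-sibling vs
#' half-sibling), and reports UCR plus decision metrics over a
#' threshold grid. Cohort seeds are spawned deterministically from
#' `seed`, so the whole report is reproducible.
#'
#' @param panel_freqs Frequency set (see [read_frequency_table()]); the
#'   same renormalized object drives both simulation and LR evaluation.
#' @param hp,hd Relationship labels of the two hypotheses.
#' @param n_pairs Pairs per cohort.
#' @param mutation A [mutation_model()].
#' @param thresholds List of `c(t1, t2)` pairs; default `(1,-1) ...
#'   (4,-4)`.
#' @param seed Root seed.
#' @param keep_lrs Keep the simulated log10 LR vectors in the report.
#' @return Object of class `power_report`: comparison metadata, a
#'   `ucr_result`, and a data frame of [threshold_metrics()] rows.
#' @export
run_power_study <- function(panel_freqs, hp = "parent_child",
                            hd = "unrelated", n_pairs = 1e5,
                            mutation = mutation_model("equal_probability"),
                            thresholds = lapply(1:4, function(t) c(t, -t)),
                            seed = 1L, keep_lrs = FALSE) {
  index <- index_for_comparison(hp, hd)
  hp_pairs <- simulate_study(hp, panel_freqs, mutation, n_pairs,
                             seed = spawn_seed(seed, 1L))
  hd_pairs <- simulate_study(hd, panel_freqs, mutation, n_pairs,
                             seed = spawn_seed(seed, 2L))
  hp_lrs <- study_log10_lr(hp_pairs, index, panel_freqs, mutation)
  hd_lrs <- study_log10_lr(hd_pairs, index, panel_freqs, mutation)
  metrics <- do.call(rbind, lapply(thresholds, function(t)
    threshold_metrics(hp_lrs, hd_lrs, t[1L], t[2L])))
  structure(list(hp = hp, hd = hd, index = index,
                 n_pairs = as.integer(n_pairs), mutation = mutation,
                 seed = as.integer(seed), ucr = ucr(hp_lrs, hd_lrs),
                 metrics = metrics,
                 hp_lrs = if (keep_lrs) hp_lrs,
                 hd_lrs = if (keep_lrs) hd_lrs),
            class = "power_report")
}

# relationship comparison -> LR index
index_for_comparison <- function(hp, hd) {
  key <- paste(hp, hd, sep = " vs ")
  switch(key,
         "parent_child vs unrelated" = "PI",
         "full_sibling vs unrelated" = "FSI",
         "half_sibling vs unrelated" = "HSI",
         "first_cousin vs unrelated" = "FCI",
         "full_sibling vs half_sibling" = "FHSI",
         stop("unsupported comparison: ", key))
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("Power study: %s vs %s (%s), %d pairs per cohort, mutation %s (rate %g), seed %d\n",
              x$hp, x$hd, x$index, x$n_pairs, x$mutation$kind,
              x$mutation$rate, x$seed))
  print(x$ucr)
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf(
      " t=%g/%g  sens %.2f%%  spec %.2f%%  ppv %s  npv %s  err %.2f%%  eff %.2f%%\n",
      m$t1[i], m$t2[i], 100 * m$sensitivity[i], 100 * m$specificity[i],
      ifelse(is.na(m$ppv[i]), "NA", sprintf("%.2f%%", 100 * m$ppv[i])),
      ifelse(is.na(m$npv[i]), "NA", sprintf("%.2f%%", 100 * m$npv[i])),
      100 * m$error_rate[i], 100 * m$effectiveness[i]))
  invisible(x)
}
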