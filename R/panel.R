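#' Validate a microhaplotype locus name
#'
#' Microhaplotype loci follow the community nomenclature
#' `mh<NN><lab><serial>`: the prefix `mh`, a two-digit chromosome number,
#' a lower-case laboratory code, a numeric serial, and an optional single
#' lower-case suffix letter marking a variant SNP combination of a
#' previously published locus (e.g. `mh04zha032a`).
#'
#' @param name Character vector of candidate locus names.
#' @return Logical vector, `TRUE` where the name conforms.
#' @examples
#' validate_locus_name(c("mh04zha032a", "mh18zha010a", "STR-D3S1358"))
#' @export
validate_locus_name <- function(name) {
  stopifnot(is.character(name))
  grepl("^mh(0[1-9]|1[0-9]|2[0-2])[a-z]+[0-9]+[a-z]?$", name)
}

#' Construct a microhaplotype locus definition
#'
#' @param name Locus name in the standard nomenclature (see
#'   [validate_locus_name()]).
#' @param chromosome Chromosome label, `"1"`–`"22"` (autosomes only).
#' @param positions Integer vector of 1-based GRCh37 coordinates of the
#'   member SNPs, strictly increasing, length >= 2.
#' @param rsids Character vector of SNP identifiers, same length as
#'   `positions`.
#' @param extent_bp Optional published extent in bp. The locus extent is
#'   the inclusive span first-to-last SNP, `max(positions) -
#'   min(positions) + 1`; when `extent_bp` is supplied it is checked
#'   against that convention and a mismatch is reported (not silently
#'   corrected).
#' @return An object of class `mh_locus`.
#' @export
mh_locus <- function(name, chromosome, positions, rsids, extent_bp = NULL) {
  if (!validate_locus_name(name))
    stop("locus name does not follow the mh nomenclature: ", name)
  chromosome <- as.character(chromosome)
  if (!chromosome %in% as.character(1:22))
    stop("chromosome must be an autosome label 1-22: ", chromosome)
  positions <- as.integer(positions)
  if (length(positions) < 2L || any(diff(positions) <= 0L))
    stop("positions must be >= 2 strictly increasing coordinates (", name, ")")
  if (length(rsids) != length(positions))
    stop("rsids and positions differ in length at ", name)
  span <- positions[length(positions)] - positions[1L] + 1L
  if (is.null(extent_bp)) {
    extent_bp <- span
  } else {
    extent_bp <- as.integer(extent_bp)
    if (extent_bp != span)
      warning(sprintf("%s: stated extent %d bp != inclusive span %d bp",
                      name, extent_bp, span))
  }
  structure(
    list(name = name, chromosome = chromosome, positions = positions,
         rsids = as.character(rsids), extent_bp = extent_bp),
    class = "mh_locus")
}

#' @export
print.mh_locus <- function(x, ...) {
  cat(sprintf("<mh_locus> %s  chr%s  %d SNPs  %d bp\n",
              x$name, x$chromosome, length(x$positions), x$extent_bp))
  invisible(x)
}

#' Bundle loci into a panel
#'
#' @param loci List of [mh_locus()] objects with unique names.
#' @param label Panel label.
#' @return An object of class `mh_panel` (a named list of loci).
#' @export
mh_panel <- function(loci, label = "panel") {
  stopifnot(is.list(loci), all(vapply(loci, inherits, TRUE, "mh_locus")))
  nm <- vapply(loci, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate locus names in panel")
  structure(list(loci = stats::setNames(loci, nm), label = label),
            class = "mh_panel")
}

#' @export
print.mh_panel <- function(x, ...) {
  cat(sprintf("<mh_panel> '%s': %d loci on %d chromosomes\n", x$label,
              length(x$loci),
              length(unique(vapply(x$loci, `[[`, "", "chromosome")))))
  invisible(x)
}

#' @export
length.mh_panel <- function(x) length(x$loci)

#' Read / write a panel definition file
#'
#' The file is comma-separated with header
#' `name,chromosome,positions,rsids,extent_bp`; `positions` and `rsids`
#' are `/`-separated lists.
#'
#' @param path File path.
#' @param label Panel label to attach on read.
#' @return `read_panel()` returns an `mh_panel`; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("name", "chromosome", "positions", "rsids", "extent_bp")
  if (!all(need %in% names(df)))
    stop("panel file must have columns: ", paste(need, collapse = ","))
  loci <- lapply(seq_len(nrow(df)), function(i)
    mh_locus(df$name[i], df$chromosome[i],
             as.integer(strsplit(df$positions[i], "/", fixed = TRUE)[[1L]]),
             strsplit(df$rsids[i], "/", fixed = TRUE)[[1L]],
             as.integer(df$extent_bp[i])))
  mh_panel(loci, label = label)
}

#' @rdname read_panel
#' @param panel An `mh_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mh_panel"))
  df <- do.call(rbind, lapply(panel$loci, function(l)
    data.frame(name = l$name, chromosome = l$chromosome,
               positions = paste(l$positions, collapse = "/"),
               rsids = paste(l$rsids, collapse = "/"),
               extent_bp = l$extent_bp)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check published extents against the inclusive-span convention
#'
#' @param panel An `mh_panel`.
#' @return Data frame with one row per locus: `name`, `extent_bp`
#'   (stated), `span_bp` (computed as last - first + 1) and `match`.
#' @export
panel_extent_check <- function(panel) {
  stopifnot(inherits(panel, "mh_panel"))
  out <- do.call(rbind, lapply(panel$loci, function(l) {
    span <- l$positions[length(l$positions)] - l$positions[1L] + 1L
    data.frame(name = l$name, extent_bp = l$extent_bp, span_bp = span,
               match = l$extent_bp == span)
  }))
  rownames(out) <- NULL
  out
}

#' Filter candidate loci by the panel-design criteria
#'
#' Applies the screening rules used to assemble a short, highly
#' polymorphic microhaplotype panel: at least two SNPs per locus, extent
#' strictly below `max_extent_bp`, effective number of alleles strictly
#' above `min_ae`, expected heterozygosity strictly above `min_het`, and
#' adjacent retained loci on the same chromosome strictly more than
#' `min_spacing_bp` apart (distance between first-SNP coordinates). When
#' two loci conflict on spacing the one with the higher Ae is kept, so
#' the filter is deterministic and idempotent.
#'
#' @param stats Data frame with columns `name`, `chromosome`, `position`
#'   (first-SNP coordinate), `n_snps`, `extent_bp`, `ae`, `het`.
#' @param max_extent_bp,min_ae,min_het,min_spacing_bp Thresholds; the
#'   defaults (100 bp, 3.00, 0.65, 5 Mb) are the panel-design values.
#' @return The rows of `stats` that survive, ordered by chromosome and
#'   position.
#' @export
filter_candidates <- function(stats, max_extent_bp = 100, min_ae = 3.00,
                              min_het = 0.65, min_spacing_bp = 5e6) {
  need <- c("name", "chromosome", "position", "n_snps", "extent_bp",
            "ae", "het")
  if (!all(need %in% names(stats)))
    stop("stats must have columns: ", paste(need, collapse = ","))
  if (nrow(stats) == 0L) return(stats)
  if (any(stats$extent_bp < 1) || any(stats$ae < 1) ||
      any(stats$het < 0 | stats$het > 1))
    stop("inconsistent screening stats (extent < 1, ae < 1 or het outside [0,1])")
  keep <- stats$n_snps >= 2L & stats$extent_bp < max_extent_bp &
    stats$ae > min_ae & stats$het > min_het
  stats <- stats[keep, , drop = FALSE]
  if (nrow(stats) == 0L) {
    rownames(stats) <- NULL
    return(stats)
  }
  out <- NULL
  for (chr in unique(stats$chromosome)) {
    s <- stats[stats$chromosome == chr, , drop = FALSE]
    s <- s[order(s$position), , drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(s))) {
      if (length(kept) == 0L) { kept <- i; next }
      last <- kept[length(kept)]
      if (s$position[i] - s$position[last] > min_spacing_bp) {
        kept <- c(kept, i)
      } else if (s$ae[i] > s$ae[last]) {
        kept[length(kept)] <- i   # replace with the higher-Ae locus
      }
    }
    out <- rbind(out, s[kept, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Are per-SNP minor-allele frequencies pairwise distinct?
#'
#' Optional screening predicate: the member SNPs of one locus should have
#' different allele frequencies (identical frequencies suggest redundant,
#' fully linked SNPs). Frequencies are considered different when they
#' differ by more than `tol`.
#'
#' @param mafs Numeric vector of per-SNP minor-allele frequencies.
#' @param tol Tolerance below which two frequencies count as equal.
#' @return `TRUE` iff all pairwise differences exceed `tol`.
#' @export
snp_maf_distinct <- function(mafs, tol = 0.01) {
  stopifnot(is.numeric(mafs), all(mafs >= 0 & mafs <= 1))
  if (length(mafs) < 2L) return(TRUE)
  all(abs(diff(sort(mafs))) > tol)
}
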