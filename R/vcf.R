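#' Extract microhaplotype genotypes from a phased VCF
#'
#' For each sample, the allele characters at the locus' SNP positions are
#' concatenated along each of the two phased haplotype columns, in
#' genomic order, yielding the sample's two microhaplotype alleles. The
#' pair is reported in lexicographic order. Only SNP records are
#' accepted, every listed position must be present, and genotypes must be
#' phased (`|` separator) — there is no imputation and no phasing here.
#'
#' @param vcf Path to a VCF file (plain or bgzipped), or a `vcfR` object.
#' @param locus An [mh_locus()].
#' @return Data frame with columns `sample`, `locus`, `allele1`,
#'   `allele2` (alleles lexicographically ordered).
#' @export
extract_microhap_genotypes <- function(vcf, locus) {
  stopifnot(inherits(locus, "mh_locus"))
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))   # single-record files drop to a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  chrom <- sub("^chr", "", fix[, "CHROM"])
  idx <- vapply(locus$positions, function(p) {
    hit <- which(pos == p & chrom == locus$chromosome)
    if (length(hit) == 0L)
      stop("no variant record at chr", locus$chromosome, ":", p,
           " for locus ", locus$name)
    if (length(hit) > 1L)
      stop("multiple records at chr", locus$chromosome, ":", p)
    hit
  }, integer(1))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix),
                 dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  hap1 <- hap2 <- matrix("", nrow = length(idx), ncol = length(samples))
  for (k in seq_along(idx)) {
    i <- idx[k]
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])
    if (any(nchar(alleles) != 1L) || any(!alleles %in% c("A", "C", "G", "T")))
      stop("non-SNP allele at chr", locus$chromosome, ":", pos[i],
           " (", paste(alleles, collapse = "/"), "): loci are SNP-only")
    g <- gt[i, ]
    bad <- is.na(g) | !grepl("^[0-9]+\\|[0-9]+$", g)
    if (any(bad))
      stop("unphased or missing genotype at chr", locus$chromosome, ":",
           pos[i], " for sample(s) ",
           paste(samples[which(bad)], collapse = ", "))
    parts <- do.call(rbind, strsplit(g, "|", fixed = TRUE))
    code <- matrix(as.integer(parts), ncol = 2L)
    if (any(code + 1L > length(alleles)))
      stop("allele index out of range at chr", locus$chromosome, ":", pos[i])
    hap1[k, ] <- alleles[code[, 1L] + 1L]
    hap2[k, ] <- alleles[code[, 2L] + 1L]
  }
  a1 <- apply(hap1, 2L, paste, collapse = "")
  a2 <- apply(hap2, 2L, paste, collapse = "")
  swap <- a2 < a1
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  data.frame(sample = samples, locus = locus$name,
             allele1 = a1, allele2 = a2, row.names = NULL)
}

#' Write a genotype table
#'
#' Genotype tables are comma-separated with header
#' `sample,locus,allele1,allele2` and lexicographically ordered alleles.
#'
#' @param genotypes Data frame as returned by
#'   [extract_microhap_genotypes()].
#' @param path Output path.
#' @export
write_genotype_table <- function(genotypes, path) {
  genotypes <- check_genotype_table(genotypes)
  utils::write.csv(genotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  check_genotype_table(utils::read.csv(path, colClasses = "character"))
}

# validate + canonicalize allele order within each genotype
check_genotype_table <- function(genotypes) {
  need <- c("sample", "locus", "allele1", "allele2")
  if (!is.data.frame(genotypes) || !all(need %in% names(genotypes)))
    stop("genotype table must have columns: ", paste(need, collapse = ","))
  swap <- genotypes$allele2 < genotypes$allele1
  if (any(swap)) {
    tmp <- genotypes$allele1[swap]
    genotypes$allele1[swap] <- genotypes$allele2[swap]
    genotypes$allele2[swap] <- tmp
  }
  genotypes
}
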