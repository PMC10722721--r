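#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT fields of a VCF 4.x file (via \pkg{vcfR}) into focal-allele copy
#' counts. Multi-allelic records and records with missing REF/ALT are skipped
#' with a message; the focal allele is initialised to ALT at every locus
#' (downstream frequency estimation may re-orient it). Phased (`|`) and
#' unphased (`/`) genotypes are treated identically; half-missing genotypes
#' (e.g. `./1`) are treated as missing.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records.")
  if (!any(grepl("GT", v@gt[, "FORMAT"]))) abort("VCF has no GT field.")
  ok <- !is.na(fix$REF) & !is.na(fix$ALT) &
    !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) > 0 & nchar(fix$ALT) > 0
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    inform(sprintf("read_vcf: skipped %d multi-allelic or incomplete records.", n_skip))
  }
  if (!any(ok)) abort("no biallelic records with complete REF/ALT.")
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  # count ALT allele copies regardless of phasing separator
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  geno <- t(matrix(code(gt), nrow(gt), ncol(gt)))      # samples x loci
  rownames(geno) <- colnames(gt)
  loci <- tibble(
    locus_id = sprintf("%s_%s", fix$CHROM, fix$POS),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, focal = "ALT")
  geno_matrix(geno, loci)
}

#' Write a genotype matrix as a GT-only VCF 4.2 file
#'
#' Loci are written in (chrom, pos) order; missing genotypes as `./.`.
#' Genotype codes are emitted with respect to the original REF/ALT alleles,
#' so loci whose focal allele has been flipped to REF are recoded back —
#' [read_vcf()] then [write_vcf()] round-trips the file content.
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  geno <- gm$geno
  flipped <- gm$loci$focal == "REF"
  geno[, flipped] <- 2L - geno[, flipped, drop = FALSE]
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno), ncol(geno))
  gt_str[is.na(geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridclines",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  body <- if (ncol(geno) > 0) {
    paste(gm$loci$chrom, gm$loci$pos, gm$loci$locus_id, gm$loci$ref,
          gm$loci$alt, ".", "PASS", ".", "GT",
          apply(gt_str, 2L, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ADMIXTURE-style Q matrix
#'
#' @param path whitespace-delimited text, one row per sample, K columns of
#'   ancestry proportions (the layout ADMIXTURE's `.Q` files use).
#' @param sample_ids character vector of sample ids in row order (ADMIXTURE
#'   writes no ids; they come from the accompanying `.fam`/sample file).
#' @return tibble: `sample_id`, `Q1` ... `QK`.
#' @export
read_qmatrix <- function(path, sample_ids) {
  q <- as.matrix(read.table(path, header = FALSE))
  if (nrow(q) != length(sample_ids)) {
    abort("number of Q-matrix rows does not match `sample_ids`.")
  }
  validate_qmatrix(q)
  colnames(q) <- paste0("Q", seq_len(ncol(q)))
  dplyr::bind_cols(tibble(sample_id = sample_ids), as_tibble(q))
}

validate_qmatrix <- function(q) {
  if (any(q < 0 | q > 1)) abort("ancestry proportions must lie in [0, 1].")
  if (any(abs(rowSums(q) - 1) > 1e-6)) {
    abort("Q-matrix rows must sum to 1 (tolerance 1e-6).")
  }
  invisible(q)
}

#' Assign samples to source and test groups from admixture proportions
#'
#' A sample is labelled `S0` when its ancestry proportion for the S0 cluster
#' strictly exceeds `threshold`, `S1` likewise for the S1 cluster, and `TEST`
#' otherwise. The comparison is strict (`> threshold`), so a proportion equal
#' to the threshold goes to `TEST`.
#'
#' @param q tibble from [read_qmatrix()] or [sim_qmatrix()] (`sample_id` plus
#'   `Q*` columns).
#' @param s0_cluster,s1_cluster 1-based indices of the ancestry clusters
#'   representing the two sources; distinct, within K.
#' @param threshold assignment threshold, in `(0.5, 1]`; default 0.99.
#' @return tibble: `sample_id`, `label` in `{S0, S1, TEST}`, with a
#'   `provenance` attribute recording the rule applied.
#' @export
assign_populations <- function(q, s0_cluster, s1_cluster, threshold = 0.99) {
  if (threshold <= 0.5 || threshold > 1) abort("threshold must be in (0.5, 1].")
  qcols <- grep("^Q[0-9]+$", names(q), value = TRUE)
  K <- length(qcols)
  if (s0_cluster == s1_cluster || max(s0_cluster, s1_cluster) > K ||
      min(s0_cluster, s1_cluster) < 1) {
    abort("cluster indices must be distinct and within 1..K.")
  }
  qm <- as.matrix(q[qcols])
  validate_qmatrix(qm)
  label <- dplyr::case_when(
    qm[, s0_cluster] > threshold ~ "S0",
    qm[, s1_cluster] > threshold ~ "S1",
    TRUE ~ "TEST")
  out <- tibble(sample_id = q$sample_id, label = label)
  attr(out, "provenance") <- sprintf(
    "S0: Q%d > %g; S1: Q%d > %g; else TEST", s0_cluster, threshold,
    s1_cluster, threshold)
  out
}

#' Remove loci with low genotype call rate
#'
#' Keeps loci whose fraction of non-missing genotypes is at least `min_rate`
#' (the comparison is `>=`, so exactly 95% call rate passes the default).
#' Samples are never removed.
#'
#' @param gm a [geno_matrix()].
#' @param min_rate minimum call rate in `(0, 1]`; default 0.95.
#' @return filtered `geno_matrix`; the number of dropped loci is messaged.
#' @export
filter_call_rate <- function(gm, min_rate = 0.95) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (min_rate <= 0 || min_rate > 1) abort("min_rate must be in (0, 1].")
  rate <- colMeans(!is.na(gm$geno))
  keep <- rate >= min_rate
  inform(sprintf("filter_call_rate: removed %d of %d loci (call rate < %g).",
                 sum(!keep), length(keep), min_rate))
  subset_loci(gm, gm$loci$locus_id[keep])
}

#' Greedy LD thinning by pairwise genotype correlation
#'
#' Scans loci left to right within each chromosome and drops a locus when its
#' squared Pearson correlation of genotype counts with any already-retained
#' locus within `window_bp` exceeds `max_r2`. Missing genotypes are deleted
#' pairwise. A lightweight utility to reduce linkage disequilibrium before
#' hybrid-index estimation; it is not a reimplementation of plink's
#' VIF-based `--indep` pruner.
#'
#' @param gm a [geno_matrix()].
#' @param window_bp window size in bp (`> 0`).
#' @param max_r2 maximum allowed r-squared, in `(0, 1]`.
#' @return thinned `geno_matrix`.
#' @export
ld_thin <- function(gm, window_bp = 50000, max_r2 = 0.8) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (window_bp <= 0) abort("window_bp must be > 0.")
  if (max_r2 <= 0 || max_r2 > 1) abort("max_r2 must be in (0, 1].")
  loci <- gm$loci
  keep <- rep(TRUE, nrow(loci))
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)
    retained <- integer()
    for (j in idx) {
      near <- retained[loci$pos[j] - loci$pos[retained] < window_bp]
      drop <- FALSE
      for (k in near) {
        r <- suppressWarnings(
          cor(gm$geno[, j], gm$geno[, k], use = "pairwise.complete.obs"))
        if (is.finite(r) && r^2 > max_r2) { drop <- TRUE; break }
      }
      if (drop) keep[j] <- FALSE else retained <- c(retained, j)
    }
  }
  subset_loci(gm, loci$locus_id[keep])
}
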