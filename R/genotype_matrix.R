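#' Construct a genotype matrix
#'
#' The package's one non-tabular container: diploid genotypes coded as copies
#' of the per-locus focal allele (0, 1, 2, or `NA` for missing), with locus
#' metadata alongside. Samples are rows, loci columns.
#'
#' @param geno integer matrix (samples x loci) with values in
#'   `{0, 1, 2, NA}`; rownames are sample ids.
#' @param loci tibble with one row per locus and columns `locus_id`, `chrom`,
#'   `pos` (1-based bp), `ref`, `alt`, and `focal` (`"ALT"` or `"REF"`,
#'   which allele the genotype codes count). Must be sorted by
#'   `(chrom, pos)` with no duplicated `(chrom, pos, ref, alt)`.
#' @return an object of class `geno_matrix`.
#' @seealso [tidy.geno_matrix()] for the long-tibble view, [read_vcf()],
#'   [write_vcf()].
#' @export
geno_matrix <- function(geno, loci) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  loci <- as_tibble(loci)
  needed <- c("locus_id", "chrom", "pos", "ref", "alt", "focal")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols)) {
    abort(paste0("`loci` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (ncol(geno) != nrow(loci)) {
    abort("number of genotype columns must equal number of loci rows.")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("genotype codes must be 0, 1, 2 or NA.")
  }
  if (any(loci$pos < 1L)) abort("positions must be >= 1 (1-based).")
  ord <- order(loci$chrom, loci$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    loci <- loci[ord, ]
    geno <- geno[, ord, drop = FALSE]
  }
  if (anyDuplicated(loci[c("chrom", "pos", "ref", "alt")])) {
    abort("duplicate (chrom, pos, ref, alt) loci are not allowed.")
  }
  if (!all(loci$focal %in% c("ALT", "REF"))) {
    abort("`focal` must be \"ALT\" or \"REF\" for every locus.")
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("sample", seq_len(nrow(geno)))
  }
  colnames(geno) <- loci$locus_id
  structure(list(geno = geno, loci = loci), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d loci (%s)\n",
              nrow(x$geno), ncol(x$geno),
              paste(unique(x$loci$chrom), collapse = ", ")))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Sample ids of a genotype matrix
#' @param gm a `geno_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(gm) rownames(gm$geno)

#' Long-tibble view of a genotype matrix
#'
#' @param x a `geno_matrix`.
#' @param ... unused.
#' @return tibble with columns `sample_id`, `locus_id`, `chrom`, `pos`,
#'   `genotype` (NA where missing).
#' @method tidy geno_matrix
#' @export
tidy.geno_matrix <- function(x, ...) {
  g <- x$geno
  tibble(
    sample_id = rep(rownames(g), times = ncol(g)),
    locus_id = rep(x$loci$locus_id, each = nrow(g)),
    chrom = rep(x$loci$chrom, each = nrow(g)),
    pos = rep(x$loci$pos, each = nrow(g)),
    genotype = as.integer(g)
  )
}

# Internal: subset to a set of locus ids (order preserved as in `gm`).
subset_loci <- function(gm, locus_ids) {
  keep <- gm$loci$locus_id %in% locus_ids
  geno_matrix(gm$geno[, keep, drop = FALSE], gm$loci[keep, ])
}

# Internal: subset to sample ids.
subset_samples <- function(gm, ids) {
  keep <- rownames(gm$geno) %in% ids
  out <- gm
  out$geno <- gm$geno[keep, , drop = FALSE]
  out
}

#' Flip the focal allele at selected loci
#'
#' Recodes genotypes `g -> 2 - g` and toggles the `focal` flag so that
#' "allele frequency" downstream always refers to the focal allele.
#'
#' @param gm a `geno_matrix`.
#' @param locus_ids loci to flip.
#' @return a `geno_matrix` with flipped coding at those loci.
#' @export
flip_focal <- function(gm, locus_ids) {
  idx <- which(gm$loci$locus_id %in% locus_ids)
  gm$geno[, idx] <- 2L - gm$geno[, idx, drop = FALSE]
  gm$loci$focal[idx] <- ifelse(gm$loci$focal[idx] == "ALT", "REF", "ALT")
  gm
}
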