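#' Call steep-cline variants (SCVs)
#'
#' A variant has a significantly steep cline when its posterior mean
#' `ln(v)` strictly exceeds `lnv_threshold` (2.3, i.e. `v > 10`) and its
#' `delta_waic` is strictly below `dwaic_threshold` (-10): steep AND
#' decisively better supported than the neutral `v = 1` model. Each SCV is
#' labelled with its cline-centre class (see [classify_centre()]).
#'
#' @param cline_tbl tibble with columns `locus_id`, `chrom`, `pos`,
#'   `lnv_mean`, `c_mean`, `delta_waic` (e.g. [tidy()] of a full-model
#'   [fit_clines()] joined with [compare_models()]).
#' @param lnv_threshold steepness threshold on `ln(v)` (strict `>`).
#' @param dwaic_threshold WAIC-difference threshold (strict `<`).
#' @param centre_lo,centre_hi centre-class boundaries passed to
#'   [classify_centre()].
#' @return the SCV subset with an added `centre_class` column.
#' @export
identify_scv <- function(cline_tbl, lnv_threshold = 2.3,
                         dwaic_threshold = -10, centre_lo = 0.45,
                         centre_hi = 0.55) {
  tbl <- as_tibble(cline_tbl)
  scv <- tbl %>%
    filter(!is.na(.data$lnv_mean), !is.na(.data$delta_waic),
           .data$lnv_mean > lnv_threshold,
           .data$delta_waic < dwaic_threshold) %>%
    mutate(centre_class = classify_centre(.data$c_mean,
                                          lo = centre_lo, hi = centre_hi))
  scv
}

#' Classify cline centres into introgression-bias groups
#'
#' Centres at or below `lo` are `S1_biased` (gene flow favouring the S1
#' allele into the S0 background), centres at or above `hi` are `S0_biased`,
#' and centres strictly between are `unbiased`. Boundaries are inclusive.
#'
#' @param c cline-centre values in `(0, 1)`; vectorised.
#' @param lo,hi class boundaries (defaults 0.45 and 0.55).
#' @return character vector in `{"S1_biased", "unbiased", "S0_biased"}`.
#' @export
classify_centre <- function(c, lo = 0.45, hi = 0.55) {
  if (any(c <= 0 | c >= 1, na.rm = TRUE)) abort("`c` must be in (0, 1).")
  dplyr::case_when(
    c <= lo ~ "S1_biased",
    c >= hi ~ "S0_biased",
    TRUE ~ "unbiased")
}

#' Pool steep-cline variants into candidate regions
#'
#' Greedy single pass per chromosome over position-sorted SCVs: a region
#' opens at an SCV and extends while the distance between consecutive SCVs is
#' strictly less than `max_gap`; it closes otherwise. Region start/end are
#' the positions of the first and last member SCV (no flanking padding).
#' Regions with fewer than `min_variants` members are discarded.
#'
#' @param scv tibble with columns `chrom`, `pos` (and optionally `lnv_mean`,
#'   `centre_class`).
#' @param max_gap maximum allowed gap between consecutive member SCVs in bp
#'   (strict `<`; default 50 kb).
#' @param min_variants minimum SCVs per region (default 10).
#' @return tibble of regions: `region_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `n_scv`, `mean_lnv`, `centre_class` (the class if all
#'   members share one, otherwise `"any"`).
#' @export
pool_regions <- function(scv, max_gap = 50000, min_variants = 10) {
  scv <- as_tibble(scv) %>% arrange(.data$chrom, .data$pos)
  if (nrow(scv) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_scv = integer(),
                  mean_lnv = numeric(), centre_class = character()))
  }
  scv %>%
    group_by(.data$chrom) %>%
    mutate(new_region = c(TRUE, diff(.data$pos) >= max_gap),
           grp = cumsum(.data$new_region)) %>%
    group_by(.data$chrom, .data$grp) %>%
    summarise(
      start = min(.data$pos), end = max(.data$pos), n_scv = n(),
      mean_lnv = if ("lnv_mean" %in% names(scv)) mean(.data$lnv_mean) else NA_real_,
      centre_class = if ("centre_class" %in% names(scv)) {
        cl <- unique(.data$centre_class)
        if (length(cl) == 1L) cl else "any"
      } else "any",
      .groups = "drop") %>%
    filter(.data$n_scv >= min_variants) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(region_id = sprintf("REG_%04d", row_number())) %>%
    select("region_id", "chrom", "start", "end", "n_scv", "mean_lnv",
           "centre_class")
}

#' Pool regions separately within each cline-centre class
#'
#' Applies [pool_regions()] to the SCVs of each centre class in turn, so a
#' region contains only same-class variants.
#'
#' @inheritParams pool_regions
#' @param scv SCV tibble with a `centre_class` column.
#' @return tibble of regions with the owning `centre_class`.
#' @export
pool_regions_by_centre <- function(scv, max_gap = 50000, min_variants = 10) {
  scv <- as_tibble(scv)
  if (!"centre_class" %in% names(scv)) {
    abort("`scv` must carry a `centre_class` column.")
  }
  out <- purrr::map_dfr(split(scv, scv$centre_class), pool_regions,
                        max_gap = max_gap, min_variants = min_variants)
  if (nrow(out)) {
    out <- out %>%
      arrange(.data$chrom, .data$start) %>%
      mutate(region_id = sprintf("REG_%04d", row_number()))
  }
  out
}

#' Read gene features from a GFF3 file
#'
#' @param path GFF3 file; only rows with feature type `gene` are kept.
#' @return tibble: `gene_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gff_genes <- function(path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("reading GFF3 requires the 'ape' package.")
  }
  g <- ape::read.gff(path, GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  id <- sub(".*(?:ID|Name)=([^;]+).*", "\\1", g$attributes)
  tibble(gene_id = id, chrom = as.character(g$seqid),
         start = as.integer(g$start), end = as.integer(g$end))
}

#' Map SCVs and regions onto gene annotation
#'
#' An SCV lies within a gene when `gene_start <= pos <= gene_end`; a region
#' overlaps a gene when the closed intervals intersect. Overlap is computed
#' with \pkg{IRanges}. Chromosome names must match between the items and the
#' annotation; if none do, a warning is raised and zero overlaps returned.
#'
#' @param items tibble of SCVs (`chrom`, `pos`) or regions
#'   (`chrom`, `start`, `end`).
#' @param genes tibble from [read_gff_genes()] (or with the same columns).
#' @return list with `items` (input plus a `genes` list-column and `n_genes`),
#'   `per_gene` (tibble `gene_id`, `n_items` counting items per gene) and
#'   `frac_in_genes` (fraction of items overlapping at least one gene).
#' @export
map_genes <- function(items, genes) {
  items <- as_tibble(items)
  genes <- as_tibble(genes)
  is_region <- all(c("start", "end") %in% names(items))
  if (!is_region && !"pos" %in% names(items)) {
    abort("`items` needs either `pos` or `start`/`end` columns.")
  }
  if (!any(items$chrom %in% genes$chrom)) {
    warn("no chromosome names shared between items and annotation; zero overlaps.")
  }
  s <- if (is_region) items$start else items$pos
  e <- if (is_region) items$end else items$pos
  hit_lists <- vector("list", nrow(items))
  for (ch in unique(items$chrom)) {
    ii <- which(items$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) { hit_lists[ii] <- list(character()); next }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(s[ii], e[ii]),
      IRanges::IRanges(genes$start[gi], genes$end[gi]))
    hl <- split(genes$gene_id[gi][S4Vectors::subjectHits(ov)],
                factor(S4Vectors::queryHits(ov), levels = seq_along(ii)))
    hit_lists[ii] <- lapply(hl, as.character)
  }
  items$genes <- hit_lists
  items$n_genes <- lengths(hit_lists)
  per_gene <- tibble(gene_id = unlist(hit_lists)) %>%
    count(.data$gene_id, name = "n_items")
  list(items = items, per_gene = per_gene,
       frac_in_genes = mean(items$n_genes > 0))
}

#' Write regions as a BED file
#'
#' Converts 1-based inclusive region coordinates to BED's 0-based half-open
#' convention.
#'
#' @param regions tibble from [pool_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, name = regions$region_id,
                    score = regions$n_scv, class = regions$centre_class)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
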