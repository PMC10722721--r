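#' Build a pipeline run configuration
#'
#' Collects every input path, MCMC setting and threshold of the analysis in
#' one validated list. Defaults are the thresholds used throughout the
#' package: assignment threshold 0.99, call rate 0.95, `ln(v) > 2.3`,
#' `delta_waic < -10`, centre classes at 0.45/0.55, 50-kb region gap with a
#' 10-variant minimum, and the standard chain lengths (hybrid index
#' nitt 2000 / burnin 1000; clines nitt 5000 / burnin 2000). A YAML file with
#' any subset of these keys can be supplied instead of arguments.
#'
#' @param file optional YAML file of configuration keys.
#' @param ... overrides for any configuration key (see Details in the
#'   package vignette): `vcf`, `qmatrix`, `sample_ids`, `annotation`, `gff`,
#'   `recomb_map`, `out_dir`, `s0_cluster`, `s1_cluster`,
#'   `assign_threshold`, `call_rate`, `esth_nitt`, `esth_burnin`,
#'   `cline_nitt`, `cline_burnin`, `seed`, `lnv_threshold`,
#'   `dwaic_threshold`, `centre_lo`, `centre_hi`, `max_gap`, `min_variants`,
#'   `min_count`, `include_source`, `ld_thin`, `ld_window_bp`, `ld_max_r2`,
#'   `resample_freqs`.
#' @return a `run_config` list.
#' @export
run_config <- function(file = NULL, ...) {
  defaults <- list(
    vcf = NULL, qmatrix = NULL, sample_ids = NULL, annotation = NULL,
    gff = NULL, recomb_map = NULL, out_dir = NULL,
    s0_cluster = 1L, s1_cluster = 2L, assign_threshold = 0.99,
    call_rate = 0.95, esth_nitt = 2000L, esth_burnin = 1000L,
    cline_nitt = 5000L, cline_burnin = 2000L, seed = NULL,
    lnv_threshold = 2.3, dwaic_threshold = -10, centre_lo = 0.45,
    centre_hi = 0.55, max_gap = 50000L, min_variants = 10L,
    min_count = 1000L, include_source = TRUE, ld_thin = FALSE,
    ld_window_bp = 50000L, ld_max_r2 = 0.8, resample_freqs = FALSE)
  cfg <- defaults
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(defaults))
    if (length(unknown)) {
      abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
    }
    cfg <- utils::modifyList(cfg, from_file)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, dots)
  if (is.null(cfg$seed)) abort("`seed` is mandatory in a run configuration.")
  cfg$seed <- stopifnot_scalar_seed(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Read a VEP-style consequence annotation table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `consequence`
#'   (one most-severe consequence per variant).
#' @return tibble with an added `locus_id` key (`chrom_pos`).
#' @export
read_annotation <- function(path) {
  a <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
  need <- c("chrom", "pos", "ref", "alt", "consequence")
  if (!all(need %in% names(a))) {
    abort(paste0("annotation needs columns: ", paste(need, collapse = ", ")))
  }
  a$locus_id <- sprintf("%s_%d", a$chrom, a$pos)
  a
}

#' Read a per-sire 1-Mb recombination-count table
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `sire1`, `sire2`.
#' @return tibble of bins.
#' @export
read_recomb_map <- function(path) {
  m <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
  need <- c("chrom", "start", "end", "sire1", "sire2")
  if (!all(need %in% names(m))) {
    abort(paste0("recombination map needs columns: ",
                 paste(need, collapse = ", ")))
  }
  m
}

#' Run the full genomic-cline analysis pipeline
#'
#' Orchestrates: population assignment -> call-rate filter -> source
#' frequency estimation -> credible-interval overlap filter -> (optional LD
#' thinning for) hybrid-index estimation -> full and reduced cline fits ->
#' WAIC model comparison -> SCV calling -> region pooling (overall and per
#' centre class) -> association statistics where the optional annotation,
#' GFF3 and recombination-map inputs are present. Inputs may be given as
#' file paths in the configuration or as in-memory objects. All stages are
#' seeded from `config$seed`; identical configurations give identical
#' outputs. Writes TSV/BED outputs plus a manifest when `out_dir` is set.
#'
#' @param config a [run_config()].
#' @param genotypes optional [geno_matrix()] (else read from `config$vcf`).
#' @param assignments optional assignment tibble (else derived from the
#'   Q-matrix inputs).
#' @return a `pipeline_result` list with elements `assignments`, `freqs`,
#'   `retained`, `h_fit`, `cline_full`, `cline_reduced`, `cline_tbl` (full
#'   fit joined with `delta_waic` and alleles), `scv`, `regions`,
#'   `regions_by_centre`, `genes` (or NULL), `assoc` (list of association
#'   results computed from available inputs) and `manifest`.
#' @export
run_pipeline <- function(config, genotypes = NULL, assignments = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  gm <- genotypes %||% stage("read_vcf", read_vcf(config$vcf))
  if (is.null(assignments)) {
    assignments <- stage("assign", {
      sample_ids <- readLines(config$sample_ids)
      q <- read_qmatrix(config$qmatrix, sample_ids)
      assign_populations(q, config$s0_cluster, config$s1_cluster,
                         config$assign_threshold)
    })
  }
  gm <- stage("call_rate", filter_call_rate(gm, config$call_rate))
  sf <- stage("source_freqs",
              estimate_source_freqs(gm, assignments))
  gm <- sf$genotypes
  retained <- stage("ci_overlap", filter_ci_overlap(sf$freqs))
  if (nrow(retained) == 0) abort("pipeline stage 'ci_overlap' retained no loci.")

  h_loci <- retained
  if (isTRUE(config$ld_thin)) {
    thinned <- stage("ld_thin", {
      gm_r <- subset_loci(gm, retained$locus_id)
      ld_thin(gm_r, config$ld_window_bp, config$ld_max_r2)
    })
    h_loci <- retained[retained$locus_id %in% thinned$loci$locus_id, ]
  }
  h_fit <- stage("esth", esth(
    gm, h_loci, assignments, nitt = config$esth_nitt,
    burnin = config$esth_burnin, seed = config$seed,
    resample_freqs = config$resample_freqs))

  cline_full <- stage("cline_full", fit_clines(
    gm, h_fit, retained, assignments, nitt = config$cline_nitt,
    burnin = config$cline_burnin, fix_v = FALSE,
    include_source = config$include_source, seed = config$seed))
  cline_reduced <- stage("cline_reduced", fit_clines(
    gm, h_fit, retained, assignments, nitt = config$cline_nitt,
    burnin = config$cline_burnin, fix_v = TRUE,
    include_source = config$include_source, seed = config$seed + 1L))
  dw <- stage("compare_models", compare_models(cline_full, cline_reduced))

  cline_tbl <- tidy(cline_full) %>%
    left_join(select(dw, "locus_id", "waic_reduced", "delta_waic"),
              by = "locus_id") %>%
    left_join(select(gm$loci, "locus_id", "ref", "alt"), by = "locus_id")

  scv <- stage("scv", identify_scv(
    cline_tbl, lnv_threshold = config$lnv_threshold,
    dwaic_threshold = config$dwaic_threshold,
    centre_lo = config$centre_lo, centre_hi = config$centre_hi))
  regions <- stage("regions", pool_regions(
    scv, max_gap = config$max_gap, min_variants = config$min_variants))
  regions_by_centre <- stage("regions_by_centre", pool_regions_by_centre(
    scv, max_gap = config$max_gap, min_variants = config$min_variants))

  genes <- NULL
  if (!is.null(config$gff)) {
    genes <- stage("map_genes", {
      ann <- read_gff_genes(config$gff)
      list(scv = map_genes(scv, ann),
           regions = map_genes(regions, ann))
    })
  }

  assoc <- list()
  if (!is.null(config$annotation)) {
    assoc <- stage("assoc_annotation", {
      ann <- read_annotation(config$annotation)
      c(assoc, list(
        effect = tryCatch(
          effect_regression(cline_tbl, ann, min_count = config$min_count),
          error = function(e) NULL),
        snp_indel = tryCatch(snp_indel_test(cline_tbl),
                             error = function(e) NULL)))
    })
  } else {
    inform("run_pipeline: no annotation input; variant-effect statistics skipped.")
  }
  if (!is.null(config$recomb_map)) {
    assoc <- stage("assoc_recomb", {
      map <- if (is.character(config$recomb_map)) {
        read_recomb_map(config$recomb_map)
      } else as_tibble(config$recomb_map)
      cl <- classify_recomb(map, variants = cline_tbl)
      c(assoc, list(recomb = tryCatch(
        recomb_category_regression(
          tibble(response = cl$variants$lnv_mean,
                 category = cl$variants$category)),
        error = function(e) {
          inform(paste0("run_pipeline: recombination contrast skipped (",
                        conditionMessage(e), ")"))
          NULL
        })))
    })
  }

  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("hybridclines")),
    n_samples = nrow(gm$geno),
    counts = list(
      loci_input = nrow(sf$freqs), loci_retained = nrow(retained),
      loci_hybrid_index = nrow(h_loci), loci_fitted = nrow(cline_tbl),
      n_scv = nrow(scv), n_regions = nrow(regions),
      n_regions_by_centre = nrow(regions_by_centre)))

  out <- list(assignments = assignments, freqs = sf$freqs,
              retained = retained, h_fit = h_fit, cline_full = cline_full,
              cline_reduced = cline_reduced, cline_tbl = cline_tbl,
              scv = scv, regions = regions,
              regions_by_centre = regions_by_centre, genes = genes,
              assoc = assoc, manifest = manifest)
  class(out) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) write.table(
      x, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(sf$freqs, "source_freqs.tsv")
    wt(tidy(h_fit), "hybrid_index.tsv")
    wt(cline_tbl, "cline_fits.tsv")
    wt(select(scv, -dplyr::any_of("genes")), "scv.tsv")
    wt(regions, "regions.tsv")
    write_regions_bed(regions, file.path(config$out_dir, "regions.bed"))
    writeLines(yaml::as.yaml(manifest),
               file.path(config$out_dir, "manifest.yaml"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest$counts
  cat(sprintf(paste0("<pipeline_result> %d loci in, %d retained, %d fitted; ",
                     "%d SCVs, %d regions\n"),
              m$loci_input, m$loci_retained, m$loci_fitted, m$n_scv,
              m$n_regions))
  invisible(x)
}

#' Plot a pipeline result: cline steepness along the genome with regions
#'
#' Manhattan-style view of posterior mean `ln(v)` against position, the
#' steep-cline threshold, and the pooled candidate regions shaded.
#'
#' @param object a `pipeline_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, ...) {
  d <- dplyr::filter(object$cline_tbl, .data$flag == "ok")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6,
                                       y = .data$lnv_mean)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.7) +
    ggplot2::geom_hline(yintercept = object$manifest$config$lnv_threshold,
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "posterior mean ln(v)") +
    ggplot2::theme_minimal()
  if (nrow(object$regions)) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE)
  }
  p
}

#' Compare two pipeline runs (e.g. alternative S1 source choices)
#'
#' Reports the SCVs shared between two runs (keyed by locus), the shared
#' count as a percentage of each run's SCV total, the candidate regions that
#' intersect by at least one bp (again with each run's own denominator), and
#' the Pearson correlation of `ln(v)` over shared fitted loci.
#'
#' @param run_a,run_b `pipeline_result` objects.
#' @return list: `scv_overlap` (tibble `n_shared`, `n_a`, `n_b`, `pct_a`,
#'   `pct_b`), `region_overlap` (same shape), `lnv_correlation`.
#' @export
compare_approaches <- function(run_a, run_b) {
  key_a <- run_a$scv$locus_id; key_b <- run_b$scv$locus_id
  shared <- intersect(key_a, key_b)
  scv_overlap <- tibble(
    n_shared = length(shared), n_a = length(key_a), n_b = length(key_b),
    pct_a = 100 * length(shared) / max(length(key_a), 1L),
    pct_b = 100 * length(shared) / max(length(key_b), 1L))

  ra <- run_a$regions; rb <- run_b$regions
  inter <- 0L
  hit_b <- rep(FALSE, nrow(rb))
  for (i in seq_len(nrow(ra))) {
    ov <- rb$chrom == ra$chrom[i] & rb$start <= ra$end[i] & rb$end >= ra$start[i]
    if (any(ov)) { inter <- inter + 1L; hit_b <- hit_b | ov }
  }
  region_overlap <- tibble(
    n_a_overlapping = inter, n_b_overlapping = sum(hit_b),
    n_a = nrow(ra), n_b = nrow(rb),
    pct_a = 100 * inter / max(nrow(ra), 1L),
    pct_b = 100 * sum(hit_b) / max(nrow(rb), 1L))

  both <- dplyr::inner_join(
    select(run_a$cline_tbl, "locus_id", lnv_a = "lnv_mean"),
    select(run_b$cline_tbl, "locus_id", lnv_b = "lnv_mean"),
    by = "locus_id") %>%
    filter(is.finite(.data$lnv_a), is.finite(.data$lnv_b))
  if (nrow(both) < 3) {
    warn("fewer than 3 shared fitted loci; correlation not computed.")
    r <- NA_real_
  } else {
    r <- correlate(both$lnv_a, both$lnv_b)
  }
  list(scv_overlap = scv_overlap, region_overlap = region_overlap,
       lnv_correlation = r)
}
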