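#' Default pipeline configuration
#'
#' Bundles every tunable constant of the end-to-end synthetic
#' reproduction: the simulated colony (founder pool and strain mosaics),
#' the segmentation rule (>= 20 supporting variants, gaps < 100
#' non-SDP variants), the HMM (error rate 0.01, 0.5 cM grid), the
#' genome-wide significance threshold (|z| > 3.89, i.e. P < 1e-4), the
#' shared/non-shared thresholds (1e-4 / 1e-8 / 0.05), the FDR level and
#' the probe call-rate filter.  The configuration round-trips losslessly
#' through JSON via [write_config()] / [read_config()].
#'
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param ... Named overrides replacing elements of the default list
#'   (partial lists are merged one level deep).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    founders = list(n_founders = 4L,
                    chrom_lengths = c(chr1 = 3e7, chr2 = 2e7),
                    variant_density = 150, alt_freq = 0.3),
    strains = list(n_strains = 13L, mean_block_cM = 15, cM_per_Mb = 1),
    segmentation = list(min_run = 20L, max_gap = 100L),
    crosses = list(
      list(type = "F2", n = 250L),
      list(type = "F2", n = 250L)),
    marker_spacing_cM = 10,
    qtls = list(),          # list of list(chrom, pos_cM, frac_var)
    hmm = list(error_rate = 0.01, grid_step = 0.5),
    expression = list(n_probes = 400L, n_cis = 0L, effect = 1,
                      n_replicates = 4L, noise_sd = 0.3, baseline = 8),
    thresholds = list(z = 3.89, shared_p = 1e-4, nonshared_p = 1e-8,
                      other_p = 0.05, fdr = 0.05, call_rate = 0.5))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
        !is.null(names(dots[[nm]])))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(th$z > 0, th$shared_p > 0, th$shared_p < 1,
            th$nonshared_p > 0, th$nonshared_p <= th$shared_p,
            th$other_p > 0, th$other_p < 1,
            th$fdr > 0, th$fdr < 1,
            th$call_rate >= 0, th$call_rate <= 1,
            cfg$hmm$error_rate >= 0, cfg$hmm$error_rate < 0.5,
            cfg$hmm$grid_step > 0,
            cfg$segmentation$min_run >= 2, cfg$segmentation$max_gap >= 1)
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  # keep chromosome names: serialize the length vector as a JSON object
  cfg$founders$chrom_lengths <- as.list(cfg$founders$chrom_lengths)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  raw$founders$chrom_lengths <- unlist(raw$founders$chrom_lengths)
  do.call(pipeline_config, c(list(seed = raw$seed),
                             raw[setdiff(names(raw), "seed")]))
}

# deterministic stage seeds below 2^31
stage_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2000000011L

#' Run the end-to-end synthetic reproduction pipeline
#'
#' Chains the four analysis stages on simulated data: (1) founder pool and
#' inbred-strain mosaics; (2) ancestral haplotype map (SDPs, segments,
#' region tiling, pairwise diversity of the two focal strains); (3)
#' per-cross genome scans (HMM posteriors, additive score test on
#' inverse-normal phenotypes, sex strata) combined by fixed-effect
#' meta-analysis; (4) cis-driven expression, two inter-strain
#' comparisons, shared/non-shared classification and cis annotation.
#' Fully reproducible for a given config.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, the VCF, segment BED,
#'   scan TSV, expression TSVs and a JSON report are written there.
#' @return A `pipeline_report` list with stage summaries.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  validate_config(cfg)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  ## stage 1: simulate colony
  pool <- do.call(simulate_founder_pool,
                  c(cfg$founders, list(seed = stage_seed(cfg$seed, 1L))))
  sim <- simulate_inbred_strains(pool, cfg$strains$n_strains,
                                 cfg$strains$mean_block_cM,
                                 cfg$strains$cM_per_Mb,
                                 seed = stage_seed(cfg$seed, 2L))
  geno <- sim$genotypes
  if (!is.null(out_dir))
    write_genotypes_vcf(geno, path("strains.vcf"),
                        chrom_lengths = cfg$founders$chrom_lengths)

  ## stage 2: haplotype map
  params <- segmentation_params(cfg$segmentation$min_run,
                                cfg$segmentation$max_gap)
  segs <- detect_segments(geno, params = params)
  rmap <- build_region_map(segs, cfg$founders$chrom_lengths)
  focal <- geno$strains[1:2]
  ref_strain <- geno$strains[3L]
  div <- pairwise_diversity(segs, focal[1L], focal[2L],
                            cfg$founders$chrom_lengths)
  if (!is.null(out_dir)) {
    write_segments_bed(segs, path("segments.bed"))
    write_tsv_commented(rmap$regions, path("regions.tsv"),
                        "haplotype-class regions")
  }

  ## stage 3: linkage scans + meta-analysis
  chroms <- names(cfg$founders$chrom_lengths)
  len_cM <- cfg$founders$chrom_lengths / 1e6 * cfg$strains$cM_per_Mb
  markers <- do.call(rbind, lapply(chroms, function(ch) {
    cM <- seq(0, len_cM[[ch]], by = cfg$marker_spacing_cM)
    data.frame(marker = sprintf("%s_m%02d", ch, seq_along(cM)),
               chrom = ch, cM = cM, stringsAsFactors = FALSE)
  }))
  qtls <- lapply(cfg$qtls, function(q)
    qtl_spec(q$chrom, q$pos_cM, q$frac_var))
  hmm <- hmm_params(cfg$hmm$error_rate, cfg$hmm$grid_step)
  strata <- list()
  for (i in seq_along(cfg$crosses)) {
    cr <- cfg$crosses[[i]]
    cross <- simulate_cross(cr$type, cr$n, markers, qtls,
                            seed = stage_seed(cfg$seed, 10L + i))
    grid <- genotype_posteriors(cross, hmm)
    for (sx in unique(cross$sex)) {       # within-stratum normalization
      idx <- cross$sex == sx
      y <- rep(NA_real_, length(idx))
      y[idx] <- inverse_normal_transform(cross$phenotypes$pheno[idx])
      sub <- grid
      sub$dosage <- grid$dosage[idx, , drop = FALSE]
      sub$prob <- grid$prob[idx, , , drop = FALSE]
      strata[[paste0("cross", i, "_", sx)]] <-
        score_test(sub, y[idx])
    }
  }
  meta <- meta_scan(strata, threshold_z = cfg$thresholds$z)
  if (!is.null(out_dir))
    write_tsv_commented(meta, path("meta_scan.tsv"), "meta-analysis scan")

  ## stage 4: expression + DE classification
  ecfg <- cfg$expression
  set.seed(stage_seed(cfg$seed, 30L))
  probe_chrom <- sample(chroms, ecfg$n_probes, replace = TRUE)
  probe_pos <- vapply(probe_chrom, function(ch)
    sample.int(cfg$founders$chrom_lengths[[ch]], 1L), 0L)
  effect <- rep(0, ecfg$n_probes)
  if (ecfg$n_cis > 0L) {
    # plant effects on probes whose first covering segment (the one the
    # expression simulator uses) splits both comparison pairs
    catalog <- attr(segs, "catalog")
    first_seg <- vapply(seq_len(ecfg$n_probes), function(i) {
      hit <- which(segs$chrom == probe_chrom[i] &
                   segs$start <= probe_pos[i] &
                   segs$end >= probe_pos[i])
      if (length(hit)) hit[1L] else NA_integer_
    }, 0L)
    splits <- function(seg_i, a, b)
      !is.na(seg_i) & catalog[segs$sdp[pmax(seg_i, 1L)], a] !=
                      catalog[segs$sdp[pmax(seg_i, 1L)], b]
    cand <- which(splits(first_seg, focal[1L], ref_strain) &
                  splits(first_seg, focal[2L], ref_strain))
    planted <- cand[seq_len(min(ecfg$n_cis, length(cand)))]
    effect[planted] <- ecfg$effect
  }
  probes <- data.frame(probe = sprintf("P%04d", seq_len(ecfg$n_probes)),
                       chrom = probe_chrom, pos = probe_pos,
                       effect = effect, stringsAsFactors = FALSE)
  em <- simulate_expression(geno, segs, probes, ecfg$n_replicates,
                            ecfg$noise_sd, ecfg$baseline,
                            seed = stage_seed(cfg$seed, 31L))
  em <- filter_probes(em, cfg$thresholds$call_rate)
  em <- quantile_normalize(em)
  de_a <- differential_expression(em, focal[1L], ref_strain)
  de_b <- differential_expression(em, focal[2L], ref_strain)
  q_a <- bh_fdr(de_a$p); q_b <- bh_fdr(de_b$p)
  category <- classify_shared_nonshared(
    de_a, de_b, cfg$thresholds$shared_p, cfg$thresholds$nonshared_p,
    cfg$thresholds$other_p)
  de <- data.frame(probe = de_a$probe,
                   log2fc_A = de_a$log2fc, p_A = de_a$p, q_A = q_a,
                   log2fc_B = de_b$log2fc, p_B = de_b$p, q_B = q_b,
                   category = category, stringsAsFactors = FALSE)
  de <- annotate_cis(de, em$probes, segs, focal[1L], ref_strain)
  if (!is.null(out_dir)) {
    write_expression_tsv(em, path("expression.tsv"), path("probes.tsv"),
                         path("samples.tsv"))
    write_tsv_commented(de, path("de_results.tsv"), "DE classification")
  }

  sig <- meta[meta$significant, , drop = FALSE]
  report <- list(
    seed = cfg$seed,
    n_variants = nrow(geno$variants),
    n_sdps = nrow(attr(segs, "catalog")),
    n_segments = nrow(segs),
    n_regions = nrow(rmap$regions),
    class_length_bp = stats::setNames(as.list(rmap$summary$bp),
                                      rmap$summary$class_paper),
    diversity_focal_pair = div,
    n_loci = nrow(meta),
    n_significant_loci = nrow(sig),
    significant_loci = sig[, c("chrom", "cM", "z")],
    de_category_counts = as.list(table(de$category)),
    cis_summary = attr(de, "cis_summary"),
    n_de_q05_A = sum(q_a < cfg$thresholds$fdr, na.rm = TRUE),
    n_de_q05_B = sum(q_b < cfg$thresholds$fdr, na.rm = TRUE))
  if (!is.null(out_dir))
    jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed ", x$seed, "\n",
      "  segments: ", x$n_segments, "  regions: ", x$n_regions, "\n",
      "  focal-pair diversity: ", signif(x$diversity_focal_pair, 3), "\n",
      "  significant loci: ", x$n_significant_loci, "/", x$n_loci, "\n",
      "  DE categories: ",
      paste(names(x$de_category_counts), unlist(x$de_category_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
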