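#' Simulate a pool of ancestral founder haplotypes
#'
#' Draws a set of biallelic variant sites along one or more chromosomes and
#' assigns each founder haplotype an allele at every site.  The founders stand
#' in for the ancestral chromosomes of an outbred colony from which inbred
#' strains were later derived; inbred strains are generated as homozygous
#' mosaics of these founders by [simulate_inbred_strains()].
#'
#' Variant counts per chromosome are Poisson with mean
#' `length/1e6 * variant_density`; founder alleles are i.i.d.
#' Bernoulli(`alt_freq`) across founders and sites (no founder linkage
#' disequilibrium beyond the mosaic structure added downstream).
#'
#' @param n_founders Number of ancestral haplotypes (>= 2).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Unnamed vectors are named `chr1`, `chr2`, ...
#' @param variant_density Expected variants per Mb (> 0).
#' @param alt_freq Probability a founder carries the alternate allele.
#' @param seed Optional integer seed (`set.seed`) for reproducibility.
#'
#' @return A `founder_pool`: list with `n_founders`, `variants`
#'   (`chrom`, `pos`, `ref`, `alt`), `alleles` (founders x variants 0/1
#'   matrix), `monomorphic` (logical per variant), `chrom_lengths`.
#' @seealso [simulate_inbred_strains()]
#' @export
simulate_founder_pool <- function(n_founders, chrom_lengths,
                                  variant_density, alt_freq = 0.3,
                                  seed = NULL) {
  if (n_founders < 2) stop("n_founders must be >= 2", call. = FALSE)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0",
                                    call. = FALSE)
  if (variant_density <= 0) stop("variant_density must be > 0",
                                 call. = FALSE)
  if (alt_freq <= 0 || alt_freq >= 1) stop("alt_freq must be in (0,1)",
                                           call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))

  bases <- c("A", "C", "G", "T")
  per_chrom <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n <- stats::rpois(1L, len / 1e6 * variant_density)
    n <- min(n, len)                      # cannot exceed distinct positions
    pos <- sort(sample.int(len, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    data.frame(chrom = rep(ch, n), pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  variants <- do.call(rbind, per_chrom)
  n_var <- nrow(variants)
  alleles <- matrix(stats::rbinom(n_founders * n_var, 1L, alt_freq),
                    nrow = n_founders)
  rownames(alleles) <- paste0("F", seq_len(n_founders))
  mono <- apply(alleles, 2L, function(col) length(unique(col)) == 1L)
  structure(list(n_founders = n_founders, variants = variants,
                 alleles = alleles, monomorphic = mono,
                 chrom_lengths = chrom_lengths),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat("<founder_pool> ", x$n_founders, " founders, ", nrow(x$variants),
      " variants (", sum(x$monomorphic), " monomorphic) on ",
      length(x$chrom_lengths), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Simulate inbred strains as homozygous founder mosaics
#'
#' Each strain's genome is a mosaic of founder haplotypes: breakpoints are a
#' Poisson process with rate `1/mean_block_cM` along the genetic length of
#' each chromosome (genetic length in cM = physical length in Mb times
#' `cM_per_Mb`), and each mosaic block is assigned a founder uniformly at
#' random.  Strains are fully homozygous, so the genotype call at a variant
#' is the allele of the founder owning that position.
#'
#' The returned `true_segments` record every drawn breakpoint even when two
#' adjacent blocks happen to carry the same founder, so the realized
#' breakpoint count is directly comparable to the Poisson rate.
#'
#' @param pool A `founder_pool` from [simulate_founder_pool()].
#' @param n_strains Number of inbred strains (>= 2).
#' @param mean_block_cM Mean mosaic block length in cM (> 0).
#' @param cM_per_Mb Fixed genetic-to-physical conversion (default 1 cM/Mb).
#' @param seed Optional integer seed.
#'
#' @return List with `genotypes` (a [genotype_table()]; monomorphic founder
#'   sites are dropped, mirroring the upstream retention of biallelic
#'   variants) and `true_segments` (`data.frame` strain/chrom/start/end/
#'   founder tiling each chromosome).
#' @export
simulate_inbred_strains <- function(pool, n_strains, mean_block_cM,
                                    cM_per_Mb = 1, seed = NULL) {
  if (!inherits(pool, "founder_pool")) stop("pool must be a founder_pool",
                                            call. = FALSE)
  if (nrow(pool$variants) == 0L) stop("empty founder pool", call. = FALSE)
  if (n_strains < 2) stop("n_strains must be >= 2", call. = FALSE)
  if (mean_block_cM <= 0) stop("mean_block_cM must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  strains <- paste0("S", seq_len(n_strains))
  chroms <- names(pool$chrom_lengths)
  segs <- list()
  calls <- matrix(0L, nrow = n_strains, ncol = nrow(pool$variants))

  for (s in seq_len(n_strains)) {
    # one ancestral founder carried across chromosome boundaries: in the
    # zero-recombination limit a strain is exactly one founder genome-wide
    cur <- sample.int(pool$n_founders, 1L)
    for (ch in chroms) {
      len_bp <- pool$chrom_lengths[[ch]]
      len_cM <- len_bp / 1e6 * cM_per_Mb
      # Poisson process: exponential inter-breakpoint distances in cM
      bp_cM <- numeric(0)
      pos <- stats::rexp(1L, rate = 1 / mean_block_cM)
      while (pos < len_cM) {
        bp_cM <- c(bp_cM, pos)
        pos <- pos + stats::rexp(1L, rate = 1 / mean_block_cM)
      }
      bp_bp <- floor(bp_cM / cM_per_Mb * 1e6)
      bp_bp <- unique(bp_bp[bp_bp >= 1 & bp_bp < len_bp])
      starts <- c(1, bp_bp + 1)
      ends <- c(bp_bp, len_bp)
      founders <- c(cur, sample.int(pool$n_founders, length(bp_bp),
                                    replace = TRUE))
      cur <- founders[length(founders)]
      segs[[length(segs) + 1L]] <- data.frame(
        strain = strains[s], chrom = ch, start = starts, end = ends,
        founder = founders, stringsAsFactors = FALSE)
      idx <- which(pool$variants$chrom == ch)
      if (length(idx)) {
        block <- findInterval(pool$variants$pos[idx], starts)
        calls[s, idx] <- pool$alleles[cbind(founders[block], idx)]
      }
    }
  }
  keep <- !pool$monomorphic
  gt <- genotype_table(strains, pool$variants[keep, , drop = FALSE],
                       calls[, keep, drop = FALSE])
  list(genotypes = gt,
       true_segments = do.call(rbind, segs))
}

#' Specify a planted additive QTL
#'
#' @param chrom Chromosome id (must match the cross marker map).
#' @param pos_cM Position in cM.
#' @param frac_var Fraction of total phenotypic variance explained, in
#'   `[0, 1)`.  The additive allelic effect is derived from this fraction
#'   under the coding used by [simulate_cross()] with total variance 1.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(chrom, pos_cM, frac_var) {
  if (frac_var < 0 || frac_var >= 1)
    stop("frac_var must be in [0, 1)", call. = FALSE)
  structure(list(chrom = as.character(chrom), pos_cM = pos_cM,
                 frac_var = frac_var), class = "qtl_spec")
}

# Haldane map function: cM distance -> recombination fraction (no
# interference).
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# Simulate one gamete's allele chain (0/1) for n individuals over loci with
# recombination fractions r between consecutive loci.
sim_gamete <- function(n, r_vec) {
  L <- length(r_vec) + 1L
  g <- matrix(0L, n, L)
  g[, 1L] <- stats::rbinom(n, 1L, 0.5)
  for (l in seq_along(r_vec)) {
    flip <- stats::runif(n) < r_vec[l]
    g[, l + 1L] <- ifelse(flip, 1L - g[, l], g[, l])
  }
  g
}

#' Simulate an experimental cross with planted additive QTLs
#'
#' Genotypes are generated by Markov simulation of meioses along each
#' chromosome using the Haldane map function (no interference).  An F2
#' individual receives two independent recombinant gametes; a backcross
#' individual receives one recombinant gamete on a fixed `A` background.
#' The phenotype is the sum of additive QTL effects (genotypes coded
#' -1/0/+1 for F2 and -1/2,+1/2 for backcross), a polygenic normal deviate,
#' and a residual whose standard deviation is chosen so that each QTL's
#' stated variance fraction holds with total phenotypic variance 1.
#'
#' The allele raising the trait (positive effect) is the `B` allele, i.e.
#' the hypertensive-strain allele under the package's sign convention.
#'
#' @param cross_type `"F2"` or `"backcross"`.
#' @param n_individuals Number of individuals (>= 1).
#' @param markers `data.frame` with columns `marker`, `chrom`, `cM`
#'   (non-decreasing within chromosome).
#' @param qtls List of [qtl_spec()] objects; variance fractions plus
#'   `polygenic_sd^2` must sum to < 1.
#' @param polygenic_sd Standard deviation of the polygenic term (>= 0).
#' @param missing_rate Fraction of marker genotypes masked to `NA`.
#' @param seed Optional integer seed.
#'
#' @return A `cross_dataset`: list with `cross_type`, `markers`, `geno`
#'   (individuals x markers character matrix `AA`/`AB`/`BB`/`NA`), `sex`
#'   (alternating `"M"`/`"F"`), and `phenotypes` (`data.frame` with column
#'   `pheno`).
#' @export
simulate_cross <- function(cross_type = c("F2", "backcross"),
                           n_individuals, markers, qtls = list(),
                           polygenic_sd = 0, missing_rate = 0,
                           seed = NULL) {
  cross_type <- match.arg(cross_type)
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chrom", "cM") %in% names(markers)))
  markers$chrom <- as.character(markers$chrom)
  for (ch in unique(markers$chrom)) {
    if (is.unsorted(markers$cM[markers$chrom == ch]))
      stop("marker cM positions must be non-decreasing within chromosome ",
           ch, call. = FALSE)
  }
  if (length(qtls)) {
    if (!all(vapply(qtls, inherits, TRUE, "qtl_spec")))
      stop("qtls must be a list of qtl_spec objects", call. = FALSE)
    off_map <- !vapply(qtls, `[[`, "", "chrom") %in% markers$chrom
    if (any(off_map))
      stop("QTL chromosome not covered by the marker map", call. = FALSE)
  }
  fracs <- vapply(qtls, `[[`, 0, "frac_var")
  resid_var <- 1 - sum(fracs) - polygenic_sd^2
  if (resid_var <= 0)
    stop("QTL variance fractions plus polygenic variance must sum to < 1",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  dose_var <- if (cross_type == "F2") 0.5 else 0.25
  effects <- sqrt(fracs / dose_var)
  n <- n_individuals
  pheno <- stats::rnorm(n, 0, polygenic_sd) +
    stats::rnorm(n, 0, sqrt(resid_var))

  geno <- matrix(NA_character_, n, nrow(markers),
                 dimnames = list(NULL, markers$marker))
  for (ch in unique(markers$chrom)) {
    m_idx <- which(markers$chrom == ch)
    q_here <- which(vapply(qtls, function(q) q$chrom == ch, TRUE))
    loci_cM <- c(markers$cM[m_idx],
                 vapply(qtls[q_here], `[[`, 0, "pos_cM"))
    kind <- c(rep("m", length(m_idx)), rep("q", length(q_here)))
    ord <- order(loci_cM)
    loci_cM <- loci_cM[ord]; kind <- kind[ord]
    src <- c(m_idx, q_here)[ord]
    r_vec <- haldane_r(diff(loci_cM))
    g1 <- sim_gamete(n, r_vec)
    g2 <- if (cross_type == "F2") sim_gamete(n, r_vec)
          else matrix(0L, n, length(loci_cM))
    dose <- g1 + g2                       # count of B alleles
    is_m <- kind == "m"
    codes <- c("AA", "AB", "BB")
    geno[, src[is_m]] <- matrix(codes[dose[, is_m, drop = FALSE] + 1L],
                                nrow = n)
    for (k in which(!is_m)) {
      coded <- if (cross_type == "F2") dose[, k] - 1 else dose[, k] - 0.5
      pheno <- pheno + effects[src[k]] * coded
    }
  }
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA_character_
  structure(list(cross_type = cross_type, markers = markers, geno = geno,
                 sex = rep_len(c("M", "F"), n),
                 phenotypes = data.frame(pheno = pheno)),
            class = "cross_dataset")
}

#' @export
print.cross_dataset <- function(x, ...) {
  cat("<cross_dataset> ", x$cross_type, ", ", nrow(x$geno),
      " individuals x ", ncol(x$geno), " markers, phenotypes: ",
      paste(names(x$phenotypes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate probe-level expression with cis effects tied to haplotype state
#'
#' Probe intensity for a sample of strain `s` is
#' `baseline + effect * h(s) + N(0, noise_sd)`, where `h(s)` is the strain's
#' haplotype class (the 0/1 SDP allele) at the probe position under the
#' first haplotype segment covering the probe.  Probes outside every
#' segment receive no genetic effect regardless of their stated effect
#' size, emulating purely cis-driven expression differences.
#'
#' @param geno A [genotype_table()] supplying the strain panel.
#' @param segments A `hap_segments` object (see [detect_segments()]) whose
#'   SDP catalog covers the same strains.
#' @param probes `data.frame` with columns `probe`, `chrom`, `pos`,
#'   `effect` (log2 fold change per haplotype-class difference; 0 for
#'   background probes).
#' @param n_replicates Arrays per strain (>= 2; downstream tests need
#'   within-group variance).
#' @param noise_sd Standard deviation of array noise on the log2 scale.
#' @param baseline Baseline log2 intensity (default 8).
#' @param seed Optional integer seed.
#'
#' @return An [expression_matrix()] with one sample per strain x replicate.
#' @export
simulate_expression <- function(geno, segments, probes, n_replicates,
                                noise_sd, baseline = 8, seed = NULL) {
  stopifnot(inherits(geno, "genotype_table"))
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "chrom", "pos", "effect") %in% names(probes)))
  known_chroms <- unique(geno$variants$chrom)
  if (!all(probes$chrom %in% known_chroms))
    stop("every probe must lie on a chromosome of the genotype table",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  catalog <- attr(segments, "catalog")
  strains <- geno$strains
  n_probe <- nrow(probes); n_strain <- length(strains)
  # haplotype class (0/1 SDP allele) per probe x strain; 0 outside segments
  hclass <- matrix(0L, n_probe, n_strain)
  if (!is.null(segments) && nrow(segments) > 0L) {
    for (i in seq_len(n_probe)) {
      hit <- which(segments$chrom == probes$chrom[i] &
                   segments$start <= probes$pos[i] &
                   segments$end >= probes$pos[i])
      if (length(hit))
        hclass[i, ] <- catalog[segments$sdp[hit[1L]], strains]
    }
  }
  samples <- data.frame(
    sample = paste0(rep(strains, each = n_replicates), "_r",
                    rep(seq_len(n_replicates), n_strain)),
    strain = rep(strains, each = n_replicates),
    stringsAsFactors = FALSE)
  mu <- baseline + probes$effect * hclass            # probes x strains
  mat <- mu[, rep(seq_len(n_strain), each = n_replicates), drop = FALSE] +
    matrix(stats::rnorm(n_probe * nrow(samples), 0, noise_sd),
           n_probe, nrow(samples))
  dimnames(mat) <- list(probes$probe, samples$sample)
  expression_matrix(
    probes  = data.frame(probe = probes$probe, chrom = probes$chrom,
                         pos = probes$pos, flag = FALSE,
                         stringsAsFactors = FALSE),
    samples = samples, mat = mat)
}
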