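#' Probe-level expression matrix
#'
#' Log2 intensities for probes x samples with probe genome coordinates and
#' sample strain labels.  Missing intensities are allowed; a logical probe
#' `flag` column marks platform-level low-quality probes.
#'
#' @param probes `data.frame` with columns `probe`, `chrom`, `pos` and
#'   optionally `flag` (logical, default `FALSE`).  Coordinates may be
#'   `NA` for unplaced probes.
#' @param samples `data.frame` with columns `sample`, `strain` and any
#'   further annotation (tissue, condition).
#' @param mat Numeric probes x samples matrix of log2 intensities.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(probes, samples, mat) {
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("probe", "chrom", "pos") %in% names(probes)),
            all(c("sample", "strain") %in% names(samples)))
  if (is.null(probes$flag)) probes$flag <- FALSE
  mat <- as.matrix(mat)
  if (nrow(mat) != nrow(probes) || ncol(mat) != nrow(samples))
    stop("mat must be probes x samples", call. = FALSE)
  if (anyDuplicated(probes$probe)) stop("duplicate probe ids",
                                        call. = FALSE)
  dimnames(mat) <- list(probes$probe, samples$sample)
  structure(list(probes = probes, samples = samples, mat = mat),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$probes), " probes x ",
      nrow(x$samples), " samples (",
      length(unique(x$samples$strain)), " strains)\n", sep = "")
  invisible(x)
}

#' Filter probes by call rate
#'
#' A call is a non-missing intensity on a non-flagged probe.  Probes whose
#' call fraction across the analysis set is below `min_call_rate` — and
#' all flagged probes — are removed; a probe called in exactly 50% of
#' samples is retained under the default.
#'
#' @param em An [expression_matrix()].
#' @param min_call_rate Minimum call fraction to retain (default 0.5).
#' @return The filtered `expression_matrix`.
#' @export
filter_probes <- function(em, min_call_rate = 0.5) {
  stopifnot(inherits(em, "expression_matrix"))
  rate <- rowMeans(!is.na(em$mat))
  keep <- !em$probes$flag & rate >= min_call_rate
  message(sum(!keep), " probe(s) removed (", sum(em$probes$flag),
          " flagged, ", sum(!em$probes$flag & rate < min_call_rate),
          " below call rate ", min_call_rate, ")")
  if (!any(keep))
    stop("no probes pass the call-rate filter", call. = FALSE)
  expression_matrix(em$probes[keep, , drop = FALSE], em$samples,
                    em$mat[keep, , drop = FALSE])
}

# Quantile-normalize a numeric matrix column-wise (samples in columns).
# Each column's sorted values are replaced by the across-column mean
# quantile curve; ties get the mean of their would-be quantiles; NAs stay.
quantile_normalize_matrix <- function(mat) {
  n_obs <- colSums(!is.na(mat))
  if (any(n_obs == 0L)) stop("sample with no observed values",
                             call. = FALSE)
  nmax <- max(n_obs)
  p_ref <- (seq_len(nmax) - 0.5) / nmax
  # reference curve: mean of per-column empirical quantile functions
  qcurves <- vapply(seq_len(ncol(mat)), function(j) {
    x <- sort(mat[, j])
    nj <- length(x)
    if (nj == nmax) x
    else stats::approx((seq_len(nj) - 0.5) / nj, x, xout = p_ref,
                       rule = 2)$y
  }, numeric(nmax))
  ref <- rowMeans(qcurves)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    obs <- which(!is.na(mat[, j]))
    nj <- length(obs)
    vals <- if (nj == nmax) ref
            else stats::approx(p_ref, ref, xout = (seq_len(nj) - 0.5) / nj,
                               rule = 2)$y
    ord <- obs[order(mat[obs, j])]
    out[ord, j] <- stats::ave(vals, mat[ord, j], FUN = mean)
  }
  out
}

#' Quantile normalization across arrays
#'
#' Replaces each sample's sorted intensities by the across-sample mean of
#' order statistics, so that every sample's intensity distribution becomes
#' identical while each sample's rank order is preserved.  Tied values
#' receive the mean of their would-be quantiles; missing values are left
#' missing and excluded from the reference distribution.
#'
#' @param em An [expression_matrix()] (>= 2 samples).
#' @return The normalized `expression_matrix`.
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (nrow(em$samples) < 2L) stop("need >= 2 samples", call. = FALSE)
  expression_matrix(em$probes, em$samples,
                    quantile_normalize_matrix(em$mat))
}

#' Two-group differential expression per probe
#'
#' Per probe, a two-group linear model on the log2 intensities: the
#' reported `log2fc` is mean(A) - mean(B), the `t` statistic uses the
#' pooled within-group variance, and the two-sided p-value comes from the
#' t distribution.  With `moderation = TRUE`, per-probe variances are
#' shrunk toward the across-probe trimmed-mean variance with `prior_df`
#' prior degrees of freedom before computing `t` (a light-weight
#' empirical-Bayes approximation; the fixed thresholds used downstream
#' dominate behaviour).  Probes with zero pooled variance and moderation
#' off fall back to the across-probe variance and are flagged.
#'
#' @param em An [expression_matrix()].
#' @param group_a,group_b Character vectors of strain labels defining the
#'   two groups (>= 2 samples each).
#' @param moderation Shrink per-probe variances (default `FALSE`).
#' @param prior_df Prior degrees of freedom for moderation (default 4).
#' @param trim Trim fraction for the across-probe mean variance
#'   (default 0.1).
#' @return `data.frame` with `probe`, `log2fc`, `t`, `p`, `df`, `flagged`.
#' @export
differential_expression <- function(em, group_a, group_b,
                                    moderation = FALSE, prior_df = 4,
                                    trim = 0.1) {
  stopifnot(inherits(em, "expression_matrix"))
  ia <- which(em$samples$strain %in% group_a)
  ib <- which(em$samples$strain %in% group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  A <- em$mat[, ia, drop = FALSE]; B <- em$mat[, ib, drop = FALSE]
  na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  ssa <- rowSums((A - ma)^2, na.rm = TRUE)
  ssb <- rowSums((B - mb)^2, na.rm = TRUE)
  df <- na + nb - 2
  ok <- na >= 2 & nb >= 2
  sp2 <- ifelse(ok & df > 0, (ssa + ssb) / df, NA_real_)
  lfc <- ma - mb
  s0 <- mean(sp2[ok & sp2 > 0], trim = trim)
  flagged <- ok & sp2 == 0 & !moderation
  if (moderation) {
    s_use <- (prior_df * s0 + df * sp2) / (prior_df + df)
    df_t <- df + prior_df
  } else {
    s_use <- ifelse(flagged, s0, sp2)
    df_t <- df
  }
  tstat <- lfc / sqrt(s_use * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), df_t)
  tstat[!ok] <- NA_real_; p[!ok] <- NA_real_; lfc[!ok] <- NA_real_
  data.frame(probe = em$probes$probe, log2fc = lfc, t = tstat, p = p,
             df = ifelse(moderation, df_t, df), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up adjustment with monotonicity enforcement; the q-value
#' of a probe is the smallest FDR at which it would be called significant.
#'
#' @param p Numeric vector of p-values in `(0, 1]` (`NA` allowed and
#'   propagated).
#' @return Vector of q-values in `(0, 1]`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Classify shared and non-shared differential expression
#'
#' Given per-probe results from two inter-strain comparisons (A and B),
#' assigns each probe one category:
#' \describe{
#'   \item{shared}{`p < shared_p` in both comparisons with a concordant
#'     direction of change.}
#'   \item{non-shared-A}{`p_A < nonshared_p` but not in B: either
#'     `p_B >= other_p` with a concordant direction, or the directions are
#'     opposite at any `p_B`.}
#'   \item{non-shared-B}{the mirror image.}
#'   \item{none}{everything else.}
#' }
#' Direction is the sign of `log2fc`.  A zero log2 fold change with a
#' p-value below any classification threshold is rejected as invalid.  In
#' the rare case that both non-shared rules fire (both p-values below
#' `nonshared_p` with opposite directions), the comparison with the
#' smaller p-value wins.
#'
#' @param res_a,res_b `data.frame`s with columns `probe`, `log2fc`, `p`
#'   covering the same probes in the same order.
#' @param shared_p Threshold for the shared rule (default 1e-4).
#' @param nonshared_p Threshold for the non-shared rule (default 1e-8).
#' @param other_p "Not significant in the other comparison" threshold
#'   (default 0.05).
#' @return Factor with levels `shared`, `non-shared-A`, `non-shared-B`,
#'   `none`; `NA` where either p-value is missing.
#' @export
classify_shared_nonshared <- function(res_a, res_b, shared_p = 1e-4,
                                      nonshared_p = 1e-8, other_p = 0.05) {
  if (nrow(res_a) != nrow(res_b) || !all(res_a$probe == res_b$probe))
    stop("results must cover the same probes in the same order",
         call. = FALSE)
  pa <- res_a$p; pb <- res_b$p
  da <- sign(res_a$log2fc); db <- sign(res_b$log2fc)
  need_dir <- (!is.na(pa) & pa < max(shared_p, other_p) & da == 0) |
              (!is.na(pb) & pb < max(shared_p, other_p) & db == 0)
  if (any(need_dir, na.rm = TRUE))
    stop("zero log2fc with p-value below a classification threshold",
         call. = FALSE)
  concord <- da == db
  shared <- pa < shared_p & pb < shared_p & concord
  ns_a <- pa < nonshared_p & ((pb >= other_p & concord) | !concord)
  ns_b <- pb < nonshared_p & ((pa >= other_p & concord) | !concord)
  shared[is.na(shared)] <- FALSE
  ns_a[is.na(ns_a)] <- FALSE
  ns_b[is.na(ns_b)] <- FALSE
  both <- ns_a & ns_b
  ns_a[both] <- pa[both] <= pb[both]
  ns_b[both] <- pb[both] < pa[both]
  cat <- rep("none", length(pa))
  cat[ns_b] <- "non-shared-B"
  cat[ns_a] <- "non-shared-A"
  cat[shared] <- "shared"
  cat[is.na(pa) | is.na(pb)] <- NA
  factor(cat, levels = c("shared", "non-shared-A", "non-shared-B", "none"))
}

#' Annotate differential-expression results with cis flags
#'
#' A probe is flagged cis when its genomic position falls inside at least
#' one ancestral haplotype segment separating the compared strain pair
#' (see [classify_cis()]).  Probes without coordinates are excluded from
#' the per-category cis fractions.
#'
#' @param de `data.frame` with a `probe` column (and typically a
#'   `category` column from [classify_shared_nonshared()]).
#' @param probes `data.frame` with `probe`, `chrom`, `pos` (e.g.
#'   `em$probes`).
#' @param segments A `hap_segments` object.
#' @param strain_a,strain_b The compared strain pair.
#' @return `de` with a logical `cis` column (`NA` for unplaced probes);
#'   attribute `"cis_summary"` holds per-category counts and cis
#'   fractions when a `category` column is present.
#' @export
annotate_cis <- function(de, probes, segments, strain_a, strain_b) {
  m <- match(de$probe, probes$probe)
  if (anyNA(m)) stop("probe(s) missing from annotation", call. = FALSE)
  de$cis <- classify_cis(probes$chrom[m], probes$pos[m], segments,
                         strain_a, strain_b)
  if (!is.null(de$category)) {
    ok <- !is.na(de$cis) & !is.na(de$category)
    lev <- levels(factor(de$category))
    n <- vapply(lev, function(l) sum(ok & de$category == l), 0L)
    frac <- vapply(lev, function(l)
      if (n[[l]] > 0) mean(de$cis[ok & de$category == l]) else NA_real_, 0)
    attr(de, "cis_summary") <- data.frame(
      category = lev, n = as.integer(n), cis_fraction = frac,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  de
}
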