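#' Rank-based inverse normal (quantile) transform
#'
#' Maps values through the standard normal quantile function at Blom-type
#' plotting positions `(rank - 0.375) / (n + 0.25)`, with tied values
#' receiving the average rank.  Missing values propagate.  Used to
#' quantile-normalize phenotypes before the genome scan.
#'
#' @param x Numeric vector with at least 2 non-missing, non-constant values.
#' @return Numeric vector, same length as `x`.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2L) stop("need >= 2 non-missing values", call. = FALSE)
  if (stats::var(x[ok]) == 0)
    stop("all values identical: ranks degenerate", call. = FALSE)
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 0.375) / (n + 0.25))
  out
}

#' Adjust a phenotype for a covariate
#'
#' Ordinary least-squares residuals of `y` on an intercept plus the
#' covariate (e.g. heart weight adjusted for blood pressure).  A constant
#' covariate yields the centered `y` with a warning.  Incomplete pairs get
#' `NA` residuals.
#'
#' @param y Numeric response.
#' @param covariate Numeric covariate of the same length.
#' @return Numeric vector of residuals.
#' @export
adjust_phenotype <- function(y, covariate) {
  if (length(y) != length(covariate))
    stop("y and covariate must have equal length", call. = FALSE)
  ok <- !is.na(y) & !is.na(covariate)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  out <- rep(NA_real_, length(y))
  if (stats::var(covariate[ok]) == 0) {
    warning("constant covariate: returning centered y")
    out[ok] <- y[ok] - mean(y[ok])
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, covariate[ok]), y[ok])
  out[ok] <- fit$residuals
  out
}

#' HMM parameters for genotype-probability calculation
#'
#' @param error_rate Genotyping error rate epsilon in `[0, 0.5)`
#'   (default 0.01): an observed marker genotype equals the true genotype
#'   with probability `1 - epsilon`, each wrong state with probability
#'   `epsilon / (n_states - 1)`.
#' @param grid_step Pseudomarker spacing in cM (default 0.5).
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(error_rate = 0.01, grid_step = 0.5) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
  structure(list(error_rate = error_rate, grid_step = grid_step),
            class = "hmm_params")
}

# F2 genotype transition matrix over {AA, AB, BB} for recombination
# fraction r (two independent meioses); backcross over {AA, AB}.
transition_matrix <- function(r, cross_type) {
  if (cross_type == "F2") {
    rbind(c((1 - r)^2,       2 * r * (1 - r), r^2),
          c(r * (1 - r), (1 - r)^2 + r^2, r * (1 - r)),
          c(r^2,             2 * r * (1 - r), (1 - r)^2))
  } else {
    rbind(c(1 - r, r),
          c(r, 1 - r))
  }
}

#' Genotype posterior probabilities on a pseudomarker grid
#'
#' Forward-backward posteriors of the true genotype at every grid locus
#' (pseudomarkers every `grid_step` cM plus every marker position), under
#' a hidden Markov model with Haldane transition probabilities
#' `r = (1 - exp(-2 d / 100)) / 2` and a symmetric genotyping-error
#' emission model.  Missing genotypes contribute a flat emission, so the
#' grid is invariant to inserting markers with all-missing calls.
#'
#' @param cross A `cross_dataset` (see [simulate_cross()],
#'   [read_cross_tsv()]).
#' @param params An [hmm_params()].
#' @return A `genotype_prob_grid`: list with `loci` (`chrom`, `cM`,
#'   `marker` id or `NA`), `prob` (individuals x loci x states array;
#'   states `AA`/`AB`/`BB` for F2, `AA`/`AB` for backcross), `dosage`
#'   (individuals x loci expected count of `B` alleles) and `cross_type`.
#' @export
genotype_posteriors <- function(cross, params = hmm_params()) {
  stopifnot(inherits(cross, "cross_dataset"),
            inherits(params, "hmm_params"))
  markers <- cross$markers
  states <- if (cross$cross_type == "F2") c("AA", "AB", "BB")
            else c("AA", "AB")
  S <- length(states)
  prior <- if (S == 3L) c(0.25, 0.5, 0.25) else c(0.5, 0.5)
  eps <- params$error_rate
  n <- nrow(cross$geno)
  bad <- setdiff(unique(as.vector(cross$geno)),
                 c(states, NA_character_))
  if (length(bad))
    stop("illegal genotype code(s) for ", cross$cross_type, " cross: ",
         paste(bad, collapse = ", "), call. = FALSE)

  loci_list <- list(); prob_list <- list()
  for (ch in unique(markers$chrom)) {
    m_idx <- which(markers$chrom == ch)
    cM_m <- markers$cM[m_idx]
    if (any(diff(cM_m) < 0)) stop("negative inter-marker distance",
                                  call. = FALSE)
    grid <- sort(unique(round(c(seq(min(cM_m), max(cM_m),
                                    by = params$grid_step), cM_m), 6)))
    L <- length(grid)
    # emission matrix per locus (n x S), flat where unobserved
    emis <- rep(list(NULL), L)
    at <- match(round(cM_m, 6), grid)
    marker_at <- rep(NA_character_, L)
    for (j in seq_along(m_idx)) {
      gcol <- markers$marker[m_idx[j]]
      obs <- match(cross$geno[, gcol], states)       # NA for missing
      E <- matrix(1, n, S)
      seen <- !is.na(obs)
      if (any(seen)) {
        E[seen, ] <- eps / (S - 1)
        E[cbind(which(seen), obs[seen])] <- 1 - eps
      }
      emis[[at[j]]] <- if (is.null(emis[[at[j]]])) E else emis[[at[j]]] * E
      marker_at[at[j]] <- markers$marker[m_idx[j]]
    }
    Tr <- lapply(haldane_r(diff(grid)), transition_matrix,
                 cross_type = cross$cross_type)
    # forward with row scaling
    alpha <- array(0, c(n, L, S))
    a <- matrix(prior, n, S, byrow = TRUE)
    if (!is.null(emis[[1L]])) a <- a * emis[[1L]]
    alpha[, 1L, ] <- a / rowSums(a)
    for (t in seq_len(L - 1L)) {
      a <- alpha[, t, , drop = FALSE]
      dim(a) <- c(n, S)
      a <- a %*% Tr[[t]]
      if (!is.null(emis[[t + 1L]])) a <- a * emis[[t + 1L]]
      alpha[, t + 1L, ] <- a / rowSums(a)
    }
    # backward with scaling
    beta <- array(0, c(n, L, S))
    beta[, L, ] <- 1
    if (L > 1L) for (t in seq(L - 1L, 1L)) {
      b <- beta[, t + 1L, , drop = FALSE]
      dim(b) <- c(n, S)
      if (!is.null(emis[[t + 1L]])) b <- b * emis[[t + 1L]]
      b <- b %*% t(Tr[[t]])
      beta[, t, ] <- b / rowSums(b)
    }
    post <- alpha * beta
    norm <- apply(post, c(1, 2), sum)
    post <- post / array(norm, dim(post))
    loci_list[[ch]] <- data.frame(chrom = ch, cM = grid,
                                  marker = marker_at,
                                  stringsAsFactors = FALSE)
    prob_list[[ch]] <- post
  }
  loci <- do.call(rbind, loci_list)
  rownames(loci) <- NULL
  Ltot <- nrow(loci)
  prob <- array(NA_real_, c(n, Ltot, S),
                dimnames = list(NULL, NULL, states))
  off <- 0L
  for (ch in names(prob_list)) {
    Lc <- dim(prob_list[[ch]])[2L]
    prob[, off + seq_len(Lc), ] <- prob_list[[ch]]
    off <- off + Lc
  }
  dose_w <- if (S == 3L) c(0, 1, 2) else c(0, 1)
  dosage <- matrix(0, n, Ltot)
  for (s in seq_len(S)) dosage <- dosage + prob[, , s] * dose_w[s]
  structure(list(loci = loci, prob = prob, dosage = dosage,
                 cross_type = cross$cross_type, states = states),
            class = "genotype_prob_grid")
}

#' Additive-model score test along the genome
#'
#' At each grid locus the phenotype is regressed on the posterior-expected
#' additive dosage (Haley-Knott substitution), accommodating genotype
#' uncertainty.  `z = beta / se` and the two-sided p-value uses the normal
#' tail.  Loci with zero dosage variance are flagged non-informative and
#' returned with `z = 0`, `p = 1`.
#'
#' @param grid A `genotype_prob_grid`.
#' @param phenotype Numeric vector, one value per individual, already
#'   transformed (see [inverse_normal_transform()]); missing allowed.
#' @return `data.frame` with one row per locus: `chrom`, `cM`, `marker`,
#'   `beta`, `se`, `z`, `p`, `informative`.
#' @export
score_test <- function(grid, phenotype) {
  stopifnot(inherits(grid, "genotype_prob_grid"))
  n_ind <- nrow(grid$dosage)
  if (length(phenotype) != n_ind)
    stop("phenotype length must match individuals", call. = FALSE)
  ok <- !is.na(phenotype)
  if (sum(ok) < 10L) stop("need >= 10 complete individuals", call. = FALSE)
  y <- phenotype[ok]
  X <- grid$dosage[ok, , drop = FALSE]
  n <- length(y)
  xbar <- colMeans(X)
  Sxx <- colSums(X^2) - n * xbar^2
  Sxy <- as.vector(crossprod(X, y)) - n * xbar * mean(y)
  Syy <- sum((y - mean(y))^2)
  beta <- ifelse(Sxx > 0, Sxy / Sxx, 0)
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- ifelse(Sxx > 0, sqrt(rss / (n - 2) / Sxx), NA_real_)
  usable <- Sxx > 0 & !is.na(se) & se > 0
  z <- ifelse(usable, beta / se, 0)
  p <- ifelse(usable, 2 * stats::pnorm(-abs(z)), 1)
  data.frame(grid$loci, beta = beta, se = se, z = z, p = p,
             informative = Sxx > 0, stringsAsFactors = FALSE)
}

#' Fixed-effect inverse-variance meta-analysis of one locus
#'
#' Combines per-stratum allelic effects with weights `w_i = 1 / se_i^2`:
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = 1 / sqrt(sum(w))`,
#' `z = beta_meta / se_meta`.  Heterogeneity is Cochran's
#' `Q = sum(w (b - beta_meta)^2)` with `p_het` from a chi-square on
#' `k - 1` degrees of freedom (`NA` for a single stratum).  Effects must
#' be sign-aligned to the same allele across strata before combining.
#'
#' @param beta Numeric vector of per-stratum effects.
#' @param se Numeric vector of per-stratum standard errors; strata with
#'   missing or non-positive `se` are dropped.
#' @param threshold_z Genome-wide significance threshold on `|z|`
#'   (default 3.89, the two-sided normal quantile for P = 1e-4).
#' @return List with `beta`, `se`, `z`, `p`, `significant`, `Q`, `p_het`,
#'   `k`.
#' @export
meta_fixed <- function(beta, se, threshold_z = 3.89) {
  if (length(beta) == 0L) stop("empty input", call. = FALSE)
  if (length(beta) != length(se)) stop("beta and se must align",
                                       call. = FALSE)
  keep <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[keep]; se <- se[keep]
  k <- length(beta)
  if (k == 0L)
    return(list(beta = NA_real_, se = NA_real_, z = 0, p = 1,
                significant = FALSE, Q = NA_real_, p_het = NA_real_,
                k = 0L))
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sem <- 1 / sqrt(sum(w))
  z <- bm / sem
  Q <- sum(w * (beta - bm)^2)
  p_het <- if (k > 1L) stats::pchisq(Q, df = k - 1L, lower.tail = FALSE)
           else NA_real_
  list(beta = bm, se = sem, z = z, p = 2 * stats::pnorm(-abs(z)),
       significant = abs(z) > threshold_z, Q = Q, p_het = p_het, k = k)
}

#' Combine genome scans across strata by fixed-effect meta-analysis
#'
#' Strata are typically cross x sex combinations scanned on a common
#' locus grid.  Loci are matched by chromosome and cM position; all scans
#' must cover the same grid.
#'
#' @param scans List of [score_test()] results on identical loci.
#' @param threshold_z Significance threshold on `|z_meta|` (default 3.89).
#' @return `data.frame` with `chrom`, `cM`, `marker`, `beta`, `se`, `z`,
#'   `p`, `significant`, `Q`, `p_het`, `k`.
#' @export
meta_scan <- function(scans, threshold_z = 3.89) {
  if (!length(scans)) stop("empty input", call. = FALSE)
  loci <- scans[[1L]][, c("chrom", "cM", "marker")]
  for (s in scans[-1L]) {
    if (nrow(s) != nrow(loci) ||
        !all(s$chrom == loci$chrom & s$cM == loci$cM))
      stop("scans must share an identical locus grid", call. = FALSE)
  }
  B <- vapply(scans, `[[`, numeric(nrow(loci)), "beta")
  SE <- vapply(scans, `[[`, numeric(nrow(loci)), "se")
  B <- matrix(B, nrow = nrow(loci)); SE <- matrix(SE, nrow = nrow(loci))
  INF <- vapply(scans, `[[`, logical(nrow(loci)), "informative")
  INF <- matrix(INF, nrow = nrow(loci))
  SE[!INF] <- NA_real_
  res <- lapply(seq_len(nrow(loci)), function(i)
    meta_fixed(B[i, ], SE[i, ], threshold_z))
  data.frame(loci,
             beta = vapply(res, `[[`, 0, "beta"),
             se = vapply(res, `[[`, 0, "se"),
             z = vapply(res, `[[`, 0, "z"),
             p = vapply(res, `[[`, 0, "p"),
             significant = vapply(res, `[[`, TRUE, "significant"),
             Q = vapply(res, `[[`, 0, "Q"),
             p_het = vapply(res, `[[`, 0, "p_het"),
             k = vapply(res, `[[`, 0L, "k"),
             stringsAsFactors = FALSE)
}

#' Screen for epistasis via effect heterogeneity across genetic backgrounds
#'
#' Applies the fixed-effect heterogeneity machinery to scans stratified by
#' the allele fixed at a conditioning locus: a locus whose effect differs
#' between backgrounds more than sampling allows (Cochran `Q`,
#' `p_het < alpha`) is flagged as a candidate interaction.
#'
#' @param scans_by_background List (length >= 2) of [score_test()] results
#'   on an identical locus grid, one per conditioning background.
#' @param alpha Heterogeneity flag level (default nominal 0.05).
#' @return `data.frame` with `chrom`, `cM`, `marker`, `Q`, `p_het`,
#'   `flagged`.
#' @export
epistasis_screen <- function(scans_by_background, alpha = 0.05) {
  if (length(scans_by_background) < 2L)
    stop("need >= 2 backgrounds", call. = FALSE)
  m <- meta_scan(scans_by_background)
  data.frame(m[, c("chrom", "cM", "marker", "Q", "p_het")],
             flagged = !is.na(m$p_het) & m$p_het < alpha,
             stringsAsFactors = FALSE)
}

#' Two-sided normal |z| threshold for a genome-wide p-value
#'
#' @param p Two-sided tail probability (default 1e-4, whose threshold is
#'   3.89 at two decimals).
#' @return The positive normal quantile `qnorm(1 - p/2)`.
#' @export
z_threshold <- function(p = 1e-4) stats::qnorm(1 - p / 2)
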