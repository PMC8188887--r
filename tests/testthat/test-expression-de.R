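make_em <- function(mat, strains = NULL, chrom = "chr1", pos = NULL,
                    flag = FALSE) {
  n_p <- nrow(mat); n_s <- ncol(mat)
  if (is.null(strains)) strains <- rep(c("A", "B"), each = n_s / 2)
  if (is.null(pos)) pos <- seq_len(n_p) * 100L
  expression_matrix(
    probes = data.frame(probe = paste0("p", seq_len(n_p)), chrom = chrom,
                        pos = pos, flag = flag),
    samples = data.frame(sample = paste0("s", seq_len(n_s)),
                         strain = strains),
    mat = mat)
}

test_that("probe filtering applies the call-rate boundary", {
  set.seed(1)
  mat <- matrix(rnorm(6 * 100, 8), 100, 6)
  # probe 1: 2/6 calls (33%) -> removed; probe 2: 3/6 (50%) -> retained
  mat[1, 1:4] <- NA
  mat[2, 1:3] <- NA
  em <- make_em(mat)
  suppressMessages(f <- filter_probes(em))
  expect_false("p1" %in% f$probes$probe)
  expect_true("p2" %in% f$probes$probe)
  expect_equal(nrow(f$probes), 99L)

  # fully observed matrix unchanged; flagged probes always removed
  suppressMessages(expect_equal(nrow(filter_probes(make_em(mat[3:10, ]))$probes), 8L))
  emf <- make_em(mat[3:10, ], flag = c(TRUE, rep(FALSE, 7)))
  suppressMessages(expect_equal(nrow(filter_probes(emf)$probes), 7L))
  allna <- make_em(matrix(NA_real_, 3, 6))
  suppressMessages(expect_error(filter_probes(allna), "no probes"))

  # random missingness: surviving set equals brute-force counting
  mat2 <- matrix(rnorm(600, 8), 100, 6)
  mat2[sample(length(mat2), 150)] <- NA
  suppressMessages(f2 <- filter_probes(make_em(mat2), 0.5))
  keep_bf <- vapply(seq_len(100), function(i)
    sum(!is.na(mat2[i, ])) / 6 >= 0.5, TRUE)
  expect_equal(f2$probes$probe, paste0("p", which(keep_bf)))
})

test_that("quantile normalization matches its definition", {
  # two samples (1,2,3) and (10,20,30) -> both (5.5, 11, 16.5)
  em <- make_em(cbind(c(1, 2, 3), c(10, 20, 30)))
  q <- quantile_normalize(em)
  expect_equal(unname(q$mat), cbind(c(5.5, 11, 16.5), c(5.5, 11, 16.5)))

  # already identical distributions: fixed point (up to reordering)
  set.seed(2)
  base <- sort(rnorm(50))
  mat <- vapply(1:4, function(j) sample(base), numeric(50))
  qq <- quantile_normalize(make_em(mat))
  expect_lt(max(abs(qq$mat - mat)), 1e-10)

  # random matrix: every column's sorted vector identical
  m <- matrix(rnorm(600), 100, 6)
  qn <- quantile_normalize(make_em(m))$mat
  ref <- unname(sort(qn[, 1]))
  for (j in 2:6) expect_equal(unname(sort(qn[, j])), ref,
                              tolerance = 1e-9)
  # rank order preserved within each sample
  for (j in 1:6) expect_equal(order(qn[, j]), order(m[, j]))

  # ties get the mean of their would-be quantiles:
  # reference is ((1,1,3)+(10,20,30))/2 = (5.5, 10.5, 16.5), the tied
  # pair receives mean(5.5, 10.5) = 8
  emt <- make_em(cbind(c(1, 1, 3), c(10, 20, 30)))
  qt <- quantile_normalize(emt)
  expect_equal(unname(qt$mat[, 1]), c(8, 8, 16.5))

  # missing values stay missing, others still align
  mna <- matrix(rnorm(300), 50, 6)
  mna[sample(300, 40)] <- NA
  qna <- quantile_normalize(make_em(mna))$mat
  expect_identical(unname(is.na(qna)), is.na(mna))
  for (j in 1:6) {
    obs <- !is.na(mna[, j])
    expect_equal(order(qna[obs, j]), order(mna[obs, j]))
  }
})

test_that("differential expression is calibrated and recovers effects", {
  set.seed(3)
  # identical groups (same samples duplicated): log2FC exactly 0
  half <- matrix(rnorm(200, 8), 20, 10)
  em0 <- make_em(cbind(half, half),
                 strains = rep(c("A", "B"), each = 10))
  de0 <- differential_expression(em0, "A", "B")
  expect_true(all(de0$log2fc == 0))

  # null simulation: p uniform, BH q < 0.05 count near 0
  emn <- make_em(matrix(rnorm(1000 * 10, 8, 0.3), 1000, 10))
  den <- differential_expression(emn, "A", "B")
  expect_gt(ks.test(den$p, "punif")$p.value, 0.001)
  expect_lte(sum(bh_fdr(den$p) < 0.05), 3)

  # planted log2FC = 1, noise 0.1, n = 5 per group
  mu <- cbind(matrix(9, 500, 5), matrix(8, 500, 5))
  emp <- make_em(mu + matrix(rnorm(5000, 0, 0.1), 500, 10))
  dep <- differential_expression(emp, "A", "B")
  se_hat <- 0.1 * sqrt(2 / 5)
  expect_gt(mean(abs(dep$log2fc - 1) < 3 * se_hat), 0.95)

  # moderation shrinks extreme t of low-variance probes
  dem <- differential_expression(emp, "A", "B", moderation = TRUE)
  expect_true(all(is.finite(dem$t)))
  expect_error(differential_expression(emp, "A", "nope"), ">= 2 samples")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_fdr(0.03), 0.03)                      # single p
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.216, 0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569,
         0.594, 0.696, 0.762, 0.94, 0.942, 0.975, 0.986)
  q <- bh_fdr(p)
  # q >= p elementwise and monotone in p-rank
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_equal(q[1], 0.025)          # 0.001 * 25 / 1
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_true(is.na(bh_fdr(c(0.5, NA))[2]))
})

test_that("shared/non-shared classification reproduces the rule table", {
  mk_res <- function(p, d) data.frame(probe = paste0("p", seq_along(p)),
                                      log2fc = d, p = p)
  # 12-case truth table over the threshold strata
  pa <- c(1e-5, 1e-9, 1e-9, 1e-9, 1e-3, 1e-5, 0.5,  1e-9, 0.2, 1e-9,
          1e-4, 1e-9)
  da <- c(1,    1,    1,    1,    1,    1,    1,    -1,   1,   1,
          1,    1)
  pb <- c(1e-5, 0.5,  1e-3, 1e-5, 1e-5, 1e-5, 1e-9, 1e-9, 0.9, 0.04,
          1e-5, 1e-9)
  db <- c(1,    1,    1,    -1,   1,    -1,   1,    1,    1,   1,
          1,    -1)
  want <- c("shared",          # both < 1e-4, concordant
            "non-shared-A",    # A < 1e-8, B >= 0.05 concordant
            "none",            # A < 1e-8 but B in (0.05, 1e-4) gap
            "non-shared-A",    # A < 1e-8, discordant at any p_B
            "none",            # A misses 1e-4
            "none",            # discordant, neither < 1e-8
            "non-shared-B",    # mirror of case 2
            "non-shared-B",    # both < 1e-8 discordant, B smaller p? tie
            "none",            # nothing significant
            "none",            # A < 1e-8 but B in (0.04) concordant
            "none",            # p_A = 1e-4 not < 1e-4 (strict)
            "non-shared-A")    # both < 1e-8 discordant, tie -> A
  got <- classify_shared_nonshared(mk_res(pa, da), mk_res(pb, db))
  # case 8: equal p both sides discordant resolves to A by the <= rule
  want[8] <- "non-shared-A"
  expect_equal(as.character(got), want)

  # classification commutes with swapping the comparisons
  swapped <- classify_shared_nonshared(mk_res(pb, db), mk_res(pa, da))
  map <- c("shared" = "shared", "none" = "none",
           "non-shared-A" = "non-shared-B",
           "non-shared-B" = "non-shared-A")
  keep <- pa != pb             # symmetric except exact-tie tie-break
  expect_equal(as.character(swapped)[keep],
               unname(map[as.character(got)[keep]]))

  # zero direction with significant p is invalid
  expect_error(
    classify_shared_nonshared(mk_res(1e-6, 0), mk_res(0.5, 1)),
    "zero log2fc")
})

test_that("cis annotation flags match the stabbing oracle", {
  set.seed(5)
  gt <- random_genotype_table(5, 200, p_alt = 0.3)
  segs <- detect_segments(gt, params = segmentation_params(2, 5))
  catalog <- attr(segs, "catalog")
  n <- 60
  probes <- data.frame(probe = paste0("p", 1:n), chrom = "chr1",
                       pos = sample(max(gt$variants$pos) + 50, n))
  de <- data.frame(probe = probes$probe,
                   category = sample(c("shared", "none"), n, TRUE))
  ann <- annotate_cis(de, probes, segs, "S1", "S4")
  want <- oracle_stab(as.data.frame(segs), catalog, "S1", "S4",
                      probes$chrom, probes$pos)
  expect_identical(ann$cis, want)
  cs <- attr(ann, "cis_summary")
  expect_equal(sum(cs$n), n)
  # probes without coordinates are excluded from fractions
  probes$pos[1] <- NA
  ann2 <- annotate_cis(de, probes, segs, "S1", "S4")
  expect_true(is.na(ann2$cis[1]))
  expect_equal(sum(attr(ann2, "cis_summary")$n), n - 1L)
})

test_that("end-to-end cis expression pipeline classifies planted probes", {
  # 3 strains, one SDP splitting S1/S3 and S2/S3 jointly: S3 differs
  calls <- matrix(rep(c(0L, 0L, 1L), 80), nrow = 3)
  gt <- genotype_table(c("S1", "S2", "S3"),
                       data.frame(chrom = "chr1",
                                  pos = seq(1000, by = 1000,
                                            length.out = 80),
                                  ref = "A", alt = "G"),
                       calls)
  segs <- detect_segments(gt)
  expect_equal(nrow(segs), 1L)
  miscls <- vapply(1:200, function(s) {
    n_probe <- 60
    planted <- 1:10
    probes <- data.frame(probe = sprintf("q%03d", 1:n_probe),
                         chrom = "chr1",
                         pos = c(seq(2000, 70000, length.out = 10),
                                 seq(90000, 200000,
                                     length.out = n_probe - 10)),
                         effect = c(rep(2, 10), rep(0, n_probe - 10)))
    em <- simulate_expression(gt, segs, probes, n_replicates = 5,
                              noise_sd = 0.15, seed = 9000 + s)
    de_a <- differential_expression(em, "S1", "S3")
    de_b <- differential_expression(em, "S2", "S3")
    cat <- classify_shared_nonshared(de_a, de_b)
    exp_cat <- rep("none", n_probe); exp_cat[planted] <- "shared"
    mean(as.character(cat) != exp_cat)
  }, 0)
  expect_lt(mean(miscls), 0.05)
})
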