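make_gt <- function(calls, pos = NULL, chrom = NULL) {
  n_var <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n_var) * 10L
  if (is.null(chrom)) chrom <- rep("chr1", n_var)
  genotype_table(paste0("S", seq_len(nrow(calls))),
                 data.frame(chrom = chrom, pos = pos, ref = "A",
                            alt = "G", stringsAsFactors = FALSE),
                 calls)
}

test_that("SDP enumeration canonicalizes complements and flags monomorphic", {
  # all strains identical at every variant -> empty catalog
  gt <- make_gt(matrix(0L, 4, 10))
  s <- enumerate_sdps(gt)
  expect_equal(nrow(s$catalog), 0L)
  expect_true(all(is.na(s$assignment)))

  # 0110 and its complement 1001 share one SDP id
  gt2 <- make_gt(cbind(c(0L, 1L, 1L, 0L), c(1L, 0L, 0L, 1L)))
  s2 <- enumerate_sdps(gt2)
  expect_equal(s2$assignment[1], s2$assignment[2])
  expect_equal(nrow(s2$catalog), 1L)
  expect_equal(unname(s2$catalog[1, ]), c(0L, 1L, 1L, 0L))
})

test_that("SDP catalog matches brute-force enumeration on random tables", {
  set.seed(101)
  for (rep in 1:20) {
    gt <- random_genotype_table(8, 500)
    s <- enumerate_sdps(gt)
    o <- oracle_sdps(gt)
    expect_identical(s$assignment, o$assignment)
    expect_identical(unname(s$catalog), unname(o$catalog))
  }
})

test_that("segment detection honors the run and gap thresholds", {
  p <- segmentation_params()           # 20 / 100 defaults
  # 19 consecutive variants of one SDP, nothing else -> no segment
  gt <- make_gt(matrix(rep(c(0L, 1L), 19), nrow = 2))
  expect_equal(nrow(detect_segments(gt, params = p)), 0L)
  # 20 -> one segment
  gt20 <- make_gt(matrix(rep(c(0L, 1L), 20), nrow = 2))
  s20 <- detect_segments(gt20, params = p)
  expect_equal(nrow(s20), 1L)
  expect_equal(s20$n_support, 20L)

  # 20 focal variants each separated by exactly 99 variants of other SDPs
  # (strict < 100 rule): one segment with n_support = 20
  n_strain <- 3
  focal <- c(0L, 1L, 1L)
  other1 <- c(0L, 1L, 0L); other2 <- c(0L, 0L, 1L)
  cols <- list()
  for (i in 1:20) {
    cols[[length(cols) + 1L]] <- focal
    if (i < 20) for (j in 1:99)
      cols[[length(cols) + 1L]] <- if (j %% 2) other1 else other2
  }
  gt99 <- make_gt(do.call(cbind, cols))
  s99 <- detect_segments(gt99, params = p)
  focal_segs <- s99[s99$n_support == 20L, ]
  expect_equal(nrow(focal_segs), 1L)
  expect_equal(focal_segs$start, gt99$variants$pos[1])
  expect_equal(focal_segs$end, gt99$variants$pos[ncol(gt99$calls)])

  # exactly 100 intervening variants splits the run
  cols100 <- c(rep(list(focal), 20),
               rep(list(other1), 100),
               rep(list(focal), 20))
  gt100 <- make_gt(do.call(cbind, cols100))
  s100 <- detect_segments(gt100, params = p)
  segs20 <- s100[s100$n_support == 20L, ]
  expect_equal(nrow(segs20), 2L)        # focal run split in two
  expect_equal(length(unique(segs20$sdp)), 1L)
})

test_that("segments match the direct-scan oracle on random assignments", {
  set.seed(202)
  for (rep in 1:25) {
    n_strain <- sample(3:13, 1)
    n_var <- sample(100:600, 1)
    gt <- random_genotype_table(n_strain, n_var,
                                n_chrom = sample(1:2, 1), p_alt = 0.3)
    params <- segmentation_params(min_run = sample(2:6, 1),
                                  max_gap = sample(c(1, 3, 10), 1))
    sdps <- enumerate_sdps(gt)
    got <- as.data.frame(detect_segments(gt, sdps, params))
    want <- oracle_segments(gt, sdps, params$min_run, params$max_gap)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("detection is invariant to strain order and ref/alt polarity", {
  set.seed(303)
  gt <- random_genotype_table(6, 300)
  params <- segmentation_params(min_run = 3, max_gap = 5)
  base <- detect_segments(gt, params = params)

  # flip ref/alt labels of random variants
  flip <- sample(c(TRUE, FALSE), 300, replace = TRUE)
  calls2 <- gt$calls
  calls2[, flip] <- 1L - calls2[, flip]
  gt2 <- genotype_table(gt$strains, gt$variants, calls2)
  flipped <- detect_segments(gt2, params = params)
  expect_equal(as.data.frame(base), as.data.frame(flipped))

  # reorder strains: segment intervals and support are preserved
  perm <- c(4, 2, 6, 1, 3, 5)
  gt3 <- genotype_table(gt$strains[perm], gt$variants,
                        gt$calls[perm, , drop = FALSE])
  reordered <- detect_segments(gt3, params = params)
  cols <- c("chrom", "start", "end", "n_support")
  expect_equal(as.data.frame(base)[cols],
               as.data.frame(reordered)[order(reordered$start,
                                              reordered$sdp), cols],
               ignore_attr = TRUE)
})

test_that("region map tiles the genome and counts classes", {
  # no segments anywhere -> one region per chromosome, class 1
  gt <- make_gt(matrix(0L, 3, 4), chrom = rep("chr1", 4))
  segs <- detect_segments(gt)
  lens <- c(chr1 = 1000, chr2 = 500)
  rm0 <- build_region_map(segs, lens)
  expect_equal(nrow(rm0$regions), 2L)
  expect_equal(rm0$regions$class_paper, c(1L, 1L))
  expect_equal(rm0$summary$bp, 1500)

  # two nested-SDP segments overlapping one region: paper 3, joint 3
  calls <- cbind(matrix(rep(c(0L, 1L, 1L, 1L), 5), nrow = 4),
                 matrix(rep(c(0L, 0L, 1L, 1L), 5), nrow = 4))
  ord <- c(rbind(1:5, 6:10))           # interleave the two SDPs
  gt2 <- make_gt(calls[, ord], pos = seq_len(10) * 10L)
  segs2 <- detect_segments(gt2, params = segmentation_params(2, 100))
  expect_equal(nrow(segs2), 2L)
  rm2 <- build_region_map(segs2, c(chr1 = 200))
  reg <- rm2$regions[rm2$regions$n_segments == 2L, ]
  expect_gte(nrow(reg), 1L)
  expect_equal(reg$class_paper[1], 3L)
  expect_equal(reg$class_joint[1], 3L)

  # sum of region lengths equals genome length exactly
  expect_equal(sum(rm2$regions$end - rm2$regions$start + 1), 200)
  expect_error(build_region_map(segs2, c(chr1 = 50)), "beyond")
})

test_that("joint class counts equal the per-position brute-force count", {
  set.seed(404)
  for (rep in 1:10) {
    gt <- random_genotype_table(sample(3:8, 1), 200, p_alt = 0.3)
    segs <- detect_segments(gt, params = segmentation_params(2, 4))
    len <- c(chr1 = max(gt$variants$pos) + 50)
    rm <- build_region_map(segs, len)
    catalog <- attr(segs, "catalog")
    pos <- sample.int(len, 40)
    for (p in pos) {
      want <- oracle_class_at(as.data.frame(segs), catalog, "chr1", p)
      row <- rm$regions[rm$regions$start <= p & rm$regions$end >= p, ]
      expect_equal(row$class_paper, unname(want["paper"]))
      expect_equal(row$class_joint, unname(want["joint"]))
    }
  }
})

test_that("pairwise diversity equals brute-force union length", {
  # single divergent segment of 17 Mb on a 100 Mb genome -> 0.17
  calls <- matrix(rep(c(0L, 1L), 20), nrow = 2)
  gt <- make_gt(calls, pos = as.integer(seq(1, 17e6, length.out = 20)))
  segs <- detect_segments(gt)
  expect_equal(pairwise_diversity(segs, "S1", "S2", c(chr1 = 1e8)),
               (17e6 - 1 + 1) / 1e8)
  # identical strains -> 0
  expect_equal(pairwise_diversity(segs, "S1", "S1", c(chr1 = 1e8)), 0)
  expect_error(pairwise_diversity(segs, "S1", "SX", c(chr1 = 1e8)),
               "unknown strain")

  set.seed(505)
  for (rep in 1:10) {
    gt <- random_genotype_table(sample(3:10, 1), 300, p_alt = 0.3)
    segs <- detect_segments(gt, params = segmentation_params(2, 6))
    if (!nrow(segs)) next
    lens <- c(chr1 = max(gt$variants$pos) + 10)
    pair <- sample(gt$strains, 2)
    catalog <- attr(segs, "catalog")
    div <- segs[catalog[segs$sdp, pair[1]] != catalog[segs$sdp, pair[2]], ,
                drop = FALSE]
    want <- oracle_union_len(as.data.frame(div), lens) / sum(lens)
    expect_equal(pairwise_diversity(segs, pair[1], pair[2], lens), want)
  }
})

test_that("cis classification equals the interval-stabbing oracle", {
  set.seed(606)
  gt <- random_genotype_table(6, 400, p_alt = 0.3)
  segs <- detect_segments(gt, params = segmentation_params(2, 6))
  catalog <- attr(segs, "catalog")
  pos <- sample.int(max(gt$variants$pos) + 100, 100)
  chrom <- rep("chr1", 100)
  got <- classify_cis(chrom, pos, segs, "S2", "S5")
  want <- oracle_stab(as.data.frame(segs), catalog, "S2", "S5",
                      chrom, pos)
  expect_identical(got, want)
  # position inside a segment whose SDP does not split the pair -> FALSE
  same <- which(catalog[segs$sdp, "S2"] == catalog[segs$sdp, "S5"])
  if (length(same)) {
    p0 <- segs$start[same[1]]
    inside_div <- oracle_stab(as.data.frame(segs), catalog, "S2", "S5",
                              "chr1", p0)
    expect_identical(classify_cis("chr1", p0, segs, "S2", "S5"),
                     inside_div)
  }
})

test_that("strain subsetting re-enumerates SDPs on the subset", {
  set.seed(707)
  gt <- random_genotype_table(8, 200)
  sub <- subset_strains(gt, c("S2", "S5", "S7"))
  expect_equal(sub$strains, c("S2", "S5", "S7"))
  s <- enumerate_sdps(sub)
  expect_lte(nrow(s$catalog), 2^2 - 1)   # canonical bipartitions of 3
  expect_error(subset_strains(gt, "nope"), "unknown strain")
})
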