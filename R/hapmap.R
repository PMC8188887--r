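#' Segmentation parameters for ancestral haplotype detection
#'
#' A haplotype segment is a run of at least `min_run` variants sharing one
#' strain distribution pattern (SDP), in which consecutive supporting
#' variants are separated by strictly fewer than `max_gap` other retained
#' polymorphic variants.  The defaults (20 and 100) reduce false segments
#' arising from isolated genotyping errors at the cost of missing very
#' short ancestral tracts.
#'
#' @param min_run Minimum supporting variants per segment (>= 2, default 20).
#' @param max_gap Runs are split when >= `max_gap` non-SDP variants intervene
#'   (>= 1, default 100).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(min_run = 20L, max_gap = 100L) {
  min_run <- as.integer(min_run); max_gap <- as.integer(max_gap)
  if (min_run < 2L) stop("min_run must be >= 2", call. = FALSE)
  if (max_gap < 1L) stop("max_gap must be >= 1", call. = FALSE)
  structure(list(min_run = min_run, max_gap = max_gap),
            class = "segmentation_params")
}

#' Enumerate strain distribution patterns (SDPs)
#'
#' Each biallelic variant splits the strain panel into reference-carrying
#' and alternate-carrying strains.  Because ref/alt polarity is arbitrary
#' with respect to haplotype sharing, a pattern and its complement are
#' merged: patterns are canonicalized so that the first strain always
#' carries 0.  Variants identical in all strains are flagged monomorphic
#' and take no part in segment detection.
#'
#' @param geno A [genotype_table()].
#' @return List with `catalog` (unique canonical patterns as an SDP x
#'   strain 0/1 matrix; row `i` is SDP id `i`) and `assignment` (integer
#'   SDP id per variant, `NA` for monomorphic variants).
#' @export
enumerate_sdps <- function(geno) {
  stopifnot(inherits(geno, "genotype_table"))
  calls <- geno$calls
  if (anyNA(calls) || !all(calls %in% c(0L, 1L)))
    stop("genotype table contains non-homozygous or missing calls",
         call. = FALSE)
  n_strain <- nrow(calls)
  if (n_strain > 52L)
    stop("SDP hashing supports at most 52 strains", call. = FALSE)
  # canonical form: complement columns whose first strain carries 1
  flip <- calls[1L, ] == 1L
  pat <- calls
  pat[, flip] <- 1L - pat[, flip, drop = FALSE]
  mono <- colSums(pat) == 0L
  key <- as.vector(2^(seq_len(n_strain) - 1) %*% pat)  # exact for <= 52
  key[mono] <- NA
  ids <- match(key, unique(key[!mono]))
  uniq <- which(!mono & !duplicated(key))
  catalog <- t(pat[, uniq, drop = FALSE])
  rownames(catalog) <- seq_len(nrow(catalog))
  colnames(catalog) <- geno$strains
  list(catalog = catalog, assignment = ids)
}

#' Detect ancestral haplotype segments
#'
#' For each SDP independently and each chromosome separately, emits maximal
#' runs of variants carrying that SDP in which every pair of consecutive
#' supporting variants is separated by fewer than `max_gap` intervening
#' retained polymorphic variants, provided the run holds at least
#' `min_run` supporting variants.  Gap counting excludes monomorphic
#' variants, which were never retained as biallelic SDP material.
#' Segments of different SDPs may overlap.
#'
#' Segment coordinates are the positions of the first and last supporting
#' variant, 1-based inclusive.
#'
#' @param geno A [genotype_table()].
#' @param sdps Result of [enumerate_sdps()]; computed from `geno` when
#'   omitted.
#' @param params A [segmentation_params()].
#' @return A `hap_segments` data.frame with columns `chrom`, `start`,
#'   `end`, `sdp`, `n_support`, ordered by chromosome then start, carrying
#'   the SDP catalog and strain panel as attributes.
#' @export
detect_segments <- function(geno, sdps = enumerate_sdps(geno),
                            params = segmentation_params()) {
  stopifnot(inherits(geno, "genotype_table"),
            inherits(params, "segmentation_params"))
  v <- geno$variants
  poly <- which(!is.na(sdps$assignment))
  out <- list()
  for (ch in unique(v$chrom)) {
    idx <- poly[v$chrom[poly] == ch]      # chrom-local polymorphic variants
    if (!length(idx)) next
    ord <- seq_along(idx)                 # already position-ordered
    ids <- sdps$assignment[idx]
    pos <- v$pos[idx]
    for (id in unique(ids)) {
      at <- which(ids == id)              # indices in the chrom-local run
      # split where >= max_gap non-SDP variants intervene (strict "<" rule)
      brk <- which(diff(at) - 1L >= params$max_gap)
      starts <- c(1L, brk + 1L)
      ends <- c(brk, length(at))
      for (r in seq_along(starts)) {
        sup <- at[starts[r]:ends[r]]
        if (length(sup) >= params$min_run)
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start = pos[sup[1L]], end = pos[sup[length(sup)]],
            sdp = id, n_support = length(sup), stringsAsFactors = FALSE)
      }
    }
  }
  segs <- if (length(out)) do.call(rbind, out)
          else data.frame(chrom = character(), start = integer(),
                          end = integer(), sdp = integer(),
                          n_support = integer(), stringsAsFactors = FALSE)
  segs <- segs[order(segs$chrom, segs$start, segs$sdp), , drop = FALSE]
  rownames(segs) <- NULL
  structure(segs, catalog = sdps$catalog, strains = geno$strains,
            params = params, class = c("hap_segments", "data.frame"))
}

#' @export
as.data.frame.hap_segments <- function(x, ...) {
  data.frame(chrom = x$chrom, start = x$start, end = x$end, sdp = x$sdp,
             n_support = x$n_support, stringsAsFactors = FALSE)
}

#' Tile the genome into haplotype-class regions
#'
#' Chromosomes are split at every segment start and at every segment
#' end + 1, yielding atomic regions each either fully inside or fully
#' outside every segment.  For a region overlapped by `k` segments two
#' class counts are reported: `class_paper = k + 1` (the convention that a
#' region overlapping one (or two) segments holds two (or three) haplotype
#' classes) and `class_joint`, the number of distinct joint patterns of
#' the overlapping SDPs across strains (1 when no segment overlaps).  The
#' cumulative-length summary is keyed by `class_paper`.
#'
#' @param segments A `hap_segments` object.
#' @param chrom_lengths Named vector of chromosome lengths in bp covering
#'   every chromosome with segments.
#' @return A `region_map`: list with `regions` (`chrom`, `start`, `end`,
#'   `n_segments`, `class_paper`, `class_joint`, `segment_ids`) and
#'   `summary` (`class_paper`, `bp`).  Region lengths sum exactly to the
#'   genome length.
#' @export
build_region_map <- function(segments, chrom_lengths) {
  stopifnot(inherits(segments, "hap_segments"))
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named", call. = FALSE)
  bad <- setdiff(unique(segments$chrom), names(chrom_lengths))
  if (length(bad))
    stop("no length for chromosome(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  catalog <- attr(segments, "catalog")
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) && any(s$end > len))
      stop("segment beyond length of chromosome ", ch, call. = FALSE)
    cuts <- sort(unique(c(1, s$start, s$end + 1)))
    cuts <- cuts[cuts <= len]
    starts <- cuts
    ends <- c(cuts[-1L] - 1, len)
    seg_rows <- as.integer(rownames(segments))[segments$chrom == ch]
    n_reg <- length(starts)
    df <- data.frame(chrom = rep(ch, n_reg), start = starts, end = ends,
                     n_segments = 0L, class_paper = 1L, class_joint = 1L,
                     segment_ids = rep("", n_reg),
                     stringsAsFactors = FALSE)
    if (nrow(s)) {
      row_of <- which(segments$chrom == ch)
      for (i in seq_len(n_reg)) {
        # regions are atomic: an overlapping segment covers the region
        ov <- which(s$start <= starts[i] & s$end >= ends[i])
        k <- length(ov)
        df$n_segments[i] <- k
        df$class_paper[i] <- k + 1L
        df$segment_ids[i] <- paste(row_of[ov], collapse = ",")
        if (k) {
          pats <- catalog[s$sdp[ov], , drop = FALSE]
          df$class_joint[i] <-
            length(unique(apply(pats, 2L, paste, collapse = "")))
        }
      }
    }
    out[[ch]] <- df
  }
  regions <- do.call(rbind, out)
  rownames(regions) <- NULL
  bp <- tapply(regions$end - regions$start + 1, regions$class_paper, sum)
  summary <- data.frame(class_paper = as.integer(names(bp)),
                        bp = as.numeric(bp))
  structure(list(regions = regions, summary = summary,
                 chrom_lengths = chrom_lengths),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map> ", nrow(x$regions), " regions over ",
      length(x$chrom_lengths), " chromosome(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

# segments of `segments` whose SDP assigns different alleles to a and b
divergent_segments <- function(segments, strain_a, strain_b) {
  catalog <- attr(segments, "catalog")
  strains <- attr(segments, "strains")
  missing <- setdiff(c(strain_a, strain_b), strains)
  if (length(missing))
    stop("unknown strain(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(segments) == 0L) return(segments[0L, , drop = FALSE])
  div <- catalog[segments$sdp, strain_a] != catalog[segments$sdp, strain_b]
  segments[div, , drop = FALSE]
}

#' Pairwise inter-strain haplotype diversity
#'
#' The proportion of the genome covered by ancestral haplotype segments
#' whose SDP assigns different alleles to the two strains.  Overlapping
#' divergent segments are merged before summing.  With
#' `normalize = "covered"` the denominator is the union length of all
#' segments instead of the genome length.
#'
#' @param segments A `hap_segments` object.
#' @param strain_a,strain_b Strain ids present in the segment catalog.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param normalize `"genome"` (default) or `"covered"`.
#' @return A proportion in `[0, 1]`.
#' @export
pairwise_diversity <- function(segments, strain_a, strain_b, chrom_lengths,
                               normalize = c("genome", "covered")) {
  normalize <- match.arg(normalize)
  div <- divergent_segments(segments, strain_a, strain_b)
  union_len <- function(df) {
    if (nrow(df) == 0L) return(0)
    sum(vapply(split(df, df$chrom), function(d) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$start, d$end))))
    }, 0))
  }
  denom <- if (normalize == "genome") sum(chrom_lengths)
           else union_len(segments)
  if (denom == 0) return(0)
  union_len(div) / denom
}

#' Does a position fall in a segment separating two strains?
#'
#' `TRUE` for positions inside at least one ancestral haplotype segment
#' whose SDP assigns different alleles to `strain_a` and `strain_b` — the
#' condition for a local (cis) genetic difference between the pair.
#'
#' @param chrom,pos Vectors of positions (recycled to common length).
#' @param segments A `hap_segments` object.
#' @param strain_a,strain_b Strain ids.
#' @return Logical vector, `NA` where `chrom`/`pos` is `NA`.
#' @export
classify_cis <- function(chrom, pos, segments, strain_a, strain_b) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  div <- divergent_segments(segments, strain_a, strain_b)
  out <- rep(FALSE, n)
  out[is.na(chrom) | is.na(pos)] <- NA
  if (nrow(div) == 0L) return(out)
  for (ch in unique(div$chrom)) {
    q <- which(!is.na(out) & chrom == ch)
    if (!length(q)) next
    d <- div[div$chrom == ch, , drop = FALSE]
    hits <- IRanges::countOverlaps(
      IRanges::IRanges(pos[q], pos[q]),
      IRanges::IRanges(d$start, d$end))
    out[q] <- hits > 0L
  }
  out
}
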