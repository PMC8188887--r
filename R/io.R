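#' Read homozygous strain genotypes from a VCF
#'
#' Parses a multi-sample VCF (via \pkg{VariantAnnotation}) and applies the
#' retention rules for inbred panels: multi-allelic records, records with
#' any heterozygous or missing genotype, and records failing the per-call
#' depth/quality pre-filters (when `DP`/`GQ` FORMAT fields are present)
#' are dropped, with per-reason counts reported.
#'
#' @param path VCF file (plain or bgzipped).
#' @param min_depth Minimum per-call read depth when `DP` is present
#'   (default 4).
#' @param min_gq Minimum per-call genotype quality when `GQ` is present
#'   (default 10).
#' @return A [genotype_table()].
#' @export
read_genotypes_vcf <- function(path, min_depth = 4, min_gq = 10) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  n <- nrow(gt)
  multi <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) != 1L
  hom <- apply(gt, 1L, function(g) all(g %in% c("0/0", "0|0", "1/1", "1|1")))
  lowdp <- rep(FALSE, n); lowgq <- rep(FALSE, n)
  gmat <- VariantAnnotation::geno(vcf)
  if ("DP" %in% names(gmat)) {
    dp <- gmat$DP
    lowdp <- apply(dp, 1L, function(d) any(is.na(d) | d < min_depth))
  }
  if ("GQ" %in% names(gmat)) {
    gq <- gmat$GQ
    lowgq <- apply(gq, 1L, function(g) any(is.na(g) | g < min_gq))
  }
  keep <- !multi & hom & !lowdp & !lowgq
  message("dropped ", sum(!keep), "/", n, " records (",
          sum(multi), " multi-allelic, ", sum(!hom & !multi),
          " het/missing, ", sum(lowdp), " low depth, ",
          sum(lowgq), " low GQ)")
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  gtk <- gt[keep, , drop = FALSE]
  calls <- matrix(as.integer(gtk %in% c("1/1", "1|1")),
                  nrow = nrow(gtk))   # variants x strains
  variants <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)[keep]),
    alt = vapply(as.list(VariantAnnotation::alt(vcf)[keep]),
                 function(a) as.character(a)[1L], ""),
    stringsAsFactors = FALSE)
  genotype_table(colnames(gtk), variants, t(calls))
}

#' Write a genotype table as VCF
#'
#' Emits a minimal VCF 4.2 with homozygous `GT` calls (`0/0` / `1/1`),
#' and optional constant-free `DP`/`GQ` matrices for testing read-side
#' filters.
#'
#' @param geno A [genotype_table()].
#' @param path Output path.
#' @param chrom_lengths Optional named lengths written as `##contig`
#'   header lines.
#' @param dp,gq Optional strains x variants integer matrices appended as
#'   `DP`/`GQ` FORMAT fields.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path, chrom_lengths = NULL,
                                dp = NULL, gq = NULL) {
  stopifnot(inherits(geno, "genotype_table"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=strainmapqtl",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(dp))
    hdr <- c(hdr, paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                         "Description=\"Read depth\">"))
  if (!is.null(gq))
    hdr <- c(hdr, paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                         "Description=\"Genotype quality\">"))
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths),
                          as.integer(chrom_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", geno$strains),
                      collapse = "\t"))
  fmt <- paste(c("GT", if (!is.null(dp)) "DP", if (!is.null(gq)) "GQ"),
               collapse = ":")
  v <- geno$variants
  lines <- vapply(seq_len(nrow(v)), function(i) {
    cells <- vapply(seq_along(geno$strains), function(s) {
      g <- if (geno$calls[s, i] == 1L) "1/1" else "0/0"
      paste(c(g, if (!is.null(dp)) dp[s, i], if (!is.null(gq)) gq[s, i]),
            collapse = ":")
    }, "")
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            ".", fmt, cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write haplotype segments as BED6
#'
#' Internal 1-based inclusive coordinates are converted to the BED
#' 0-based half-open convention; `name` holds the SDP id and `score` the
#' supporting variant count.  Lines are sorted by chromosome then start.
#'
#' @param segments A `hap_segments` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  stopifnot(inherits(segments, "hap_segments"))
  lines <- "# strainmapqtl ancestral haplotype segments (BED6)"
  if (nrow(segments)) {
    o <- order(segments$chrom, segments$start)
    s <- segments[o, , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t%d\tsdp%d\t%d\t+",
                              s$chrom, s$start - 1L, s$end, s$sdp,
                              s$n_support))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read segments written by [write_segments_bed()]
#'
#' Restores the internal 1-based inclusive coordinates.  The SDP catalog
#' is not representable in BED, so the result carries intervals, ids and
#' support counts only.
#'
#' @param path BED file.
#' @return `data.frame` with `chrom`, `start`, `end`, `sdp`, `n_support`.
#' @export
read_segments_bed <- function(path) {
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (!length(body))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sdp = integer(),
                      n_support = integer(), stringsAsFactors = FALSE))
  g <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(g)),
             start = BiocGenerics::start(g),
             end = BiocGenerics::end(g),
             sdp = as.integer(sub("^sdp", "", g$name)),
             n_support = as.integer(g$score),
             stringsAsFactors = FALSE)
}

# read a TSV, tolerating '#' comment lines before/inside the header
read_tsv_commented <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#")]
  data.table::fread(text = paste(raw, collapse = "\n"), sep = "\t",
                    na.strings = "NA", data.table = FALSE)
}

write_tsv_commented <- function(df, path, comment = NULL) {
  append <- FALSE
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    append <- TRUE
  }
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE,
                     append = append, col.names = TRUE)
  invisible(path)
}

#' Write a cross dataset as map + genotype/phenotype TSVs
#'
#' @param cross A `cross_dataset`.
#' @param map_path Marker map TSV (`marker`, `chrom`, `cM`).
#' @param data_path Data TSV: one row per individual with `individual`,
#'   `sex`, one column per marker (`AA`/`AB`/`BB`/`NA`) and one per
#'   phenotype.
#' @return `data_path`, invisibly.
#' @export
write_cross_tsv <- function(cross, map_path, data_path) {
  stopifnot(inherits(cross, "cross_dataset"))
  write_tsv_commented(cross$markers, map_path,
                      comment = paste("marker map,", cross$cross_type))
  df <- data.frame(individual = seq_len(nrow(cross$geno)),
                   sex = cross$sex, cross$geno, cross$phenotypes,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv_commented(df, data_path,
                      comment = paste("cross data,", cross$cross_type))
  invisible(data_path)
}

#' Read a cross dataset from map + data TSVs
#'
#' Columns of the data TSV named in the map are marker genotypes; the
#' remaining numeric columns (other than `individual`) are phenotypes.
#'
#' @param map_path,data_path Files written by [write_cross_tsv()] or of
#'   the same layout.
#' @param cross_type `"F2"` or `"backcross"`.
#' @return A `cross_dataset`.
#' @export
read_cross_tsv <- function(map_path, data_path,
                           cross_type = c("F2", "backcross")) {
  cross_type <- match.arg(cross_type)
  markers <- read_tsv_commented(map_path)
  stopifnot(all(c("marker", "chrom", "cM") %in% names(markers)))
  markers$chrom <- as.character(markers$chrom)
  dat <- read_tsv_commented(data_path)
  miss <- setdiff(markers$marker, names(dat))
  if (length(miss))
    stop("marker(s) missing from data file: ",
         paste(miss, collapse = ", "), call. = FALSE)
  geno <- as.matrix(dat[, markers$marker, drop = FALSE])
  legal <- if (cross_type == "F2") c("AA", "AB", "BB") else c("AA", "AB")
  badv <- setdiff(unique(as.vector(geno)), c(legal, NA_character_))
  if (length(badv))
    stop("illegal genotype code(s): ", paste(badv, collapse = ", "),
         call. = FALSE)
  ph_cols <- setdiff(names(dat), c("individual", "sex", markers$marker))
  structure(list(cross_type = cross_type,
                 markers = as.data.frame(markers),
                 geno = geno,
                 sex = if ("sex" %in% names(dat)) as.character(dat$sex)
                       else rep(NA_character_, nrow(dat)),
                 phenotypes = dat[, ph_cols, drop = FALSE]),
            class = "cross_dataset")
}

#' Write / read an expression matrix as TSVs
#'
#' The matrix TSV holds `probe` plus one column per sample; sidecars hold
#' the probe annotation (`probe`, `chrom`, `pos`, `flag`) and the sample
#' annotation (`sample`, `strain`, ...).
#'
#' @param em An [expression_matrix()].
#' @param matrix_path,probes_path,samples_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_tsv <- function(em, matrix_path, probes_path,
                                 samples_path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(probe = em$probes$probe, em$mat,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv_commented(df, matrix_path, comment = "log2 intensities")
  write_tsv_commented(em$probes, probes_path, comment = "probe annotation")
  write_tsv_commented(em$samples, samples_path,
                      comment = "sample annotation")
  invisible(matrix_path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(matrix_path, probes_path, samples_path) {
  m <- read_tsv_commented(matrix_path)
  probes <- read_tsv_commented(probes_path)
  samples <- read_tsv_commented(samples_path)
  mat <- as.matrix(m[, setdiff(names(m), "probe"), drop = FALSE])
  rownames(mat) <- m$probe
  probes <- probes[match(m$probe, probes$probe), , drop = FALSE]
  expression_matrix(probes, samples,
                    mat[, samples$sample, drop = FALSE])
}
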