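#' Genotype table of homozygous calls for an inbred strain panel
#'
#' Container for biallelic, fully homozygous genotype calls across a panel of
#' inbred strains.  Heterozygous or missing calls are not representable: they
#' must be filtered upstream (see [read_genotypes_vcf()]).  Calls are coded
#' `0` (reference homozygote) and `1` (alternate homozygote).
#'
#' @param strains Character vector of strain identifiers (ordered; the first
#'   strain anchors SDP canonicalization).
#' @param variants `data.frame` with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`.  Positions must be strictly increasing within each
#'   chromosome and rows ordered by chromosome then position.
#' @param calls Integer matrix, strains x variants, values in `{0, 1}`.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `strains`, `variants` and `calls`.
#' @examples
#' gt <- genotype_table(
#'   strains  = c("S1", "S2"),
#'   variants = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                         ref = "A", alt = "G"),
#'   calls    = rbind(c(0L, 0L), c(1L, 1L))
#' )
#' @export
genotype_table <- function(strains, variants, calls) {
  strains <- as.character(strains)
  if (anyDuplicated(strains)) stop("duplicate strain ids", call. = FALSE)
  if (length(strains) < 1L) stop("need at least one strain", call. = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns chrom, pos, ref, alt", call. = FALSE)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(strains) || ncol(calls) != nrow(variants))
    stop("calls must be a strains x variants matrix", call. = FALSE)
  if (anyNA(calls) || !all(calls %in% c(0L, 1L)))
    stop("calls must be homozygous 0/1 with no missing values",
         call. = FALSE)
  # positions strictly increasing per chromosome, chromosome blocks contiguous
  if (nrow(variants) > 0L) {
    if (anyDuplicated(rle(variants$chrom)$values))
      stop("variants of one chromosome must be contiguous", call. = FALSE)
    for (ch in unique(variants$chrom)) {
      p <- variants$pos[variants$chrom == ch]
      if (any(diff(p) <= 0))
        stop("positions must be strictly increasing within chromosome ",
             ch, call. = FALSE)
    }
  }
  rownames(calls) <- strains
  structure(list(strains = strains, variants = variants, calls = calls),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", length(x$strains), " strains x ",
      nrow(x$variants), " variants on ",
      length(unique(x$variants$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Subset a genotype table to a strain panel
#'
#' Pre-filter used before re-enumerating SDPs on a strain subset (e.g. the
#' colony-derived strains of a larger panel).  Variants that become
#' monomorphic in the subset are retained; SDP enumeration flags them.
#'
#' @param geno A [genotype_table()].
#' @param strains Character vector of strains to keep, in the desired order.
#' @return A `genotype_table` restricted to `strains`.
#' @export
subset_strains <- function(geno, strains) {
  stopifnot(inherits(geno, "genotype_table"))
  missing <- setdiff(strains, geno$strains)
  if (length(missing))
    stop("unknown strain(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  genotype_table(strains, geno$variants,
                 geno$calls[match(strains, geno$strains), , drop = FALSE])
}
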