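# Independent brute-force oracles.  These deliberately avoid the package's
# vectorized/IRanges code paths: everything is plain loops over variants,
# positions and base pairs.

# canonical SDP enumeration by direct per-variant comparison
oracle_sdps <- function(geno) {
  calls <- geno$calls
  pats <- character(ncol(calls))
  for (j in seq_len(ncol(calls))) {
    v <- calls[, j]
    if (v[1] == 1) v <- 1 - v
    pats[j] <- paste(v, collapse = "")
  }
  mono <- pats == paste(rep(0, nrow(calls)), collapse = "")
  uniq <- unique(pats[!mono])
  assignment <- rep(NA_integer_, ncol(calls))
  assignment[!mono] <- match(pats[!mono], uniq)
  catalog <- do.call(rbind, lapply(strsplit(uniq, ""), as.integer))
  if (is.null(catalog)) catalog <- matrix(0L, 0, nrow(calls))
  colnames(catalog) <- geno$strains
  rownames(catalog) <- seq_len(nrow(catalog))
  list(catalog = catalog, assignment = assignment)
}

# direct segment scan: for one SDP on one chromosome, walk supporting
# variants and count intervening polymorphic variants one by one
oracle_segments <- function(geno, sdps, min_run, max_gap) {
  v <- geno$variants
  out <- list()
  for (ch in unique(v$chrom)) {
    on_ch <- which(v$chrom == ch & !is.na(sdps$assignment))
    ids <- sdps$assignment[on_ch]
    for (id in unique(ids)) {
      sup <- on_ch[ids == id]
      runs <- list(sup[1])
      if (length(sup) > 1) for (k in 2:length(sup)) {
        # count polymorphic variants strictly between sup[k-1] and sup[k]
        between <- sum(on_ch > sup[k - 1] & on_ch < sup[k])
        if (between < max_gap)
          runs[[length(runs)]] <- c(runs[[length(runs)]], sup[k])
        else runs[[length(runs) + 1]] <- sup[k]
      }
      for (r in runs) if (length(r) >= min_run)
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = v$pos[r[1]], end = v$pos[r[length(r)]],
          sdp = id, n_support = length(r), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sdp = integer(),
                      n_support = integer()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$sdp), , drop = FALSE]
}

# per-position count of distinct strain haplotype vectors given segments
oracle_class_at <- function(segments, catalog, ch, pos) {
  ov <- which(segments$chrom == ch & segments$start <= pos &
              segments$end >= pos)
  if (!length(ov)) return(c(paper = 1L, joint = 1L))
  pats <- catalog[segments$sdp[ov], , drop = FALSE]
  joint <- length(unique(apply(pats, 2, paste, collapse = "")))
  c(paper = length(ov) + 1L, joint = joint)
}

# base-resolution union length of intervals (small genomes only)
oracle_union_len <- function(df, chrom_lengths) {
  total <- 0L
  for (ch in names(chrom_lengths)) {
    covered <- logical(chrom_lengths[[ch]])
    d <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) covered[d$start[i]:d$end[i]] <- TRUE
    total <- total + sum(covered)
  }
  total
}

# interval stabbing by explicit loop
oracle_stab <- function(segments, catalog, strain_a, strain_b, chrom, pos) {
  out <- logical(length(pos))
  for (i in seq_along(pos)) {
    hit <- FALSE
    for (j in seq_len(nrow(segments))) {
      if (segments$chrom[j] == chrom[i] &&
          segments$start[j] <= pos[i] && segments$end[j] >= pos[i] &&
          catalog[segments$sdp[j], strain_a] !=
            catalog[segments$sdp[j], strain_b]) { hit <- TRUE; break }
    }
    out[i] <- hit
  }
  out
}

# random genotype table fixture
random_genotype_table <- function(n_strains, n_variants, n_chrom = 1,
                                  p_alt = 0.4) {
  chroms <- paste0("chr", seq_len(n_chrom))
  per <- diff(floor(seq(0, n_variants, length.out = n_chrom + 1)))
  variants <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
    n <- per[ci]
    data.frame(chrom = chroms[ci],
               pos = sort(sample.int(n * 50L + 10L, n)),
               ref = "A", alt = "G", stringsAsFactors = FALSE)
  }))
  calls <- matrix(rbinom(n_strains * nrow(variants), 1, p_alt),
                  nrow = n_strains)
  genotype_table(paste0("S", seq_len(n_strains)), variants, calls)
}
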