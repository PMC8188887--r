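# plain interval arithmetic on (start, end) integer intervals, 1-based
# inclusive; used for truth/recovery comparisons without IRanges

merge_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = integer(),
                                        end = integer()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- c(); oute <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) me <- max(me, end[i])
    else { outs <- c(outs, ms); oute <- c(oute, me)
           ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

interval_len <- function(iv) sum(iv$end - iv$start + 1)

intersect_intervals <- function(a, b) {
  outs <- c(); oute <- c()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (s <= e) { outs <- c(outs, s); oute <- c(oute, e) }
  }
  merge_intervals(outs, oute)
}

jaccard_intervals <- function(a, b) {
  a <- merge_intervals(a$start, a$end)
  b <- merge_intervals(b$start, b$end)
  inter <- interval_len(intersect_intervals(a, b))
  union <- interval_len(a) + interval_len(b) - inter
  if (union == 0) return(1)
  inter / union
}

# true divergent founder blocks on one chromosome: intervals where >= 2
# distinct founders are present among the strains
true_divergent_blocks <- function(true_segments, chrom) {
  d <- true_segments[true_segments$chrom == chrom, ]
  cuts <- sort(unique(c(d$start, d$end + 1)))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1] - 1
  div <- vapply(seq_along(starts), function(i) {
    f <- d$founder[d$start <= starts[i] & d$end >= starts[i]]
    length(unique(f)) >= 2
  }, TRUE)
  merge_intervals(starts[div], ends[div])
}
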