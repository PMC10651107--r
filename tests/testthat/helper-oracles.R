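# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (dense arrays, all-pairs loops) so they share no code
# path with the implementation they check.

# dense per-base expansion of a (start, end, value) interval table
dense_signal <- function(intervals, chrom_len) {
  v <- numeric(chrom_len)
  for (i in seq_len(nrow(intervals))) {
    v[(intervals$start[i] + 1):intervals$end[i]] <- intervals$value[i]
  }
  v
}

# per-base window read off the dense array; out-of-bounds bases are 0
oracle_window_values <- function(dense, start, end, strand = "+") {
  pos <- seq(start, end - 1)
  out <- numeric(length(pos))
  inb <- pos >= 0 & pos < length(dense)
  out[inb] <- dense[pos[inb] + 1]
  if (strand == "-") rev(out) else out
}

# random non-overlapping sorted intervals on one chromosome
rand_intervals <- function(chrom_len = 10000, n = 30, chrom = "chr1") {
  cuts <- sort(sample(0:chrom_len, 2 * n))
  starts <- cuts[seq(1, 2 * n, by = 2)]
  ends <- cuts[seq(2, 2 * n, by = 2)]
  keep <- starts < ends
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             value = round(stats::runif(sum(keep), 0, 10), 3))
}

rand_annotation <- function(n = 20, chrom_len = 100000, chrom = "chr1",
                            min_len = 200, max_len = 4000) {
  start <- sort(sample(0:(chrom_len - max_len - 1), n))
  len <- sample(min_len:max_len, n, replace = TRUE)
  genome_annotation(data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
    start = start, end = pmin(start + len, chrom_len),
    strand = sample(c("+", "-"), n, replace = TRUE)))
}

rand_peaks <- function(n = 50, chrom_len = 100000, chrom = "chr1") {
  start <- sample(0:(chrom_len - 1000), n, replace = TRUE)
  peak_set(data.frame(chrom = chrom, start = start,
                      end = start + sample(50:800, n, replace = TRUE)))
}

# all-pairs strand-aware window overlap, straight from the assignment rule
oracle_assign <- function(peaks, annotation, upstream = 1000, past_tes = 100) {
  out <- list()
  for (g in seq_len(nrow(annotation))) {
    if (annotation$strand[g] == "+") {
      ws <- annotation$start[g] - upstream
      we <- annotation$end[g] + past_tes
    } else {
      ws <- annotation$start[g] - past_tes
      we <- annotation$end[g] + upstream
    }
    ws <- max(ws, 0)
    hit <- integer(0)
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] == annotation$chrom[g] &&
          max(peaks$start[p], ws) < min(peaks$end[p], we)) {
        hit <- c(hit, p)
      }
    }
    if (length(hit) > 0L) out[[annotation$gene_id[g]]] <- hit
  }
  out
}

# single-chromosome constant-value track
constant_track <- function(value, chrom_len = 100000, chrom = "chr1") {
  signal_track(data.frame(chrom = chrom, start = 0, end = chrom_len,
                          value = value))
}
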