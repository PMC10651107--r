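#' Construct a signal track
#'
#' A signal track stores genome-wide coverage/enrichment as per-chromosome
#' ordered, non-overlapping `(start, end, value)` intervals (0-based
#' half-open). Bases not covered by any interval have implicit value 0.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param chrom_sizes optional named numeric vector of chromosome lengths;
#'   when known, window queries count bases beyond chromosome bounds as
#'   clipped (they contribute value 0).
#' @return A `signal_track` object.
#' @export
signal_track <- function(intervals, chrom_sizes = NULL) {
  required <- c("chrom", "start", "end", "value")
  missing_cols <- setdiff(required, names(intervals))
  if (length(missing_cols) > 0L) {
    stop("signal intervals missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  intervals <- as.data.frame(intervals)[required]
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  intervals$value <- as.numeric(intervals$value)
  if (anyNA(intervals$value) || any(!is.finite(intervals$value))) {
    stop("signal values must be finite")
  }
  if (any(intervals$start >= intervals$end)) stop("interval with start >= end")
  if (any(intervals$start < 0)) stop("negative interval start")
  chroms <- split(intervals, intervals$chrom)
  chroms <- lapply(chroms, function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    if (nrow(df) > 1L) {
      ov <- which(df$start[-1L] < df$end[-nrow(df)])
      if (length(ov) > 0L) {
        i <- ov[1L]
        stop(sprintf(
          "overlapping intervals on %s: [%s,%s) and [%s,%s)",
          df$chrom[1L],
          format(df$start[i], scientific = FALSE),
          format(df$end[i], scientific = FALSE),
          format(df$start[i + 1L], scientific = FALSE),
          format(df$end[i + 1L], scientific = FALSE)))
      }
    }
    rownames(df) <- NULL
    df
  })
  structure(list(chroms = chroms, chrom_sizes = chrom_sizes),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  n <- sum(vapply(x$chroms, nrow, 0L))
  cat(sprintf("signal_track: %d interval(s) on %d chromosome(s)\n",
              n, length(x$chroms)))
  invisible(x)
}

#' Read a 4-column bedGraph file
#'
#' Track definition lines and `#` comments are tolerated. Intervals that
#' overlap within a chromosome are rejected (the error names the pair);
#' non-numeric values are an error.
#'
#' @param path bedGraph file path.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  scan <- .scan_tab_file(path, min_fields = 4L)
  if (length(scan$lines) == 0L) {
    return(signal_track(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0), value = numeric(0)),
                        chrom_sizes))
  }
  fields <- strsplit(scan$lines, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
    value = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value))
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: non-numeric field",
                 scan$line_no[bad[1]], basename(path)))
  }
  signal_track(df, chrom_sizes)
}

#' Write a signal track as bedGraph
#'
#' @param track a [signal_track()].
#' @param path output file path.
#' @export
write_bedgraph <- function(track, path) {
  all <- do.call(rbind, track$chroms)
  if (is.null(all)) all <- data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), value = numeric(0))
  df <- data.frame(all$chrom,
                   format(all$start, scientific = FALSE, trim = TRUE),
                   format(all$end, scientific = FALSE, trim = TRUE),
                   format(all$value, scientific = FALSE, trim = TRUE, digits = 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Count of v[i] <= x for sorted v (binary search; the constructor already
## guarantees sorted finite coordinates, so no per-query O(n) checks).
.n_le <- function(v, x) {
  lo <- 0L
  hi <- length(v)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (v[mid] <= x) lo <- mid else hi <- mid - 1L
  }
  lo
}

## Overlapping-interval run for a sorted chromosome table: contiguous indices.
.overlap_run <- function(df, start, end) {
  if (is.null(df) || nrow(df) == 0L) return(integer(0))
  i <- .n_le(df$end, start) + 1L   # first interval with end > start
  j <- .n_le(df$start, end - 1)    # last interval with start < end
  if (i > j) return(integer(0))
  i:j
}

.clipped_count <- function(track, chrom, start, end) {
  clipped <- if (start < 0) min(end, 0) - start else 0   # bases below position 0
  if (!is.null(track$chrom_sizes) && chrom %in% names(track$chrom_sizes)) {
    size <- track$chrom_sizes[[chrom]]
    if (end > size) clipped <- clipped + (end - max(start, size))
  }
  clipped
}

#' Per-base signal values over a window
#'
#' Returns one value per base over `[start, end)`. Uncovered positions and
#' positions beyond chromosome bounds yield 0; the number of out-of-bounds
#' bases is attached as attribute `"clipped"`. For `strand = "-"` the vector
#' is reversed so that index 1 is the most 5' position in transcription
#' orientation. A query on an unknown chromosome returns zeros with a
#' warning.
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window; `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector of length `end - start` with attribute `clipped`.
#' @export
window_values <- function(track, chrom, start, end, strand = "+") {
  if (start >= end) stop("window start must be < end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  n <- end - start
  out <- numeric(n)
  df <- track$chroms[[chrom]]
  if (is.null(df)) {
    warning("chromosome '", chrom, "' not present in signal track; returning zeros",
            call. = FALSE)
  } else {
    for (k in .overlap_run(df, start, end)) {
      s <- max(df$start[k], start)
      e <- min(df$end[k], end)
      out[(s - start + 1):(e - start)] <- df$value[k]
    }
  }
  if (strand == "-") out <- rev(out)
  attr(out, "clipped") <- .clipped_count(track, chrom, start, end)
  out
}

## sum of signal over [start, end) without per-base expansion
.window_sum <- function(track, chrom, start, end, warn = TRUE) {
  df <- track$chroms[[chrom]]
  if (is.null(df)) {
    if (warn) warning("chromosome '", chrom,
                      "' not present in signal track; returning zeros",
                      call. = FALSE)
    return(0)
  }
  run <- .overlap_run(df, start, end)
  if (length(run) == 0L) return(0)
  s <- pmax(df$start[run], start)
  e <- pmin(df$end[run], end)
  sum(df$value[run] * (e - s))
}

#' Mean signal over a window
#'
#' Arithmetic mean of [window_values()] over `[start, end)`: the "enrichment
#' value" of a region. Uncovered and out-of-bounds bases count as 0 in the
#' mean, so the result is the window sum divided by the window length.
#'
#' @inheritParams window_values
#' @return A single numeric value.
#' @export
window_mean <- function(track, chrom, start, end) {
  if (start >= end) stop("zero-length window")
  .window_sum(track, chrom, start, end) / (end - start)
}
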