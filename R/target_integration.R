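#' Construct a peak set
#'
#' Peaks are genomic intervals (0-based half-open) with an optional score and
#' an optional summit offset relative to the peak start.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `summit` (offset in `[0, end - start)`, or
#'   `NA`/`-1` for unknown).
#' @return A `peak_set` data.frame.
#' @export
peak_set <- function(peaks) {
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0L) {
    stop("peak table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  peaks <- as.data.frame(peaks)
  peaks$chrom <- as.character(peaks$chrom)
  peaks$start <- as.numeric(peaks$start)
  peaks$end <- as.numeric(peaks$end)
  if (!"name" %in% names(peaks)) {
    peaks$name <- if (nrow(peaks) > 0L) sprintf("peak_%d", seq_len(nrow(peaks))) else character(0)
  }
  if (!"score" %in% names(peaks)) peaks$score <- rep(0, nrow(peaks))
  if (!"summit" %in% names(peaks)) peaks$summit <- rep(NA_real_, nrow(peaks))
  peaks$summit[!is.na(peaks$summit) & peaks$summit < 0] <- NA_real_
  if (any(peaks$start >= peaks$end)) stop("peak with start >= end")
  width <- peaks$end - peaks$start
  bad <- !is.na(peaks$summit) & peaks$summit >= width
  if (any(bad)) stop("peak summit offset outside peak width")
  rownames(peaks) <- NULL
  structure(peaks[, c("chrom", "start", "end", "name", "score", "summit")],
            class = c("peak_set", "data.frame"))
}

#' Read peak calls (BED3+ or ENCODE narrowPeak)
#'
#' Column count decides the format: 10 columns are read as narrowPeak (the
#' last column is the summit offset, `-1` meaning unknown); otherwise the
#' first three (plus optional name/score) BED columns are used.
#'
#' @param path file path.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path) {
  scan <- .scan_tab_file(path, min_fields = 3L)
  if (length(scan$lines) == 0L) {
    return(peak_set(data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0))))
  }
  fields <- strsplit(scan$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  df <- data.frame(
    chrom = get_col(1L),
    start = suppressWarnings(as.numeric(get_col(2L))),
    end = suppressWarnings(as.numeric(get_col(3L))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: non-numeric coordinates",
                 scan$line_no[bad[1]], basename(path)))
  }
  if (any(nf >= 4L)) df$name <- get_col(4L, default = "")
  if (any(nf >= 5L)) df$score <- suppressWarnings(as.numeric(get_col(5L, "0")))
  if (all(nf >= 10L)) {
    summit <- suppressWarnings(as.numeric(get_col(10L)))
    summit[!is.na(summit) & summit < 0] <- NA_real_
    df$summit <- summit
  }
  peak_set(df)
}

#' Write a peak set as a 10-column narrowPeak file
#'
#' @param peaks a [peak_set()].
#' @param path output file path.
#' @export
write_narrowpeak <- function(peaks, path) {
  summit <- ifelse(is.na(peaks$summit), -1, peaks$summit)
  df <- data.frame(peaks$chrom,
                   format(peaks$start, scientific = FALSE, trim = TRUE),
                   format(peaks$end, scientific = FALSE, trim = TRUE),
                   peaks$name, peaks$score, ".", 0, -1, -1,
                   format(summit, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read simple BED intervals (e.g. enhancer sets)
#'
#' @param path BED3+ file path.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_intervals <- function(path) {
  scan <- .scan_tab_file(path, min_fields = 3L)
  if (length(scan$lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  fields <- strsplit(scan$lines, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s", scan$line_no[bad[1]], basename(path)))
  }
  df
}

#' Read a differential-expression table
#'
#' Tab-separated with header `gene_id  log2fc  pvalue  fdr`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_id`, `log2fc`, `p_value`, `fdr`.
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  names(df)[names(df) == "pvalue"] <- "p_value"
  required <- c("gene_id", "log2fc", "p_value", "fdr")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("DE table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  .validate_de(df[required])
}

.validate_de <- function(df) {
  if (any(!is.finite(df$log2fc))) stop("log2fc must be finite")
  if (any(df$p_value < 0 | df$p_value > 1)) stop("p_value outside [0,1]")
  if (any(df$fdr < 0 | df$fdr > 1)) stop("fdr outside [0,1]")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in DE table")
  df
}

#' Read an expression (FPKM) table
#'
#' Tab-separated with header `gene_id  fpkm`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_id`, `fpkm`.
#' @export
read_fpkm_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("gene_id", "fpkm") %in% names(df))) {
    stop("FPKM table must have columns gene_id, fpkm")
  }
  if (any(df$fpkm < 0)) stop("negative FPKM")
  df[, c("gene_id", "fpkm")]
}

#' Perturbation configuration for direct-target calling
#'
#' Encodes the experimental design used to generate the differential
#' expression: under a knockdown, a gene that goes up when the factor is
#' removed is repressed by the factor; under overexpression the sign logic
#' is inverted. Default thresholds follow the originating analyses:
#' FDR < 0.05 for the knockdown (SIN3 220) data, FDR < 0.001 for the
#' overexpression (SIN3 187) data, and p < 0.05 in both.
#'
#' @param polarity `"knockdown"` or `"overexpression"`.
#' @param fdr_threshold FDR significance cutoff, in (0, 1).
#' @param p_threshold p-value cutoff, in (0, 1).
#' @return A `perturbation_config` list.
#' @export
perturbation_config <- function(polarity = c("knockdown", "overexpression"),
                                fdr_threshold = 0.05, p_threshold = 0.05) {
  polarity <- match.arg(polarity)
  if (!(fdr_threshold > 0 && fdr_threshold < 1)) stop("fdr_threshold outside (0,1)")
  if (!(p_threshold > 0 && p_threshold < 1)) stop("p_threshold outside (0,1)")
  structure(list(polarity = polarity, fdr_threshold = fdr_threshold,
                 p_threshold = p_threshold),
            class = "perturbation_config")
}

#' Assign peaks to genes by a strand-aware TSS-to-past-TES window
#'
#' A peak is assigned to a gene when it overlaps by at least one base the
#' window running from `upstream_bp` upstream of the TSS through
#' `past_tes_bp` past the TES, in transcription orientation. In genomic
#' coordinates that is `[start - upstream_bp, end + past_tes_bp)` for a `+`
#' strand gene and `[start - past_tes_bp, end + upstream_bp)` for a `-`
#' strand gene. Windows falling below position 0 are clipped. A peak may be
#' assigned to several (overlapping) genes; genes without peaks are absent
#' from the result.
#'
#' @param peaks a [peak_set()] or data.frame with `chrom`, `start`, `end`.
#' @param annotation a [genome_annotation()].
#' @param upstream_bp bases upstream of the TSS included (default 1000).
#' @param past_tes_bp bases past the TES included (default 100).
#' @return Named list, `gene_id` -> data.frame of assigned peak rows.
#' @export
assign_peaks_to_genes <- function(peaks, annotation, upstream_bp = 1000,
                                  past_tes_bp = 100) {
  if (upstream_bp < 0 || past_tes_bp < 0) stop("window extensions must be >= 0")
  if (nrow(peaks) == 0L || nrow(annotation) == 0L) return(stats::setNames(list(), character(0)))
  plus <- annotation$strand == "+"
  wstart <- ifelse(plus, annotation$start - upstream_bp,
                   annotation$start - past_tes_bp)
  wend <- ifelse(plus, annotation$end + past_tes_bp,
                 annotation$end + upstream_bp)
  n_clip <- sum(wstart < 0)
  if (n_clip > 0L) {
    message(n_clip, " gene window(s) clipped at chromosome start")
    wstart <- pmax(wstart, 0)
  }
  gene_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(wstart + 1, wend))
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  hits <- GenomicRanges::findOverlaps(peak_gr, gene_gr, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(stats::setNames(list(), character(0)))
  by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  out <- lapply(by_gene, function(i) as.data.frame(peaks)[i, , drop = FALSE])
  names(out) <- annotation$gene_id[as.integer(names(by_gene))]
  out
}

#' Classify differential-expression direction under a perturbation design
#'
#' A record is `not_significant` when it misses either threshold or has
#' `log2fc == 0` (direction undefined). Otherwise, under a knockdown, a
#' positive log2FC (gene up when the factor is removed) means the gene is
#' repressed by the factor; under overexpression the mapping is inverted.
#'
#' @param de data.frame with columns `gene_id`, `log2fc`, `p_value`, `fdr`
#'   (one or more rows).
#' @param config a [perturbation_config()].
#' @return Character vector, one of `"repressed"`, `"activated"`,
#'   `"not_significant"` per row.
#' @export
classify_direction <- function(de, config) {
  .validate_de(de)
  sig <- de$fdr <= config$fdr_threshold & de$p_value <= config$p_threshold &
    de$log2fc != 0
  up_means_repressed <- config$polarity == "knockdown"
  dir <- ifelse((de$log2fc > 0) == up_means_repressed, "repressed", "activated")
  ifelse(sig, dir, "not_significant")
}

#' Build a direct-target table
#'
#' Direct targets are the genes both bound by the factor (at least one
#' assigned peak) and significantly differentially expressed on perturbing
#' it. DE records whose gene_id is absent from the annotation are dropped
#' with a message.
#'
#' @param peaks a [peak_set()].
#' @param annotation a [genome_annotation()].
#' @param de differential-expression table (see [read_de_table()]).
#' @param config a [perturbation_config()].
#' @param label character label for the table (isoform / sample name).
#' @param upstream_bp,past_tes_bp passed to [assign_peaks_to_genes()].
#' @return A `direct_target_table`: data.frame with columns `gene_id`,
#'   `bound`, `n_peaks`, `direction`, `log2fc`, `fdr`, with the label as an
#'   attribute.
#' @export
build_direct_targets <- function(peaks, annotation, de, config,
                                 label = "targets", upstream_bp = 1000,
                                 past_tes_bp = 100) {
  unmatched <- setdiff(de$gene_id, annotation$gene_id)
  if (length(unmatched) > 0L) {
    message(length(unmatched),
            " DE record(s) with gene_id absent from annotation dropped")
    de <- de[!de$gene_id %in% unmatched, , drop = FALSE]
  }
  assignment <- assign_peaks_to_genes(peaks, annotation, upstream_bp, past_tes_bp)
  n_peaks <- vapply(assignment, nrow, 0L)
  direction <- classify_direction(de, config)
  keep <- de$gene_id %in% names(assignment) & direction != "not_significant"
  out <- data.frame(
    gene_id = de$gene_id[keep],
    bound = rep(TRUE, sum(keep)),
    n_peaks = as.integer(n_peaks[de$gene_id[keep]]),
    direction = direction[keep],
    log2fc = de$log2fc[keep],
    fdr = de$fdr[keep],
    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) message("no direct targets: empty bound x significant intersection")
  rownames(out) <- NULL
  direct_target_table(out, label)
}

#' Construct a direct-target table from its columns
#'
#' Used by [build_direct_targets()] and available directly for tables built
#' from published counts.
#'
#' @param df data.frame with columns `gene_id`, `direction`, `log2fc` and
#'   optionally `bound`, `n_peaks`, `fdr`.
#' @param label table label.
#' @return A `direct_target_table`.
#' @export
direct_target_table <- function(df, label = "targets") {
  df <- as.data.frame(df)
  if (!"bound" %in% names(df)) df$bound <- rep(TRUE, nrow(df))
  if (!"n_peaks" %in% names(df)) df$n_peaks <- rep(1L, nrow(df))
  if (!"fdr" %in% names(df)) df$fdr <- rep(0, nrow(df))
  required <- c("gene_id", "bound", "n_peaks", "direction", "log2fc", "fdr")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("direct-target table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!df$direction %in% c("repressed", "activated"))) {
    stop("direction must be 'repressed' or 'activated'")
  }
  if (any(!df$bound)) stop("all direct targets must be bound")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in direct-target table")
  structure(df[, required], label = label,
            class = c("direct_target_table", "data.frame"))
}

#' @export
print.direct_target_table <- function(x, ...) {
  cat(sprintf("direct_target_table '%s': %d gene(s)\n",
              attr(x, "label"), nrow(x)))
  if (nrow(x) > 0L) {
    tab <- table(x$direction)
    for (d in names(tab)) {
      cat(sprintf("  %s: %d (%.1f%%)\n", d, tab[[d]], 100 * tab[[d]] / nrow(x)))
    }
  }
  invisible(x)
}

#' @method summary direct_target_table
#' @export
summary.direct_target_table <- function(object, ...) {
  n <- nrow(object)
  counts <- c(repressed = sum(object$direction == "repressed"),
              activated = sum(object$direction == "activated"))
  pct <- if (n > 0L) 100 * counts / n else c(repressed = NA_real_, activated = NA_real_)
  out <- list(label = attr(object, "label"), n = n, counts = counts,
              pct = round(pct, 1), pct_int = round(pct))
  class(out) <- "direct_target_summary"
  out
}

#' @export
print.direct_target_summary <- function(x, ...) {
  cat(sprintf("direct targets '%s': n = %d\n", x$label, x$n))
  for (d in names(x$counts)) {
    cat(sprintf("  %s: %d (%.1f%%)\n", d, x$counts[[d]], x$pct[[d]]))
  }
  invisible(x)
}

#' Overlap (Venn) summary of two direct-target tables
#'
#' Set algebra on the gene_id sets, with the shared/unique percentages of
#' each table reported to one decimal place and rounded to integers for
#' display.
#'
#' @param table_a,table_b `direct_target_table`s (or data.frames with a
#'   `gene_id` column).
#' @return An `overlap_summary` list with counts `only_a`, `only_b`,
#'   `shared`, sizes `n_a`, `n_b`, and percentage entries `shared_pct_a`,
#'   `shared_pct_b`, `unique_pct_a`, `unique_pct_b` (each with `pct` and
#'   `pct_int`).
#' @export
overlap_summary <- function(table_a, table_b) {
  a <- unique(table_a$gene_id)
  b <- unique(table_b$gene_id)
  shared <- length(intersect(a, b))
  pctize <- function(num, den) {
    p <- if (den > 0L) 100 * num / den else NA_real_
    list(pct = round(p, 1), pct_int = round(p))
  }
  out <- list(
    label_a = attr(table_a, "label"), label_b = attr(table_b, "label"),
    n_a = length(a), n_b = length(b),
    only_a = length(a) - shared, only_b = length(b) - shared,
    shared = shared,
    shared_pct_a = pctize(shared, length(a)),
    shared_pct_b = pctize(shared, length(b)),
    unique_pct_a = pctize(length(a) - shared, length(a)),
    unique_pct_b = pctize(length(b) - shared, length(b)))
  class(out) <- "overlap_summary"
  out
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap: |A|=%d, |B|=%d, shared=%d (%.1f%% of A, %.1f%% of B)\n",
              x$n_a, x$n_b, x$shared, x$shared_pct_a$pct, x$shared_pct_b$pct))
  cat(sprintf("unique: A %d (%.1f%%), B %d (%.1f%%)\n",
              x$only_a, x$unique_pct_a$pct, x$only_b, x$unique_pct_b$pct))
  invisible(x)
}

#' Annotate peaks by enhancer overlap
#'
#' A peak is an enhancer peak when it overlaps at least one base of any
#' enhancer interval.
#'
#' @param peaks a [peak_set()].
#' @param enhancers data.frame of intervals (`chrom`, `start`, `end`; 0-based
#'   half-open), e.g. from [read_intervals()].
#' @return List with `peaks` (the input with a logical `enhancer` column)
#'   and `counts` (`enhancer_peaks`, `non_enhancer_peaks`).
#' @export
annotate_enhancer_overlap <- function(peaks, enhancers) {
  flag <- rep(FALSE, nrow(peaks))
  if (nrow(peaks) > 0L && !is.null(enhancers) && nrow(enhancers) > 0L) {
    peak_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
    enh_gr <- GenomicRanges::GRanges(
      enhancers$chrom, IRanges::IRanges(enhancers$start + 1, enhancers$end))
    flag <- IRanges::overlapsAny(peak_gr, enh_gr, minoverlap = 1L)
  }
  peaks <- as.data.frame(peaks)
  peaks$enhancer <- flag
  list(peaks = peaks,
       counts = c(enhancer_peaks = sum(flag),
                  non_enhancer_peaks = sum(!flag)))
}
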