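#' Compute a TSS-anchored metagene matrix
#'
#' For each gene, per-base signal over `[TSS - flank_bp, TSS + flank_bp)` in
#' transcription orientation is averaged within consecutive bins of
#' `bin_bp`. Column 1 is the most upstream bin in transcription direction;
#' the bin containing the anchor itself is the first bin of the downstream
#' half. Missing signal (uncovered bases, absent chromosomes, positions past
#' chromosome bounds) contributes zeros; the number of out-of-bounds bases
#' is tallied per row.
#'
#' @param track a [signal_track()].
#' @param annotation a [genome_annotation()].
#' @param gene_ids genes to include (default: all genes in the annotation).
#'   Unknown ids are an error.
#' @param flank_bp half-window around the TSS in bp (default 3000); must be
#'   divisible by `bin_bp`.
#' @param bin_bp bin width in bp (default 10).
#' @param order `"signal"` (rows sorted by descending row mean, ties broken
#'   by gene_id — heatmap order) or `"given"` (caller's order kept).
#' @param stat per-bin statistic, `"mean"` (default) or `"median"`.
#' @return A `metagene_matrix`: list with `values` (genes x bins matrix),
#'   `gene_ids`, `bin_mid` (bin midpoints relative to the TSS), `flank_bp`,
#'   `bin_bp`, `clipped` (per-row out-of-bounds base counts), `stat`.
#' @export
compute_matrix <- function(track, annotation, gene_ids = NULL,
                           flank_bp = 3000, bin_bp = 10,
                           order = c("signal", "given"),
                           stat = c("mean", "median")) {
  order <- match.arg(order)
  stat <- match.arg(stat)
  if (flank_bp <= 0 || bin_bp <= 0) stop("flank_bp and bin_bp must be positive")
  if (flank_bp %% bin_bp != 0) stop("flank_bp must be divisible by bin_bp")
  if (is.null(gene_ids)) gene_ids <- annotation$gene_id
  unknown <- setdiff(gene_ids, annotation$gene_id)
  if (length(unknown) > 0L) {
    stop("gene_id(s) not in annotation: ", paste(unknown, collapse = ", "))
  }
  idx <- match(gene_ids, annotation$gene_id)
  tss <- gene_tss(annotation)[idx]
  n_bins <- as.integer(2 * flank_bp / bin_bp)
  values <- matrix(0, nrow = length(gene_ids), ncol = n_bins)
  clipped <- integer(length(gene_ids))
  binfun <- if (stat == "mean") colMeans else function(m) apply(m, 2L, stats::median)
  for (i in seq_along(gene_ids)) {
    g <- idx[i]
    strand <- annotation$strand[g]
    # genomic window whose strand-oriented read covers [TSS-flank, TSS+flank)
    if (strand == "+") {
      ws <- tss[i] - flank_bp; we <- tss[i] + flank_bp
    } else {
      ws <- tss[i] - flank_bp + 1; we <- tss[i] + flank_bp + 1
    }
    vals <- window_values(track, annotation$chrom[g], ws, we, strand)
    clipped[i] <- attr(vals, "clipped")
    values[i, ] <- binfun(matrix(vals, nrow = bin_bp))
  }
  rownames(values) <- gene_ids
  if (order == "signal" && length(gene_ids) > 1L) {
    o <- base::order(-rowMeans(values), gene_ids)
    values <- values[o, , drop = FALSE]
    gene_ids <- gene_ids[o]
    clipped <- clipped[o]
  }
  structure(list(values = values, gene_ids = gene_ids,
                 bin_mid = seq(-flank_bp + bin_bp / 2, flank_bp - bin_bp / 2,
                               by = bin_bp),
                 flank_bp = flank_bp, bin_bp = bin_bp,
                 clipped = clipped, stat = stat),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("metagene_matrix: %d gene(s) x %d bins (TSS +/- %d bp, %d bp bins, %s)\n",
              nrow(x$values), ncol(x$values), x$flank_bp, x$bin_bp, x$stat))
  invisible(x)
}

#' Average metagene profile
#'
#' Column-wise arithmetic mean of a metagene matrix, with the number of
#' contributing rows.
#'
#' @param matrix a `metagene_matrix` from [compute_matrix()].
#' @return data.frame with columns `bin_mid`, `mean`, `n_genes`.
#' @export
average_profile <- function(matrix) {
  if (nrow(matrix$values) == 0L) stop("empty metagene matrix")
  data.frame(bin_mid = matrix$bin_mid,
             mean = colMeans(matrix$values),
             n_genes = nrow(matrix$values))
}

#' Export / import a metagene matrix as TSV
#'
#' The header row carries the bin midpoints relative to the TSS; the first
#' column is the gene_id. `import_matrix(export_matrix(m, f))` restores the
#' matrix values, gene order and bin structure.
#'
#' @param matrix a `metagene_matrix`.
#' @param path output (input) TSV path.
#' @return `export_matrix` invisibly returns `path`; `import_matrix` returns
#'   a `metagene_matrix`.
#' @export
export_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = matrix$gene_ids, matrix$values,
                   check.names = FALSE)
  names(df) <- c("gene_id", format(matrix$bin_mid, trim = TRUE,
                                   scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_matrix
#' @export
import_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  bin_mid <- as.numeric(names(df)[-1L])
  if (anyNA(bin_mid)) stop("matrix TSV header must be numeric bin midpoints")
  bin_bp <- if (length(bin_mid) > 1L) bin_mid[2L] - bin_mid[1L] else 2 * abs(bin_mid)
  values <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(values) <- list(df$gene_id, NULL)
  structure(list(values = values, gene_ids = df$gene_id, bin_mid = bin_mid,
                 flank_bp = max(bin_mid) + bin_bp / 2, bin_bp = bin_bp,
                 clipped = rep(NA_integer_, nrow(values)), stat = "mean"),
            class = "metagene_matrix")
}

#' Plot a metagene matrix
#'
#' `type = "profile"` draws the average profile against distance from the
#' TSS; `type = "heatmap"` draws the row-ordered matrix with
#' [graphics::image()].
#'
#' @param x a `metagene_matrix`.
#' @param type `"profile"` or `"heatmap"`.
#' @param ... further arguments passed to the underlying plot function.
#' @return Invisibly, `x`.
#' @method plot metagene_matrix
#' @export
plot.metagene_matrix <- function(x, type = c("profile", "heatmap"), ...) {
  type <- match.arg(type)
  if (type == "profile") {
    prof <- average_profile(x)
    graphics::plot(prof$bin_mid, prof$mean, type = "l",
                   xlab = "distance from TSS (bp)", ylab = "mean signal", ...)
    graphics::abline(v = 0, lty = 2, col = "grey50")
  } else {
    graphics::image(x = x$bin_mid, y = seq_len(nrow(x$values)),
                    z = t(x$values[rev(seq_len(nrow(x$values))), , drop = FALSE]),
                    xlab = "distance from TSS (bp)", ylab = "genes",
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  }
  invisible(x)
}

#' TSS-localization score of a metagene matrix
#'
#' Ratio of the mean signal within `core_bp` of the anchor to the mean
#' signal over the whole window: 1 for a flat profile, larger the more the
#' signal concentrates at the TSS.
#'
#' @param matrix a `metagene_matrix`.
#' @param core_bp half-width of the TSS core window in bp (default 250).
#' @return A single numeric score.
#' @export
tss_localization_score <- function(matrix, core_bp = 250) {
  prof <- average_profile(matrix)
  core <- abs(prof$bin_mid) <= core_bp
  if (!any(core)) stop("core_bp smaller than half a bin")
  overall <- mean(prof$mean)
  if (overall == 0) return(NA_real_)
  mean(prof$mean[core]) / overall
}

#' Contrast TSS localization between two gene sets
#'
#' Pairs the average profiles of two metagene matrices sharing a bin
#' structure and reports a TSS-localization score for each (see
#' [tss_localization_score()]); a higher score means the binding is more
#' strictly localized at the TSS.
#'
#' @param matrix_candidates,matrix_all `metagene_matrix` objects with
#'   identical bin structure.
#' @param core_bp half-width of the TSS core window in bp (default 250).
#' @return List with `profile_candidates`, `profile_all` (data.frames from
#'   [average_profile()]) and `score_candidates`, `score_all`.
#' @export
candidate_binding_contrast <- function(matrix_candidates, matrix_all,
                                       core_bp = 250) {
  if (length(matrix_candidates$bin_mid) != length(matrix_all$bin_mid) ||
      any(matrix_candidates$bin_mid != matrix_all$bin_mid)) {
    stop("metagene matrices have mismatched bin structure")
  }
  list(profile_candidates = average_profile(matrix_candidates),
       profile_all = average_profile(matrix_all),
       score_candidates = tss_localization_score(matrix_candidates, core_bp),
       score_all = tss_localization_score(matrix_all, core_bp))
}
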