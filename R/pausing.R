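#' Per-gene RNA polymerase II pausing index
#'
#' The pausing index of a gene is the mean signal over its promoter window
#' divided by the mean signal over its gene-body window, both in
#' transcription orientation: promoter `[TSS - promoter_up, TSS +
#' promoter_down)` and body `[TSS + body_start_offset, TES' -
#' body_end_offset)` where `TES'` is the exclusive 3' end of the gene. High
#' values indicate promoter-proximal pausing. Genes whose body window is
#' empty or inverted (length <= `body_start_offset + body_end_offset`) are
#' excluded as `excluded_short_gene`; genes with zero body signal as
#' `excluded_zero_body` (a ratio there would be infinite and break rank
#' statistics downstream).
#'
#' @param track a [signal_track()] of polymerase (e.g. Rpb3) enrichment.
#' @param annotation a [genome_annotation()].
#' @param gene_ids genes to score (default: all). Unknown ids are an error.
#' @param promoter_up,promoter_down promoter window extent around the TSS in
#'   bp (defaults 50 and 50).
#' @param body_start_offset body window start downstream of the TSS (default
#'   300 bp).
#' @param body_end_offset body window end upstream of the gene 3' end
#'   (default 100 bp).
#' @return data.frame with columns `gene_id`, `promoter_mean`, `body_mean`,
#'   `pi`, `status` (`ok`, `excluded_short_gene`, `excluded_zero_body`);
#'   `pi` is `NA` unless `status == "ok"`.
#' @export
pausing_index <- function(track, annotation, gene_ids = NULL,
                          promoter_up = 50, promoter_down = 50,
                          body_start_offset = 300, body_end_offset = 100) {
  if (promoter_up < 0 || promoter_down < 0 || body_start_offset < 0 ||
      body_end_offset < 0) stop("window offsets must be >= 0")
  if (promoter_up + promoter_down <= 0) stop("empty promoter window")
  if (is.null(gene_ids)) gene_ids <- annotation$gene_id
  unknown <- setdiff(gene_ids, annotation$gene_id)
  if (length(unknown) > 0L) {
    stop("gene_id(s) not in annotation: ", paste(unknown, collapse = ", "))
  }
  idx <- match(gene_ids, annotation$gene_id)
  out <- data.frame(gene_id = gene_ids,
                    promoter_mean = NA_real_, body_mean = NA_real_,
                    pi = NA_real_, status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(gene_ids)) {
    g <- idx[i]
    chrom <- annotation$chrom[g]
    strand <- annotation$strand[g]
    len <- annotation$end[g] - annotation$start[g]
    if (len <= body_start_offset + body_end_offset) {
      out$status[i] <- "excluded_short_gene"
      next
    }
    if (strand == "+") {
      ps <- annotation$start[g] - promoter_up
      pe <- annotation$start[g] + promoter_down
      bs <- annotation$start[g] + body_start_offset
      be <- annotation$end[g] - body_end_offset
    } else {
      ps <- annotation$end[g] - promoter_down
      pe <- annotation$end[g] + promoter_up
      bs <- annotation$start[g] + body_end_offset
      be <- annotation$end[g] - body_start_offset
    }
    prom <- window_mean(track, chrom, ps, pe)
    body <- window_mean(track, chrom, bs, be)
    out$promoter_mean[i] <- prom
    out$body_mean[i] <- body
    if (body == 0) {
      out$status[i] <- "excluded_zero_body"
    } else {
      out$pi[i] <- prom / body
    }
  }
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from the rank-sum identity with midranks for ties. The
#' two-sided p-value comes from full enumeration of rank assignments when
#' the samples are small (`n_a + n_b <= exact_max_n`) and tie-free, and from
#' the normal approximation with tie-corrected variance and continuity
#' correction otherwise. When all observations are tied the variance is zero
#' and p = 1.
#'
#' @param values_a,values_b numeric vectors (each non-empty, finite).
#' @param exact_max_n largest combined sample size for exact enumeration
#'   (default 12).
#' @return A `group_comparison` list: `u_statistic` (`min(U_a, U_b)`), `u_a`,
#'   `p_two_sided`, `n_a`, `n_b`, `method` (`"exact"` or
#'   `"normal_tie_corrected"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1 by enumeration
#' @export
mann_whitney_u <- function(values_a, values_b, exact_max_n = 12) {
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop("both groups must be non-empty")
  }
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop("values must be finite")
  }
  n_a <- length(values_a)
  n_b <- length(values_b)
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  u <- min(u_a, u_b)
  ties <- anyDuplicated(pooled) > 0L
  n <- n_a + n_b
  if (n <= exact_max_n && !ties) {
    # enumerate every assignment of n_a of the n distinct ranks to group A
    combos <- utils::combn(n, n_a)
    u_null <- colSums(combos) - n_a * (n_a + 1) / 2
    p <- mean(pmin(u_null, n_a * n_b - u_null) <= u)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(pooled)
    sigma2 <- (n_a * n_b / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u_a - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal_tie_corrected"
  }
  structure(list(u_statistic = u, u_a = u_a, p_two_sided = p,
                 n_a = n_a, n_b = n_b, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: U = %g, p (two-sided) = %.4g [%s], n = %d vs %d\n",
              x$u_statistic, x$p_two_sided, x$method, x$n_a, x$n_b))
  invisible(x)
}

#' Compare pausing indices between two gene groups
#'
#' Computes per-gene pausing indices for two disjoint gene groups
#' (typically repressed vs activated direct targets), drops excluded genes
#' (tallying them per group), and compares the remaining index values with
#' the two-sided Mann-Whitney U test. The direction of effect is reported as
#' the difference of group medians.
#'
#' @param track a [signal_track()].
#' @param annotation a [genome_annotation()].
#' @param group_a,group_b character vectors of gene_ids (disjoint).
#' @param check_disjoint set `FALSE` to allow overlapping groups (self-test
#'   use only).
#' @param ... passed to [pausing_index()].
#' @return List with `per_gene` (pausing-index table for both groups, plus a
#'   `group` column), `comparison` (a `group_comparison`), `excluded`
#'   (per-group exclusion counts), `median_a`, `median_b`,
#'   `median_difference` (a minus b).
#' @export
compare_pausing <- function(track, annotation, group_a, group_b,
                            check_disjoint = TRUE, ...) {
  if (check_disjoint && length(intersect(group_a, group_b)) > 0L) {
    stop("gene groups must be disjoint")
  }
  pa <- pausing_index(track, annotation, group_a, ...)
  pb <- pausing_index(track, annotation, group_b, ...)
  pa$group <- "a"
  pb$group <- "b"
  ok_a <- pa$pi[pa$status == "ok"]
  ok_b <- pb$pi[pb$status == "ok"]
  if (length(ok_a) == 0L || length(ok_b) == 0L) {
    stop("a group has no usable genes after exclusions (short genes / zero body signal)")
  }
  list(per_gene = rbind(pa, pb),
       comparison = mann_whitney_u(ok_a, ok_b),
       excluded = c(a = sum(pa$status != "ok"), b = sum(pb$status != "ok")),
       median_a = stats::median(ok_a),
       median_b = stats::median(ok_b),
       median_difference = stats::median(ok_a) - stats::median(ok_b))
}
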