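#' Bin log2 fold changes into soft / mid / hard classes
#'
#' Absolute log2FC is binned as `lt2` (< 2: soft regulation, fine-tuning of
#' expression), `two_to_three` (2 <= |log2FC| <= 3; both boundaries fall in
#' this middle bin) and `gt3` (> 3: hard, switch-like regulation).
#'
#' @param log2fc numeric vector of finite log2 fold changes.
#' @return Factor with levels `lt2`, `two_to_three`, `gt3`.
#' @export
log2fc_bin <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  a <- abs(log2fc)
  cut(a, breaks = c(-Inf, 2, 3, Inf), right = TRUE,
      labels = c("lt2", "two_to_three", "gt3"),
      include.lowest = TRUE) -> bins
  # cut(right = TRUE) puts exactly 2 in the first bin; move it to the middle
  bins[a == 2] <- "two_to_three"
  bins
}

#' Summarize a direct-target table by log2FC bin
#'
#' Per direction (repressed / activated), counts and percentages of targets
#' in each |log2FC| bin (see [log2fc_bin()]). Percentages are reported to
#' one decimal place and integer-rounded for display; for an empty direction
#' they are `NA`.
#'
#' @param table a `direct_target_table`.
#' @return A `regulation_summary`: data.frame with columns `direction`,
#'   `bin`, `count`, `n`, `pct`, `pct_int`, with the table label as an
#'   attribute.
#' @export
bin_log2fc <- function(table) {
  bins <- log2fc_bin(table$log2fc)
  out <- expand.grid(bin = levels(bins),
                     direction = c("repressed", "activated"),
                     stringsAsFactors = FALSE)[, 2:1]
  out$count <- mapply(function(d, b) {
    sum(table$direction == d & bins == b)
  }, out$direction, out$bin)
  out$n <- vapply(out$direction, function(d) sum(table$direction == d), 0)
  out$pct <- ifelse(out$n > 0, round(100 * out$count / out$n, 1), NA_real_)
  out$pct_int <- ifelse(out$n > 0, round(100 * out$count / out$n), NA_real_)
  structure(out, label = attr(table, "label"),
            class = c("regulation_summary", "data.frame"))
}

#' @export
print.regulation_summary <- function(x, ...) {
  cat(sprintf("log2FC bins for '%s':\n", attr(x, "label")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Categorize expression level from FPKM
#'
#' Control-cell expression categories: `strong` (FPKM > 1000), `moderate`
#' (10 <= FPKM <= 1000), `low` (1 <= FPKM < 10), `silenced` (FPKM < 1).
#' Exactly 1 is `low`, exactly 10 and exactly 1000 are `moderate`, so the
#' four categories partition all FPKM >= 0.
#'
#' @param fpkm numeric vector of FPKM values (>= 0).
#' @return Factor with levels `silenced`, `low`, `moderate`, `strong`.
#' @export
expression_category <- function(fpkm) {
  if (any(fpkm < 0)) stop("negative FPKM")
  cut(fpkm, breaks = c(-Inf, 1, 10, 1000, Inf), right = FALSE,
      labels = c("silenced", "low", "moderate", "strong")) -> cats
  cats[fpkm == 1000] <- "moderate"   # 1000 belongs to the moderate range
  cats
}

#' Expression-category counts for a gene set
#'
#' Assigns each gene its [expression_category()] and tabulates counts and
#' percentages, optionally restricted to a gene set. Genes of the set
#' missing from the FPKM table are counted as `missing` and excluded from
#' the percentages.
#'
#' @param fpkm_table data.frame with columns `gene_id`, `fpkm`.
#' @param gene_ids optional character vector restricting the summary.
#' @return List with `per_gene` (data.frame `gene_id`, `fpkm`, `category`),
#'   `counts`, `pct` (one decimal), `pct_int`, `n`, `missing`.
#' @export
categorize_expression <- function(fpkm_table, gene_ids = NULL) {
  if (any(fpkm_table$fpkm < 0)) stop("negative FPKM")
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, fpkm_table$gene_id)
    fpkm_table <- fpkm_table[fpkm_table$gene_id %in% gene_ids, , drop = FALSE]
  } else {
    missing <- character(0)
  }
  per_gene <- data.frame(gene_id = fpkm_table$gene_id, fpkm = fpkm_table$fpkm,
                         category = expression_category(fpkm_table$fpkm),
                         stringsAsFactors = FALSE)
  counts <- table(per_gene$category)
  n <- nrow(per_gene)
  pct <- if (n > 0) 100 * as.numeric(counts) / n else rep(NA_real_, length(counts))
  names(pct) <- names(counts)
  list(per_gene = per_gene, counts = counts,
       pct = round(pct, 1), pct_int = round(pct),
       n = n, missing = length(missing))
}

#' Detect hard-regulation candidates
#'
#' Hard-regulation candidates are activated direct targets whose control
#' expression is at or below `fpkm_ceiling` (default 1: "FPKM of 1 or less",
#' deliberately inclusive, unlike the strict `< 1` silenced category): genes
#' switched on from a silent state rather than fine-tuned. The summary also
#' reports the fraction of candidates with `|log2fc| > min_abs_log2fc`, and,
#' when the other isoform's data are supplied, the fraction of candidates
#' bound by and regulated by the other isoform.
#'
#' @param table a `direct_target_table`; only `activated` rows are
#'   considered.
#' @param control_fpkm data.frame with columns `gene_id`, `fpkm` (control
#'   cells). Activated targets missing from it are excluded and counted.
#' @param fpkm_ceiling candidate ceiling on control FPKM (default 1.0).
#' @param min_abs_log2fc hard-regulation fold-change cutoff (default 3.0).
#' @param other_bound_genes optional character vector of genes bound by a
#'   second isoform.
#' @param other_table optional `direct_target_table` of the second isoform.
#' @return List with `candidates` (gene_id vector), `candidate_table`
#'   (their rows) and `summary` (n_activated, n_candidates, pct_candidates
#'   with `pct`/`pct_int`, n_gt, pct_gt likewise, n_missing_fpkm, and when
#'   supplied pct_bound_other / pct_regulated_other).
#' @export
detect_hard_candidates <- function(table, control_fpkm, fpkm_ceiling = 1.0,
                                   min_abs_log2fc = 3.0,
                                   other_bound_genes = NULL,
                                   other_table = NULL) {
  act <- table[table$direction == "activated", , drop = FALSE]
  fpkm <- control_fpkm$fpkm[match(act$gene_id, control_fpkm$gene_id)]
  n_missing <- sum(is.na(fpkm))
  if (n_missing > 0L) {
    message(n_missing, " activated target(s) without control FPKM excluded")
  }
  usable <- !is.na(fpkm)
  is_cand <- usable & fpkm <= fpkm_ceiling
  cand <- act[is_cand, , drop = FALSE]
  pctize <- function(num, den) {
    p <- if (den > 0) 100 * num / den else NA_real_
    list(pct = round(p, 1), pct_int = round(p))
  }
  n_gt <- sum(abs(cand$log2fc) > min_abs_log2fc)
  summary <- list(
    n_activated = nrow(act),
    n_usable = sum(usable),
    n_missing_fpkm = n_missing,
    n_candidates = nrow(cand),
    pct_candidates = pctize(nrow(cand), sum(usable)),
    n_gt = n_gt,
    pct_gt = pctize(n_gt, nrow(cand)))
  if (!is.null(other_bound_genes)) {
    summary$n_bound_other <- sum(cand$gene_id %in% other_bound_genes)
    summary$pct_bound_other <- pctize(summary$n_bound_other, nrow(cand))
  }
  if (!is.null(other_table)) {
    summary$n_regulated_other <- sum(cand$gene_id %in% other_table$gene_id)
    summary$pct_regulated_other <- pctize(summary$n_regulated_other, nrow(cand))
  }
  list(candidates = cand$gene_id, candidate_table = cand, summary = summary)
}
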