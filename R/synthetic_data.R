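## Run code under a given seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

## Split n items into groups by fractions, using largest-remainder rounding
## so the counts are exact and sum to n.
.exact_counts <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Configuration for the synthetic dataset generator
#'
#' Bundles every knob of the generator with the defaults used throughout the
#' package's tests: gene lengths uniform on 1-10 kb, half the genes bound,
#' direction mix 50/40/10 repressed/activated/null among bound genes, effect
#' sizes drawn per class (soft |log2FC| ~ U(0.3, 1.8), mid ~ U(2, 3), hard ~
#' U(3.2, 6)) with weights 0.9/0.06/0.04, planted significance (true targets
#' p and FDR ~ U(0, 0.04); nulls ~ U(0.05, 1)), promoter:body pausing ratios
#' 5.0 (repressed) vs 1.5 (activated), per-gene body signal ~ Gamma(2, 1),
#' and FPKM categories (weights strong 0.05 / moderate 0.7 / low 0.2 /
#' silenced 0.05) drawn from log-normals with medians 2000 / 100 / 3 / 0.3.
#' All randomness flows from `seed`; an identical config yields an identical
#' dataset.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param gene_length_range,intergenic_gap_range uniform ranges in bp. Gaps
#'   default to 2.2-4 kb so that a promoter peak can never reach a
#'   neighbouring gene's assignment window (planted bound labels stay
#'   exactly identifiable).
#' @param chrom chromosome name of the synthetic genome.
#' @param chrom_length chromosome length in bp, or `NULL` to size it to the
#'   simulated genes plus a peak-free tail for decoys.
#' @param fraction_bound fraction of genes given a promoter peak.
#' @param direction_fractions named fractions (`repressed`, `activated`,
#'   `null`) among bound genes; unbound genes are always null.
#' @param effect_weights named soft/mid/hard class weights among true
#'   targets.
#' @param effect_ranges list of |log2FC| uniform ranges per class.
#' @param polarity `"knockdown"` or `"overexpression"` (sets log2FC signs).
#' @param sig_p_range,sig_fdr_range uniform ranges for true-target p / FDR.
#' @param null_p_range uniform range for null p and FDR.
#' @param r_repressed,r_activated,r_null promoter:body pausing multipliers.
#' @param body_shape,body_scale Gamma parameters of the per-gene body level.
#' @param background background signal outside gene segments.
#' @param noise logical; Poisson per-base resampling of gene signal
#'   segments.
#' @param decoy_fraction decoy (intergenic) peaks as a fraction of
#'   `n_genes`.
#' @param peak_width_range uniform range of peak widths in bp.
#' @param peak_jitter maximal distance of a peak center from the TSS in bp.
#' @param fpkm_weights named category weights (strong, moderate, low,
#'   silenced).
#' @param fpkm_medians,fpkm_sdlog log-normal median and sdlog per category.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 500L,
                              gene_length_range = c(1000, 10000),
                              intergenic_gap_range = c(2200, 4000),
                              chrom = "chrS", chrom_length = NULL,
                              fraction_bound = 0.5,
                              direction_fractions = c(repressed = 0.5,
                                                      activated = 0.4,
                                                      null = 0.1),
                              effect_weights = c(soft = 0.9, mid = 0.06,
                                                 hard = 0.04),
                              effect_ranges = list(soft = c(0.3, 1.8),
                                                   mid = c(2, 3),
                                                   hard = c(3.2, 6)),
                              polarity = c("knockdown", "overexpression"),
                              sig_p_range = c(0, 0.04),
                              sig_fdr_range = c(0, 0.04),
                              null_p_range = c(0.05, 1),
                              r_repressed = 5.0, r_activated = 1.5,
                              r_null = 1.0,
                              body_shape = 2, body_scale = 1,
                              background = 0.1, noise = FALSE,
                              decoy_fraction = 0,
                              peak_width_range = c(300, 600),
                              peak_jitter = 200,
                              fpkm_weights = c(strong = 0.05, moderate = 0.7,
                                               low = 0.2, silenced = 0.05),
                              fpkm_medians = c(strong = 2000, moderate = 100,
                                               low = 3, silenced = 0.3),
                              fpkm_sdlog = c(strong = 0.25, moderate = 0.5,
                                             low = 0.3, silenced = 0.35)) {
  polarity <- match.arg(polarity)
  stopifnot(n_genes >= 1, fraction_bound >= 0, fraction_bound <= 1,
            gene_length_range[1] > 0,
            gene_length_range[2] >= gene_length_range[1],
            intergenic_gap_range[1] >= 200,
            all(direction_fractions >= 0), all(effect_weights >= 0),
            all(fpkm_weights >= 0), background >= 0,
            r_repressed > 0, r_activated > 0, r_null > 0)
  if (abs(sum(direction_fractions) - 1) > 1e-8) {
    stop("direction_fractions must sum to 1")
  }
  if (abs(sum(effect_weights) - 1) > 1e-8) stop("effect_weights must sum to 1")
  if (abs(sum(fpkm_weights) - 1) > 1e-8) stop("fpkm_weights must sum to 1")
  if (!all(c("repressed", "activated", "null") %in% names(direction_fractions))) {
    stop("direction_fractions must be named repressed/activated/null")
  }
  if (!all(c("soft", "mid", "hard") %in% names(effect_weights))) {
    stop("effect_weights must be named soft/mid/hard")
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_length_range = gene_length_range,
    intergenic_gap_range = intergenic_gap_range,
    chrom = chrom, chrom_length = chrom_length,
    fraction_bound = fraction_bound,
    direction_fractions = direction_fractions,
    effect_weights = effect_weights, effect_ranges = effect_ranges,
    polarity = polarity,
    sig_p_range = sig_p_range, sig_fdr_range = sig_fdr_range,
    null_p_range = null_p_range,
    r_repressed = r_repressed, r_activated = r_activated, r_null = r_null,
    body_shape = body_shape, body_scale = body_scale,
    background = background, noise = noise,
    decoy_fraction = decoy_fraction,
    peak_width_range = peak_width_range, peak_jitter = peak_jitter,
    fpkm_weights = fpkm_weights, fpkm_medians = fpkm_medians,
    fpkm_sdlog = fpkm_sdlog), class = "simulation_config")
}

#' Simulate a gene annotation
#'
#' Non-overlapping genes with intergenic gaps drawn from the configured
#' range (always >= 200 bp), lengths uniform on the configured range, and
#' random strands; deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return A [genome_annotation()] with `chrom_sizes` set.
#' @export
simulate_annotation <- function(config) {
  .with_seed(config$seed + 1L, {
    n <- config$n_genes
    len <- round(stats::runif(n, config$gene_length_range[1],
                              config$gene_length_range[2]))
    gap <- round(stats::runif(n, config$intergenic_gap_range[1],
                              config$intergenic_gap_range[2]))
    start <- cumsum(gap) + cumsum(c(0, len[-n]))
    end <- start + len
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom_length <- config$chrom_length
    if (is.null(chrom_length)) {
      chrom_length <- end[n] + 50000  # peak-free tail for decoy placement
    } else if (chrom_length < end[n]) {
      stop("chrom_length too small for the simulated genes (need >= ",
           end[n], ")")
    }
    genome_annotation(
      data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                 chrom = config$chrom, start = start, end = end,
                 strand = strand, stringsAsFactors = FALSE),
      chrom_sizes = stats::setNames(chrom_length, config$chrom))
  })
}

#' Ground-truth labels for a synthetic dataset
#'
#' Assigns the planted per-gene labels: bound (exact count
#' `round(fraction_bound * n)`), direction among bound genes (exact counts
#' by the direction fractions; unbound genes are null), effect class among
#' true targets (exact counts by the effect weights), pausing ratio by
#' direction, expression category (exact counts by the FPKM weights, with
#' hard-activated genes forced to `silenced` and any other activated target
#' that drew `silenced` swapped with a non-target so planted hard candidates
#' stay exactly identifiable), and the hard-candidate flag.
#'
#' @param config a [simulation_config()].
#' @param annotation annotation from [simulate_annotation()].
#' @return data.frame with columns `gene_id`, `bound`, `direction`,
#'   `effect_class`, `pausing_ratio`, `expr_category`, `hard_candidate`.
#' @export
simulate_ground_truth <- function(config, annotation) {
  .with_seed(config$seed + 2L, {
    n <- config$n_genes
    ids <- annotation$gene_id
    truth <- data.frame(gene_id = ids, bound = FALSE, direction = "null",
                        effect_class = NA_character_,
                        pausing_ratio = config$r_null,
                        expr_category = NA_character_,
                        hard_candidate = FALSE, stringsAsFactors = FALSE)
    n_bound <- round(config$fraction_bound * n)
    bound_idx <- sample(n, n_bound)
    truth$bound[bound_idx] <- TRUE
    dir_counts <- .exact_counts(n_bound, config$direction_fractions)
    shuffled <- sample(bound_idx)
    truth$direction[shuffled] <- rep(c("repressed", "activated", "null"),
                                     dir_counts[c("repressed", "activated", "null")])
    for (d in c("repressed", "activated")) {
      idx <- which(truth$direction == d)
      if (length(idx) == 0L) next
      cls_counts <- .exact_counts(length(idx), config$effect_weights)
      truth$effect_class[sample(idx)] <- rep(c("soft", "mid", "hard"),
                                             cls_counts[c("soft", "mid", "hard")])
    }
    truth$pausing_ratio[truth$direction == "repressed"] <- config$r_repressed
    truth$pausing_ratio[truth$direction == "activated"] <- config$r_activated
    # planted expression categories, exact counts overall
    cat_names <- c("strong", "moderate", "low", "silenced")
    cat_counts <- .exact_counts(n, config$fpkm_weights[cat_names])
    truth$expr_category <- rep(cat_names, cat_counts)[sample(n)]
    hard_act <- truth$direction == "activated" & truth$effect_class == "hard" &
      !is.na(truth$effect_class)
    truth$expr_category[hard_act] <- "silenced"
    # activated non-hard targets must not look silent: swap with a non-target
    bad <- which(truth$direction == "activated" & !hard_act &
                   truth$expr_category == "silenced")
    pool <- which(truth$direction != "activated" &
                    truth$expr_category != "silenced")
    if (length(bad) > 0L) {
      # swap with non-targets to preserve the planted category counts;
      # when the pool is short (nearly everything activated), redraw from
      # the expressed categories instead
      n_swap <- min(length(bad), length(pool))
      if (n_swap > 0L) {
        swap <- pool[seq_len(n_swap)]
        tmp <- truth$expr_category[swap]
        truth$expr_category[swap] <- "silenced"
        truth$expr_category[bad[seq_len(n_swap)]] <- tmp
      }
      if (n_swap < length(bad)) {
        rest <- bad[(n_swap + 1):length(bad)]
        w <- config$fpkm_weights[c("strong", "moderate", "low")]
        truth$expr_category[rest] <- sample(c("strong", "moderate", "low"),
                                            length(rest), replace = TRUE,
                                            prob = w / sum(w))
      }
    }
    truth$hard_candidate <- hard_act
    truth
  })
}

#' Simulate a polymerase-like signal track
#'
#' Piecewise-constant enrichment per gene: body level `b` (Gamma-distributed
#' per gene) over `[TSS + 300, TES' - 100)`, promoter level `r * b` over
#' `[TSS - 50, TSS + 50)` where `r` is the gene's planted pausing ratio, a
#' linear ramp between promoter and body, and constant background elsewhere.
#' With `noise = TRUE` the gene segments are resampled per base as
#' Poisson(value) (the background stays constant). With noise off,
#' [pausing_index()] returns exactly `r` for every sufficiently long gene.
#'
#' @param config a [simulation_config()].
#' @param annotation annotation from [simulate_annotation()].
#' @param ground_truth labels from [simulate_ground_truth()].
#' @return A [signal_track()] carrying the annotation's `chrom_sizes`.
#' @export
simulate_signal <- function(config, annotation, ground_truth) {
  .with_seed(config$seed + 3L, {
    n <- config$n_genes
    body_level <- stats::rgamma(n, shape = config$body_shape,
                                scale = config$body_scale)
    seg_start <- vector("list", n)
    seg_end <- vector("list", n)
    seg_val <- vector("list", n)
    for (i in seq_len(n)) {
      b <- body_level[i]
      r <- ground_truth$pausing_ratio[i]
      len <- annotation$end[i] - annotation$start[i]
      # segments in transcription offsets relative to the TSS
      off_start <- c(-50, 50:299)
      off_end <- c(50, 51:300)
      val <- c(r * b, r * b + (50:299 - 50) / 250 * (b - r * b))
      if (len > 400) {
        off_start <- c(off_start, 300)
        off_end <- c(off_end, len - 100)
        val <- c(val, b)
      }
      if (config$noise) {
        widths <- off_end - off_start
        lam <- rep(val, widths)
        noisy <- stats::rpois(length(lam), lam)
        runs <- rle(noisy)
        ends <- off_start[1] + cumsum(runs$lengths)
        off_end <- ends
        off_start <- c(off_start[1], ends[-length(ends)])
        val <- runs$values
      }
      # map offsets to genomic coordinates
      if (annotation$strand[i] == "+") {
        gs <- annotation$start[i] + off_start
        ge <- annotation$start[i] + off_end
      } else {
        t <- annotation$end[i] - 1
        gs <- rev(t - off_end + 1)
        ge <- rev(t - off_start + 1)
        val <- rev(val)
      }
      seg_start[[i]] <- gs
      seg_end[[i]] <- ge
      seg_val[[i]] <- val
    }
    gene_segs <- data.frame(start = unlist(seg_start), end = unlist(seg_end),
                            value = unlist(seg_val))
    # genes are generated left to right, so concatenation is already sorted
    chrom_length <- attr(annotation, "chrom_sizes")[[config$chrom]]
    # fill everything between gene segments with the background level
    bg_start <- c(0, gene_segs$end)
    bg_end <- c(gene_segs$start, chrom_length)
    keep <- bg_start < bg_end
    bg <- data.frame(start = bg_start[keep], end = bg_end[keep],
                     value = config$background)
    all <- rbind(gene_segs, bg)
    all <- all[all$value != 0, , drop = FALSE]
    all$chrom <- config$chrom
    signal_track(all, chrom_sizes = attr(annotation, "chrom_sizes"))
  })
}

#' Simulate promoter-proximal peak calls
#'
#' Every bound gene receives one peak of width drawn from
#' `peak_width_range`, centered within `peak_jitter` bp of its TSS, with the
#' summit placed at the TSS when it falls inside the peak. Decoy peaks
#' (`decoy_fraction * n_genes`, rounded) are placed in the peak-free
#' intergenic tail of the chromosome.
#'
#' @inheritParams simulate_signal
#' @return A [peak_set()].
#' @export
simulate_peaks <- function(config, annotation, ground_truth) {
  .with_seed(config$seed + 4L, {
    bound <- which(ground_truth$bound)
    tss <- gene_tss(annotation)
    rows <- list()
    if (length(bound) > 0L) {
      w <- round(stats::runif(length(bound), config$peak_width_range[1],
                              config$peak_width_range[2]))
      center <- tss[bound] + round(stats::runif(length(bound),
                                                -config$peak_jitter,
                                                config$peak_jitter))
      start <- pmax(0, center - floor(w / 2))
      end <- start + w
      summit <- tss[bound] - start
      summit[summit < 0 | summit >= w] <- floor(w[summit < 0 | summit >= w] / 2)
      rows$bound <- data.frame(
        chrom = config$chrom, start = start, end = end,
        name = paste0("peak_", annotation$gene_id[bound]),
        score = round(stats::runif(length(bound), 100, 1000)),
        summit = summit, stringsAsFactors = FALSE)
    }
    n_decoy <- round(config$decoy_fraction * config$n_genes)
    if (n_decoy > 0L) {
      chrom_length <- attr(annotation, "chrom_sizes")[[config$chrom]]
      tail_start <- max(annotation$end) + 5000
      if (tail_start + 10000 > chrom_length) {
        stop("no intergenic tail available for decoy peaks")
      }
      w <- round(stats::runif(n_decoy, config$peak_width_range[1],
                              config$peak_width_range[2]))
      start <- round(stats::runif(n_decoy, tail_start,
                                  chrom_length - max(w) - 1))
      rows$decoy <- data.frame(
        chrom = config$chrom, start = start, end = start + w,
        name = sprintf("decoy_%03d", seq_len(n_decoy)),
        score = round(stats::runif(n_decoy, 100, 1000)),
        summit = floor(w / 2), stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) {
      return(peak_set(data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0))))
    }
    peak_set(do.call(rbind, rows))
  })
}

#' Simulate differential-expression and FPKM tables
#'
#' True targets get |log2FC| drawn from their planted effect-class range and
#' signed by direction under the configured polarity (knockdown: repressed
#' genes go up when the factor is removed; overexpression: inverted), with p
#' and FDR from the significance ranges. Null genes get a small centred
#' log2FC and non-significant p/FDR. FPKM values are drawn per planted
#' category from its log-normal, by rejection, so each value lies inside the
#' category's interval; hard-activated genes are forced to control FPKM
#' below 1.
#'
#' @inheritParams simulate_signal
#' @return List with `de` (gene_id, log2fc, p_value, fdr) and `fpkm`
#'   (gene_id, fpkm).
#' @export
simulate_de_and_fpkm <- function(config, ground_truth) {
  .with_seed(config$seed + 5L, {
    n <- nrow(ground_truth)
    log2fc <- stats::rnorm(n, 0, 0.25)
    p <- stats::runif(n, config$null_p_range[1], config$null_p_range[2])
    fdr <- stats::runif(n, config$null_p_range[1], config$null_p_range[2])
    true <- ground_truth$direction %in% c("repressed", "activated")
    for (cls in c("soft", "mid", "hard")) {
      idx <- which(true & ground_truth$effect_class == cls)
      if (length(idx) == 0L) next
      rng <- config$effect_ranges[[cls]]
      log2fc[idx] <- stats::runif(length(idx), rng[1], rng[2])
    }
    up_if_repressed <- config$polarity == "knockdown"
    neg <- (ground_truth$direction == "repressed") != up_if_repressed
    log2fc[true & neg] <- -log2fc[true & neg]
    p[true] <- stats::runif(sum(true), config$sig_p_range[1],
                            config$sig_p_range[2])
    fdr[true] <- stats::runif(sum(true), config$sig_fdr_range[1],
                              config$sig_fdr_range[2])
    # FPKM by planted category, rejection-sampled inside the category bounds
    bounds <- list(silenced = c(0, 1), low = c(1, 10),
                   moderate = c(10, 1000 + 1), strong = c(1000 + 1e-9, Inf))
    fpkm <- numeric(n)
    for (cat in names(bounds)) {
      idx <- which(ground_truth$expr_category == cat)
      if (length(idx) == 0L) next
      lo <- bounds[[cat]][1]; hi <- bounds[[cat]][2]
      meanlog <- log(config$fpkm_medians[[cat]])
      sdlog <- config$fpkm_sdlog[[cat]]
      x <- stats::rlnorm(length(idx), meanlog, sdlog)
      for (tries in 1:50) {
        out <- x < lo | x >= hi
        if (!any(out)) break
        x[out] <- stats::rlnorm(sum(out), meanlog, sdlog)
      }
      x[x < lo | x >= hi] <- config$fpkm_medians[[cat]]
      fpkm[idx] <- x
    }
    # moderate includes exactly 1000; anything that landed in (1000, 1001)
    # during rejection is still moderate by design of the bounds above
    fpkm[ground_truth$expr_category == "moderate" & fpkm > 1000] <- 1000
    fpkm[ground_truth$hard_candidate] <-
      pmin(fpkm[ground_truth$hard_candidate], 0.99)
    list(de = data.frame(gene_id = ground_truth$gene_id, log2fc = log2fc,
                         p_value = p, fdr = fdr, stringsAsFactors = FALSE),
         fpkm = data.frame(gene_id = ground_truth$gene_id, fpkm = fpkm,
                           stringsAsFactors = FALSE))
  })
}

#' Simulate a complete labelled dataset
#'
#' Runs every generator stage under the config seed and bundles the results
#' with their ground truth.
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_dataset` list: `annotation`, `ground_truth`,
#'   `track`, `peaks`, `de`, `fpkm`, `config`.
#' @export
simulate_dataset <- function(config) {
  annotation <- simulate_annotation(config)
  truth <- simulate_ground_truth(config, annotation)
  track <- simulate_signal(config, annotation, truth)
  peaks <- simulate_peaks(config, annotation, truth)
  tables <- simulate_de_and_fpkm(config, truth)
  structure(list(annotation = annotation, ground_truth = truth,
                 track = track, peaks = peaks,
                 de = tables$de, fpkm = tables$fpkm, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d genes, %d peaks, %d signal intervals (seed %d)\n",
    nrow(x$annotation), nrow(x$peaks),
    sum(vapply(x$track$chroms, nrow, 0L)), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `genes.bed`, `peaks.narrowPeak`, `signal.bedgraph`, `de.tsv`,
#' `fpkm.tsv`, `ground_truth.tsv` and a `manifest.json` holding the config
#' and per-file MD5 checksums. Every file is readable by the package's own
#' readers into structures identical to the in-memory dataset.
#'
#' @param dataset a `synthetic_dataset`.
#' @param directory output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(directory, "genes.bed"),
             peaks = file.path(directory, "peaks.narrowPeak"),
             signal = file.path(directory, "signal.bedgraph"),
             de = file.path(directory, "de.tsv"),
             fpkm = file.path(directory, "fpkm.tsv"),
             ground_truth = file.path(directory, "ground_truth.tsv"))
  write_bed(dataset$annotation, paths[["genes"]])
  write_narrowpeak(dataset$peaks, paths[["peaks"]])
  write_bedgraph(dataset$track, paths[["signal"]])
  de <- dataset$de
  names(de)[names(de) == "p_value"] <- "pvalue"
  utils::write.table(de, paths[["de"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$fpkm, paths[["fpkm"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$ground_truth, paths[["ground_truth"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = dataset$config[setdiff(names(dataset$config), "effect_ranges")],
    effect_ranges = dataset$config$effect_ranges,
    md5 = as.list(tools::md5sum(paths)))
  manifest_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}
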