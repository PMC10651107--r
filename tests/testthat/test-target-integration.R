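ann1 <- genome_annotation(data.frame(
  gene_id = c("plus", "minus"), chrom = "chr1",
  start = c(5000, 5000), end = c(8000, 8000), strand = c("+", "-")))

test_that("peak assignment follows the strand-aware TSS-1kb / TES+100bp window", {
  plus_only <- ann1[1, ]
  class(plus_only) <- class(ann1)
  # within 1 kb upstream of a + strand TSS
  p <- peak_set(data.frame(chrom = "chr1", start = 4200, end = 4300))
  expect_equal(names(assign_peaks_to_genes(p, plus_only)), "plus")
  # past TES + 100
  p <- peak_set(data.frame(chrom = "chr1", start = 8150, end = 8200))
  expect_equal(length(assign_peaks_to_genes(p, plus_only)), 0L)
  # just inside TES + 100
  p <- peak_set(data.frame(chrom = "chr1", start = 8050, end = 8099))
  expect_equal(names(assign_peaks_to_genes(p, plus_only)), "plus")
  # upstream of a - strand TSS (TSS at 7999, window extends to 9000)
  minus_only <- ann1[2, ]
  class(minus_only) <- class(ann1)
  p <- peak_set(data.frame(chrom = "chr1", start = 8500, end = 8600))
  expect_equal(names(assign_peaks_to_genes(p, minus_only)), "minus")
  p <- peak_set(data.frame(chrom = "chr1", start = 9050, end = 9100))
  expect_equal(length(assign_peaks_to_genes(p, minus_only)), 0L)
})

test_that("assignment equals the brute-force all-pairs oracle on random instances", {
  set.seed(77)
  for (rep in 1:25) {
    ann <- rand_annotation(n = sample(10:40, 1))
    peaks <- rand_peaks(n = sample(20:120, 1))
    got <- assign_peaks_to_genes(peaks, ann)
    want <- oracle_assign(peaks, ann)
    expect_equal(sort(names(got)), sort(names(want)))
    for (g in names(want)) {
      expect_equal(sort(got[[g]]$start), sort(peaks$start[want[[g]]]))
    }
  }
})

test_that("direction classification applies thresholds and polarity", {
  kd <- perturbation_config("knockdown", 0.05, 0.05)
  oe <- perturbation_config("overexpression", 0.05, 0.05)
  de <- data.frame(gene_id = "g", log2fc = 1.2, p_value = 0.001, fdr = 0.01)
  expect_equal(classify_direction(de, kd), "repressed")
  expect_equal(classify_direction(de, oe), "activated")
  de$fdr <- 0.2
  expect_equal(classify_direction(de, kd), "not_significant")
  de <- data.frame(gene_id = "g", log2fc = 0, p_value = 0.001, fdr = 0.01)
  expect_equal(classify_direction(de, kd), "not_significant")
})

test_that("classification is a partition and polarity swap exchanges the labels", {
  set.seed(5)
  de <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   log2fc = round(stats::rnorm(200, 0, 2), 2),
                   p_value = stats::runif(200), fdr = stats::runif(200))
  de$log2fc[1:5] <- 0   # boundary: zero fold change
  kd <- classify_direction(de, perturbation_config("knockdown"))
  oe <- classify_direction(de, perturbation_config("overexpression"))
  expect_true(all(kd %in% c("repressed", "activated", "not_significant")))
  ns <- kd == "not_significant"
  expect_equal(oe == "not_significant", ns)
  expect_equal(oe[!ns] == "repressed", kd[!ns] == "activated")
})

test_that("direct targets are exactly the bound and significant genes", {
  set.seed(9)
  cfg <- simulation_config(seed = 21, n_genes = 100, fraction_bound = 0.4,
                           direction_fractions = c(repressed = 0.6,
                                                   activated = 0.4, null = 0))
  ds <- simulate_dataset(cfg)
  tt <- build_direct_targets(ds$peaks, ds$annotation, ds$de,
                             perturbation_config("knockdown"))
  planted <- ds$ground_truth$gene_id[ds$ground_truth$bound &
                                       ds$ground_truth$direction != "null"]
  expect_equal(sort(tt$gene_id), sort(planted))
  expect_equal(
    tt$direction,
    ds$ground_truth$direction[match(tt$gene_id, ds$ground_truth$gene_id)])
  # significant but unbound genes are excluded
  de2 <- ds$de
  unbound <- ds$ground_truth$gene_id[!ds$ground_truth$bound][1]
  de2[de2$gene_id == unbound, c("p_value", "fdr")] <- 0.001
  de2[de2$gene_id == unbound, "log2fc"] <- 2
  tt2 <- build_direct_targets(ds$peaks, ds$annotation, de2,
                              perturbation_config("knockdown"))
  expect_false(unbound %in% tt2$gene_id)
  # DE ids missing from the annotation are dropped with a message
  de3 <- rbind(ds$de, data.frame(gene_id = "ghost", log2fc = 3,
                                 p_value = 0.001, fdr = 0.001))
  expect_message(
    tt3 <- build_direct_targets(ds$peaks, ds$annotation, de3,
                                perturbation_config("knockdown")),
    "absent from annotation")
  expect_equal(sort(tt3$gene_id), sort(tt$gene_id))
})

test_that("overlap summaries reproduce the published sharing percentages", {
  mk <- function(ids, label) direct_target_table(
    data.frame(gene_id = ids, direction = "repressed", log2fc = 1), label)
  a <- mk(sprintf("s%04d", 1:405), "iso220")
  b <- mk(sprintf("s%04d", c(1:335, 5001:5524)), "iso187")
  ov <- overlap_summary(a, b)
  expect_equal(ov$shared, 335)
  expect_equal(ov$shared_pct_a$pct, 82.7)
  expect_equal(ov$shared_pct_a$pct_int, 83)
  expect_equal(ov$unique_pct_b$pct, 61.0)
  expect_equal(ov$only_a + ov$shared, ov$n_a)
  expect_equal(ov$only_b + ov$shared, ov$n_b)
  # identical and disjoint sets
  same <- overlap_summary(a, a)
  expect_equal(same$shared_pct_a$pct, 100)
  expect_equal(same$only_a, 0)
  disj <- overlap_summary(a, mk("other", "x"))
  expect_equal(disj$shared, 0)
})

test_that("enhancer annotation matches the quadratic all-pairs oracle", {
  p <- peak_set(data.frame(chrom = "chr1", start = 100, end = 200))
  enh <- data.frame(chrom = "chr1", start = 150, end = 160)
  expect_true(annotate_enhancer_overlap(p, enh)$peaks$enhancer)
  expect_equal(
    annotate_enhancer_overlap(p, enh[0, ])$counts[["non_enhancer_peaks"]], 1)
  set.seed(33)
  for (rep in 1:5) {
    peaks <- rand_peaks(n = 1000)
    enh <- rand_peaks(n = 200)[, c("chrom", "start", "end")]
    got <- annotate_enhancer_overlap(peaks, enh)
    want <- vapply(seq_len(nrow(peaks)), function(i) {
      any(pmax(peaks$start[i], enh$start) < pmin(peaks$end[i], enh$end))
    }, TRUE)
    expect_equal(got$peaks$enhancer, want)
    expect_equal(got$counts[["enhancer_peaks"]], sum(want))
  }
})

test_that("narrowPeak files round-trip through write/read", {
  p <- peak_set(data.frame(chrom = c("chr1", "chr2"), start = c(10, 400),
                           end = c(200, 900), name = c("a", "b"),
                           score = c(100, 550), summit = c(90, NA)))
  f <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(p, f)
  back <- read_peaks(f)
  expect_equal(as.data.frame(back), as.data.frame(p))
  expect_error(peak_set(data.frame(chrom = "c", start = 10, end = 20,
                                   summit = 15)), "summit")
})
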