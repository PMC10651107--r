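test_that("simulated annotations respect spacing, bounds, and determinism", {
  cfg <- simulation_config(seed = 1, n_genes = 10)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 10L)
  expect_true(all(ann$start[-1] - ann$end[-10] >= 200))   # intergenic gaps
  expect_true(all(ann$end <= attr(ann, "chrom_sizes")[[cfg$chrom]]))
  expect_true(all(ann$start < ann$end))
  # same config -> byte-identical BED
  f1 <- tempfile(); f2 <- tempfile()
  write_bed(simulate_annotation(cfg), f1)
  write_bed(simulate_annotation(cfg), f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(simulate_annotation(simulation_config(seed = 1, n_genes = 50,
                                                     chrom_length = 1000)),
               "too small")
})

test_that("gene lengths follow the configured uniform law", {
  cfg <- simulation_config(seed = 12, n_genes = 2000)
  ann <- simulate_annotation(cfg)
  len <- ann$end - ann$start
  expect_true(all(len >= 1000 & len <= 10000))
  expect_lt(abs(mean(len) - 5500) / 5500, 0.1)
})

test_that("noise-free signal reproduces the planted pausing ratios exactly", {
  cfg <- simulation_config(seed = 5, n_genes = 60, fraction_bound = 1,
                           direction_fractions = c(repressed = 0.5,
                                                   activated = 0.5, null = 0))
  ds <- simulate_dataset(cfg)
  pi <- pausing_index(ds$track, ds$annotation)
  expect_true(all(pi$status == "ok"))
  expect_equal(pi$pi, ds$ground_truth$pausing_ratio)
})

test_that("peaks land on exactly the planted bound genes; decoys bind nothing", {
  cfg <- simulation_config(seed = 17, n_genes = 100, fraction_bound = 0.4)
  ds <- simulate_dataset(cfg)
  hit <- assign_peaks_to_genes(ds$peaks, ds$annotation)
  expect_equal(length(hit), 40L)
  expect_setequal(names(hit),
                  ds$ground_truth$gene_id[ds$ground_truth$bound])
  # same seed -> identical narrowPeak file
  f1 <- tempfile(); f2 <- tempfile()
  write_narrowpeak(simulate_peaks(cfg, ds$annotation, ds$ground_truth), f1)
  write_narrowpeak(ds$peaks, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # decoys only: peaks exist but no gene is bound, so no direct targets
  dcfg <- simulation_config(seed = 18, n_genes = 50, fraction_bound = 0,
                            decoy_fraction = 0.3)
  dds <- simulate_dataset(dcfg)
  expect_gt(nrow(dds$peaks), 0L)
  expect_equal(length(assign_peaks_to_genes(dds$peaks, dds$annotation)), 0L)
  tt <- build_direct_targets(dds$peaks, dds$annotation, dds$de,
                             perturbation_config("knockdown"))
  expect_equal(nrow(tt), 0L)
})

test_that("planted effect classes land in their log2FC bins with planted signs", {
  cfg <- simulation_config(seed = 23, n_genes = 500)
  ds <- simulate_dataset(cfg)
  tt <- build_direct_targets(ds$peaks, ds$annotation, ds$de,
                             perturbation_config("knockdown"))
  s <- bin_log2fc(tt)
  truth <- ds$ground_truth[match(tt$gene_id, ds$ground_truth$gene_id), ]
  map <- c(soft = "lt2", mid = "two_to_three", hard = "gt3")
  expect_equal(as.character(log2fc_bin(tt$log2fc)),
               unname(map[truth$effect_class]))
  # knockdown polarity: repressed genes go up without the factor
  expect_true(all(tt$log2fc[tt$direction == "repressed"] > 0))
  expect_true(all(tt$log2fc[tt$direction == "activated"] < 0))
  # overexpression polarity flips the signs
  ocfg <- simulation_config(seed = 23, polarity = "overexpression", n_genes = 100)
  ods <- simulate_dataset(ocfg)
  ott <- build_direct_targets(ods$peaks, ods$annotation, ods$de,
                              perturbation_config("overexpression"))
  otruth <- ods$ground_truth[match(ott$gene_id, ods$ground_truth$gene_id), ]
  expect_true(all(ott$log2fc[otruth$direction == "repressed"] < 0))
})

test_that("an all-null configuration yields no direct targets", {
  cfg <- simulation_config(seed = 29, n_genes = 300, fraction_bound = 0.5,
                           direction_fractions = c(repressed = 0,
                                                   activated = 0, null = 1))
  ds <- simulate_dataset(cfg)
  expect_message(
    tt <- build_direct_targets(ds$peaks, ds$annotation, ds$de,
                               perturbation_config("knockdown")),
    "empty")
  expect_equal(nrow(tt), 0L)
})

test_that("written datasets are re-read into the same structures", {
  cfg <- simulation_config(seed = 41, n_genes = 40, decoy_fraction = 0.2,
                           noise = TRUE)
  ds <- simulate_dataset(cfg)
  dir <- file.path(tempdir(), "synthds")
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(manifest))
  ann <- read_bed(file.path(dir, "genes.bed"),
                  chrom_sizes = attr(ds$annotation, "chrom_sizes"))
  expect_equal(as.data.frame(ann), as.data.frame(ds$annotation))
  peaks <- read_peaks(file.path(dir, "peaks.narrowPeak"))
  expect_equal(peaks$start, ds$peaks$start)
  expect_equal(peaks$summit, ds$peaks$summit)
  track <- read_bedgraph(file.path(dir, "signal.bedgraph"))
  expect_equal(names(track$chroms), names(ds$track$chroms))
  got <- track$chroms[[cfg$chrom]]
  want <- ds$track$chroms[[cfg$chrom]]
  expect_equal(got$start, want$start)
  expect_equal(got$value, want$value, tolerance = 1e-8)
  de <- read_de_table(file.path(dir, "de.tsv"))
  expect_equal(de$gene_id, ds$de$gene_id)
  expect_equal(de$log2fc, ds$de$log2fc, tolerance = 1e-10)
  fpkm <- read_fpkm_table(file.path(dir, "fpkm.tsv"))
  expect_equal(fpkm$fpkm, ds$fpkm$fpkm, tolerance = 1e-10)
  # end-to-end determinism: a second write of the same config is byte-identical
  dir2 <- file.path(tempdir(), "synthds2")
  write_dataset(simulate_dataset(cfg), dir2)
  for (f in c("genes.bed", "peaks.narrowPeak", "signal.bedgraph", "de.tsv",
              "fpkm.tsv", "ground_truth.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(dir, f))),
                 unname(tools::md5sum(file.path(dir2, f))))
  }
})

test_that("generator randomness does not leak into the caller's RNG state", {
  set.seed(999)
  before <- stats::runif(1)
  set.seed(999)
  invisible(simulate_dataset(simulation_config(seed = 3, n_genes = 20)))
  after <- stats::runif(1)
  expect_equal(before, after)
})
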