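pi_ann <- genome_annotation(data.frame(
  gene_id = c("fwd", "rev", "short"), chrom = "chr1",
  start = c(20000, 50000, 70000), end = c(25000, 55000, 70350),
  strand = c("+", "-", "+")))

test_that("pausing index is the promoter/body ratio with the stated windows", {
  # uniform signal: ratio of equal means is 1
  u <- pausing_index(constant_track(2), pi_ann, c("fwd", "rev"))
  expect_equal(u$pi, c(1, 1))
  expect_equal(u$status, c("ok", "ok"))
  # piecewise track: promoter mean 10, body mean 2 -> pi 5 on both strands
  tr <- signal_track(data.frame(
    chrom = "chr1",
    start = c(19950, 20300, 54950, 50100),
    end   = c(20050, 24900, 55050, 54700),
    value = c(10, 2, 10, 2)))
  r <- pausing_index(tr, pi_ann, c("fwd", "rev"))
  expect_equal(r$promoter_mean, c(10, 10))
  expect_equal(r$body_mean, c(2, 2))
  expect_equal(r$pi, c(5, 5))
  # 350 bp gene: body window inverted
  s <- pausing_index(constant_track(2), pi_ann, "short")
  expect_equal(s$status, "excluded_short_gene")
  expect_true(is.na(s$pi))
  # zero body signal is excluded, not infinite
  prom_only <- signal_track(data.frame(chrom = "chr1", start = 19950,
                                       end = 20050, value = 4))
  z <- pausing_index(prom_only, pi_ann, "fwd")
  expect_equal(z$status, "excluded_zero_body")
  expect_true(is.na(z$pi))
})

test_that("promoter and body means match dense-array oracles on random tracks", {
  set.seed(88)
  for (rep in 1:30) {
    iv <- rand_intervals(chrom_len = 60000, n = 150)
    tr <- signal_track(iv)
    dense <- dense_signal(iv, 60000)
    start <- sample(10000:30000, 1)
    len <- sample(500:8000, 1)
    strand <- sample(c("+", "-"), 1)
    ann <- genome_annotation(data.frame(gene_id = "g", chrom = "chr1",
                                        start = start, end = start + len,
                                        strand = strand))
    r <- pausing_index(tr, ann)
    if (strand == "+") {
      prom <- mean(oracle_window_values(dense, start - 50, start + 50))
      body <- mean(oracle_window_values(dense, start + 300, start + len - 100))
    } else {
      prom <- mean(oracle_window_values(dense, start + len - 50, start + len + 50))
      body <- mean(oracle_window_values(dense, start + 100, start + len - 300))
    }
    expect_equal(r$promoter_mean, prom)
    expect_equal(r$body_mean, body)
    if (body > 0) expect_equal(r$pi, prom / body)
  }
})

test_that("the Mann-Whitney U test reproduces exact and tied worked examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_two_sided, 0.1)   # 2 of the C(6,3)=20 assignments as extreme
  expect_equal(r$method, "exact")
  tied <- mann_whitney_u(c(5, 5), c(5, 5))
  expect_equal(tied$u_statistic, 2)  # n_a * n_b / 2 under complete symmetry
  expect_equal(tied$p_two_sided, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  expect_error(mann_whitney_u(c(1, Inf), c(2, 3)), "finite")
})

test_that("large-sample p-values agree with the reference implementation to 1e-6", {
  set.seed(99)
  for (rep in 1:25) {
    a <- stats::rnorm(30, mean = stats::runif(1, -1, 1))
    b <- stats::rnorm(30)
    got <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-6)
    expect_equal(got$u_a, unname(ref$statistic))
    expect_true(got$u_statistic >= 0 && got$u_statistic <= 900)
  }
  # ties: midranks + tie-corrected variance, still matching the reference
  for (rep in 1:10) {
    a <- sample(1:6, 25, replace = TRUE)
    b <- sample(2:8, 25, replace = TRUE)
    got <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-6)
  }
})

test_that("exact enumeration and the normal approximation agree at n = 10 + 10", {
  set.seed(123)
  for (rep in 1:10) {
    a <- stats::rnorm(10)
    b <- stats::rnorm(10)
    exact <- mann_whitney_u(a, b, exact_max_n = 20)
    approx <- mann_whitney_u(a, b, exact_max_n = 0)
    expect_equal(exact$method, "exact")
    expect_equal(approx$method, "normal_tie_corrected")
    expect_lt(abs(exact$p_two_sided - approx$p_two_sided), 0.02)
  }
})

test_that("rank statistics are invariant to positive scaling and monotone in shifts", {
  set.seed(14)
  iv <- rand_intervals(chrom_len = 60000, n = 100)
  tr <- signal_track(iv)
  scaled <- signal_track(transform(iv, value = value * 7.3))
  ann <- rand_annotation(n = 30, chrom_len = 55000, min_len = 600)
  p1 <- pausing_index(tr, ann)
  p2 <- pausing_index(scaled, ann)
  expect_equal(p1$pi, p2$pi)
  a <- stats::rnorm(15); b <- stats::rnorm(15)
  expect_equal(mann_whitney_u(a, b)$p_two_sided,
               mann_whitney_u(a * 7.3, b * 7.3)$p_two_sided)
  u_shift <- vapply(c(0, 1, 3), function(d) mann_whitney_u(a + d, b)$u_a, 0)
  expect_true(all(diff(u_shift) >= 0))
})

test_that("group comparisons drop exclusions, report medians, and guard group overlap", {
  cfg <- simulation_config(seed = 31, n_genes = 80, fraction_bound = 1,
                           direction_fractions = c(repressed = 0.5,
                                                   activated = 0.5, null = 0))
  ds <- simulate_dataset(cfg)
  rep_ids <- ds$ground_truth$gene_id[ds$ground_truth$direction == "repressed"]
  act_ids <- ds$ground_truth$gene_id[ds$ground_truth$direction == "activated"]
  cmp <- compare_pausing(ds$track, ds$annotation, rep_ids, act_ids)
  expect_equal(cmp$median_a, 5)
  expect_equal(cmp$median_b, 1.5)
  expect_lt(cmp$comparison$p_two_sided, 0.01)
  expect_error(compare_pausing(ds$track, ds$annotation, rep_ids,
                               c(act_ids, rep_ids[1])), "disjoint")
  # a group against itself (guard off) has no rank signal
  self <- compare_pausing(ds$track, ds$annotation, rep_ids, rep_ids,
                          check_disjoint = FALSE)
  expect_gt(self$comparison$p_two_sided, 0.9)
  # all-short group is an informative error
  short_ann <- genome_annotation(data.frame(
    gene_id = c("s1", "ok1"), chrom = "chr1", start = c(1000, 5000),
    end = c(1300, 11000), strand = "+"))
  expect_error(
    compare_pausing(constant_track(1), short_ann, "s1", "ok1"),
    "no usable genes")
})
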