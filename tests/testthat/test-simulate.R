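test_that("the same seed reproduces the dataset byte for byte", {
  s1 <- simulate_assays(paper_like_config(seed = 7))
  s2 <- simulate_assays(paper_like_config(seed = 7))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  p1 <- tempfile(); p2 <- tempfile()
  write_assay_table(s1$records, p1)
  write_assay_table(s2$records, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  s3 <- simulate_assays(paper_like_config(seed = 8))
  expect_false(identical(s1$records$n_fraction, s3$records$n_fraction))
})

test_that("the null configuration reproduces baselines exactly with zero
           TSS", {
  cfg <- simulation_config(n_genes = 10, silencing_prob = 0,
                           noise_concentration = Inf,
                           detection_dropout = 0, seed = 3)
  sim <- simulate_assays(cfg)
  # every observed fraction equals its gene's baseline
  by_gene <- tapply(sim$records$n_fraction, sim$records$gene_id,
                    function(x) length(unique(x)))
  expect_true(all(by_gene == 1))
  fit <- homeolog_partition(sim$records, contrasts = NA)
  expect_equal(nrow(fit$events), 0L)
  expect_true(all(fit$scores$percent_tss == 0))
})

test_that("deterministically injected reciprocal patterns are counted
           exactly", {
  for (k in c(0L, 3L, 11L)) {
    cfg <- simulation_config(n_genes = 10, silencing_prob = 0,
                             noise_concentration = Inf,
                             deterministic_reciprocal = k, seed = 5)
    sim <- simulate_assays(cfg)
    calls <- classify_records(sim$records)
    ev <- partition_events(calls, sets = tissue_sets()["booting"])
    expect_equal(count_reciprocal(ev), k)
  }
})

test_that("realized silencing frequencies match the configured rates", {
  cfg <- simulation_config(n_genes = 80, silencing_prob = 0.1,
                           noise_concentration = Inf, seed = 13)
  sim <- simulate_assays(cfg)
  n <- nrow(sim$truth)
  expect_gt(n, 10000)
  for (h in c("silenced_N", "silenced_9")) {
    p_hat <- mean(sim$truth[[h]])
    se <- sqrt(0.1 * 0.9 / n)
    expect_lt(abs(p_hat - 0.1), 3 * se)
  }
})

test_that("observed fractions converge to the truth as noise vanishes", {
  cfg <- simulation_config(n_genes = 20, silencing_prob = 0,
                           noise_concentration = 1e6, seed = 17)
  sim <- simulate_assays(cfg)
  expect_lt(max(abs(sim$records$n_fraction - sim$truth$true_fraction)),
            1)
  expect_lt(abs(mean(sim$records$n_fraction - sim$truth$true_fraction)),
            0.1)
})

test_that("noise-free detection recovers the ground truth perfectly", {
  cfg <- simulation_config(
    n_genes = 15, silencing_prob = 0.12, nonfunc_prob = 0.02,
    reciprocal_prob = 0.05, noise_concentration = Inf,
    baseline_concentration = 60,  # baselines well inside the expressed bands
    seed = 23)
  sim <- simulate_assays(cfg)
  calls <- classify_records(sim$records)
  ev <- partition_events(calls)
  rep <- recovery_report(sim$truth, ev)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  expect_equal(rep$fp, 0L)
  expect_equal(rep$fn, 0L)
})

test_that("with moderate noise and no true events the false-positive rate
           stays small", {
  cfg <- simulation_config(n_genes = 30, silencing_prob = 0,
                           noise_concentration = 200,
                           baseline_concentration = 60, seed = 29)
  sim <- simulate_assays(cfg)
  calls <- classify_records(sim$records)
  ev <- partition_events(calls)
  rep <- recovery_report(sim$truth, ev)
  # no true positives exist; specificity is the per-slot true-negative rate
  expect_equal(rep$tp + rep$fn, 0L)
  expect_gt(rep$specificity, 0.95)
})

test_that("total dropout leaves nothing to score", {
  cfg <- simulation_config(n_genes = 5, silencing_prob = 0.2,
                           detection_dropout = 1, seed = 31)
  sim <- simulate_assays(cfg)
  expect_equal(nrow(sim$records), 0L)
  calls <- classify_records(sim$records)
  ev <- partition_events(calls)
  expect_equal(nrow(ev), 0L)
  expect_error(score_tss(ev, calls, tissue_sets()$all_six), "insufficient")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(silencing_prob = 1.2), "outside")
  expect_error(simulation_config(nonfunc_prob = -0.1), "outside")
  expect_error(simulation_config(reciprocal_prob = c(MIX = 0.1)),
               "cover all groups")
})

test_that("the analytic expectation matches a direct Monte Carlo average", {
  # small config, many replicates through the real pipeline
  cfg <- simulation_config(
    n_genes = 40, group_sizes = c(MIX = 4),
    silencing_prob = matrix(c(0.08, 0.25, 0.1, 0.1), 1, 4,
                            dimnames = list("MIX", c("leaf", "root", "flag",
                                                     "spike"))),
    nonfunc_prob = 0.01, reciprocal_prob = 0.03,
    noise_concentration = 300, baseline_concentration = 6, seed = 1)
  set <- tissue_sets()$all_six
  nominal <- expected_tss_percent(cfg, "MIX", set)
  means <- vapply(1:30, function(s) {
    cfg$seed <- s
    sim <- simulate_assays(cfg)
    calls <- classify_records(sim$records)
    ev <- detect_tss(calls, set, set_name = "all_six")
    mean(score_tss(ev, calls, set, set_name = "all_six")$percent_tss)
  }, numeric(1))
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - nominal), 4 * mc_se)
})
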