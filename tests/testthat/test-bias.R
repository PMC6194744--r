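test_that("bias categories follow the published bands", {
  expect_equal(as.character(classify_bias(50)), "EQUIVALENT")
  expect_equal(as.character(classify_bias(97)), "COMPLETE_N")
  expect_equal(as.character(classify_bias(3)), "COMPLETE_9")
  expect_equal(as.character(classify_bias(NA)), "NO_EXPRESSION")
  # half-open boundaries, top interval closed
  expect_equal(as.character(classify_bias(c(0, 5, 20, 40, 60, 80, 95, 100))),
               c("COMPLETE_9", "STRONG_9", "BIASED_9", "EQUIVALENT",
                 "BIASED_N", "STRONG_N", "COMPLETE_N", "COMPLETE_N"))
  expect_error(classify_bias(101), "outside")
  expect_error(classify_bias(-0.1), "outside")
})

test_that("classification is mirror-symmetric away from boundaries", {
  mirror <- c(COMPLETE_9 = "COMPLETE_N", STRONG_9 = "STRONG_N",
              BIASED_9 = "BIASED_N", EQUIVALENT = "EQUIVALENT",
              BIASED_N = "BIASED_9", STRONG_N = "STRONG_9",
              COMPLETE_N = "COMPLETE_9")
  set.seed(3)
  f <- runif(2000, 0, 100)
  f <- f[!f %in% c(0, 5, 20, 40, 60, 80, 95, 100)]
  expect_equal(as.character(classify_bias(100 - f)),
               unname(mirror[as.character(classify_bias(f))]))
})

test_that("silencing calls derive only from complete bias", {
  cs <- call_silencing(c("COMPLETE_N", "COMPLETE_9", "EQUIVALENT",
                         "NO_EXPRESSION"))
  expect_equal(cs$silenced_N, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(cs$silenced_9, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cs$expressed_N, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cs$expressed_9, c(FALSE, TRUE, TRUE, FALSE))
  expect_error(call_silencing("HALFWAY"), "unknown")
})

test_that("state tabulation produces row-normalized proportions", {
  calls <- data.frame(group = "MIX", tissue = "L1",
                      category = rep("EQUIVALENT", 10),
                      stringsAsFactors = FALSE)
  tab <- tabulate_states(calls)
  expect_equal(tab$proportion[tab$category == "EQUIVALENT"], 1)

  calls2 <- data.frame(group = "F1", tissue = "R1",
                       category = rep(c("COMPLETE_N", "COMPLETE_9"), 2),
                       stringsAsFactors = FALSE)
  tab2 <- tabulate_states(calls2)
  expect_equal(sort(tab2$proportion[tab2$n > 0]), c(0.5, 0.5))

  empty <- tabulate_states(calls[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("group", "tissue", "category", "n", "proportion") %in%
                    names(empty)))
})

test_that("state proportions sum to one within every group x tissue cell", {
  sim <- simulate_assays(paper_like_config(seed = 9))
  calls <- classify_records(sim$records)
  tab <- tabulate_states(calls)
  sums <- tapply(tab$proportion, paste(tab$group, tab$tissue), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("tabulated category frequencies recover the generator's nominal
           single-tissue rates", {
  # F1 leaves: silencing 0.01/homeolog, attenuation 0.3 keeps baselines in
  # the equivalent band, so EQUIVALENT should dominate at a predictable rate
  cfg <- paper_like_config(seed = 14)
  sim <- simulate_assays(cfg)
  calls <- classify_records(sim$records)
  f1_leaf <- calls[calls$group == "F1" & calls$tissue %in% c("L1", "L2"), ]
  n <- nrow(f1_leaf)
  p_comp <- mean(f1_leaf$category %in% c("COMPLETE_N", "COMPLETE_9"))
  # nominal: either homeolog silenced alone -> complete bias (noise cannot
  # move a 1%/99% mean across the 5%/95% line by much at concentration 300)
  nominal <- 2 * 0.01 * 0.99
  ci <- 2.58 * sqrt(nominal * (1 - nominal) / n)
  expect_lt(abs(p_comp - nominal), ci + 0.005)
})

test_that("locus patterns split equal from unequal expression", {
  calls <- rbind(
    make_calls("G1", "I1", c("L1", "R1", "L2"),
               c("EQUIVALENT", "EQUIVALENT", "BIASED_N")),
    make_calls("G2", "I1", c("L1", "R1"),
               c("BIASED_N", "EQUIVALENT")),
    make_calls("G3", "I1", c("L1", "R1"),
               c("NO_EXPRESSION", "NO_EXPRESSION")))
  calls$n_fraction <- ifelse(calls$category == "NO_EXPRESSION", NA_real_,
                             ifelse(calls$category == "EQUIVALENT", 50, 70))
  lp <- locus_patterns(calls)
  expect_equal(lp$pattern[lp$gene_id == "G1"], "EQUAL")     # 2/3 equivalent
  expect_equal(lp$pattern[lp$gene_id == "G2"], "UNEQUAL")   # tie -> unequal
  expect_equal(lp$pattern[lp$gene_id == "G3"], "NO_CALLS")
})
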