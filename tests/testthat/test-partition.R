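all_six <- tissue_sets()$all_six
booting <- tissue_sets()$booting

test_that("a homeolog silenced in both roots but expressed in leaves is TSS", {
  # the FtsH-protease-like pattern: 9 copy off in R1 and R2, on elsewhere
  cats <- ifelse(all_six %in% c("R1", "R2"), "COMPLETE_N", "EQUIVALENT")
  calls <- make_calls("HK_5", "MIX_1", all_six, cats)
  ev <- detect_tss(calls, all_six, set_name = "all_six")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$homeolog, "9")
  expect_equal(ev$kind, "TSS")
  expect_equal(ev$silenced_in, "R1,R2")
  expect_equal(ev$expressed_in, "L1,L2,F,S")
})

test_that("complementary silencing of the two homeologs is reciprocal TSS", {
  cats <- c(L2 = "COMPLETE_9", R2 = "COMPLETE_N", F = "EQUIVALENT",
            S = "BIASED_N")
  calls <- make_calls("G1", "99NN_1", booting, unname(cats[booting]))
  ev <- detect_tss(calls, booting, set_name = "booting")
  expect_equal(sort(ev$kind), c("RECIPROCAL_TSS", "TSS", "TSS"))
  expect_equal(count_reciprocal(ev), 1L)
  expect_equal(count_reciprocal(ev, groups = "F1"), 0L)
})

test_that("silencing in every measured tissue is nonfunctionalization,
           never TSS", {
  calls <- make_calls("G1", "I1", all_six, rep("COMPLETE_9", 6))
  ev <- detect_tss(calls, all_six, set_name = "all_six")
  expect_equal(ev$kind, "NONFUNCTIONALIZATION")
  expect_equal(ev$homeolog, "N")
  expect_equal(ev$expressed_in, "")
  expect_equal(ev$silenced_in, paste(all_six, collapse = ","))
})

test_that("uniformly equivalent expression yields no events", {
  calls <- make_calls("G1", "I1", all_six, rep("EQUIVALENT", 6))
  ev <- detect_tss(calls, all_six, set_name = "all_six")
  expect_equal(nrow(ev), 0L)
})

test_that("no-expression tissues are neutral for both homeologs", {
  # N silenced in L1; all other tissues have both copies off: no expressed
  # contrast exists, so neither TSS nor nonfunctionalization
  cats <- c("COMPLETE_9", rep("NO_EXPRESSION", 5))
  calls <- make_calls("G1", "I1", all_six, cats)
  ev <- detect_tss(calls, all_six, set_name = "all_six")
  expect_equal(nrow(ev), 0L)
})

test_that("gene x individual pairs with fewer than two measured tissues are
           excluded", {
  calls <- make_calls("G1", "I1", "L1", "COMPLETE_9")
  ev <- detect_tss(calls, all_six, set_name = "all_six")
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "n_insufficient"), 1L)
})

test_that("TSS scores implement the triple-counting definition", {
  # 30 genes x 2 tissues; one homeolog silenced in one tissue of one gene
  calls <- do.call(rbind, lapply(1:30, function(g)
    make_calls(paste0("G", g), "I1", c("L1", "R1"),
               if (g == 1) c("COMPLETE_9", "EQUIVALENT")
               else c("EQUIVALENT", "EQUIVALENT"))))
  ev <- detect_tss(calls, c("L1", "R1"), set_name = "tillering")
  sc <- score_tss(ev, calls, c("L1", "R1"), set_name = "tillering")
  expect_equal(sc$numerator, 1L)
  expect_equal(sc$denominator, 120L)
  expect_equal(sc$percent_tss, 100 / 120)

  # no events -> 0%
  calls0 <- calls[calls$gene_id != "G1", ]
  ev0 <- detect_tss(calls0, c("L1", "R1"), set_name = "tillering")
  sc0 <- score_tss(ev0, calls0, c("L1", "R1"), set_name = "tillering")
  expect_equal(sc0$percent_tss, 0)

  # gene x tissue denominator convention counts cells once
  sc_gt <- score_tss(ev, calls, c("L1", "R1"), set_name = "tillering",
                     denominator = "gene_tissue")
  expect_equal(sc_gt$denominator, 60L)
  expect_equal(sc_gt$numerator, 1L)
})

test_that("development TSS contrasts the same organ across stages", {
  calls <- rbind(
    make_calls("G1", "I1", c("R1", "R2"), c("COMPLETE_9", "EQUIVALENT")),
    make_calls("G2", "I1", c("R1", "R2"), c("EQUIVALENT", "EQUIVALENT")))
  sc <- score_development_tss(calls, "root")
  expect_equal(sc$tissue_set, "root_dev")
  expect_equal(sc$numerator, 1L)
  expect_equal(sc$denominator, 8L)

  # identical categories at both stages -> 0
  calls2 <- rbind(
    make_calls("G1", "I1", c("L1", "L2"), c("BIASED_N", "BIASED_N")))
  sc2 <- score_development_tss(calls2, "leaf")
  expect_equal(sc2$percent_tss, 0)
})

test_that("group summaries report mean, SE and n", {
  scores <- data.frame(individual_id = c("A", "B", "C", "D"),
                       group = c("F1", "F1", "NN99", "NN99"),
                       tissue_set = "all_six",
                       numerator = 1, denominator = 10,
                       percent_tss = c(10, 20, 5, 5),
                       stringsAsFactors = FALSE)
  gs <- summarize_groups(scores)
  f1 <- gs[gs$group == "F1", ]
  expect_equal(f1$mean_tss, 15)
  expect_equal(f1$se_tss, 5)
  expect_equal(gs$se_tss[gs$group == "NN99"], 0)
  expect_equal(gs$n, c(2L, 2L))

  one <- summarize_groups(scores[1, ])
  expect_true(is.na(one$se_tss))
})

test_that("a homeolog never has both TSS and nonfunctionalization in the
           same set, over random assignments", {
  set.seed(77)
  for (i in 1:300) {
    cats <- sample(bias_levels(), 6, replace = TRUE)
    ev <- detect_tss(make_calls("G1", "I1", all_six, cats), all_six,
                     set_name = "s")
    for (h in c("N", "9")) {
      kinds <- ev$kind[!is.na(ev$homeolog) & ev$homeolog == h]
      expect_lte(sum(kinds %in% c("TSS", "NONFUNCTIONALIZATION")), 1L)
    }
  }
})

test_that("restricting the tissue set never creates new TSS beyond the
           superset's events", {
  set.seed(78)
  for (i in 1:200) {
    cats <- sample(bias_levels(), 6, replace = TRUE,
                   prob = c(3, 1, 1, 3, 1, 1, 3, 2))
    calls <- make_calls("G1", "I1", all_six, cats)
    ev_full <- detect_tss(calls, all_six, set_name = "s")
    ev_sub <- detect_tss(calls, booting, set_name = "s")
    for (j in seq_len(nrow(ev_sub))) {
      if (ev_sub$kind[j] != "TSS") next
      h <- ev_sub$homeolog[j]
      sup <- ev_full[!is.na(ev_full$homeolog) & ev_full$homeolog == h &
                       ev_full$kind == "TSS", ]
      expect_equal(nrow(sup), 1L)
      sub_sil <- strsplit(ev_sub$silenced_in[j], ",")[[1]]
      sup_sil <- strsplit(sup$silenced_in, ",")[[1]]
      expect_true(all(sub_sil %in% sup_sil))
    }
  }
})
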