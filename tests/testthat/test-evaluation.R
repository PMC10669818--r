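test_that("discrete tallies cover the four cells exactly once per report", {
  sys <- data.frame(report_id = "r1", outcome = "AR level", value = 1)
  ref <- data.frame(report_id = "r1", outcome = "AR level", value = 1)
  t1 <- tally_discrete(sys, ref, "AR level")
  expect_equal(unlist(t1[c("TP", "FN", "FP", "TN")]),
               c(TP = 1L, FN = 0L, FP = 0L, TN = 0L))
  t2 <- tally_discrete(sys[0, ], ref, "AR level", report_ids = "r1")
  expect_equal(t2$FN, 1L)
  # wrong category counts once, as a false positive
  sys3 <- data.frame(report_id = "r1", outcome = "AR level", value = 3)
  t3 <- tally_discrete(sys3, ref, "AR level")
  expect_equal(unlist(t3[c("TP", "FN", "FP", "TN")]),
               c(TP = 0L, FN = 0L, FP = 1L, TN = 0L))
  # cells sum to the number of evaluated instances
  ids <- paste0("r", 1:10)
  t4 <- tally_discrete(sys, ref, "AR level", report_ids = ids)
  expect_equal(t4$TP + t4$FN + t4$FP + t4$TN, 10L)
  expect_error(tally_discrete(sys, ref, "Bogus", lexicon = lex),
               "unknown outcome")
})

test_that("precision/recall/F1 handle perfect and undefined tallies", {
  m <- precision_recall_f1(discrete_tally("x", 1, 0, 0, 0))
  expect_equal(unlist(m), c(precision = 1, recall = 1, f1 = 1))
  und <- precision_recall_f1(discrete_tally("x", 0, 0, 0, 10))
  expect_true(all(is.na(unlist(und))))
})

test_that("rare-outcome aggregation sums cells and concatenates labels", {
  parts <- list(discrete_tally("AV Stenosis", 2, 1, 3, 92),
                discrete_tally("MV Stenosis", 1, 1, 2, 94),
                discrete_tally("PV Stenosis", 1, 1, 2, 94),
                discrete_tally("TV Stenosis", 1, 1, 1, 95))
  agg <- aggregate_rare(parts)
  expect_equal(agg$outcome, "AV Stenosis + MV Stenosis + PV Stenosis + TV Stenosis")
  expect_equal(unlist(agg[c("TP", "FN", "FP", "TN")]),
               c(TP = 5L, FN = 4L, FP = 8L, TN = 375L))
  single <- aggregate_rare(parts[1])
  expect_equal(unlist(single[-1]), unlist(parts[[1]][-1]))
  zz <- aggregate_rare(list(discrete_tally("a", 0, 0, 0, 0),
                            discrete_tally("b", 0, 0, 0, 0)))
  expect_equal(zz$TP + zz$FN + zz$FP + zz$TN, 0L)
})

test_that("pooled accuracy degenerates sensibly", {
  expect_equal(pooled_accuracy(list(discrete_tally("x", 1, 0, 0, 0)))$accuracy,
               100)
  expect_equal(pooled_accuracy(list(discrete_tally("x", 0, 1, 0, 0)))$accuracy,
               0)
  expect_true(is.na(pooled_accuracy(list(discrete_tally("x", 0, 0, 0, 0)))$accuracy))
})

test_that("R-squared is scale-blind while absolute-agreement ICC is not", {
  expect_equal(r_squared(paired(c(5, 7, 9), c(5, 7, 9))), 1)
  ps <- paired(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r_squared(ps), 1)            # perfect line, wrong scale
  ic <- icc(ps)
  expect_lt(ic$icc, r_squared(ps))          # agreement penalises the scale
  expect_true(is.na(r_squared(paired(c(1, 1, 1), c(1, 2, 3)))))
  # independent pairs decorrelate at large n
  withr::with_seed(99, {
    expect_lt(r_squared(paired(rnorm(1000), rnorm(1000))), 0.02)
  })
})

test_that("ICC matches a hand-coded ANOVA oracle and bands follow thresholds", {
  expect_equal(icc(paired(c(5, 7, 9), c(5, 7, 9)))$icc, 1)
  expect_equal(icc(paired(c(5, 7, 9), c(5, 7, 9)))$band, "excellent")
  expect_equal(icc_band(0.85), "good")
  expect_equal(icc_band(0.49999), "poor")
  expect_equal(icc_band(0.5), "moderate")
  expect_equal(icc_band(0.91), "excellent")
  # degenerate: identical constant series -> 1 by convention, p undefined
  deg <- icc(paired(rep(4, 5), rep(4, 5)))
  expect_equal(deg$icc, 1)
  expect_true(is.na(deg$p))
  # oracle: two-way ANOVA mean squares via lm/anova
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(5:30, 1)
      ref <- rnorm(n, 10, 3)
      sys <- ref * runif(1, 0.8, 1.2) + rnorm(n, 0, 1)
      ps <- paired(ref, sys)
      got <- icc(ps)
      d <- data.frame(y = c(ref, sys), subj = factor(rep(seq_len(n), 2)),
                      rater = factor(rep(1:2, each = n)))
      ms <- stats::anova(stats::lm(y ~ subj + rater, d))$`Mean Sq`
      want <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / n)
      expect_equal(got$icc, want, tolerance = 1e-10)
      f <- ms[1] / ms[3]
      expect_equal(got$p, stats::pf(f, n - 1, n - 1, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })
})

test_that("bubble calibration data sits on the diagonal when extraction is perfect", {
  corpus <- generate_corpus(generator_profile(n_reports = 15, seed = 3,
                                              noise = zero_noise))
  recs <- extract_corpus(corpus$reports, lex, rules)
  bd <- bubble_data(to_long(recs), corpus$truth, lex)
  expect_equal(bd$system_magnitude, bd$reference_magnitude, tolerance = 1e-9)
  # an outcome absent everywhere is (0, 0, 0)
  absent <- bd[bd$frequency == 0, ]
  if (nrow(absent)) {
    expect_true(all(absent$reference_magnitude == 0 &
                      absent$system_magnitude == 0))
  }
  # under-extraction drops the system below the diagonal
  half <- recs[seq_len(nrow(recs)) %% 2 == 0, ]
  bd2 <- bubble_data(to_long(half), corpus$truth, lex)
  expect_true(sum(bd2$system_magnitude) < sum(bd2$reference_magnitude))
})

test_that("injected corruption moves recall and precision as designed", {
  corpus <- generate_corpus(generator_profile(n_reports = 60, seed = 21,
                                              noise = zero_noise))
  recs <- to_long(extract_corpus(corpus$reports, lex, rules))
  miss <- corrupt_records(recs, miss_rate = 0.3, lexicon = lex, seed = 2)
  cmp <- compare_records(miss, corpus$truth)
  se <- sqrt(0.7 * 0.3 / nrow(corpus$truth))
  expect_lt(abs(cmp$recall - 0.7), 4 * se)
  expect_equal(cmp$precision, 1)
  conf <- corrupt_records(recs, confusion_rate = 0.5, lexicon = lex, seed = 3)
  cmp2 <- compare_records(conf, corpus$truth)
  expect_lt(cmp2$precision, 1)
  expect_equal(cmp2$fp + cmp2$tp, nrow(conf))
})

test_that("full evaluation agrees with itself on identical inputs", {
  corpus <- generate_corpus(generator_profile(n_reports = 25, seed = 13,
                                              noise = zero_noise))
  recs <- to_long(extract_corpus(corpus$reports, lex, rules))
  ev <- evaluate_extractions(recs, recs, lex)
  seen <- ev$continuous[!is.na(ev$continuous$icc), ]
  expect_true(all(seen$icc == 1))
  expect_true(all(seen$band == "excellent"))
  expect_equal(ev$pooled$accuracy, 100)
  expect_error(evaluate_extractions(
    data.frame(report_id = "a", outcome = "EF", value = 1),
    data.frame(report_id = "b", outcome = "EF", value = 1), lex),
    "share no report ids")
})
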