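test_that("profiles validate their probabilities", {
  expect_error(generator_profile(noise = list(miss = 1.2)), "\\[0, 1\\]")
  expect_error(generator_profile(inclusion_prob = -0.1), "\\[0, 1\\]")
  expect_error(generator_profile(noise = list(bogus = 0.1)), "unknown noise")
  expect_error(generator_profile(n_reports = -1), "non-negative")
})

test_that("generation is deterministic and n = 0 yields an empty corpus", {
  p <- generator_profile(n_reports = 20, seed = 123)
  a <- generate_corpus(p)
  b <- generate_corpus(p)
  expect_identical(a$reports, b$reports)
  expect_identical(a$truth, b$truth)
  e <- generate_corpus(generator_profile(n_reports = 0, seed = 1))
  expect_equal(nrow(e$reports), 0L)
  expect_equal(nrow(e$truth), 0L)
})

test_that("ground truth is normalised: canonical units, pre-averaged ranges", {
  corpus <- generate_corpus(generator_profile(
    n_reports = 40, seed = 17,
    noise = list(miss = 0, unit_jitter = 1, range = 0, negation = 0,
                 malformed = 0, prosthesis = 0)))
  canon <- lex$canonical_unit[match(corpus$truth$outcome, lex$canonical_name)]
  expect_equal(corpus$truth$unit[canon != ""], canon[canon != ""])
  # jittered units in text, canonical truth: extraction still recovers it
  recs <- extract_corpus(corpus$reports, lex, rules)
  cmp <- compare_records(recs, corpus$truth)
  expect_equal(cmp$recall, 1)
  expect_equal(cmp$precision, 1)
  # ranges are pre-averaged to the midpoint
  rng <- generate_corpus(generator_profile(
    n_reports = 20, seed = 18,
    noise = list(miss = 0, unit_jitter = 0, range = 1, negation = 0,
                 malformed = 0, prosthesis = 0)))
  recs2 <- extract_corpus(rng$reports, lex, rules)
  cmp2 <- compare_records(recs2, rng$truth)
  expect_equal(cmp2$recall, 1)
})

test_that("noise modes update text and truth consistently", {
  base <- generate_corpus(generator_profile(n_reports = 30, seed = 5,
                                            noise = zero_noise))
  # perturbing with all-zero rates is the identity
  same <- perturb(base, list())
  expect_identical(same$reports, base$reports)
  expect_identical(same$truth, base$truth)
  # negation noise rewrites discrete grades as negated zeros
  neg <- perturb(base, list(negation = 1))
  disc <- neg$truth[neg$truth$ordinal_label != "", ]
  allows <- lex$severity_scale[match(disc$outcome, lex$canonical_name)] !=
    "lv_function"
  expect_true(all(disc$value[allows] == 0))
  expect_true(all(disc$negated[allows]))
  recs <- extract_corpus(neg$reports, lex, rules)
  expect_equal(compare_records(recs, neg$truth)$recall, 1)
  # malformed decimals are marked uncertain and written as split numbers
  mal <- perturb(base, list(malformed = 1))
  expect_true(any(mal$truth$uncertain))
  unc <- mal$truth[mal$truth$uncertain, ][1, ]
  txt <- mal$reports$text[mal$reports$report_id == unc$report_id]
  parts <- strsplit(format(unc$value), ".", fixed = TRUE)[[1]]
  expect_match(txt, paste0(parts[1], " ", parts[2]))
  # wrong-terminology misses keep the truth record but defeat extraction
  mis <- perturb(base, list(miss = 1))
  recs2 <- extract_corpus(mis$reports, lex, rules)
  expect_equal(compare_records(recs2, mis$truth)$tp, 0)
  expect_equal(nrow(mis$truth), nrow(base$truth))
})

test_that("a forced single-mention corpus renders the expected clause", {
  p <- generator_profile(n_reports = 60, seed = 7, noise = zero_noise)
  corpus <- generate_corpus(p)
  vti <- corpus$truth[corpus$truth$outcome == "AV VTI", ]
  expect_gt(nrow(vti), 0)
  rid <- vti$report_id[1]
  txt <- corpus$reports$text[corpus$reports$report_id == rid]
  expect_match(txt, "(AV VTI|Ao VTI)")
  one <- extract_report(txt, rid, lex, rules)
  expect_equal(one$value[one$outcome == "AV VTI"], vti$value[1])
  expect_equal(one$unit[one$outcome == "AV VTI"], "cm")
})
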