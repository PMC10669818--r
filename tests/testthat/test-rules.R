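test_that("rule file validation catches configuration errors at load time", {
  r <- load_rules(lexicon = lex)
  expect_s3_class(r, "echo_rules")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "  - name: a", "    priority: 10", "    outcome_type: discrete",
               "    lhs: [{elem: lookup}]", "    rhs: [negate, annotate]",
               "  - name: b", "    priority: 10", "    outcome_type: discrete",
               "    lhs: [{elem: lookup}]", "    rhs: [negate, annotate]"), tmp)
  expect_error(load_rules(tmp), "priorities must be unique")
  writeLines(c("rules:",
               "  - name: a", "    priority: 10", "    outcome_type: continuous",
               "    lhs: [{elem: lookup}]",
               "    rhs: [bind_value, annotate]"), tmp)
  expect_error(load_rules(tmp), "not declared in LHS")
  writeLines(c("rules:",
               "  - name: a", "    priority: 10", "    outcome_type: continuous",
               "    outcome: Bogus Outcome",
               "    lhs: [{elem: lookup}, {elem: number, bind: v1}]",
               "    rhs: [bind_value, annotate]"), tmp)
  expect_error(load_rules(tmp, lexicon = lex), "unknown outcome: Bogus Outcome")
})

test_that("value binding averages ranges and converts units", {
  r <- extract_report("Ejection Fraction (EF) 45-50%", "r", lex, rules)
  expect_equal(r$outcome, "EF")
  expect_equal(r$value, 47.5)
  expect_equal(r$value_low, 45)
  expect_equal(r$value_high, 50)
  expect_equal(r$unit, "%")
  # metres standardise to centimetres by multiplication of 100
  r2 <- extract_report("LVOT Diam 0.027 m", "r", lex, rules)
  expect_equal(r2$value, 2.7)
  expect_equal(r2$unit, "cm")
  expect_match(r2$note, "unit_converted:m->cm")
  # en-dash range with "to" connector
  r3 <- extract_report("EF 45 to 50%", "r", lex, rules)
  expect_equal(r3$value, 47.5)
})

test_that("severity and negation rules produce ordinal codes", {
  r <- extract_report("Trivial aortic regurgitation", "r", lex, rules)
  expect_equal(r$value, 1)
  expect_equal(r$ordinal_label, "trivial")
  r2 <- extract_report("No aortic regurgitation", "r", lex, rules)
  expect_equal(r2$value, 0)
  expect_true(r2$negated)
  r3 <- extract_report("Aortic Valve: Trivial-mild paravalvular aortic regurgitation.",
                       "r", lex, rules)
  expect_equal(r3$value, 2)   # combined label -> upper member
  expect_true(r3$prosthetic)  # paravalvular flags prosthesis context
  r4 <- extract_report("LV systolic function appears Normal.", "r", lex, rules)
  expect_equal(r4$value, 1)
  expect_equal(r4$ordinal_label, "normal")
  # report without lexicon terms yields nothing
  r5 <- extract_report("Technically difficult study.", "r", lex, rules)
  expect_equal(nrow(r5), 0L)
})

test_that("split decimals are flagged, never merged", {
  r <- extract_report("AV max PG 38 9 mmHg", "r", lex, rules)
  expect_equal(r$value, 38)
  expect_match(r$note, "suspected_malformed_decimal")
})

test_that("overlap resolution is dominance-ordered, unique and idempotent", {
  txt <- paste0("Aortic Valve: Trivial AR.\n",
                "Aortic Valve (AVR): Mild paraprosthetic regurgitation seen.")
  doc <- annotate_report(txt, "r", lex)
  cands <- apply_rules(doc, rules, lex)
  res <- resolve_overlaps(cands)
  kept <- res[!is.na(res$retained) & res$retained, ]
  # one retained record per outcome; the native mention wins
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$value, 1)
  expect_false(kept$prosthetic[1])
  expect_match(kept$note, "conflict_multiple_mentions")
  # the prosthetic reading survives un-retained, context flagged
  other <- res[!res$retained & res$outcome == "AR level", ]
  expect_true(any(other$prosthetic))
  again <- resolve_overlaps(res)
  o1 <- order(again$tok_first); o2 <- order(res$tok_first)
  expect_equal(again[o1, ], res[o2, ], ignore_attr = TRUE)
  # higher priority suppresses an overlapping lower-priority match:
  # the range rule beats the single-value rule on the same span
  doc2 <- annotate_report("EF 45-50%", "r", lex)
  res2 <- resolve_overlaps(apply_rules(doc2, rules, lex))
  expect_equal(res2$rule_name[res2$retained], "value_range")
  # single candidate is retained unchanged
  doc3 <- annotate_report("AV VTI 78 cm", "r", lex)
  res3 <- resolve_overlaps(apply_rules(doc3, rules, lex))
  expect_equal(nrow(res3), 1L)
  expect_true(res3$retained)
})

test_that("grouping by parent ontology level conserves counts", {
  recs <- extract_report("Sinotubular Junction 2.8 cm. LA Area 23 cm^2. Trivial AR.",
                         "r", lex, rules)
  grp <- group_to_parent(recs, lex)
  expect_true("Sinotubular Junction" %in% grp$VesselsMeasurements$outcome)
  expect_equal(sum(vapply(grp, nrow, 1L)), nrow(recs))
  expect_equal(length(group_to_parent(recs[0, ], lex)), 0L)
})

test_that("batch extraction isolates per-report failures", {
  reports <- data.frame(report_id = c("good", "bad", "good2"),
                        text = c("AV VTI 78 cm", NA, "Trivial AR."),
                        stringsAsFactors = FALSE)
  expect_warning(recs <- extract_corpus(reports, lex, rules), "bad failed")
  expect_setequal(unique(recs$report_id), c("good", "good2"))
  expect_equal(attr(recs, "failed"), "bad")
})

test_that("trace renders every candidate with provenance offsets", {
  r <- extract_report("Aortic Valve: Trivial AR. AV VTI 78 cm.", "r", lex, rules)
  tr <- trace_report(r)
  expect_match(tr[1], "2 retained")
  expect_true(any(grepl("AV VTI", tr)))
  expect_true(any(grepl("trivial \\(code 1\\)", tr)))
})
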