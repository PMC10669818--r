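test_that("tokeniser classifies measurement clauses and keeps units whole", {
  t <- tokenize("AV Vmax 4.2 m/s")
  expect_equal(t$text, c("AV", "Vmax", "4.2", "m/s"))
  expect_equal(t$class, c("word", "word", "number", "unit"))
  t2 <- tokenize("MPD 46 mmHg VTI 103 cm AVA 1.8 cm^2 AVAi 0.45 cm/m^2")
  expect_equal(t2$text[t2$class == "unit"], c("mmHg", "cm", "cm^2", "cm/m^2"))
  # split decimal stays two separate number tokens - never merged
  expect_equal(tokenize("38 9")$text, c("38", "9"))
  expect_equal(tokenize("38 9")$class, c("number", "number"))
  expect_error(tokenize(""), "empty")
  expect_equal(nrow(tokenize(" ")), 0L)
})

test_that("tokenisation partitions all non-whitespace and is deterministic", {
  texts <- c("EF 45-50%. LVIDd: 4.8 cm;",
             "Peak V = 0.7 m/s, E/A 1.2 Lateral E' 10 cm/s",
             "? BAV. No AS (prev. severe)")
  for (txt in texts) {
    t <- tokenize(txt)
    # 0 <= start < end <= nchar, disjoint, covering all non-space chars
    expect_true(all(t$start >= 0 & t$start < t$end & t$end <= nchar(txt)))
    expect_true(all(diff(t$start) > 0))
    expect_true(all(t$end[-nrow(t)] <= t$start[-1]))
    covered <- unlist(mapply(function(s, e) (s + 1):e, t$start, t$end))
    chars <- strsplit(txt, "")[[1]]
    expect_setequal(covered, which(chars != " "))
    expect_identical(t, tokenize(txt))
  }
})

test_that("sentences split at terminators and semicolons but not decimals", {
  lexd <- annotate_report(
    "No aortic stenosis. Trivial aortic regurgitation. AV Vmax: 1.6 m/s.",
    "r1", lex)
  expect_equal(nrow(split_sentences(lexd)), 3L)
  one <- annotate_report("AV Vmax 4.2 m/s MPD 46 mmHg", "r2", lex)
  expect_equal(nrow(split_sentences(one)), 1L)
  semi <- annotate_report("Ao VTI 36 cm; AVA (VTI) 1.8 cm^2", "r3", lex)
  expect_equal(nrow(split_sentences(semi)), 2L)
  # every token lies in exactly one sentence
  s <- split_sentences(lexd)
  tok_sent <- lexd$tokens$sentence
  expect_equal(sort(unique(tok_sent)), s$sentence)
  for (i in seq_len(nrow(s))) {
    expect_equal(sum(tok_sent == s$sentence[i]),
                 s$last_tok[i] - s$first_tok[i] + 1L)
  }
})

test_that("gazetteer resolves aliases, context and exclusions", {
  d <- annotate_report("Ao VTI 36 cm", "r", lex)
  expect_equal(d$lookups$canonical_name, "AV VTI")
  # excluded valve-area term blocks the embedded VTI
  d2 <- annotate_report("AVA (VTI) 1.8 cm^2", "r", lex)
  expect_false("AV VTI" %in%
                 d2$lookups$canonical_name[!d2$lookups$excluded])
  # no lexicon terms at all
  d3 <- annotate_report("Study of adequate quality throughout.", "r", lex)
  expect_equal(sum(!d3$lookups$excluded), 0L)
  # section heading gives bare aliases their valve context
  d4 <- annotate_report("Aortic Valve: VTI: 62.3 cm.", "r", lex)
  lk <- d4$lookups[!d4$lookups$excluded, ]
  expect_equal(lk$canonical_name, "AV VTI")
  expect_equal(lk$context_used, "aortic_valve")
  # nearest anchoring lookup wins over the section for bare aliases
  d5 <- annotate_report("AV Vmax 4 m/s VTI 87.9 cm LVOT 2.7 cm VTI 16.2 cm",
                        "r", lex)
  lk5 <- d5$lookups[!d5$lookups$excluded, ]
  expect_equal(lk5$canonical_name,
               c("AV Vmax", "AV VTI", "LVOT Diam", "LVOT VTI"))
  # lower-case "as" must not fire the case-sensitive AS alias
  d6 <- annotate_report("Imaging as expected.", "r", lex)
  expect_equal(sum(!d6$lookups$excluded), 0L)
})

test_that("annotation is deterministic and spans stay in bounds", {
  txt <- "Aortic Valve (TAVI): No aortic stenosis. Trivial-mild paravalvular aortic regurgitation."
  a <- annotate_report(txt, "r", lex)
  b <- annotate_report(txt, "r", lex)
  expect_identical(a$tokens, b$tokens)
  expect_identical(a$lookups, b$lookups)
  expect_true(all(a$lookups$start >= 0 & a$lookups$end <= nchar(txt)))
})
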