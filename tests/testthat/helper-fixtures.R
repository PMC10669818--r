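# Shared helpers: a cached lexicon/rule set, paired-series constructor,
# and comparison of extraction output against an expected record table.

lex <- echo_lexicon()
rules <- load_rules(lexicon = lex)

paired <- function(reference, system, outcome = "AV VTI") {
  structure(list(outcome = outcome, report_id = seq_along(reference),
                 reference = reference, system = system),
            class = "paired_series")
}

zero_noise <- list(miss = 0, unit_jitter = 0, range = 0, negation = 0,
                   malformed = 0, prosthesis = 0)

# Compare extracted records to an expected table on the identifying
# columns, ignoring row order.
expect_extraction <- function(records, expected,
                              cols = c("outcome", "value", "unit",
                                       "ordinal_label", "negated",
                                       "prosthetic")) {
  got <- records[order(records$outcome), cols, drop = FALSE]
  want <- expected[order(expected$outcome), cols, drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want, ignore_attr = TRUE)
}

variation_fixtures <- function() {
  reports <- read_reports(system.file("extdata/fixtures/variation_reports.csv",
                                      package = "echoparse"))
  truth <- utils::read.csv(
    system.file("extdata/fixtures/variation_truth.csv", package = "echoparse"),
    stringsAsFactors = FALSE)
  truth$unit[is.na(truth$unit)] <- ""
  truth$ordinal_label[is.na(truth$ordinal_label)] <- ""
  list(reports = reports, truth = truth)
}
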