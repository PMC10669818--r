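# Long/wide serialisation of extraction records. Absence is always an
# empty cell, never zero, preserving the distinction between "extracted
# as 0" and "not extracted" that the evaluation layer depends on.

LONG_COLUMNS <- c("report_id", "outcome", "value", "unit", "ordinal_label",
                  "negated", "context", "provenance", "rule_name")

validate_records <- function(records) {
  need <- c("report_id", "outcome", "value")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  }
  key <- paste(records$report_id, records$outcome, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (report_id, outcome) pair: ", gsub("\r", " / ", d))
  }
  invisible(records)
}

#' Long-format extraction table
#'
#' One row per (report, outcome) with a stable column order. Duplicate
#' (report, outcome) pairs are an integrity error.
#'
#' @param records Extraction records from [extract_report()] /
#'   [extract_corpus()] or compatible.
#' @return Data frame with columns `report_id`, `outcome`, `value`,
#'   `unit`, `ordinal_label`, `negated`, `context`, `provenance`,
#'   `rule_name`.
#' @export
to_long <- function(records) {
  validate_records(records)
  for (col in LONG_COLUMNS) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col == "negated") logical(nrow(records)) else
        character(nrow(records))
    }
  }
  out <- records[, LONG_COLUMNS, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wide-format extraction table
#'
#' One row per report, one column per canonical outcome in the lexicon.
#' Cells hold the numeric value (continuous) or ordinal code (discrete);
#' outcomes not extracted for a report are `NA` (serialised as empty),
#' never zero.
#'
#' @param records Extraction records.
#' @param lexicon An `echo_lexicon` fixing the column set and order.
#' @return Data frame with `report_id` plus one column per outcome.
#' @export
to_wide <- function(records, lexicon = echo_lexicon()) {
  validate_records(records)
  ids <- unique(records$report_id)
  out <- data.frame(report_id = ids, stringsAsFactors = FALSE)
  for (oc in lexicon$canonical_name) {
    col <- rep(NA_real_, length(ids))
    rows <- records$outcome == oc
    col[match(records$report_id[rows], ids)] <- records$value[rows]
    out[[oc]] <- col
  }
  out
}

#' Rebuild long records from a wide table
#'
#' Inverse of [to_wide()] up to the fields a wide cell can carry: value,
#' canonical unit and ordinal code/label are restored exactly (unit and
#' label come from the lexicon); provenance fields are empty.
#'
#' @param wide Output of [to_wide()].
#' @param lexicon The same `echo_lexicon`.
#' @return Long-format data frame as from [to_long()].
#' @export
from_wide <- function(wide, lexicon = echo_lexicon()) {
  scales <- attr(lexicon, "scales")
  rows <- list()
  outcomes <- intersect(names(wide), lexicon$canonical_name)
  for (oc in outcomes) {
    def <- lexicon[lexicon$canonical_name == oc, ]
    vals <- wide[[oc]]
    keep <- !is.na(vals)
    if (!any(keep)) next
    lab <- ""
    if (def$data_type == "discrete") {
      sc <- scales[[def$severity_scale]]
      lab <- sc$levels$label[vals[keep] + 1L]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      report_id = wide$report_id[keep], outcome = oc, value = vals[keep],
      unit = def$canonical_unit, ordinal_label = lab,
      negated = FALSE, context = "", provenance = "", rule_name = "",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(to_long(data.frame(report_id = character(), outcome = character(),
                              value = numeric(), stringsAsFactors = FALSE)))
  }
  long <- do.call(rbind, rows)
  long <- long[order(match(long$report_id, wide$report_id),
                     match(long$outcome, lexicon$canonical_name)), ]
  rownames(long) <- NULL
  long
}

#' Write / read the long CSV interchange format
#'
#' UTF-8, comma-delimited, quoted text fields, "." decimal; missing
#' values are empty fields.
#'
#' @param records Long-format records (or anything [to_long()] accepts).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(records, path) {
  long <- to_long(records)
  utils::write.csv(long, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_long_csv
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(report_id = "character"))
  df$value <- as.numeric(df$value)
  if ("negated" %in% names(df)) df$negated <- as.logical(df$negated)
  for (col in setdiff(LONG_COLUMNS, names(df))) {
    df[[col]] <- if (col == "negated") logical(nrow(df)) else
      character(nrow(df))
  }
  df[is.na(df$unit) | is.null(df$unit), "unit"] <- ""
  df$unit[is.na(df$unit)] <- ""
  df$ordinal_label[is.na(df$ordinal_label)] <- ""
  df
}
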