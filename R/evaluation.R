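# Dual-track validation: agreement metrics (R-squared, ICC with
# reliability bands) for continuous outcomes; confusion tallies,
# precision/recall/F1 and pooled accuracy for discrete outcomes.

#' Align system and reference values for one continuous outcome
#'
#' @param system,reference Long-format record data frames sharing
#'   `report_id`, `outcome`, `value`.
#' @param outcome Canonical outcome name.
#' @param report_ids Report universe; defaults to the union of ids seen
#'   in either table.
#' @return A `paired_series`: list with `outcome`, `report_id`,
#'   `reference` and `system` vectors aligned by report (NA = missing).
#' @export
pair_series <- function(system, reference, outcome, report_ids = NULL) {
  ids <- report_ids %||% union(reference$report_id, system$report_id)
  pick <- function(df) {
    rows <- df[df$outcome == outcome, ]
    rows$value[match(ids, rows$report_id)]
  }
  structure(list(outcome = outcome, report_id = ids,
                 reference = pick(reference), system = pick(system)),
            class = "paired_series")
}

complete_pairs <- function(series) {
  ok <- !is.na(series$reference) & !is.na(series$system)
  cbind(reference = series$reference[ok], system = series$system[ok])
}

#' Coefficient of determination between raters
#'
#' Squared Pearson correlation over complete pairs. High R-squared with
#' low ICC indicates a systematic scale difference (e.g. one rater
#' recording in different units): the correlation is blind to scale,
#' absolute-agreement ICC is not.
#'
#' @param series A `paired_series`.
#' @return R-squared in `[0, 1]`, or `NA` (undefined signal) with fewer
#'   than 2 complete pairs or zero variance on either side.
#' @export
r_squared <- function(series) {
  m <- complete_pairs(series)
  if (nrow(m) < 2L) return(NA_real_)
  if (stats::var(m[, 1]) == 0 || stats::var(m[, 2]) == 0) return(NA_real_)
  stats::cor(m[, 1], m[, 2])^2
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measure: the
#' standard form for comparing two raters (here: system vs clinician)
#' on the same subjects. Computed from the two-way ANOVA mean squares
#' MSR (subjects), MSC (raters) and MSE:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' The p-value is the one-sided F test of MSR/MSE. Reliability bands:
#' poor < 0.5, moderate 0.5-0.75, good 0.75-0.9, excellent > 0.9.
#'
#' @param series A `paired_series` with at least 2 complete pairs.
#' @return List with `icc`, `p`, `band`, `n` (complete pairs) and the
#'   mean squares. If all values are identical across both raters the
#'   ICC is 1 by convention and `p` is `NA`.
#' @export
icc <- function(series) {
  m <- complete_pairs(series)
  n <- nrow(m)
  if (n < 2L) stop("ICC needs at least 2 complete pairs")
  k <- 2L
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst == 0) {
    return(list(icc = 1, p = NA_real_, band = icc_band(1), n = n,
                msr = 0, msc = 0, mse = 0))
  }
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  p <- if (mse == 0) NA_real_ else
    stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = val, p = p, band = icc_band(val), n = n,
       msr = msr, msc = msc, mse = mse)
}

#' @rdname icc
#' @param value An ICC value.
#' @export
icc_band <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value < 0.5) "poor"
  else if (value < 0.75) "moderate"
  else if (value <= 0.9) "good"
  else "excellent"
}

#' Per-outcome confusion tally for a discrete outcome
#'
#' For each report: TP if both sides extracted the outcome with equal
#' category codes; FP if the system asserted it where the reference did
#' not, or asserted the wrong category; FN if the reference has it and
#' the system missed it; TN if both sides are silent. Each (report,
#' outcome) instance contributes to exactly one cell, so the cells sum
#' to the number of evaluated instances.
#'
#' @param system,reference Long-format record data frames.
#' @param outcome Canonical outcome name (must appear in at least one
#'   lexicon-backed record set; unknown outcomes are an error when a
#'   lexicon is supplied).
#' @param report_ids Report universe (needed for TN counts); defaults to
#'   the union of ids in either table.
#' @param lexicon Optional `echo_lexicon` used to validate `outcome`.
#' @return A `discrete_tally`: list with `outcome`, `TP`, `FN`, `FP`,
#'   `TN`.
#' @export
tally_discrete <- function(system, reference, outcome, report_ids = NULL,
                           lexicon = NULL) {
  if (!is.null(lexicon) && !outcome %in% lexicon$canonical_name) {
    stop("unknown outcome: ", outcome)
  }
  ids <- report_ids %||% union(reference$report_id, system$report_id)
  s <- system[system$outcome == outcome, ]
  r <- reference[reference$outcome == outcome, ]
  sv <- s$value[match(ids, s$report_id)]
  rv <- r$value[match(ids, r$report_id)]
  tp <- sum(!is.na(sv) & !is.na(rv) & sv == rv)
  fp <- sum(!is.na(sv) & (is.na(rv) | sv != rv))
  fn <- sum(is.na(sv) & !is.na(rv))
  tn <- sum(is.na(sv) & is.na(rv))
  structure(list(outcome = outcome, TP = tp, FN = fn, FP = fp, TN = tn),
            class = "discrete_tally")
}

#' @rdname tally_discrete
#' @param TP,FN,FP,TN Cell counts.
#' @export
discrete_tally <- function(outcome, TP, FN, FP, TN) {
  stopifnot(TP >= 0, FN >= 0, FP >= 0, TN >= 0)
  structure(list(outcome = outcome, TP = as.integer(TP), FN = as.integer(FN),
                 FP = as.integer(FP), TN = as.integer(TN)),
            class = "discrete_tally")
}

#' @export
print.discrete_tally <- function(x, ...) {
  cat(sprintf("<discrete_tally> %s: TP=%d FN=%d FP=%d TN=%d\n",
              x$outcome, x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Precision, recall and F1 from a confusion tally
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R). Computed at full
#' precision; round to 2 decimals for reporting. A metric whose
#' denominator is zero is `NA` (the undefined signal), never 0 - this is
#' why rare outcomes are aggregated before metric computation.
#'
#' @param tally A `discrete_tally`.
#' @return Named list `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tally) {
  p <- if (tally$TP + tally$FP > 0) tally$TP / (tally$TP + tally$FP) else NA_real_
  r <- if (tally$TP + tally$FN > 0) tally$TP / (tally$TP + tally$FN) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  list(precision = p, recall = r, f1 = f1)
}

#' Aggregate rare-outcome tallies
#'
#' Cell-wise sum; the label is the " + " concatenation of the parts.
#' Used to avoid undefined precision/recall on outcomes with very few
#' positive instances.
#'
#' @param tallies List of `discrete_tally` objects (at least one).
#' @param label Optional label for the merged tally.
#' @return A `discrete_tally`.
#' @export
aggregate_rare <- function(tallies, label = NULL) {
  stopifnot(length(tallies) >= 1L)
  lab <- label %||% paste(vapply(tallies, function(t) t$outcome, ""),
                          collapse = " + ")
  discrete_tally(lab,
                 sum(vapply(tallies, function(t) t$TP, 1)),
                 sum(vapply(tallies, function(t) t$FN, 1)),
                 sum(vapply(tallies, function(t) t$FP, 1)),
                 sum(vapply(tallies, function(t) t$TN, 1)))
}

#' Pooled accuracy over discrete tallies
#'
#' @param tallies List of `discrete_tally` objects.
#' @return List with `total` instances, `accuracy` (percent of TP+TN),
#'   `fn_pct` and `fp_pct` (error components as percent of total). All
#'   at full precision; `NA` signal when no instances were evaluated.
#' @export
pooled_accuracy <- function(tallies) {
  agg <- aggregate_rare(tallies, label = "pooled")
  total <- agg$TP + agg$FN + agg$FP + agg$TN
  if (total == 0) {
    return(list(total = 0L, accuracy = NA_real_, fn_pct = NA_real_,
                fp_pct = NA_real_))
  }
  list(total = total,
       accuracy = 100 * (agg$TP + agg$TN) / total,
       fn_pct = 100 * agg$FN / total,
       fp_pct = 100 * agg$FP / total)
}

#' Magnitude-calibration (bubble plot) data
#'
#' For each continuous outcome: x = summed magnitude of reference
#' values, y = summed magnitude of system values, size = how often the
#' system extracted it. Well-calibrated extraction puts every point on
#' the x = y diagonal; systematic under-extraction falls below it.
#'
#' @param system,reference Long-format record data frames.
#' @param lexicon An `echo_lexicon` (fixes the outcome set).
#' @return Data frame with `outcome`, `reference_magnitude`,
#'   `system_magnitude`, `frequency`.
#' @export
bubble_data <- function(system, reference, lexicon = echo_lexicon()) {
  outs <- lexicon$canonical_name[lexicon$data_type == "continuous"]
  do.call(rbind, lapply(outs, function(oc) {
    s <- system[system$outcome == oc, ]
    r <- reference[reference$outcome == oc, ]
    data.frame(outcome = oc,
               reference_magnitude = sum(abs(r$value), na.rm = TRUE),
               system_magnitude = sum(abs(s$value), na.rm = TRUE),
               frequency = nrow(s), stringsAsFactors = FALSE)
  }))
}

#' Record-level precision and recall against ground truth
#'
#' Compares extracted records to a ground-truth record set: a true
#' positive is a (report, outcome) pair present on both sides with
#' matching value (within `tol` for continuous values; exact for
#' ordinal codes). Truth records flagged `uncertain` (e.g. malformed
#' split decimals) are excluded from both sides.
#'
#' @param system Extracted records.
#' @param truth Ground-truth records (e.g. from [generate_corpus()]).
#' @param tol Numeric tolerance for continuous value equality.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
compare_records <- function(system, truth, tol = 1e-6) {
  if ("uncertain" %in% names(truth) && any(truth$uncertain)) {
    bad <- paste(truth$report_id[truth$uncertain],
                 truth$outcome[truth$uncertain], sep = "\r")
    truth <- truth[!truth$uncertain, ]
    system <- system[!paste(system$report_id, system$outcome, sep = "\r")
                     %in% bad, ]
  }
  skey <- paste(system$report_id, system$outcome, sep = "\r")
  tkey <- paste(truth$report_id, truth$outcome, sep = "\r")
  hit <- match(skey, tkey)
  value_ok <- !is.na(hit) &
    abs(system$value - truth$value[hit]) <= tol
  tp <- sum(value_ok, na.rm = TRUE)
  fp <- nrow(system) - tp
  fn <- nrow(truth) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (nrow(system) > 0) tp / nrow(system) else NA_real_,
       recall = if (nrow(truth) > 0) tp / nrow(truth) else NA_real_)
}

#' Corrupt extraction records with misses and category confusions
#'
#' Testing utility for the evaluation layer: deletes each record with
#' probability `miss_rate` and, independently, replaces the category
#' code of each surviving discrete record with a different random code
#' of its scale with probability `confusion_rate`. With a reference
#' equal to the uncorrupted records, measured recall estimates
#' `1 - miss_rate` and precision falls with `confusion_rate`.
#'
#' @param records Record data frame.
#' @param miss_rate,confusion_rate Probabilities in `[0, 1]`.
#' @param lexicon An `echo_lexicon` (scales for confusion draws).
#' @param seed Integer seed.
#' @return Corrupted copy of `records`.
#' @export
corrupt_records <- function(records, miss_rate = 0, confusion_rate = 0,
                            lexicon = echo_lexicon(), seed = 1L) {
  stopifnot(miss_rate >= 0, miss_rate <= 1,
            confusion_rate >= 0, confusion_rate <= 1)
  withr::with_seed(seed, {
    keep <- stats::runif(nrow(records)) >= miss_rate
    out <- records[keep, , drop = FALSE]
    if (confusion_rate > 0 && nrow(out)) {
      disc <- lexicon$data_type[match(out$outcome, lexicon$canonical_name)] ==
        "discrete"
      flip <- disc & stats::runif(nrow(out)) < confusion_rate
      scales <- attr(lexicon, "scales")
      for (i in which(flip)) {
        sc <- scales[[lexicon$severity_scale[
          match(out$outcome[i], lexicon$canonical_name)]]]
        other <- setdiff(sc$levels$code, out$value[i])
        out$value[i] <- sample(other, 1L)
        out$ordinal_label[i] <- sc$levels$label[out$value[i] + 1L]
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Full dual-track evaluation of system vs reference extractions
#'
#' @param system,reference Long-format record data frames sharing report
#'   ids (an error if the id sets are disjoint).
#' @param lexicon An `echo_lexicon`.
#' @param report_ids Report universe; defaults to the union of ids.
#' @param aggregate Named list mapping an aggregate label to the
#'   outcomes merged under it before metric computation (rare-outcome
#'   aggregation). Default merges the four valve stenosis grades.
#' @return List with `continuous` (per-outcome n, R-squared, ICC, p,
#'   band), `discrete` (per-tally counts and P/R/F1) and `pooled`
#'   (total, accuracy, error split).
#' @export
evaluate_extractions <- function(system, reference, lexicon = echo_lexicon(),
                                 report_ids = NULL,
                                 aggregate = list(
                                   "AV + MV + PV + TV Stenosis" =
                                     c("AV Stenosis", "MV Stenosis",
                                       "PV Stenosis", "TV Stenosis"))) {
  if (!length(intersect(system$report_id, reference$report_id))) {
    stop("system and reference share no report ids")
  }
  ids <- report_ids %||% union(reference$report_id, system$report_id)

  cont <- lexicon$canonical_name[lexicon$data_type == "continuous"]
  cont_rows <- lapply(cont, function(oc) {
    ps <- pair_series(system, reference, oc, ids)
    m <- complete_pairs(ps)
    if (nrow(m) < 2L) {
      return(data.frame(outcome = oc, n = nrow(m), r_squared = NA_real_,
                        icc = NA_real_, icc_p = NA_real_,
                        band = NA_character_, stringsAsFactors = FALSE))
    }
    ic <- icc(ps)
    data.frame(outcome = oc, n = nrow(m), r_squared = r_squared(ps),
               icc = ic$icc, icc_p = ic$p, band = ic$band,
               stringsAsFactors = FALSE)
  })
  continuous <- do.call(rbind, cont_rows)

  disc <- lexicon$canonical_name[lexicon$data_type == "discrete"]
  merged <- unlist(aggregate, use.names = FALSE)
  singles <- setdiff(disc, merged)
  tallies <- lapply(singles, function(oc)
    tally_discrete(system, reference, oc, ids, lexicon))
  for (lab in names(aggregate)) {
    parts <- lapply(aggregate[[lab]], function(oc)
      tally_discrete(system, reference, oc, ids, lexicon))
    tallies[[length(tallies) + 1L]] <- aggregate_rare(parts, label = lab)
  }
  discrete <- do.call(rbind, lapply(tallies, function(t) {
    m <- precision_recall_f1(t)
    data.frame(outcome = t$outcome, TP = t$TP, FN = t$FN, FP = t$FP,
               TN = t$TN, precision = m$precision, recall = m$recall,
               f1 = m$f1, stringsAsFactors = FALSE)
  }))

  list(continuous = continuous, discrete = discrete,
       pooled = pooled_accuracy(tallies))
}
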