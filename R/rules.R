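# Rule cascade: priority-ordered LHS pattern / RHS action rules that turn
# gazetteer lookups into normalised outcome annotations.

#' Load an extraction rule file
#'
#' Rules are declarative data (see the bundled `rules.yaml` for the
#' documented pattern mini-language): a linear LHS pattern of elements
#' anchored on one gazetteer lookup, and an ordered RHS action list.
#' Priorities resolve overlapping candidate annotations.
#'
#' @param path Rule YAML file; defaults to the bundled cascade.
#' @param lexicon Optional `echo_lexicon`; when given, any rule that
#'   restricts itself to a named outcome is validated against it at load
#'   time (unknown names are a configuration error, caught here rather
#'   than at match time).
#' @return List of rules of class `echo_rules`.
#' @export
load_rules <- function(path = NULL, lexicon = NULL) {
  path <- path %||% pkg_file("rules.yaml")
  raw <- yaml::read_yaml(path)$rules
  if (is.null(raw)) stop("rule file has no 'rules' entry: ", path)
  prios <- vapply(raw, function(r) as.integer(r$priority), integer(1))
  if (anyDuplicated(prios)) stop("rule priorities must be unique")
  for (r in raw) {
    if (is.null(r$name) || is.null(r$lhs) || is.null(r$rhs)) {
      stop("rule missing name/lhs/rhs")
    }
    kinds <- vapply(r$lhs, function(e) e$elem, "")
    if (sum(kinds == "lookup") != 1L) {
      stop("rule '", r$name, "': LHS must contain exactly one lookup element")
    }
    binds <- unlist(lapply(r$lhs, function(e) e$bind))
    need <- c(bind_value = "v1", bind_range = "v1", map_severity = "label")
    for (act in unlist(r$rhs)) {
      if (act %in% names(need) && !need[[act]] %in% binds) {
        stop("rule '", r$name, "': RHS action ", act,
             " references binding '", need[[act]], "' not declared in LHS")
      }
    }
    if (identical(unlist(r$rhs)[1], "bind_range") &&
        !all(c("v1", "v2") %in% binds)) {
      stop("rule '", r$name, "': bind_range needs v1 and v2")
    }
    if (!is.null(r[["outcome"]]) && !is.null(lexicon) &&
        !r[["outcome"]] %in% lexicon$canonical_name) {
      stop("rule '", r$name, "' references unknown outcome: ", r$outcome)
    }
  }
  structure(raw, class = "echo_rules")
}

#' @export
print.echo_rules <- function(x, ...) {
  cat("<echo_rules> ", length(x), " rules, priorities ",
      paste(vapply(x, function(r) r$priority, 1L), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

severity_words <- function(lexicon) {
  scales <- attr(lexicon, "scales")
  labs <- unlist(lapply(scales, function(s) names(s$label_map)))
  unique(unlist(strsplit(labs, "-", fixed = TRUE)))
}

# --- LHS matching ----------------------------------------------------------

# Match a sequence of elements forwards (dir = 1) or backwards (dir = -1)
# from `pos`, staying inside [lo, hi] token indices and never letting
# filler/qualifier skips cross a clause boundary. Elements arrive in
# scan order (callers reverse the pre-lookup part). Returns NULL or
# list(bind = <named list>, used = <token indices>).
match_elems <- function(elems, tokens, pos, lo, hi, dir, sev_words) {
  if (!length(elems)) return(list(bind = list(), used = integer()))
  e <- elems[[1]]
  rest <- elems[-1]
  in_range <- function(p) p >= lo && p <= hi
  tok_at <- function(p) tokens$lower[p]
  is_clause_end <- function(p) tokens$text[p] %in% CLAUSE_BOUNDARIES

  try_consume <- function(k, bind1, used1) {
    res <- match_elems(rest, tokens, pos + dir * k, lo, hi, dir, sev_words)
    if (is.null(res)) return(NULL)
    list(bind = c(bind1, res$bind), used = c(used1, res$used))
  }

  kind <- e$elem
  if (kind %in% c("filler", "qualifier")) {
    maxk <- e$max %||% 3L
    ok_tok <- function(p) {
      if (!in_range(p) || is_clause_end(p)) return(FALSE)
      if (kind == "filler") tok_at(p) %in% FILLER_TOKENS
      else tokens$class[p] == "word"
    }
    for (k in 0:maxk) {
      if (k > 0L && !ok_tok(pos + dir * (k - 1L))) return(NULL)
      used <- if (k > 0L) pos + dir * (0:(k - 1L)) else integer()
      bind1 <- if (!is.null(e$bind) && k > 0L) {
        stats::setNames(list(paste(tokens$text[sort(used)], collapse = " ")),
                        e$bind)
      } else list()
      res <- try_consume(k, bind1, used)
      if (!is.null(res)) return(res)
    }
    return(NULL)
  }

  if (kind == "severity") {
    # combined label (word dash word) preferred over single word
    widths <- c(3L, 1L)
    for (w in widths) {
      p2 <- pos + dir * (w - 1L)
      if (!in_range(pos) || !in_range(p2)) next
      idx <- sort(c(pos, p2))
      span <- idx[1]:idx[2]
      if (w == 3L) {
        mid <- span[2]
        if (!(tok_at(span[1]) %in% sev_words && tokens$text[mid] %in% DASHES &&
              tok_at(span[3]) %in% sev_words)) next
        label <- paste0(tok_at(span[1]), "-", tok_at(span[3]))
      } else {
        if (!(tokens$class[pos] == "word" && tok_at(pos) %in% sev_words)) next
        label <- tok_at(pos)
      }
      bind1 <- stats::setNames(list(label), e$bind %||% "label")
      res <- try_consume(w, bind1, span)
      if (!is.null(res)) return(res)
    }
    return(NULL)
  }

  # single-token elements
  if (!in_range(pos)) {
    if (isTRUE(e$optional)) return(try_consume(0L, list(), integer()))
    return(NULL)
  }
  matched <- switch(kind,
    number = tokens$class[pos] == "number",
    unit = tokens$class[pos] == "unit",
    range_sep = tok_at(pos) %in% RANGE_SEPS,
    negation = tokens$class[pos] == "word" && tok_at(pos) %in% NEGATION_WORDS,
    stop("unknown LHS element: ", kind))
  if (matched) {
    val <- if (kind == "number") as.numeric(tokens$text[pos]) else
      if (kind == "unit") normalise_unit(tokens$text[pos]) else tokens$text[pos]
    bind1 <- if (!is.null(e$bind)) stats::setNames(list(val), e$bind) else list()
    res <- try_consume(1L, bind1, pos)
    if (!is.null(res)) return(res)
  }
  if (isTRUE(e$optional)) return(try_consume(0L, list(), integer()))
  NULL
}

# --- RHS actions -----------------------------------------------------------

run_rhs <- function(actions, bind, lookup, def, lexicon, tokens) {
  scales <- attr(lexicon, "scales")
  units <- attr(lexicon, "units")
  cand <- list(value = NA_real_, value_low = NA_real_, value_high = NA_real_,
               unit = "", ordinal_label = "", negated = FALSE, note = "")
  add_note <- function(x) {
    cand$note <<- if (nzchar(cand$note)) paste(cand$note, x, sep = ";") else x
  }
  for (act in actions) {
    if (act == "bind_value") {
      cand$value <- bind$v1
    } else if (act == "bind_range") {
      cand$value_low <- bind$v1
      cand$value_high <- bind$v2
      cand$value <- (bind$v1 + bind$v2) / 2
    } else if (act == "bind_unit") {
      canon <- def$canonical_unit
      u <- bind$unit
      if (is.null(u)) {
        cand$unit <- canon
        if (canon != "dimensionless") add_note("unit_assumed")
      } else if (identical(u, canon)) {
        cand$unit <- canon
      } else {
        f <- unit_factor(u, canon, units)
        if (is.na(f)) {
          cand$unit <- u
          add_note(paste0("unit_unconverted:", u))
        } else {
          cand$unit <- canon
          cand$value <- cand$value * f
          if (!is.na(cand$value_low)) cand$value_low <- cand$value_low * f
          if (!is.na(cand$value_high)) cand$value_high <- cand$value_high * f
          add_note(paste0("unit_converted:", u, "->", canon))
        }
      }
    } else if (act == "map_severity") {
      scale <- scales[[def$severity_scale]]
      code <- severity_to_ordinal(bind$label, scale)
      if (is.na(code)) return(NULL)  # no-match signal: drop candidate
      cand$value <- as.numeric(code)
      cand$ordinal_label <- scale$levels$label[code + 1L]
    } else if (act == "negate") {
      scale <- scales[[def$severity_scale]]
      if (!scale$allows_negation_zero) return(NULL)
      cand$value <- 0
      cand$ordinal_label <- scale$levels$label[1L]
      cand$negated <- TRUE
      if (!is.null(bind$qualifier)) {
        add_note(paste0("negation_qualifier:", bind$qualifier))
      }
    } else if (act == "annotate") {
      # terminal; emission handled by caller
    } else {
      stop("unknown RHS action: ", act)
    }
  }
  cand
}

empty_candidates <- function() {
  data.frame(outcome = character(), value = numeric(),
             value_low = numeric(), value_high = numeric(), unit = character(),
             ordinal_label = character(), negated = logical(),
             context = character(), prosthetic = logical(),
             rule_name = character(), priority = integer(),
             tok_first = integer(), tok_last = integer(),
             start = integer(), end = integer(), provenance = character(),
             note = character(), retained = logical(),
             stringsAsFactors = FALSE)
}

#' Apply the rule cascade to an annotated document
#'
#' Attempts every rule around every gazetteer lookup of the matching
#' data type. Each successful match is normalised on the spot: units are
#' converted to the outcome's canonical unit, range bounds are averaged
#' into `value`, and severity labels are mapped to ordinal codes.
#' Overlap resolution is left to [resolve_overlaps()].
#'
#' @param doc An `echo_document`.
#' @param rules An `echo_rules` object.
#' @param lexicon The `echo_lexicon` the document was annotated with.
#' @return Data frame of candidate outcome annotations (one row per
#'   rule match), with value bounds, unit, ordinal label, negation flag,
#'   section context, prosthetic flag, rule name, priority, token and
#'   character spans, provenance text and notes.
#' @export
apply_rules <- function(doc, rules = load_rules(), lexicon = echo_lexicon()) {
  lookups <- doc$lookups
  tokens <- doc$tokens
  sev_words <- severity_words(lexicon)
  sent_lo <- doc$sentences$first_tok[match(tokens$sentence,
                                           doc$sentences$sentence)]
  sent_hi <- doc$sentences$last_tok[match(tokens$sentence,
                                          doc$sentences$sentence)]
  lex_row <- match(lookups$canonical_name, lexicon$canonical_name)
  cands <- list()
  for (r in rules) {
    kinds <- vapply(r$lhs, function(e) e$elem, "")
    li <- which(kinds == "lookup")
    pre <- rev(r$lhs[seq_len(li - 1L)])
    post <- if (li < length(r$lhs)) r$lhs[(li + 1L):length(r$lhs)] else list()
    ok <- !lookups$excluded & lookups$data_type == r$outcome_type
    if (!is.null(r[["outcome"]])) {
      ok <- ok & lookups$canonical_name == r[["outcome"]]
    }
    for (k in which(ok)) {
      k_first <- lookups$first_tok[k]
      k_last <- lookups$last_tok[k]
      lo <- sent_lo[k_first]; hi <- sent_hi[k_first]
      mpre <- match_elems(pre, tokens, k_first - 1L, lo, hi, -1L, sev_words)
      if (is.null(mpre)) next
      mpost <- match_elems(post, tokens, k_last + 1L, lo, hi, 1L, sev_words)
      if (is.null(mpost)) next
      bind <- c(mpre$bind, mpost$bind)
      def <- lexicon[lex_row[k], ]
      cand <- run_rhs(unlist(r$rhs), bind, lookups[k, ], def, lexicon, tokens)
      if (is.null(cand)) next
      used <- c(mpre$used, k_first:k_last, mpost$used)
      tf <- min(used); tl <- max(used)
      # unmerged split decimal: a bare number directly after the matched
      # value with no unit or connector in between
      if (r$outcome_type == "continuous" && tl < nrow(tokens) &&
          tokens$class[tl + 1L] == "number" &&
          tokens$sentence[tl + 1L] == tokens$sentence[k_first]) {
        cand$note <- paste0(cand$note,
                            if (nzchar(cand$note)) ";" else "",
                            "suspected_malformed_decimal")
      }
      cands[[length(cands) + 1L]] <- list(
        outcome = lookups$canonical_name[k], value = cand$value,
        value_low = cand$value_low, value_high = cand$value_high,
        unit = cand$unit, ordinal_label = cand$ordinal_label,
        negated = cand$negated,
        context = tokens$region[k_first],
        prosthetic = tokens$prosthetic[k_first] ||
          grepl("paravalvular|paraprosthetic|periprosthetic|prosthetic",
                tolower(bind$qualifier %||% "")),
        rule_name = r$name, priority = as.integer(r$priority),
        tok_first = tf, tok_last = tl,
        start = tokens$start[tf], end = tokens$end[tl],
        provenance = substr(doc$text, tokens$start[tf] + 1L, tokens$end[tl]),
        note = cand$note)
    }
  }
  if (!length(cands)) return(empty_candidates())
  col <- function(nm, fun) fun(vapply(cands, function(c) c[[nm]], fun(NA)))
  out <- data.frame(
    outcome = col("outcome", as.character), value = col("value", as.numeric),
    value_low = col("value_low", as.numeric),
    value_high = col("value_high", as.numeric),
    unit = col("unit", as.character),
    ordinal_label = col("ordinal_label", as.character),
    negated = col("negated", as.logical), context = col("context", as.character),
    prosthetic = col("prosthetic", as.logical),
    rule_name = col("rule_name", as.character),
    priority = col("priority", as.integer),
    tok_first = col("tok_first", as.integer),
    tok_last = col("tok_last", as.integer),
    start = col("start", as.integer), end = col("end", as.integer),
    provenance = col("provenance", as.character),
    note = col("note", as.character), stringsAsFactors = FALSE)
  out$retained <- NA
  out
}

#' Resolve overlapping candidate annotations
#'
#' Within each outcome, candidates are ranked by (priority descending,
#' span length descending, start ascending) and overlapping
#' lower-ranked matches are suppressed. Of the surviving non-overlapping
#' mentions, exactly one is retained per outcome: the first in document
#' order, with native-valve readings preferred over prosthetic-context
#' ones. Suppressed and secondary mentions stay in the output with
#' `retained = FALSE` (visible to the trace), and a multiplicity
#' conflict is noted on the retained row. Idempotent.
#'
#' @param cands Candidate data frame from [apply_rules()].
#' @return The same frame with `retained` filled in, ordered by outcome
#'   and position.
#' @export
resolve_overlaps <- function(cands) {
  if (nrow(cands) == 0L) return(cands)
  cands$note <- sub(";?conflict_multiple_mentions", "", cands$note)
  out <- lapply(split(cands, cands$outcome), function(g) {
    g <- g[order(-g$priority, -(g$tok_last - g$tok_first), g$tok_first), ]
    keep <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      overlaps <- keep & pmax(g$tok_first[i], g$tok_first) <=
        pmin(g$tok_last[i], g$tok_last)
      keep[i] <- !any(overlaps)
    }
    g <- g[keep, , drop = FALSE]
    pick <- order(g$prosthetic, g$tok_first)[1]
    g$retained <- seq_len(nrow(g)) == pick
    if (nrow(g) > 1L) {
      g$note[pick] <- paste0(g$note[pick],
                             if (nzchar(g$note[pick])) ";" else "",
                             "conflict_multiple_mentions")
    }
    g[order(g$tok_first), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group records by parent ontology level
#'
#' @param records Extraction records or resolved annotations with an
#'   `outcome` column.
#' @param lexicon An `echo_lexicon` supplying `parent_level` per outcome.
#' @return Named list of data frames keyed by parent level; the total
#'   row count is conserved.
#' @export
group_to_parent <- function(records, lexicon = echo_lexicon()) {
  if (nrow(records) == 0L) return(stats::setNames(list(), character()))
  parent <- lexicon$parent_level[match(records$outcome, lexicon$canonical_name)]
  if (any(is.na(parent) | !nzchar(parent))) {
    stop("missing parent_level for: ",
         paste(unique(records$outcome[is.na(parent) | !nzchar(parent)]),
               collapse = ", "))
  }
  split(records, parent)
}

#' Extract structured records from one report
#'
#' End-to-end single-report pipeline: annotate, apply the rule cascade,
#' resolve overlaps, and shape the retained annotations into extraction
#' records (one row per report and outcome).
#'
#' @param text Report text.
#' @param report_id Report identifier.
#' @param lexicon An `echo_lexicon`.
#' @param rules An `echo_rules` cascade.
#' @return Data frame of extraction records with columns `report_id`,
#'   `outcome`, `value`, `unit`, `ordinal_label`, `negated`, `context`,
#'   `provenance`, `rule_name`, plus `value_low`, `value_high`,
#'   `prosthetic` and `note`. The full candidate set (for tracing) is
#'   attached as attribute `candidates`.
#' @export
extract_report <- function(text, report_id = "r1", lexicon = echo_lexicon(),
                           rules = load_rules()) {
  doc <- annotate_report(text, report_id, lexicon)
  cands <- resolve_overlaps(apply_rules(doc, rules, lexicon))
  rec <- cands[isTRUE_vec(cands$retained), , drop = FALSE]
  out <- data.frame(report_id = rep(report_id, nrow(rec)),
                    outcome = rec$outcome, value = rec$value,
                    unit = rec$unit, ordinal_label = rec$ordinal_label,
                    negated = rec$negated, context = rec$context,
                    provenance = rec$provenance, rule_name = rec$rule_name,
                    value_low = rec$value_low, value_high = rec$value_high,
                    prosthetic = rec$prosthetic, note = rec$note,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "candidates") <- cands
  attr(out, "document") <- doc
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Extract a corpus of reports
#'
#' Per-report failures are logged and skipped; one malformed report can
#' never abort the batch.
#'
#' @param reports Data frame with `report_id` and `text`.
#' @param lexicon,rules As in [extract_report()].
#' @param verbose Log per-report record counts.
#' @return Combined extraction record data frame. Failed report ids (if
#'   any) are attached as attribute `failed`.
#' @export
extract_corpus <- function(reports, lexicon = echo_lexicon(),
                           rules = load_rules(), verbose = FALSE) {
  out <- vector("list", nrow(reports))
  failed <- character()
  for (i in seq_len(nrow(reports))) {
    rec <- tryCatch(
      extract_report(reports$text[i], reports$report_id[i], lexicon, rules),
      error = function(e) {
        warning("report ", reports$report_id[i], " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(rec)) {
      failed <- c(failed, reports$report_id[i])
    } else {
      attr(rec, "candidates") <- NULL
      attr(rec, "document") <- NULL
      out[[i]] <- rec
      if (verbose) message(reports$report_id[i], ": ", nrow(rec), " records")
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) {
    res <- extract_report("none", "empty", lexicon, rules)[0, ]
    attr(res, "candidates") <- NULL
    attr(res, "document") <- NULL
  }
  rownames(res) <- NULL
  attr(res, "failed") <- failed
  res
}

#' Render a textual extraction trace
#'
#' A plain-text stand-in for an interactive extraction viewer: for each
#' candidate annotation it prints the rule, span offsets, matched text
#' and the normalised result, marking which mention was retained.
#'
#' @param records Output of [extract_report()] (with its `candidates`
#'   attribute).
#' @return Character vector of trace lines, invisibly printable.
#' @export
trace_report <- function(records) {
  cands <- attr(records, "candidates")
  doc <- attr(records, "document")
  if (is.null(cands)) stop("records carry no candidate trace")
  header <- sprintf("report %s: %d candidate(s), %d retained",
                    doc$report_id, nrow(cands), sum(isTRUE_vec(cands$retained)))
  lines <- vapply(seq_len(nrow(cands)), function(i) {
    c <- cands[i, ]
    val <- if (nzchar(c$ordinal_label)) {
      sprintf("%s (code %d)", c$ordinal_label, as.integer(c$value))
    } else sprintf("%g %s", c$value, c$unit)
    sprintf("%s [%d,%d) '%s' -> %s = %s%s%s (rule %s, prio %d)",
            if (isTRUE_vec(c$retained)) "*" else " ",
            c$start, c$end, c$provenance, c$outcome, val,
            if (c$negated) " [negated]" else "",
            if (c$prosthetic) " [prosthetic]" else "",
            c$rule_name, c$priority)
  }, "")
  c(header, lines)
}
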