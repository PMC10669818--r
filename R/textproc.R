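# Text processing: tokens, sentences, section headings, gazetteer lookups.
# Offsets are 0-based, half-open [start, end), used consistently everywhere.

UNIT_SURFACES <- c("cm/m^2", "cm/m2", "l/min", "mmHg", "cm/s", "mm/s",
                   "cm^2", "cm2", "m/s", "bpm", "mL", "mm", "cm", "ms",
                   "m", "s", "L", "%")

# Lower-cased surface -> canonical symbol.
UNIT_CANON <- c("cm/m^2" = "cm/m^2", "cm/m2" = "cm/m^2", "l/min" = "L/min",
                "mmhg" = "mmHg", "cm/s" = "cm/s", "mm/s" = "mm/s",
                "cm^2" = "cm^2", "cm2" = "cm^2", "m/s" = "m/s", "bpm" = "bpm",
                "ml" = "mL", "mm" = "mm", "cm" = "cm", "ms" = "ms",
                "m" = "m", "s" = "s", "l" = "L", "%" = "%")

RANGE_SEPS <- c("-", "‐", "‑", "‒", "–", "—", "to")
DASHES <- setdiff(RANGE_SEPS, "to")
NEGATION_WORDS <- "no"
FILLER_TOKENS <- c(":", "=", "(", ")")
CLAUSE_BOUNDARIES <- c(",", ";", ".")

PROSTHESIS_MARKERS <- c("avr", "mvr", "tvr", "tavi", "tavr", "prosthesis",
                        "prosthetic", "bioprosthesis", "bioprosthetic",
                        "paraprosthetic", "paravalvular", "periprosthetic")

# Region names recognised as section headings ("Aortic Valve:"). The
# outflow tract is deliberately not a heading region: "LVOT:" in running
# text is a measurement label (LVOT diameter), and lvot context is
# established by anchoring lookups instead.
SECTION_REGIONS <- list(
  "aortic valve" = "aortic_valve", "aorta" = "aorta",
  "left ventricle" = "left_ventricle", "right ventricle" = "right_ventricle",
  "left atrium" = "left_atrium", "right atrium" = "right_atrium",
  "mitral valve" = "mitral_valve", "tricuspid valve" = "tricuspid_valve",
  "pulmonary valve" = "pulmonary_valve")

token_regex <- function() {
  esc <- function(x) gsub("([\\^$.|?*+()\\[\\]{}/%-])", "\\\\\\1", x, perl = TRUE)
  units <- UNIT_SURFACES[order(nchar(UNIT_SURFACES), decreasing = TRUE)]
  alpha <- units[grepl("^[A-Za-z]", units)]
  other <- setdiff(units, alpha)
  unit_alt <- paste0(
    "(?<![A-Za-z0-9])(?:", paste(vapply(alpha, esc, ""), collapse = "|"),
    ")(?!['’A-Za-z0-9])")
  if (length(other)) {
    unit_alt <- paste0(unit_alt, "|", paste(vapply(other, esc, ""), collapse = "|"))
  }
  paste0("(?i)(?:", unit_alt, ")",
         "|[0-9]+(?:\\.[0-9]+)?",
         "|[A-Za-z]+['’]?",
         "|\\S")
}

TOKEN_PATTERN <- token_regex()

#' Tokenise report text
#'
#' Splits text into word, number, unit and punctuation tokens. Numbers
#' with internal decimal points are single tokens; unit strings such as
#' `m/s`, `mmHg`, `cm^2` and `cm/m^2` are single tokens of class `unit`.
#' Concatenating the token surfaces with the skipped whitespace
#' reproduces the input exactly. A malformed split decimal such as
#' `38 9` yields two separate number tokens; the rule engine flags the
#' pair downstream rather than merging it.
#'
#' @param text A single non-empty string.
#' @return Data frame with columns `start`, `end` (0-based, half-open
#'   character offsets), `text`, `lower`, and `class`
#'   (`word`/`number`/`unit`/`punctuation`).
#' @export
tokenize <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("text must be a single character string")
  }
  if (!nzchar(text)) stop("cannot tokenise empty text")
  m <- gregexpr(TOKEN_PATTERN, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      lower = character(), class = character(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  toks <- substring(text, m, m + len - 1L)
  lower <- tolower(toks)
  cls <- ifelse(lower %in% names(UNIT_CANON), "unit",
         ifelse(grepl("^[0-9]", toks), "number",
         ifelse(grepl("^[A-Za-z]", toks), "word", "punctuation")))
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) + len - 1L,
             text = toks, lower = lower, class = cls, stringsAsFactors = FALSE)
}

normalise_unit <- function(u) unname(UNIT_CANON[tolower(u)])

# Sentence ids per token: boundaries after the last of a run of
# terminator tokens (".", ";", ellipsis) and at newlines.
sentence_ids <- function(tokens, text) {
  n <- nrow(tokens)
  if (n == 0L) return(integer())
  terminator <- tokens$text %in% c(".", ";", "…")
  boundary <- logical(n)
  for (i in seq_len(n)) {
    if (i == n) break
    gap <- substr(text, tokens$end[i] + 1L, tokens$start[i + 1L])
    if (grepl("\n", gap, fixed = TRUE)) boundary[i] <- TRUE
    if (terminator[i] && !terminator[i + 1L]) boundary[i] <- TRUE
  }
  c(1L, 1L + cumsum(boundary))[seq_len(n)]
}

#' Split an annotated document into sentences
#'
#' Boundaries fall at sentence-final punctuation (".", ";", ellipsis)
#' and at newlines; decimal points never split because decimal numbers
#' are single tokens. Every token lies in exactly one sentence.
#'
#' @param doc An `echo_document` from [annotate_report()].
#' @return Data frame with `sentence`, `first_tok`, `last_tok`,
#'   `start`, `end`.
#' @export
split_sentences <- function(doc) doc$sentences

sentence_table <- function(tokens, sent) {
  if (!length(sent)) {
    return(data.frame(sentence = integer(), first_tok = integer(),
                      last_tok = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  first <- match(unique(sent), sent)
  last <- length(sent) + 1L - match(unique(sent), rev(sent))
  data.frame(sentence = unique(sent), first_tok = first, last_tok = last,
             start = tokens$start[first], end = tokens$end[last],
             stringsAsFactors = FALSE)
}

# Detect section headings: a known region name at a clause start
# (document start, after punctuation, or after a newline), optionally
# followed by a parenthesised qualifier (up to 6 tokens), then ":".
# Returns a data frame of headings and a per-token section id / region
# tag. "Asc Aorta: 3.5 cm" is a measurement clause, not an Aorta
# heading, because "Aorta" follows a word token.
detect_sections <- function(tokens, text = "") {
  n <- nrow(tokens)
  clause_start <- rep(TRUE, n)
  if (n > 1L) {
    prev_word <- tokens$class[-n] %in% c("word", "number", "unit")
    gaps <- substring(text, tokens$end[-n] + 1L, tokens$start[-1L])
    clause_start[-1L] <- !prev_word | grepl("\n", gaps, fixed = TRUE)
  }
  region_seqs <- lapply(names(SECTION_REGIONS),
                        function(s) strsplit(s, " ", fixed = TRUE)[[1]])
  ord <- order(vapply(region_seqs, length, 1L), decreasing = TRUE)
  region_seqs <- region_seqs[ord]
  region_tags <- unname(unlist(SECTION_REGIONS))[ord]

  headings <- list()
  i <- 1L
  while (i <= n) {
    if (!clause_start[i]) {
      i <- i + 1L
      next
    }
    matched <- FALSE
    for (k in seq_along(region_seqs)) {
      sq <- region_seqs[[k]]
      len <- length(sq)
      if (i + len - 1L > n) next
      if (!all(tokens$lower[i:(i + len - 1L)] == sq)) next
      j <- i + len
      if (j <= n && tokens$text[j] == "(") {
        close <- which(tokens$text == ")" & seq_len(n) > j & seq_len(n) <= j + 7L)
        if (length(close)) j <- close[1] + 1L
      }
      if (j <= n && tokens$text[j] == ":") {
        headings[[length(headings) + 1L]] <- data.frame(
          first_tok = i, colon_tok = j, region = region_tags[k],
          stringsAsFactors = FALSE)
        i <- j + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  heads <- if (length(headings)) do.call(rbind, headings) else
    data.frame(first_tok = integer(), colon_tok = integer(),
               region = character(), stringsAsFactors = FALSE)

  section <- rep(0L, n)
  region <- rep("", n)
  if (nrow(heads)) {
    for (h in seq_len(nrow(heads))) {
      from <- heads$first_tok[h]
      to <- if (h < nrow(heads)) heads$first_tok[h + 1L] - 1L else n
      section[from:to] <- h
      region[from:to] <- heads$region[h]
    }
  }
  # prosthesis markers flag the whole section (heading parentheticals and
  # clause mentions alike)
  prosthetic <- rep(FALSE, n)
  marker <- tokens$lower %in% PROSTHESIS_MARKERS
  if (n > 1L) {
    marker <- marker | (tokens$lower == "situ" &
                        c(FALSE, tokens$lower[-n] == "in"))
  }
  if (any(marker)) {
    for (s in unique(section[marker])) prosthetic[section == s] <- TRUE
  }
  list(headings = heads, section = section, region = region,
       prosthetic = prosthetic)
}

# Longest-match-wins gazetteer scan over token sequences. Context-tagged
# aliases resolve against the nearest preceding lookup in the same
# sentence, falling back to the section region.
gazetteer_scan <- function(tokens, sent, region, lexicon) {
  aliases <- attr(lexicon, "aliases")
  n <- nrow(tokens)
  empty <- data.frame(first_tok = integer(), last_tok = integer(),
                      start = integer(), end = integer(),
                      canonical_name = character(), data_type = character(),
                      context_tag = character(), context_used = character(),
                      excluded = logical(), sentence = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L || nrow(aliases) == 0L) return(empty)

  alias_toks <- aliases$tok_lower
  alias_texts <- aliases$tok_text
  alias_len <- vapply(alias_toks, length, 1L)
  first_key <- vapply(alias_toks, `[`, "", 1L)
  # candidate alias rows by first-token key, longest first
  ord <- order(alias_len, decreasing = TRUE)
  by_key <- split(seq_len(nrow(aliases))[ord], first_key[ord])

  type_of <- stats::setNames(lexicon$data_type, lexicon$canonical_name)
  tag_of <- stats::setNames(lexicon$context_tag, lexicon$canonical_name)

  ft <- integer(); lt <- integer(); canons <- character()
  ctxs <- character()
  anchor_tag <- ""
  anchor_sent <- -1L
  i <- 1L
  while (i <= n) {
    cands <- by_key[[tokens$lower[i]]]
    hit <- 0L
    if (!is.null(cands)) {
      for (a in cands) {
        len <- alias_len[a]
        j <- i + len - 1L
        if (j > n) next
        if (!identical(tokens$lower[i:j], alias_toks[[a]])) next
        if (aliases$case_sensitive[a] &&
            !identical(tokens$text[i:j], alias_texts[[a]])) next
        ctx_used <- ""
        if (nzchar(aliases$context[a])) {
          eff <- if (anchor_sent == sent[i]) anchor_tag else region[i]
          if (!identical(eff, aliases$context[a])) next
          ctx_used <- eff
        }
        canon <- aliases$canonical_name[a]
        ft <- c(ft, i); lt <- c(lt, j); canons <- c(canons, canon)
        ctxs <- c(ctxs, ctx_used)
        if (canon != ".exclude") {
          anchor_tag <- unname(tag_of[canon])
          anchor_sent <- sent[i]
        }
        hit <- len
        break
      }
    }
    i <- i + max(hit, 1L)
  }
  if (!length(ft)) return(empty)
  excl <- canons == ".exclude"
  data.frame(first_tok = ft, last_tok = lt,
             start = tokens$start[ft], end = tokens$end[lt],
             canonical_name = canons,
             data_type = ifelse(excl, "", unname(type_of[canons])),
             context_tag = ifelse(excl, "", unname(tag_of[canons])),
             context_used = ctxs, excluded = excl, sentence = sent[ft],
             stringsAsFactors = FALSE)
}

#' Annotate a report
#'
#' Runs the full annotation pipeline on one report: tokenisation,
#' sentence splitting, section-heading detection (with prosthetic-valve
#' context flags) and gazetteer lookup against the lexicon.
#'
#' @param text Report text (UTF-8).
#' @param report_id Identifier carried into all downstream records.
#' @param lexicon An `echo_lexicon`.
#' @return An object of class `echo_document`: a list with `report_id`,
#'   `text`, `tokens`, `sentences`, `headings`, and `lookups`. Tokens
#'   carry their sentence id, section region and prosthetic flag.
#' @export
annotate_report <- function(text, report_id = "r1", lexicon = echo_lexicon()) {
  tokens <- tokenize(text)
  sent <- sentence_ids(tokens, text)
  tokens$sentence <- sent
  sec <- detect_sections(tokens, text)
  tokens$region <- sec$region
  tokens$prosthetic <- sec$prosthetic
  # heading tokens are structural; exclude them from gazetteer matching
  masked <- tokens
  if (nrow(sec$headings)) {
    for (h in seq_len(nrow(sec$headings))) {
      idx <- sec$headings$first_tok[h]:sec$headings$colon_tok[h]
      masked$lower[idx] <- paste0("§", masked$lower[idx])
    }
  }
  lookups <- gazetteer_scan(masked, sent, sec$region, lexicon)
  structure(list(report_id = report_id, text = text, tokens = tokens,
                 sentences = sentence_table(tokens, sent),
                 headings = sec$headings, lookups = lookups),
            class = "echo_document")
}

#' Gazetteer lookups of a document
#'
#' @param doc An `echo_document`.
#' @param lexicon Optional `echo_lexicon` to re-match against; by default
#'   the lookups computed by [annotate_report()] are returned.
#' @return Data frame of lookup annotations (token span, character span,
#'   canonical name, context used, exclusion flag).
#' @export
gazetteer_match <- function(doc, lexicon = NULL) {
  if (is.null(lexicon)) return(doc$lookups)
  sec <- detect_sections(doc$tokens, doc$text)
  gazetteer_scan(doc$tokens, doc$tokens$sentence, sec$region, lexicon)
}

#' @export
print.echo_document <- function(x, ...) {
  cat("<echo_document> ", x$report_id, ": ", nrow(x$tokens), " tokens, ",
      nrow(x$sentences), " sentences, ",
      sum(!x$lookups$excluded), " lookups\n", sep = "")
  invisible(x)
}

#' Read a batch of reports
#'
#' Accepts either a directory of `.txt` files (report id = file name
#' without extension) or a delimited file with columns `report_id` and
#' `text`.
#'
#' @param path Directory or CSV/TSV file path.
#' @return Data frame with `report_id` and `text`.
#' @export
read_reports <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    texts <- vapply(files, function(f)
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n"), "")
    return(data.frame(report_id = sub("\\.txt$", "", basename(files)),
                      text = unname(texts), stringsAsFactors = FALSE))
  }
  if (!file.exists(path)) stop("input not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", colClasses = "character")
  if (!all(c("report_id", "text") %in% names(df))) {
    stop("report file must have columns report_id and text")
  }
  df[, c("report_id", "text")]
}
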