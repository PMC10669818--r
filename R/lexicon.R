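#' Load an outcome lexicon
#'
#' Reads the outcome dictionary that drives gazetteer matching and value
#' normalisation. Each record defines one canonical outcome: its names,
#' heart-region category, data type (continuous or discrete), canonical
#' unit, severity scale (discrete outcomes only), parent ontology level
#' and alias surface forms. Aliases are `|`-separated; a form written as
#' `surface@context` only matches when the surrounding context (nearest
#' anchoring lookup in the sentence, else the section heading) carries
#' that context tag, which is how bare forms such as `VTI` are
#' disambiguated between valves.
#'
#' Short all-uppercase aliases (three characters or fewer, e.g. `AS`,
#' `MR`, `EF`) match case-sensitively so that ordinary words such as
#' "as" cannot fire a lookup; all other matching is case-insensitive.
#'
#' @param path Path to a lexicon CSV. Defaults to the bundled lexicon of
#'   43 clinically validated outcomes (35 continuous, 8 discrete).
#' @param scales_path Path to a severity-scale YAML file (see
#'   [load_severity_scales()]).
#' @param units_path Path to a unit conversion CSV (see
#'   [load_unit_table()]).
#' @param exclusions_path Path to a plain-text file of gazetteer
#'   exclusion surfaces, one per line; `#` lines are comments.
#' @return An object of class `echo_lexicon`: a data frame with one row
#'   per outcome and attributes `aliases` (the alias table), `scales`,
#'   `units` and `exclusions`.
#' @export
load_lexicon <- function(path = NULL, scales_path = NULL, units_path = NULL,
                         exclusions_path = NULL) {
  path <- path %||% pkg_file("lexicon.csv")
  scales_path <- scales_path %||% pkg_file("severity_scales.yaml")
  units_path <- units_path %||% pkg_file("units.csv")
  exclusions_path <- exclusions_path %||% pkg_file("exclusions.txt")
  if (!file.exists(path)) stop("lexicon file not found: ", path)

  lex <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  scales <- load_severity_scales(scales_path)
  units <- load_unit_table(units_path)
  exclusions <- load_exclusions(exclusions_path)

  if (nrow(lex) == 0L) {
    warning("lexicon file is empty: ", path)
    return(empty_lexicon(scales, units, exclusions))
  }

  required <- c("canonical_name", "clinician_name", "definition", "category",
                "data_type", "canonical_unit", "severity_scale",
                "parent_level", "context_tag", "aliases")
  missing <- setdiff(required, names(lex))
  if (length(missing)) {
    stop("lexicon is missing columns: ", paste(missing, collapse = ", "))
  }

  dup <- lex$canonical_name[duplicated(lex$canonical_name)]
  if (length(dup)) {
    stop("duplicate canonical_name in lexicon: ", paste(unique(dup), collapse = ", "))
  }
  bad_type <- !lex$data_type %in% c("continuous", "discrete")
  if (any(bad_type)) {
    stop("invalid data_type for: ",
         paste(lex$canonical_name[bad_type], collapse = ", "))
  }
  disc <- lex$data_type == "discrete"
  if (any(disc & !nzchar(lex$severity_scale))) {
    stop("discrete outcome without severity_scale: ",
         paste(lex$canonical_name[disc & !nzchar(lex$severity_scale)], collapse = ", "))
  }
  dangling <- disc & nzchar(lex$severity_scale) &
    !lex$severity_scale %in% names(scales)
  if (any(dangling)) {
    stop("severity_scale not defined for: ",
         paste(lex$canonical_name[dangling], collapse = ", "))
  }
  if (any(!disc & !nzchar(lex$canonical_unit))) {
    stop("continuous outcome without canonical_unit: ",
         paste(lex$canonical_name[!disc & !nzchar(lex$canonical_unit)], collapse = ", "))
  }
  if (any(disc & nzchar(lex$canonical_unit))) {
    stop("discrete outcome must not carry a canonical_unit: ",
         paste(lex$canonical_name[disc & nzchar(lex$canonical_unit)], collapse = ", "))
  }

  aliases <- build_alias_table(lex, exclusions)
  structure(lex,
            aliases = aliases, scales = scales, units = units,
            exclusions = exclusions,
            class = c("echo_lexicon", "data.frame"))
}

#' @rdname load_lexicon
#' @export
echo_lexicon <- function() load_lexicon()

empty_lexicon <- function(scales, units, exclusions) {
  lex <- data.frame(canonical_name = character(), clinician_name = character(),
                    definition = character(), category = character(),
                    data_type = character(), canonical_unit = character(),
                    severity_scale = character(), parent_level = character(),
                    context_tag = character(), aliases = character(),
                    stringsAsFactors = FALSE)
  structure(lex, aliases = build_alias_table(lex, exclusions),
            scales = scales, units = units, exclusions = exclusions,
            class = c("echo_lexicon", "data.frame"))
}

# One row per (surface, target, context); exclusion surfaces get the
# pseudo-target ".exclude". case_sensitive marks short all-caps forms.
build_alias_table <- function(lex, exclusions) {
  rows <- list()
  for (i in seq_len(nrow(lex))) {
    forms <- strsplit(lex$aliases[i], "|", fixed = TRUE)[[1]]
    forms <- trimws(forms[nzchar(trimws(forms))])
    for (f in forms) {
      at <- regexpr("@", f, fixed = TRUE)
      if (at > 0) {
        surface <- substr(f, 1L, at - 1L)
        context <- substring(f, at + 1L)
      } else {
        surface <- f
        context <- ""
      }
      rows[[length(rows) + 1L]] <- data.frame(
        surface = surface, canonical_name = lex$canonical_name[i],
        context = context, stringsAsFactors = FALSE)
    }
  }
  for (x in exclusions) {
    rows[[length(rows) + 1L]] <- data.frame(
      surface = x, canonical_name = ".exclude", context = "",
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(surface = character(), canonical_name = character(),
               context = character(), stringsAsFactors = FALSE)
  tab$case_sensitive <- nchar(tab$surface) <= 3L &
    tab$surface == toupper(tab$surface)
  # pre-tokenised surfaces; tokenising per document would dominate runtime
  tab$tok_text <- lapply(tab$surface, function(s) tokenize(s)$text)
  tab$tok_lower <- lapply(tab$tok_text, tolower)
  tab
}

load_exclusions <- function(path) {
  if (is.null(path) || !file.exists(path)) return(character())
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Look up one outcome definition
#'
#' @param lexicon An `echo_lexicon`.
#' @param outcome Canonical outcome name.
#' @return A one-row data frame, or an error if the outcome is unknown.
#' @export
outcome_definition <- function(lexicon, outcome) {
  i <- match(outcome, lexicon$canonical_name)
  if (is.na(i)) stop("unknown outcome: ", outcome)
  lexicon[i, , drop = FALSE]
}

#' Severity scales
#'
#' Loads the ordinal severity scales used to quantify qualitative grades.
#' Each scale is an ordered list of levels; codes are consecutive integers
#' starting at 0 and combined labels ("trivial-mild") map to the code of
#' their upper member on the valve scales. A scale with
#' `allows_negation_zero` maps negated mentions ("No aortic
#' regurgitation") to code 0.
#'
#' @param path YAML file of scales; defaults to the bundled file.
#' @return Named list of scales. Each scale is a list with elements
#'   `name`, `levels` (data frame of code and primary label), `label_map`
#'   (named integer vector from normalised surface label to code) and
#'   `allows_negation_zero`.
#' @export
load_severity_scales <- function(path = NULL) {
  path <- path %||% pkg_file("severity_scales.yaml")
  raw <- yaml::read_yaml(path)
  scales <- lapply(names(raw$scales), function(nm) {
    sc <- raw$scales[[nm]]
    codes <- vapply(sc$levels, function(l) as.integer(l$code), integer(1))
    if (!identical(codes, seq_along(codes) - 1L)) {
      stop("scale '", nm, "': codes must be consecutive integers from 0")
    }
    label_map <- integer()
    primary <- character(length(codes))
    for (l in sc$levels) {
      labs <- normalise_label(unlist(l$labels))
      primary[as.integer(l$code) + 1L] <- labs[1]
      lm <- rep(as.integer(l$code), length(labs))
      names(lm) <- labs
      label_map <- c(label_map, lm)
    }
    list(name = nm,
         levels = data.frame(code = codes, label = primary,
                             stringsAsFactors = FALSE),
         label_map = label_map,
         allows_negation_zero = isTRUE(sc$allows_negation_zero))
  })
  names(scales) <- names(raw$scales)
  scales
}

# Lower-case, unify unicode dashes to "-", strip spaces around dashes,
# collapse runs of whitespace.
normalise_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[‐‑‒–—−]", "-", x)
  x <- gsub("\\s*-\\s*", "-", x)
  gsub("\\s+", " ", x)
}

#' Map a severity label to its ordinal code
#'
#' Case-insensitive; en dash and hyphen are equivalent. A negated phrase
#' ("No aortic regurgitation") returns 0 when the scale allows it. A
#' label followed by trailing words ("mild aortic regurgitation") is
#' resolved by its leading severity term.
#'
#' @param label Surface text of the grade.
#' @param scale One scale from [load_severity_scales()].
#' @return Integer code, or `NA_integer_` if the label is not recognised
#'   (the no-match signal; callers decide whether to skip or flag).
#' @export
severity_to_ordinal <- function(label, scale) {
  lab <- normalise_label(label)
  if (!nzchar(lab)) return(NA_integer_)
  if (scale$allows_negation_zero && (lab == "no" || startsWith(lab, "no "))) {
    return(0L)
  }
  hit <- scale$label_map[lab]
  if (!is.na(hit)) return(unname(hit))
  # longest surface that is a word-boundary prefix of the label
  surfs <- names(scale$label_map)
  surfs <- surfs[order(nchar(surfs), decreasing = TRUE)]
  for (s in surfs) {
    if (startsWith(lab, paste0(s, " ")) || identical(lab, s)) {
      return(unname(scale$label_map[s]))
    }
  }
  NA_integer_
}

#' Unit conversion table
#'
#' @param path CSV with columns `from`, `to`, `factor`; defaults to the
#'   bundled table (powers of ten between m/cm/mm, s/ms, m/s and cm/s,
#'   L and mL).
#' @return A data frame of class `echo_unit_table`.
#' @export
load_unit_table <- function(path = NULL) {
  path <- path %||% pkg_file("units.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "factor") %in% names(tab)))
  tab$factor <- as.numeric(tab$factor)
  class(tab) <- c("echo_unit_table", "data.frame")
  tab
}

unit_factor <- function(from, to, table) {
  if (identical(from, to)) return(1)
  i <- which(table$from == from & table$to == to)
  if (!length(i)) return(NA_real_)
  table$factor[i[1]]
}

#' Convert a measurement between units
#'
#' Multiplies by the tabulated factor; the identity factor is implicit.
#' The bundled factors are exact powers of ten, so e.g. 0.47 m converts
#' to exactly 47 cm.
#'
#' @param value Numeric value(s).
#' @param from,to Unit symbols.
#' @param table An `echo_unit_table`; defaults to the bundled table.
#' @return Converted numeric value.
#' @export
convert_unit <- function(value, from, to, table = load_unit_table()) {
  f <- unit_factor(from, to, table)
  if (is.na(f)) stop("no unit conversion from '", from, "' to '", to, "'")
  value * f
}

#' @export
print.echo_lexicon <- function(x, ...) {
  cat("<echo_lexicon> ", nrow(x), " outcomes (",
      sum(x$data_type == "continuous"), " continuous, ",
      sum(x$data_type == "discrete"), " discrete), ",
      nrow(attr(x, "aliases")), " alias surfaces\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_file <- function(...) {
  p <- system.file("extdata", ..., package = "echoparse")
  if (!nzchar(p)) stop("bundled file not found: ", file.path(...))
  p
}
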