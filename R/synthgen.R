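# Ground-truthed synthetic TTE report generator. Reports follow the
# section-heading layout of real semi-structured echo reports; every
# rendered mention has exactly one ground-truth record on canonical
# units/scales, so the whole pipeline is testable without any data.

# Plausible clinical value ranges per outcome (generator conveniences,
# not claims about any population): low, high, decimal digits.
VALUE_SPECS <- local({
  s <- function(low, high, digits) list(low = low, high = high, digits = digits)
  list(
    "EF" = s(10, 80, 0), "LVIDd" = s(3.5, 7, 1), "LVIDs" = s(2, 5, 1),
    "IVS" = s(0.6, 2, 1), "PWd" = s(0.6, 1.8, 1),
    "LVOT Diam" = s(1.8, 2.6, 1), "LVOT VTI" = s(10, 30, 1),
    "LVOT Vmax" = s(0.5, 1.5, 1), "RV S'" = s(5, 16, 1),
    "RVD1" = s(2.5, 5.3, 1), "RV TAPSE" = s(1, 3, 1),
    "LA Area" = s(12, 40, 1), "LA Volume" = s(30, 120, 0),
    "RA Area" = s(10, 30, 1), "AV Vmax" = s(1, 5.5, 1),
    "AV max PG" = s(5, 120, 0), "AV MPG" = s(3, 60, 0),
    "AR PHT" = s(200, 600, 0), "AV VTI" = s(15, 120, 1),
    "Lateral MAPSE" = s(0.8, 1.8, 1), "Peak E Velocity" = s(0.4, 1.5, 1),
    "Peak A Velocity" = s(0.3, 1.2, 1), "DcT" = s(120, 280, 0),
    "E/A ratio" = s(0.5, 3, 1), "Average E/E'" = s(4, 20, 1),
    "Lateral S' Velocity" = s(4, 16, 1), "Lateral E' Velocity" = s(4, 16, 1),
    "Septal S' Velocity" = s(4, 16, 1), "Septal E' Velocity" = s(4, 16, 1),
    "TR Vmax" = s(1.5, 5.5, 1), "TR max PG" = s(10, 90, 0),
    "PV Vmax" = s(0.5, 1.5, 1), "Sinuses of Valsalva" = s(2.5, 4.5, 1),
    "Sinotubular Junction" = s(2, 3.6, 1), "Ascending Aorta" = s(2.5, 4.5, 1))
})

CODE_PROBS <- list(
  regurgitation = c(0.35, 0.2, 0.2, 0.15, 0.1),
  stenosis = c(0.5, 0.1, 0.15, 0.15, 0.1),
  lv_function = c(0.05, 0.5, 0.1, 0.1, 0.05, 0.1, 0.05, 0.05))

SECTION_ORDER <- c("left ventricle", "right ventricle", "left atrium",
                   "right atrium", "aortic valve", "mitral valve",
                   "tricuspid valve", "pulmonary valve", "aorta")
SECTION_HEADINGS <- c("left ventricle" = "Left Ventricle",
                      "right ventricle" = "Right Ventricle",
                      "left atrium" = "Left Atrium",
                      "right atrium" = "Right Atrium",
                      "aortic valve" = "Aortic Valve",
                      "mitral valve" = "Mitral Valve",
                      "tricuspid valve" = "Tricuspid Valve",
                      "pulmonary valve" = "Pulmonary Valve",
                      "aorta" = "Aorta")

#' Load report rendering templates
#'
#' @param path Template YAML; defaults to the bundled file.
#' @return Named list of template string vectors.
#' @export
load_templates <- function(path = NULL) {
  path <- path %||% pkg_file("templates.yaml")
  yaml::read_yaml(path)$templates
}

#' Synthetic corpus generator profile
#'
#' Fixes the conditions under which a corpus is generated: size, seed,
#' per-outcome inclusion probability, and noise rates. The noise rates
#' emulate the error modes seen in real report text: `miss` renders a
#' mention in out-of-dictionary terminology (so the extractor must miss
#' it while ground truth keeps it); `unit_jitter` emits an equivalent
#' non-canonical unit ("27 mm" for 2.7 cm); `range` emits "a-b" with
#' truth at the midpoint; `negation` renders a discrete grade as a
#' negated finding (truth code 0); `malformed` splits a decimal value
#' ("38 9" for 38.9; the truth record is marked uncertain); `prosthesis`
#' wraps a regurgitation grade in prosthetic-valve language.
#'
#' @param n_reports Number of reports.
#' @param seed Integer seed; fixes the corpus byte-exactly.
#' @param inclusion_prob Scalar probability that an outcome appears in a
#'   report, or a named vector by canonical outcome name.
#' @param noise Named list of rates: `miss`, `unit_jitter`, `range`,
#'   `negation`, `malformed`, `prosthesis`. Omitted entries default to
#'   the rates above.
#' @return An object of class `echo_profile`.
#' @export
generator_profile <- function(n_reports = 100L, seed = 1L,
                              inclusion_prob = 0.35, noise = list()) {
  defaults <- list(miss = 0.05, unit_jitter = 0.05, range = 0.15,
                   negation = 0.3, malformed = 0.01, prosthesis = 0.05)
  unknown <- setdiff(names(noise), names(defaults))
  if (length(unknown)) stop("unknown noise rate(s): ",
                            paste(unknown, collapse = ", "))
  noise <- utils::modifyList(defaults, noise)
  rates <- c(unlist(noise), inclusion_prob)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (n_reports < 0) stop("n_reports must be non-negative")
  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 inclusion_prob = inclusion_prob, noise = noise),
            class = "echo_profile")
}

inclusion_for <- function(profile, outcome) {
  p <- profile$inclusion_prob
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  out <- p[outcome]
  if (is.na(out)) 0 else unname(out)
}

# Context-free surface forms usable for rendering, preferring wordy
# aliases for discrete outcomes (natural in running text).
render_aliases <- function(lexicon, outcome) {
  al <- attr(lexicon, "aliases")
  al$surface[al$canonical_name == outcome & al$context == ""]
}

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))

fmt_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

# Build the mention plan: everything except noise is decided here, so
# that perturb() can re-render the same corpus under different noise.
make_plan <- function(profile, lexicon) {
  scales <- attr(lexicon, "scales")
  plan <- list()
  for (i in seq_len(profile$n_reports)) {
    rid <- sprintf("s%04d", i)
    for (j in seq_len(nrow(lexicon))) {
      oc <- lexicon$canonical_name[j]
      if (stats::runif(1) >= inclusion_for(profile, oc)) next
      aliases <- render_aliases(lexicon, oc)
      alias <- aliases[sample.int(length(aliases), 1L)]
      if (lexicon$data_type[j] == "continuous") {
        sp <- VALUE_SPECS[[oc]]
        value <- round(stats::runif(1, sp$low, sp$high), sp$digits)
        plan[[length(plan) + 1L]] <- list(
          report_id = rid, outcome = oc, type = "continuous",
          category = lexicon$category[j], alias = alias, value = value,
          digits = sp$digits, unit = lexicon$canonical_unit[j],
          tpl = stats::runif(1))
      } else {
        sc <- scales[[lexicon$severity_scale[j]]]
        probs <- CODE_PROBS[[lexicon$severity_scale[j]]]
        code <- sample(sc$levels$code, 1L, prob = probs)
        labs <- names(sc$label_map)[sc$label_map == code]
        label <- labs[sample.int(length(labs), 1L)]
        plan[[length(plan) + 1L]] <- list(
          report_id = rid, outcome = oc, type = "discrete",
          category = lexicon$category[j], alias = alias, code = code,
          label = label, scale = lexicon$severity_scale[j],
          tpl = stats::runif(1))
      }
    }
  }
  plan
}

pick_tpl <- function(templates, kind, u) {
  v <- templates[[kind]]
  v[[1L + floor(u * length(v)) %% length(v)]]
}

fill_tpl <- function(tpl, slots) {
  for (nm in names(slots)) {
    tpl <- gsub(paste0("{", nm, "}"), slots[[nm]], tpl, fixed = TRUE)
  }
  tpl <- gsub("\\s+", " ", tpl)
  tpl <- gsub(" ([.,;%])", "\\1", trimws(tpl))
  if (!grepl("[.,;:]$", tpl)) tpl <- paste0(tpl, ".")
  tpl
}

render_value_unit <- function(value, unit) {
  if (unit == "dimensionless") list(value = fmt_num(value), unit = "")
  else if (unit == "%") list(value = paste0(fmt_num(value), "%"), unit = "")
  else list(value = fmt_num(value), unit = unit)
}

# Render one mention under the given noise rates; returns the clause
# text plus its ground-truth record.
render_mention <- function(m, noise, templates, lexicon, scales, units) {
  truth <- list(report_id = m$report_id, outcome = m$outcome,
                value = NA_real_, unit = "", ordinal_label = "",
                negated = FALSE,
                context = unname(SECTION_REGIONS[[m$category]]),
                prosthetic = FALSE, uncertain = FALSE)
  draws <- stats::runif(6)  # miss, jitter, range, negation, malformed, prosth

  if (m$type == "continuous") {
    truth$value <- m$value
    truth$unit <- m$unit
    vu <- render_value_unit(m$value, m$unit)
    if (draws[1] < noise$miss) {
      text <- fill_tpl(pick_tpl(templates, "miss_continuous", m$tpl),
                       list(value = vu$value, unit = vu$unit))
      return(list(text = text, truth = truth, missed = TRUE))
    }
    has_decimal <- m$digits > 0 && round(m$value) != m$value
    if (draws[5] < noise$malformed && has_decimal && m$unit != "%") {
      parts <- strsplit(fmt_num(m$value), ".", fixed = TRUE)[[1]]
      text <- fill_tpl(pick_tpl(templates, "malformed", m$tpl),
                       list(name = m$alias, intpart = parts[1],
                            fracpart = parts[2], unit = m$unit))
      truth$uncertain <- TRUE
      return(list(text = text, truth = truth, missed = FALSE))
    }
    # range rendering needs a strictly positive lower bound
    step <- 10^(-m$digits)
    kmax <- min(5L, as.integer(floor(m$value / step + 1e-9)) - 1L)
    if (draws[3] < noise$range && kmax >= 1L) {
      d <- step * sample.int(kmax, 1L)
      v1 <- round(m$value - d, m$digits)
      v2 <- round(m$value + d, m$digits)
      truth$value <- (v1 + v2) / 2
      if (m$unit == "dimensionless") {
        text <- fill_tpl(pick_tpl(templates, "continuous_nounit", m$tpl),
                         list(name = m$alias,
                              value = paste0(fmt_num(v1), "-", fmt_num(v2))))
      } else {
        u2 <- if (m$unit == "%") "" else m$unit
        v2s <- if (m$unit == "%") paste0(fmt_num(v2), "%") else fmt_num(v2)
        text <- fill_tpl(pick_tpl(templates, "range", m$tpl),
                         list(name = m$alias, v1 = fmt_num(v1), v2 = v2s,
                              unit = u2))
      }
      return(list(text = text, truth = truth, missed = FALSE))
    }
    alts <- units$to[units$from == m$unit]
    if (draws[2] < noise$unit_jitter && length(alts)) {
      alt <- alts[1L + floor(m$tpl * length(alts)) %% length(alts)]
      jv <- m$value * unit_factor(m$unit, alt, units)
      text <- fill_tpl(pick_tpl(templates, "unit_jitter", m$tpl),
                       list(name = m$alias, value = fmt_num(jv), unit = alt))
      return(list(text = text, truth = truth, missed = FALSE))
    }
    kind <- if (m$unit == "dimensionless") "continuous_nounit" else "continuous"
    text <- fill_tpl(pick_tpl(templates, kind, m$tpl),
                     list(name = m$alias, value = vu$value, unit = vu$unit))
    return(list(text = text, truth = truth, missed = FALSE))
  }

  # discrete mention
  sc <- scales[[m$scale]]
  code <- m$code
  if (draws[4] < noise$negation && sc$allows_negation_zero) code <- 0L
  truth$value <- as.numeric(code)
  truth$ordinal_label <- sc$levels$label[code + 1L]
  label <- if (code == m$code) m$label else sc$levels$label[code + 1L]

  if (draws[1] < noise$miss) {
    # the primary level label only ("none", "mild", ...): a multi-word
    # variant such as "no stenosis" would hand the extractor a lookup
    text <- fill_tpl(pick_tpl(templates, "miss_discrete", m$tpl),
                     list(label = sc$levels$label[code + 1L]))
    return(list(text = text, truth = truth, missed = TRUE))
  }
  if (code == 0L && sc$allows_negation_zero) {
    truth$negated <- TRUE
    text <- fill_tpl(pick_tpl(templates, "negation", m$tpl),
                     list(name = m$alias))
    return(list(text = text, truth = truth, missed = FALSE))
  }
  if (draws[6] < noise$prosthesis && m$scale == "regurgitation" && code >= 1L) {
    truth$prosthetic <- TRUE
    text <- fill_tpl(pick_tpl(templates, "prosthetic", m$tpl),
                     list(label = cap1(label), name = m$alias))
    return(list(text = text, truth = truth, missed = FALSE))
  }
  text <- fill_tpl(pick_tpl(templates, "severity", m$tpl),
                   list(label = cap1(label), name = m$alias))
  list(text = text, truth = truth, missed = FALSE)
}

render_plan <- function(plan, noise, templates, lexicon) {
  scales <- attr(lexicon, "scales")
  units <- attr(lexicon, "units")
  truth_rows <- vector("list", length(plan))
  clause <- character(length(plan))
  m_rid <- vapply(plan, function(m) m$report_id, "")
  m_cat <- vapply(plan, function(m) m$category, "")
  for (idx in seq_along(plan)) {
    r <- render_mention(plan[[idx]], noise, templates, lexicon, scales, units)
    truth_rows[[idx]] <- as.data.frame(r$truth, stringsAsFactors = FALSE)
    clause[idx] <- r$text
  }
  ids <- unique(m_rid)
  cat_rank <- match(m_cat, SECTION_ORDER)
  report_texts <- vapply(ids, function(rid) {
    sel <- which(m_rid == rid)
    sel <- sel[order(cat_rank[sel])]
    secs <- vapply(split(sel, cat_rank[sel]), function(ix) {
      paste0(SECTION_HEADINGS[[SECTION_ORDER[cat_rank[ix[1]]]]], ": ",
             paste(clause[ix], collapse = " "))
    }, "")
    paste(secs, collapse = "\n")
  }, "")
  reports <- data.frame(report_id = ids, text = unname(report_texts),
                        stringsAsFactors = FALSE)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(report_id = character(), outcome = character(),
               value = numeric(), unit = character(),
               ordinal_label = character(), negated = logical(),
               context = character(), prosthetic = logical(),
               uncertain = logical(), stringsAsFactors = FALSE)
  list(reports = reports, truth = truth)
}

#' Generate a ground-truthed synthetic report corpus
#'
#' @param profile An `echo_profile` from [generator_profile()].
#' @param lexicon An `echo_lexicon`.
#' @param templates Output of [load_templates()].
#' @return An object of class `echo_corpus`: list with `reports`
#'   (report_id, text), `truth` (ground-truth records on canonical
#'   units/scales; ranges pre-averaged), the mention `plan` and the
#'   `profile`. The same profile always yields a byte-identical corpus.
#' @export
generate_corpus <- function(profile = generator_profile(),
                            lexicon = echo_lexicon(),
                            templates = load_templates()) {
  stopifnot(inherits(profile, "echo_profile"))
  withr::with_seed(profile$seed, {
    plan <- make_plan(profile, lexicon)
    rendered <- render_plan(plan, profile$noise, templates, lexicon)
  })
  structure(list(reports = rendered$reports, truth = rendered$truth,
                 plan = plan, profile = profile),
            class = "echo_corpus")
}

#' Re-render a corpus under different noise rates
#'
#' Re-renders the stored mention plan of `corpus` with the given noise,
#' updating text and ground truth consistently. With all rates zero the
#' corpus is reproduced unchanged (rendering is deterministic given the
#' plan); noise draws use `seed`.
#'
#' @param corpus An `echo_corpus`.
#' @param noise Named list of noise rates as in [generator_profile()];
#'   omitted entries default to 0.
#' @param seed Seed for the noise draws.
#' @return A new `echo_corpus` with the same plan.
#' @export
perturb <- function(corpus, noise = list(), seed = corpus$profile$seed) {
  stopifnot(inherits(corpus, "echo_corpus"))
  zero <- list(miss = 0, unit_jitter = 0, range = 0, negation = 0,
               malformed = 0, prosthesis = 0)
  unknown <- setdiff(names(noise), names(zero))
  if (length(unknown)) stop("unknown noise rate(s): ",
                            paste(unknown, collapse = ", "))
  noise <- utils::modifyList(zero, noise)
  rates <- unlist(noise)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  lexicon <- echo_lexicon()
  rendered <- withr::with_seed(as.integer(seed),
    render_plan(corpus$plan, noise, load_templates(), lexicon))
  profile <- corpus$profile
  profile$noise <- noise
  structure(list(reports = rendered$reports, truth = rendered$truth,
                 plan = corpus$plan, profile = profile),
            class = "echo_corpus")
}

#' @export
print.echo_corpus <- function(x, ...) {
  cat("<echo_corpus> ", nrow(x$reports), " reports, ",
      nrow(x$truth), " ground-truth records (seed ",
      x$profile$seed, ")\n", sep = "")
  invisible(x)
}
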