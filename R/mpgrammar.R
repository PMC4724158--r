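# Melting-point declaration grammar:
#   FromLiterature? MeltingPoint Qualifier? (Value|Range|MeasurementError) OutcomeQualifier?
# implemented as a staged regex parser over UTF-8 text.  All offsets exposed to
# the user are 0-based, half-open [start, end), so re-slicing the source with a
# span returns exactly the matched text.

.mp_num_re <- "[-−]?[0-9]+(?:[.,][0-9]+)?"
.mp_prefix_re <- paste0(
  "(?i)\\b(?:",
  "(melting\\s+point)",                    # 1: phrase form
  "|(m\\.\\s?p\\.?\\s?t?\\.?|mpt?\\.?)",   # 2: abbreviated form
  ")(?=[\\s:=(°>≥<≤~])"
)
.mp_qual_re <- paste0(
  "(?i)^(?:(>=|≥|>)|(<=|≤|<)|",
  "(~|approximately\\b|approx\\.?|about\\b|ca\\.))\\s*"
)
.mp_unit_re <- paste0(
  "^\\s*(?:°\\s?([CcFf])|deg(?:rees?)?\\.?\\s+([Cc]elsius|[Cc]entigrade|[Ff]ahrenheit)",
  "|([CF]))(?![A-Za-z])"
)
.mp_outcome_re <- paste0(
  "(?i)^[\\s,]*(?:\\(\\s*)?(",
  "with\\s+decomposition|decomp(?:osition|oses|osed)?\\.?|dec\\.|",
  "subl(?:imes|imation)?\\.?",
  ")(\\s*\\))?"
)

.mp_units_words <- c(
  one = 1, two = 2, three = 3, four = 4, five = 5, six = 6, seven = 7,
  eight = 8, nine = 9, ten = 10, eleven = 11, twelve = 12, thirteen = 13,
  fourteen = 14, fifteen = 15, sixteen = 16, seventeen = 17, eighteen = 18,
  nineteen = 19, twenty = 20, thirty = 30, forty = 40, fifty = 50,
  sixty = 60, seventy = 70, eighty = 80, ninety = 90
)
.mp_word_re <- paste0(
  "(?i)^((?:", paste(c(names(.mp_units_words), "hundred", "and"), collapse = "|"),
  ")(?:[\\s-]+(?:",
  paste(c(names(.mp_units_words), "hundred", "and"), collapse = "|"),
  "))*)\\b"
)

# Convert a run of spelled-out number words ("one hundred eighty-four") to a
# cardinal.  Supports tens/hundreds composition up to 999; returns NA when the
# token sequence is not a well-formed cardinal.
words_to_number <- function(words) {
  toks <- tolower(unlist(strsplit(words, "[\\s-]+", perl = TRUE)))
  toks <- toks[toks != "" & toks != "and"]
  if (!length(toks)) return(NA_real_)
  total <- 0
  seen <- FALSE
  for (tok in toks) {
    if (tok == "hundred") {
      if (!seen || total == 0 || total >= 10) return(NA_real_)
      total <- total * 100
    } else if (tok %in% names(.mp_units_words)) {
      total <- total + .mp_units_words[[tok]]
      seen <- TRUE
    } else {
      return(NA_real_)
    }
  }
  if (!seen || total > 999) return(NA_real_)
  total
}

# Inverse used by the synthetic corpus generator.
number_to_words <- function(n) {
  stopifnot(n == floor(n), n >= 0, n <= 999)
  if (n == 0) return("zero")
  small <- names(.mp_units_words)
  word1 <- function(k) small[match(k, .mp_units_words)]
  out <- character(0)
  if (n >= 100) {
    out <- c(out, word1(n %/% 100), "hundred")
    n <- n %% 100
  }
  if (n > 0) {
    if (n <= 20 || n %in% .mp_units_words) {
      out <- c(out, word1(n))
    } else {
      tens <- (n %/% 10) * 10
      out <- c(out, paste0(word1(tens), "-", word1(n %% 10)))
    }
  }
  paste(out, collapse = " ")
}

.mp_parse_num <- function(tok) {
  as.numeric(gsub(",", ".", gsub("−", "-", tok), fixed = TRUE))
}

.re_first <- function(re, x) {
  m <- regexpr(re, x, perl = TRUE)
  if (m[1] == -1L) return(NULL)
  st <- attr(m, "capture.start")
  len <- attr(m, "capture.length")
  groups <- if (is.null(st)) character(0) else {
    vapply(seq_along(st), function(i) {
      if (st[i] <= 0L) NA_character_ else substr(x, st[i], st[i] + len[i] - 1L)
    }, character(1))
  }
  list(start = as.integer(m[1]), end = as.integer(m[1] + attr(m, "match.length") - 1L),
       match = substr(x, m[1], m[1] + attr(m, "match.length") - 1L),
       groups = groups)
}

.mp_unit_of <- function(g) {
  u <- g[!is.na(g)]
  if (!length(u)) return("celsius")
  if (toupper(substr(u[1], 1, 1)) == "F") "fahrenheit" else "celsius"
}

#' Repair a malformed temperature range
#'
#' Applies the two repair rules for range expressions recovered from
#' experimental text: a decimal comma in either bound is replaced by a
#' decimal point (`"82-82,5"`), and a truncated upper bound is expanded by
#' borrowing the missing leading digits from the lower bound (`"159-62"`
#' becomes 159--162, `"160-2"` becomes 160--162) so that the upper bound is
#' at least the lower bound and both have the same number of digits before
#' any decimal point.  If no borrowing yields `upper >= lower` the values
#' are returned unchanged, leaving the inverted range to be flagged
#' downstream.
#'
#' @param raw_low,raw_high character (or numeric) tokens of the two bounds
#'   as they appeared in the text.
#' @return numeric vector `c(low, high)` of the repaired bounds.
#' @examples
#' repair_range("159", "62")   # 159 162
#' repair_range("82", "82,5")  # 82 82.5
#' @export
repair_range <- function(raw_low, raw_high) {
  lo_s <- gsub(",", ".", gsub("−", "-", as.character(raw_low)), fixed = TRUE)
  hi_s <- gsub(",", ".", gsub("−", "-", as.character(raw_high)), fixed = TRUE)
  lo <- as.numeric(lo_s)
  hi <- as.numeric(hi_s)
  if (is.na(lo) || is.na(hi)) return(c(lo, hi))
  if (hi >= lo) return(c(lo, hi))
  if (grepl("^-", lo_s) || grepl("^-", hi_s)) return(c(lo, hi))
  lo_int <- sub("\\..*$", "", lo_s)
  hi_int <- sub("\\..*$", "", hi_s)
  need <- nchar(lo_int) - nchar(hi_int)
  if (need > 0) {
    cand_s <- paste0(substr(lo_int, 1, need), hi_s)
    cand <- as.numeric(cand_s)
    if (!is.na(cand) && cand >= lo) return(c(lo, cand))
  }
  c(lo, hi)
}

#' Parse the first melting-point declaration in a text
#'
#' Scans `text` from `start_offset` (0-based) for the first substring
#' conforming to the melting-point grammar
#' `FromLiterature? MeltingPoint Qualifier? (Value|Range|MeasurementError)
#' OutcomeQualifier?`.  Numerals, decimals and spelled-out cardinals (up to
#' 999), symbol and word qualifiers, Celsius and Fahrenheit units and the
#' hyphen/dash/"to" range separators are all accepted and collapsed to a
#' single representation.  Malformed ranges are repaired with
#' [repair_range()] before the numeric values are stored; the raw text is
#' always retained.
#'
#' @param text a character scalar.
#' @param start_offset 0-based character offset at which to start scanning.
#' @return an object of class `mp_mention` (a list with fields `raw_text`,
#'   `prefix_kind`, `from_literature`, `qualifier`, `value_kind`, `v1`,
#'   `v2`, `unit`, `outcome`, `char_span`), or `NULL` when no declaration
#'   matches at or after `start_offset`.
#' @examples
#' parse_mention("white solid, m.p. 184-186 (decomp.)")
#' @export
parse_mention <- function(text, start_offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  pos <- as.integer(start_offset)  # 0-based scan position
  nch <- nchar(text)
  while (pos < nch) {
    tail_all <- substr(text, pos + 1L, nch)
    pm <- .re_first(.mp_prefix_re, tail_all)
    if (is.null(pm)) return(NULL)
    p0 <- pos + pm$start - 1L          # 0-based start of prefix
    pe <- pos + pm$end                 # 0-based exclusive end of prefix
    prefix_kind <- if (!is.na(pm$groups[1])) "mp_phrase" else "mp_abbrev"

    rest <- substr(text, pe + 1L, nch)
    cur <- 0L  # consumed chars within rest

    sep <- .re_first("^[\\s:=]*", rest)
    cur <- cur + nchar(sep$match)

    qualifier <- "none"
    qm <- .re_first(.mp_qual_re, substr(rest, cur + 1L, nchar(rest)))
    if (!is.null(qm)) {
      qualifier <- if (!is.na(qm$groups[1])) "greater"
                   else if (!is.na(qm$groups[2])) "less" else "approx"
      cur <- cur + qm$end
    }

    val <- .mp_match_value(substr(rest, cur + 1L, nchar(rest)))
    if (is.null(val)) { pos <- pe; next }
    cur <- cur + val$consumed

    outcome <- "melt"
    om <- .re_first(.mp_outcome_re, substr(rest, cur + 1L, nchar(rest)))
    if (!is.null(om)) {
      outcome <- if (grepl("^subl", tolower(om$groups[1]))) "sublime" else "decompose"
      cur <- cur + om$end
    }

    start0 <- p0
    from_literature <- FALSE
    head_txt <- substr(text, 1L, p0)
    lm <- .re_first("(?i)\\b(lit(?:erature)?\\.?)[\\s,:]*$", head_txt)
    if (!is.null(lm)) {
      from_literature <- TRUE
      start0 <- lm$start - 1L
    }
    end0 <- pe + cur

    return(structure(list(
      raw_text = substr(text, start0 + 1L, end0),
      prefix_kind = prefix_kind,
      from_literature = from_literature,
      qualifier = qualifier,
      value_kind = val$value_kind,
      v1 = val$v1, v2 = val$v2,
      unit = val$unit,
      outcome = outcome,
      char_span = c(start0, end0)
    ), class = "mp_mention"))
  }
  NULL
}

# Match one Value | Range | MeasurementError at the start of `s`.
# Returns list(value_kind, v1, v2, unit, consumed) or NULL.
.mp_match_value <- function(s) {
  err <- .re_first(paste0("^(", .mp_num_re, ")\\s*(?:±|\\+/-|\\+-)\\s*(",
                          .mp_num_re, ")"), s)
  if (!is.null(err)) {
    consumed <- err$end
    unit <- "celsius"
    um <- .re_first(.mp_unit_re, substr(s, consumed + 1L, nchar(s)))
    if (!is.null(um)) { unit <- .mp_unit_of(um$groups); consumed <- consumed + um$end }
    return(list(value_kind = "measurement_error",
                v1 = .mp_parse_num(err$groups[1]), v2 = .mp_parse_num(err$groups[2]),
                unit = unit, consumed = consumed))
  }
  rng <- .re_first(paste0("^(", .mp_num_re, ")\\s*(?:[–—-]|to\\b)\\s*(",
                          "[0-9]+(?:[.,][0-9]+)?", ")"), s)
  if (!is.null(rng)) {
    consumed <- rng$end
    unit <- "celsius"
    um <- .re_first(.mp_unit_re, substr(s, consumed + 1L, nchar(s)))
    if (!is.null(um)) { unit <- .mp_unit_of(um$groups); consumed <- consumed + um$end }
    v <- repair_range(rng$groups[1], rng$groups[2])
    return(list(value_kind = "range", v1 = v[1], v2 = v[2],
                unit = unit, consumed = consumed))
  }
  sng <- .re_first(paste0("^(", .mp_num_re, ")"), s)
  if (!is.null(sng)) {
    consumed <- sng$end
    unit <- "celsius"
    um <- .re_first(.mp_unit_re, substr(s, consumed + 1L, nchar(s)))
    if (!is.null(um)) { unit <- .mp_unit_of(um$groups); consumed <- consumed + um$end }
    return(list(value_kind = "single",
                v1 = .mp_parse_num(gsub(",", ".", sng$groups[1])), v2 = NULL,
                unit = unit, consumed = consumed))
  }
  wrd <- .re_first(.mp_word_re, s)
  if (!is.null(wrd)) {
    v <- words_to_number(wrd$groups[1])
    if (!is.na(v)) {
      consumed <- wrd$end
      unit <- "celsius"
      um <- .re_first(.mp_unit_re, substr(s, consumed + 1L, nchar(s)))
      if (!is.null(um)) { unit <- .mp_unit_of(um$groups); consumed <- consumed + um$end }
      return(list(value_kind = "single", v1 = v, v2 = NULL,
                  unit = unit, consumed = consumed))
    }
  }
  NULL
}

#' Parse all melting-point declarations in a text
#'
#' Repeatedly applies [parse_mention()], resuming after each match.
#'
#' @inheritParams parse_mention
#' @return a list of `mp_mention` objects (possibly empty).
#' @export
parse_mentions <- function(text) {
  out <- list()
  pos <- 0L
  repeat {
    m <- parse_mention(text, pos)
    if (is.null(m)) break
    out[[length(out) + 1L]] <- m
    pos <- m$char_span[2]
  }
  out
}

#' Normalize a parsed melting-point mention to a Celsius interval
#'
#' Measurement errors `v1 +/- v2` are converted to the range
#' `[v1 - v2, v1 + v2]`, Fahrenheit temperatures to Celsius via
#' `(F - 32) * 5/9`, and single values are stored as degenerate intervals
#' with `low_c == high_c`.  The original text is retained verbatim.
#'
#' @param m an `mp_mention` from [parse_mention()].
#' @return an object of class `normalized_mp`: a list with `low_c`,
#'   `high_c` (degrees Celsius), `qualifier`, `outcome`, `suspicious`,
#'   `suspicious_reasons` and `raw_text`.
#' @export
normalize_mention <- function(m) {
  stopifnot(inherits(m, "mp_mention"))
  if (m$value_kind == "single") {
    lo <- m$v1; hi <- m$v1
  } else if (m$value_kind == "range") {
    lo <- m$v1; hi <- m$v2
  } else {
    lo <- m$v1 - m$v2; hi <- m$v1 + m$v2
  }
  if (m$unit == "fahrenheit") {
    lo <- (lo - 32) * 5 / 9
    hi <- (hi - 32) * 5 / 9
  }
  structure(list(
    low_c = lo, high_c = hi,
    qualifier = m$qualifier,
    outcome = m$outcome,
    suspicious = FALSE,
    suspicious_reasons = character(0),
    raw_text = m$raw_text
  ), class = "normalized_mp")
}

#' Flag suspicious melting-point values
#'
#' Marks a normalized record as suspicious when any of the following holds:
#' a value above 500 degrees C (`above_500`), a range wider than 50 degrees C
#' (`range_over_50`), a range whose second temperature is lower than the
#' first (`inverted_range`), or a value below absolute zero
#' (`below_absolute_zero`, below -273.15 degrees C).  The interval itself is
#' never altered; non-triggering records are returned unchanged.
#'
#' @param n a `normalized_mp` object.
#' @return the same object with `suspicious` and `suspicious_reasons` set.
#' @export
flag_suspicious <- function(n) {
  stopifnot(inherits(n, "normalized_mp"))
  reasons <- character(0)
  if (max(n$low_c, n$high_c) > 500) reasons <- c(reasons, "above_500")
  if (abs(n$high_c - n$low_c) > 50) reasons <- c(reasons, "range_over_50")
  if (n$high_c < n$low_c) reasons <- c(reasons, "inverted_range")
  if (min(n$low_c, n$high_c) < -273.15) reasons <- c(reasons, "below_absolute_zero")
  n$suspicious <- length(reasons) > 0
  n$suspicious_reasons <- reasons
  n
}

#' @export
print.mp_mention <- function(x, ...) {
  v <- if (x$value_kind == "single") format(x$v1)
       else if (x$value_kind == "range") paste0(format(x$v1), "-", format(x$v2))
       else paste0(format(x$v1), " +/- ", format(x$v2))
  cat(sprintf("<mp_mention> %s %s [%s] outcome=%s span=[%d,%d) %s\n",
              x$value_kind, v, x$unit, x$outcome,
              x$char_span[1], x$char_span[2], dQuote(x$raw_text)))
  invisible(x)
}

#' @export
print.normalized_mp <- function(x, ...) {
  cat(sprintf("<normalized_mp> [%.2f, %.2f] C qualifier=%s outcome=%s%s\n",
              x$low_c, x$high_c, x$qualifier, x$outcome,
              if (x$suspicious)
                paste0(" SUSPICIOUS{", paste(x$suspicious_reasons, collapse = ","), "}")
              else ""))
  invisible(x)
}
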