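# Synthetic patent-style corpus with ground truth.  Sections follow the
# shape of a typical experimental section: a heading naming the product,
# synthesis prose mentioning a precursor, and a characterization tail
# carrying the melting-point declaration, either in a bracket directly
# after the product entity (explicit) or at the end of the section
# (implicit).  Error patterns observed in mined text (decimal commas,
# truncated ranges, inverted ranges, missing decimal points, misprinted
# huge values) are injected at configurable rates and recorded in the
# truth stream.

.corpus_prefix_forms <- c("m.p.", "mp", "mpt", "M.p.", "melting point",
                          "Melting point")
.corpus_name_parts <- list(
  prefix = c("2-chloro", "4-methyl", "3-nitro", "N-phenyl", "4-methoxy",
             "2-fluoro", "3-bromo", "4-amino"),
  base = c("benzamide", "aniline", "phenol", "benzoic acid", "acetanilide",
           "pyridine carboxamide", "quinoline", "indole-2-carboxylate"))

#' Configuration for the synthetic corpus generator
#'
#' @param n_sections number of experimental sections.
#' @param seed integer seed.
#' @param typo_rates named numeric vector of injection probabilities for
#'   the error classes `missing_decimal`, `comma_decimal`,
#'   `truncated_range`, `inverted_range` and `huge_value` (at most one
#'   class fires per section, tested in this order).
#' @param unit_mix fraction of declarations written in Fahrenheit.
#' @param spelled_out_fraction fraction of single values written as
#'   spelled-out cardinals.
#' @return a `corpus_config` list.
#' @export
corpus_config <- function(n_sections = 50, seed = 1,
                          typo_rates = c(missing_decimal = 0.02,
                                         comma_decimal = 0.02,
                                         truncated_range = 0.02,
                                         inverted_range = 0.02,
                                         huge_value = 0.02),
                          unit_mix = 0.05, spelled_out_fraction = 0.1) {
  need <- c("missing_decimal", "comma_decimal", "truncated_range",
            "inverted_range", "huge_value")
  full <- stats::setNames(rep(0, length(need)), need)
  full[names(typo_rates)] <- typo_rates
  stopifnot(all(full >= 0), all(full <= 1),
            unit_mix >= 0, unit_mix <= 1,
            spelled_out_fraction >= 0, spelled_out_fraction <= 1)
  structure(list(n_sections = n_sections, seed = as.integer(seed),
                 typo_rates = full, unit_mix = unit_mix,
                 spelled_out_fraction = spelled_out_fraction),
            class = "corpus_config")
}

.fmt_temp <- function(x) {
  if (x %% 1 == 0) sprintf("%d", as.integer(x)) else sprintf("%.1f", x)
}

# Render one declaration.  Returns list(text, truth) where truth holds the
# expected normalized interval, qualifier, outcome, flags and value kind.
.render_decl <- function(cfg, value_kind, typo) {
  prefix <- sample(.corpus_prefix_forms, 1)
  lit <- stats::runif(1) < 0.1
  qual <- "none"; qual_txt <- ""
  outcome <- sample(c("melt", "decompose", "sublime"), 1,
                    prob = c(0.92, 0.06, 0.02))
  outcome_txt <- switch(outcome,
    melt = "",
    decompose = sample(c(" (decomp.)", " decomp.", ", with decomposition"), 1),
    sublime = sample(c(" (subl.)", " subl."), 1))
  fahrenheit <- is.na(typo) && value_kind %in% c("single", "range") &&
    stats::runif(1) < cfg$unit_mix

  base <- round(stats::runif(1, 50, 280)) + sample(c(0, 0.5), 1, prob = c(0.7, 0.3))
  txt <- NULL; lo <- hi <- NA_real_
  suspicious_reasons <- character(0)

  if (!is.na(typo)) {
    if (typo == "comma_decimal") {
      lo <- round(stats::runif(1, 60, 280)); hi <- lo + 0.5
      txt <- sprintf("%d-%d,5", as.integer(lo), as.integer(lo))
      value_kind <- "range"
    } else if (typo == "truncated_range") {
      h <- sample(1:2, 1); t <- sample(0:8, 1)
      lo <- h * 100 + t * 10 + sample(0:6, 1)
      hi <- lo + sample(1:3, 1)
      ls <- sprintf("%d", lo); hs <- sprintf("%d", hi)
      k <- 0L
      for (j in 1:(nchar(ls) - 1)) if (substr(ls, 1, j) == substr(hs, 1, j)) k <- j
      if (k == 0L) { hi <- lo + 1; hs <- sprintf("%d", hi)
                     for (j in 1:(nchar(ls) - 1)) if (substr(ls, 1, j) == substr(hs, 1, j)) k <- j }
      txt <- sprintf("%s-%s", ls, substring(hs, k + 1))
      value_kind <- "range"
    } else if (typo == "inverted_range") {
      # equal digit counts so that digit borrowing cannot "repair" the swap
      a <- round(stats::runif(1, 100, 280)); b <- a + sample(4:9, 1)
      lo <- b; hi <- a                      # written inverted, unrepairable
      txt <- sprintf("%d-%d", as.integer(b), as.integer(a))
      suspicious_reasons <- "inverted_range"
      value_kind <- "range"
    } else if (typo == "missing_decimal") {
      lo <- round(stats::runif(1, 60, 280)); hi <- (lo + 1) * 10
      txt <- sprintf("%d-%d", as.integer(lo), as.integer(hi))
      suspicious_reasons <- c("above_500", "range_over_50")
      value_kind <- "range"
    } else if (typo == "huge_value") {
      lo <- hi <- round(stats::runif(1, 60, 280)) * 10
      txt <- sprintf("%d", as.integer(lo))
      suspicious_reasons <- "above_500"
      value_kind <- "single"
    }
  } else if (value_kind == "single") {
    if (stats::runif(1) < 0.25) {
      qual <- sample(c("greater", "less", "approx"), 1)
      qual_txt <- switch(qual, greater = sample(c(">", ">="), 1),
                         less = sample(c("<", "<="), 1),
                         approx = sample(c("about ", "approximately ", "ca. ", "~"), 1))
    }
    if (fahrenheit) {
      f <- round(base * 9 / 5 + 32, 1)
      lo <- hi <- (f - 32) * 5 / 9
      txt <- paste0(.fmt_temp(f), " °F")
    } else {
      lo <- hi <- base
      txt <- paste0(.fmt_temp(base),
                    sample(c(" °C", ""), 1, prob = c(0.7, 0.3)))
    }
  } else if (value_kind == "range") {
    width <- sample(1:3, 1)
    if (fahrenheit) {
      f1 <- round(base * 9 / 5 + 32); f2 <- f1 + width
      lo <- (f1 - 32) * 5 / 9; hi <- (f2 - 32) * 5 / 9
      txt <- sprintf("%d-%d °F", as.integer(f1), as.integer(f2))
    } else {
      lo <- base; hi <- base + width
      sepc <- sample(c("-", "–", " to "), 1)
      txt <- paste0(.fmt_temp(lo), sepc, .fmt_temp(hi),
                    sample(c(" °C", ""), 1, prob = c(0.6, 0.4)))
    }
  } else if (value_kind == "measurement_error") {
    v <- round(base); e <- sample(c(0.5, 1, 2), 1)
    lo <- v - e; hi <- v + e
    txt <- sprintf("%d ± %s °C", as.integer(v), .fmt_temp(e))
  } else if (value_kind == "spelled") {
    v <- sample(50:260, 1)
    lo <- hi <- v
    txt <- paste0(number_to_words(v), " degrees Celsius")
    value_kind <- "single"
  }

  full <- paste0(if (lit) "lit. " else "", prefix, " ", qual_txt, txt, outcome_txt)
  # suspicious flags implied by the value itself (only typo classes here)
  list(text = full,
       truth = list(low_c = lo, high_c = hi, qualifier = qual,
                    outcome = outcome, from_literature = lit,
                    value_kind = value_kind,
                    suspicious = length(suspicious_reasons) > 0,
                    suspicious_reasons = paste(sort(suspicious_reasons),
                                               collapse = ",")))
}

#' Generate a synthetic annotated corpus with ground truth
#'
#' Produces patent-style documents (up to five experimental sections
#' each) whose blocks, entity annotations and melting-point declarations
#' are constructed jointly with a truth table, so the parsing and
#' association pipeline can be scored exactly.  Value kinds (numeric
#' single values, ranges, measurement errors, spelled-out cardinals)
#' cycle deterministically so every grammar production is exercised;
#' qualifiers, literature markers, outcomes, Fahrenheit units and error
#' injections are sampled at the configured rates.
#'
#' @param cfg a [corpus_config()].
#' @return list with `documents` (list of [annotated_document()]s) and
#'   `truth` (data frame, one row per declaration: provenance, expected
#'   normalized interval, flags and association kind).
#' @export
generate_corpus <- function(cfg = corpus_config()) {
  stopifnot(inherits(cfg, "corpus_config"))
  set.seed(cfg$seed)
  fam <- smiles_family()
  docs <- list()
  truth <- list()
  kinds <- c("single", "range", "measurement_error", "spelled")
  n_docs <- ceiling(cfg$n_sections / 5)
  sec_i <- 0L
  for (d in seq_len(n_docs)) {
    doc_id <- sprintf("US%07dA1", 8000000 + d)
    blocks <- list(); entities <- list()
    par_no <- 0L
    n_here <- min(5L, cfg$n_sections - (d - 1L) * 5L)
    for (s in seq_len(n_here)) {
      sec_i <- sec_i + 1L
      name <- paste0(sample(.corpus_name_parts$prefix, 1), "-",
                     sample(.corpus_name_parts$base, 1))
      smi <- fam$smiles[sample(nrow(fam), 1)]
      precursor <- paste0(sample(.corpus_name_parts$prefix, 1), "benzaldehyde")

      typo <- NA_character_
      for (cl in names(cfg$typo_rates)) {
        if (stats::runif(1) < cfg$typo_rates[[cl]]) { typo <- cl; break }
      }
      vk <- if (is.na(typo) && stats::runif(1) < cfg$spelled_out_fraction)
        "spelled" else kinds[(sec_i - 1L) %% 4L + 1L]
      decl <- .render_decl(cfg, vk, typo)
      explicit <- stats::runif(1) < 0.4

      # heading block
      head_txt <- sprintf("Example %d: Synthesis of %s", sec_i, name)
      blocks[[length(blocks) + 1L]] <- data.frame(
        kind = "heading", paragraph_number = NA_integer_, text = head_txt,
        stringsAsFactors = FALSE)
      hb <- length(blocks)
      st <- regexpr(name, head_txt, fixed = TRUE)[1] - 1L
      entities[[length(entities) + 1L]] <- data.frame(
        block_index = hb, start = st, end = st + nchar(name),
        smiles = smi, label = name, stringsAsFactors = FALSE)

      # paragraph block(s)
      par_no <- par_no + 1L
      p1 <- sprintf(paste0("To a stirred solution of %s (2.1 g) in ethanol ",
                           "(25 mL) was added sodium borohydride (0.4 g). "),
                    precursor)
      pre_start <- regexpr(precursor, p1, fixed = TRUE)[1] - 1L
      if (explicit) {
        tail_txt <- sprintf("Recrystallization from ethanol gave %s (%s) as a white solid, yield 74%%.",
                            name, decl$text)
      } else {
        tail_txt <- sprintf("Recrystallization from ethanol gave %s as a white solid, yield 74%%. %s.",
                            name, decl$text)
      }
      ptxt <- paste0(p1, tail_txt)
      blocks[[length(blocks) + 1L]] <- data.frame(
        kind = "paragraph", paragraph_number = par_no, text = ptxt,
        stringsAsFactors = FALSE)
      pb <- length(blocks)
      entities[[length(entities) + 1L]] <- data.frame(
        block_index = pb, start = pre_start, end = pre_start + nchar(precursor),
        smiles = NA_character_, label = precursor, stringsAsFactors = FALSE)
      nm_start <- nchar(p1) + regexpr(name, tail_txt, fixed = TRUE)[1] - 1L
      entities[[length(entities) + 1L]] <- data.frame(
        block_index = pb, start = nm_start, end = nm_start + nchar(name),
        smiles = smi, label = name, stringsAsFactors = FALSE)

      truth[[length(truth) + 1L]] <- data.frame(
        doc_id = doc_id, paragraph_number = par_no, label = name, smiles = smi,
        low_c = decl$truth$low_c, high_c = decl$truth$high_c,
        qualifier = decl$truth$qualifier, outcome = decl$truth$outcome,
        from_literature = decl$truth$from_literature,
        value_kind = decl$truth$value_kind,
        suspicious = decl$truth$suspicious,
        suspicious_reasons = decl$truth$suspicious_reasons,
        association_kind = if (explicit) "explicit" else "implicit",
        typo = typo, raw_decl = decl$text,
        stringsAsFactors = FALSE)
    }
    docs[[d]] <- annotated_document(
      doc_id = doc_id,
      blocks = do.call(rbind, c(blocks, list(make.row.names = FALSE))),
      entities = do.call(rbind, c(entities, list(make.row.names = FALSE))))
  }
  list(documents = docs,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
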