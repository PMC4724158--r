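# Shared fixtures, built in code.  Heavier shared objects are cached per
# test run so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A typo-free corpus configuration.
canonical_corpus_config <- function(n_sections, seed = 101) {
  corpus_config(
    n_sections = n_sections, seed = seed,
    typo_rates = c(missing_decimal = 0, comma_decimal = 0,
                   truncated_range = 0, inverted_range = 0, huge_value = 0),
    unit_mix = 0.05, spelled_out_fraction = 0.1)
}

# Rate-1.0 config for one error class.
typo_corpus_config <- function(class, n_sections = 150, seed = 103) {
  rates <- c(missing_decimal = 0, comma_decimal = 0, truncated_range = 0,
             inverted_range = 0, huge_value = 0)
  rates[class] <- 1.0
  corpus_config(n_sections = n_sections, seed = seed, typo_rates = rates,
                unit_mix = 0, spelled_out_fraction = 0)
}

# Align extracted records with the generator's truth table by provenance.
match_truth <- function(records, truth) {
  key <- function(d) paste(d$doc_id, d$paragraph_number)
  m <- match(key(truth), key(records))
  list(records = records[m, , drop = FALSE], truth = truth, matched = !is.na(m))
}

sorted_reasons <- function(s) {
  vapply(strsplit(s, ",", fixed = TRUE),
         function(x) paste(sort(x), collapse = ","), character(1))
}

# Record data frame from bare values (minimal columns for curation tests).
records_of <- function(values, smiles = "CCO", doc_id = NULL) {
  n <- length(values)
  data.frame(
    smiles = rep_len(smiles, n),
    low_c = values, high_c = values,
    qualifier = "none", outcome = "melt",
    suspicious = FALSE, suspicious_reasons = "",
    raw_text = sprintf("m.p. %s", values),
    doc_id = if (is.null(doc_id)) sprintf("US%03d", seq_len(n)) else doc_id,
    paragraph_number = seq_len(n),
    association_kind = "implicit",
    stringsAsFactors = FALSE)
}

# Small deterministic QSPR table for modeling tests.
small_qspr <- function() {
  fixture("small_qspr", function()
    generate_qspr(qspr_config(n_molecules = 800, duplicate_rate = 0,
                              outlier_rate = 0, seed = 71)))
}
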