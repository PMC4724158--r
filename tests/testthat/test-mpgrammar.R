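test_that("declaration forms from the grammar parse to the expected values", {
  cases <- list(
    list(txt = "m.p. 75 °C", kind = "single", v1 = 75, v2 = NULL,
         unit = "celsius", outcome = "melt"),
    list(txt = "melting point one hundred degrees Celsius", kind = "single",
         v1 = 100, v2 = NULL, unit = "celsius", outcome = "melt"),
    list(txt = "mp 184–186", kind = "range", v1 = 184, v2 = 186,
         unit = "celsius", outcome = "melt"),
    list(txt = "mpt 50 ± 1 °C", kind = "measurement_error",
         v1 = 50, v2 = 1, unit = "celsius", outcome = "melt"),
    list(txt = "m.p. 210 °C decomp.", kind = "single", v1 = 210,
         v2 = NULL, unit = "celsius", outcome = "decompose"),
    list(txt = "m.p. 200 °F", kind = "single", v1 = 200, v2 = NULL,
         unit = "fahrenheit", outcome = "melt"),
    list(txt = "mp 100 to 102 subl.", kind = "range", v1 = 100, v2 = 102,
         unit = "celsius", outcome = "sublime"))
  for (cs in cases) {
    m <- parse_mention(cs$txt)
    expect_false(is.null(m), info = cs$txt)
    expect_equal(m$value_kind, cs$kind, info = cs$txt)
    expect_equal(m$v1, cs$v1, info = cs$txt)
    if (is.null(cs$v2)) expect_null(m$v2, info = cs$txt)
    else expect_equal(m$v2, cs$v2, info = cs$txt)
    expect_equal(m$unit, cs$unit, info = cs$txt)
    expect_equal(m$outcome, cs$outcome, info = cs$txt)
  }
})

test_that("non-melting-point prefixes and prose do not match", {
  expect_null(parse_mention("boiling point 75 °C"))
  expect_null(parse_mention("the sample weighed 75 mg"))
  expect_null(parse_mention("melting point was not determined"))
})

test_that("qualifiers and literature markers are recognized", {
  expect_equal(parse_mention("mp >300 °C")$qualifier, "greater")
  expect_equal(parse_mention("mp ≤ 25 °C")$qualifier, "less")
  expect_equal(parse_mention("mp ca. 140")$qualifier, "approx")
  expect_equal(parse_mention("mp ~140")$qualifier, "approx")
  m <- parse_mention("lit. m.p. 101-102 °C")
  expect_true(m$from_literature)
  expect_equal(m$char_span[1], 0)
  expect_false(parse_mention("m.p. 101-102 °C")$from_literature)
})

test_that("parsing starts at the requested offset and finds later mentions", {
  txt <- "m.p. 75 °C; after drying m.p. 80 °C"
  first <- parse_mention(txt, 0L)
  second <- parse_mention(txt, first$char_span[2])
  expect_equal(first$v1, 75)
  expect_equal(second$v1, 80)
  expect_length(parse_mentions(txt), 2L)
})

test_that("char spans re-slice to text whose parse equals the original", {
  g <- generate_corpus(canonical_corpus_config(60, seed = 17))
  n_checked <- 0L
  for (doc in g$documents) {
    for (b in seq_len(nrow(doc$blocks))) {
      for (m in parse_mentions(doc$blocks$text[b])) {
        slice <- substr(doc$blocks$text[b], m$char_span[1] + 1L, m$char_span[2])
        expect_equal(slice, m$raw_text)
        m2 <- parse_mention(slice)
        expect_equal(m2$v1, m$v1)
        expect_equal(m2$value_kind, m$value_kind)
        expect_equal(m2$outcome, m$outcome)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 60L)
})

test_that("normalization converts errors to ranges and Fahrenheit to Celsius", {
  n <- normalize_mention(parse_mention("m.p. 75 °C"))
  expect_equal(c(n$low_c, n$high_c), c(75, 75))
  n <- normalize_mention(parse_mention("mp 50 ± 1 °C"))
  expect_equal(c(n$low_c, n$high_c), c(49, 51))
  # independent conversion oracle: C = (F - 32) * 5/9
  n <- normalize_mention(parse_mention("mp 200 °F"))
  expect_equal(n$low_c, (200 - 32) * 5 / 9, tolerance = 1e-12)
  expect_equal(round(n$low_c, 2), 93.33)
  # raw text retained verbatim
  expect_equal(n$raw_text, "mp 200 °F")
})

test_that("range repair borrows leading digits and fixes decimal commas", {
  expect_equal(repair_range("159", "62"), c(159, 162))
  expect_equal(repair_range("160", "2"), c(160, 162))
  expect_equal(repair_range("82", "82,5"), c(82, 82.5))
  expect_equal(repair_range("100", "100"), c(100, 100))
  # no borrowing can help: same digit count, left unchanged
  expect_equal(repair_range("186", "184"), c(186, 184))
  # borrowing would not reach the lower bound: unchanged
  expect_equal(repair_range("95", "2"), c(95, 2))
})

test_that("suspicious flags are exactly the triggered rules and values are untouched", {
  mk <- function(lo, hi) {
    structure(list(low_c = lo, high_c = hi, qualifier = "none",
                   outcome = "melt", suspicious = FALSE,
                   suspicious_reasons = character(0), raw_text = ""),
              class = "normalized_mp")
  }
  f <- flag_suspicious(mk(235, 2360))
  expect_setequal(f$suspicious_reasons, c("above_500", "range_over_50"))
  expect_equal(c(f$low_c, f$high_c), c(235, 2360))
  expect_setequal(flag_suspicious(mk(186, 184))$suspicious_reasons, "inverted_range")
  expect_setequal(flag_suspicious(mk(-383, -383))$suspicious_reasons,
                  "below_absolute_zero")
  clean <- flag_suspicious(mk(120, 122))
  expect_false(clean$suspicious)
  expect_length(clean$suspicious_reasons, 0)
  # property: reasons match predicates over a random grid
  set.seed(5)
  for (i in 1:200) {
    lo <- runif(1, -600, 600); hi <- lo + runif(1, -80, 80)
    r <- flag_suspicious(mk(lo, hi))$suspicious_reasons
    expect_equal("above_500" %in% r, max(lo, hi) > 500)
    expect_equal("range_over_50" %in% r, abs(hi - lo) > 50)
    expect_equal("inverted_range" %in% r, hi < lo)
    expect_equal("below_absolute_zero" %in% r, min(lo, hi) < -273.15)
  }
})

test_that("normalization is idempotent on degenerate intervals", {
  m <- parse_mention("mp 120-122")
  n <- normalize_mention(m)
  # re-flagging a flagged record changes nothing
  f1 <- flag_suspicious(n)
  f2 <- flag_suspicious(f1)
  expect_identical(f1, f2)
})

test_that("spelled-out cardinals convert both ways up to 999", {
  expect_equal(words_to_number("one hundred eighty-four"), 184)
  expect_equal(words_to_number("two hundred and five"), 205)
  expect_equal(words_to_number("ninety"), 90)
  expect_true(is.na(words_to_number("hundred")))
  for (v in c(1, 7, 15, 21, 99, 100, 101, 110, 250, 555, 999)) {
    expect_equal(words_to_number(number_to_words(v)), v, info = v)
  }
})
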