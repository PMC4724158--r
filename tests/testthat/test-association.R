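mk_doc <- function(kinds, texts = NULL, entities = NULL, doc_id = "DOC1") {
  n <- length(kinds)
  if (is.null(texts)) texts <- sprintf("block %d text", seq_len(n))
  pn <- ifelse(kinds == "paragraph", cumsum(kinds == "paragraph"), NA_integer_)
  annotated_document(doc_id,
    blocks = data.frame(kind = kinds, paragraph_number = pn, text = texts,
                        stringsAsFactors = FALSE),
    entities = entities)
}

test_that("sections partition blocks at headings", {
  doc <- mk_doc(c("heading", "paragraph", "paragraph", "heading", "paragraph"))
  s <- group_sections(doc)
  expect_length(s, 2)
  expect_equal(s[[1]]$heading, 1)
  expect_equal(s[[1]]$paragraphs, c(2, 3))
  expect_equal(s[[2]]$heading, 4)
  expect_equal(s[[2]]$paragraphs, 5)

  # degenerate: a single headingless paragraph forms one anonymous section
  s <- group_sections(mk_doc("paragraph"))
  expect_length(s, 1)
  expect_true(is.na(s[[1]]$heading))
  expect_equal(s[[1]]$paragraphs, 1)

  # consecutive headings: the first owns no paragraphs
  s <- group_sections(mk_doc(c("heading", "heading", "paragraph")))
  expect_length(s, 2)
  expect_equal(s[[1]]$paragraphs, integer(0))
  expect_equal(s[[2]]$paragraphs, 3)
})

test_that("a mention in a bracket after an entity binds explicitly", {
  txt <- "The product benzamide (m.p. 101-102 °C) was isolated."
  st <- regexpr("benzamide", txt, fixed = TRUE)[1] - 1L
  doc <- mk_doc(c("heading", "paragraph"),
                texts = c("Example 1", txt),
                entities = data.frame(block_index = 2L, start = st,
                                      end = st + 9L, smiles = "NC(=O)c1ccccc1",
                                      label = "benzamide", stringsAsFactors = FALSE))
  recs <- extract_records(doc)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$association_kind, "explicit")
  expect_equal(recs$smiles, "NC(=O)c1ccccc1")
  expect_equal(recs$low_c, 101)
  expect_equal(recs$high_c, 102)
  expect_equal(recs$paragraph_number, 1L)
})

test_that("end-of-section mentions bind implicitly to the section target", {
  head_txt <- "Example 3: Synthesis of phenol"
  p1 <- "Phenol was prepared from chlorobenzene."
  p2 <- "White needles, yield 80%. m.p. 40-42 °C."
  st <- regexpr("phenol", head_txt, fixed = TRUE)[1] - 1L
  doc <- mk_doc(c("heading", "paragraph", "paragraph"),
                texts = c(head_txt, p1, p2),
                entities = data.frame(block_index = 1L, start = st,
                                      end = st + 6L, smiles = "Oc1ccccc1",
                                      label = "phenol", stringsAsFactors = FALSE))
  recs <- extract_records(doc)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$association_kind, "implicit")
  expect_equal(recs$smiles, "Oc1ccccc1")
  # the mention sits in the final paragraph of the section
  expect_equal(recs$paragraph_number, 2L)
})

test_that("mentions without any candidate entity are reported with a reason", {
  doc <- mk_doc(c("heading", "paragraph"),
                texts = c("Example 9", "Colorless oil. m.p. 55 °C."))
  recs <- extract_records(doc)
  expect_equal(nrow(recs), 0)
  un <- attr(recs, "unassociated")
  expect_equal(nrow(un), 1)
  expect_equal(un$reason, "no candidate")
})

test_that("explicit association takes precedence over implicit", {
  # the mention is in the final paragraph AND bracketed after an entity
  head_txt <- "Example 4: Synthesis of aniline"
  txt <- "Reduction gave toluene (m.p. 90-91 °C) in high yield."
  hst <- regexpr("aniline", head_txt, fixed = TRUE)[1] - 1L
  tst <- regexpr("toluene", txt, fixed = TRUE)[1] - 1L
  doc <- mk_doc(c("heading", "paragraph"),
                texts = c(head_txt, txt),
                entities = data.frame(
                  block_index = c(1L, 2L), start = c(hst, tst),
                  end = c(hst + 7L, tst + 7L),
                  smiles = c("Nc1ccccc1", "Cc1ccccc1"),
                  label = c("aniline", "toluene"), stringsAsFactors = FALSE))
  recs <- extract_records(doc)
  expect_equal(recs$association_kind, "explicit")
  expect_equal(recs$smiles, "Cc1ccccc1")
})

test_that("ambiguous explicit candidates warn and bind to the nearest", {
  txt <- "From aniline and toluene (m.p. 90-91 °C)."
  s1 <- regexpr("aniline", txt, fixed = TRUE)[1] - 1L
  s2 <- regexpr("toluene", txt, fixed = TRUE)[1] - 1L
  doc <- mk_doc(c("heading", "paragraph"), texts = c("Example 5", txt),
                entities = data.frame(
                  block_index = 2L, start = c(s1, s2),
                  end = c(s1 + 7L, s2 + 7L),
                  smiles = c("Nc1ccccc1", "Cc1ccccc1"),
                  label = c("aniline", "toluene"), stringsAsFactors = FALSE))
  expect_warning(recs <- extract_records(doc), "candidates")
  expect_equal(recs$smiles, "Cc1ccccc1")
})

test_that("association recall and precision are 1 on the canonical corpus", {
  g <- fixture("assoc_corpus", function()
    generate_corpus(canonical_corpus_config(120, seed = 23)))
  recs <- extract_records(g$documents)
  expect_equal(nrow(recs), nrow(g$truth))       # precision: nothing extra
  al <- match_truth(recs, g$truth)
  expect_true(all(al$matched))                  # recall: everything found
  expect_equal(al$records$smiles, al$truth$smiles)
  expect_equal(al$records$association_kind, al$truth$association_kind)
})

test_that("records point at blocks containing the mention provenance", {
  g <- fixture("assoc_corpus", function()
    generate_corpus(canonical_corpus_config(120, seed = 23)))
  recs <- extract_records(g$documents)
  by_id <- setNames(g$documents, vapply(g$documents, `[[`, "", "doc_id"))
  for (i in seq_len(nrow(recs))) {
    doc <- by_id[[recs$doc_id[i]]]
    blk <- which(doc$blocks$paragraph_number == recs$paragraph_number[i])
    expect_length(blk, 1)
    expect_true(grepl(recs$raw_text[i], doc$blocks$text[blk], fixed = TRUE))
  }
})

test_that("documents survive a JSON round trip", {
  g <- generate_corpus(canonical_corpus_config(6, seed = 31))
  path <- withr::local_tempfile(fileext = ".json")
  write_documents(g$documents, path)
  back <- read_documents(path)
  expect_length(back, length(g$documents))
  r1 <- extract_records(g$documents)
  r2 <- extract_records(back)
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("records survive an SDF round trip with provenance fields", {
  g <- generate_corpus(canonical_corpus_config(8, seed = 37))
  recs <- extract_records(g$documents)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_records_sdf(recs, path)
  back <- read_records_sdf(path)
  expect_equal(nrow(back), nrow(recs))
  expect_equal(back$low_c, recs$low_c)
  expect_equal(back$high_c, recs$high_c)
  expect_equal(back$doc_id, recs$doc_id)
  expect_equal(back$outcome, recs$outcome)
  expect_equal(canonical_smiles(back$smiles), canonical_smiles(recs$smiles))
})
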