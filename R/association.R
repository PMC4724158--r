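# Association of melting-point mentions with chemical entities.  Documents
# arrive with pre-annotated entity spans (chemical NER is an input, not an
# implementation): headings and paragraphs are grouped into experimental
# sections, then each mention is bound either explicitly (inside a bracket
# following an entity) or implicitly (characterization tail of a section,
# bound to the section's synthesized target compound).

#' Construct an annotated document
#'
#' @param doc_id document identifier (e.g. a patent number).
#' @param blocks data frame with columns `kind` (`"heading"` or
#'   `"paragraph"`), `paragraph_number` (integer, `NA` for headings) and
#'   `text`, in document order.
#' @param entities data frame with columns `block_index` (1-based index
#'   into `blocks`), `start`, `end` (0-based half-open character span
#'   within the block's text), `smiles` (`NA` when the entity carries no
#'   structure) and `label`.
#' @return an object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, blocks, entities) {
  stopifnot(is.data.frame(blocks),
            all(c("kind", "paragraph_number", "text") %in% names(blocks)),
            all(blocks$kind %in% c("heading", "paragraph")))
  if (is.null(entities) || nrow(entities) == 0) {
    entities <- data.frame(block_index = integer(0), start = integer(0),
                           end = integer(0), smiles = character(0),
                           label = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(entities$block_index >= 1),
            all(entities$block_index <= nrow(blocks)))
  n_ok <- mapply(function(b, e) e <= nchar(blocks$text[b]),
                 entities$block_index, entities$end)
  if (!all(n_ok)) stop("entity span outside its block's text")
  pn <- blocks$paragraph_number[!is.na(blocks$paragraph_number)]
  if (anyDuplicated(pn)) stop("paragraph numbers must be unique within a document")
  structure(list(doc_id = doc_id, blocks = blocks, entities = entities),
            class = "annotated_document")
}

#' Group document blocks into experimental sections
#'
#' Each heading opens a section containing all following paragraphs until
#' the next heading; paragraphs before the first heading form one
#' anonymous section.
#'
#' @param doc an `annotated_document`.
#' @return a list of sections, each a list with `heading` (block index or
#'   `NA`) and `paragraphs` (integer vector of block indices).
#' @export
group_sections <- function(doc) {
  stopifnot(inherits(doc, "annotated_document"))
  kinds <- doc$blocks$kind
  sections <- list()
  cur <- NULL
  for (i in seq_along(kinds)) {
    if (kinds[i] == "heading") {
      if (!is.null(cur)) sections[[length(sections) + 1L]] <- cur
      cur <- list(heading = i, paragraphs = integer(0))
    } else {
      if (is.null(cur)) cur <- list(heading = NA_integer_, paragraphs = integer(0))
      cur$paragraphs <- c(cur$paragraphs, i)
    }
  }
  if (!is.null(cur)) sections[[length(sections) + 1L]] <- cur
  sections
}

# Position (0-based) of the opening bracket of the innermost bracketed group
# containing 0-based position `pos`, or NA.
.open_bracket_before <- function(text, pos) {
  if (pos <= 0) return(NA_integer_)
  chars <- strsplit(substr(text, 1, pos), "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in rev(seq_along(chars))) {
    if (chars[i] == ")") depth <- depth + 1L
    else if (chars[i] == "(") {
      if (depth == 0L) return(i - 1L)
      depth <- depth - 1L
    }
  }
  NA_integer_
}

# TRUE when the 0-based interval [from, to) of `text` contains a sentence
# boundary (terminator followed by whitespace and an upper-case letter or
# an opening bracket).
.sentence_break_between <- function(text, from, to) {
  if (to <= from) return(FALSE)
  seg <- substr(text, from + 1L, to)
  grepl("[.!?]\\s+[A-Z(]", seg)
}

#' Associate melting-point mentions with chemical entities in a section
#'
#' Binding is attempted in two ways, explicit association always taking
#' precedence.  (1) Explicit: a mention lying inside a bracketed group
#' whose opening bracket begins within `window` characters after the end
#' of a structure-bearing entity, in the same sentence, is bound to the
#' nearest such preceding entity (a warning is issued when several
#' candidates fall inside the window).  (2) Implicit: a remaining mention
#' in the final paragraph of the section is bound to the section's target
#' compound -- the last structure-bearing entity of the heading, or
#' failing that the first structure-bearing entity of the section.
#' Mentions that bind neither way are reported with a reason.
#'
#' @param doc an `annotated_document`.
#' @param section one element of [group_sections()].
#' @param window proximity window in characters for explicit binding.
#' @return list with `records` (data frame, one row per bound mention:
#'   normalized interval, flags, provenance and `association_kind`) and
#'   `unassociated` (data frame of mention spans with a `reason`).
#' @export
associate_section <- function(doc, section, window = 80) {
  stopifnot(inherits(doc, "annotated_document"))
  blocks <- section$paragraphs
  recs <- list()
  unas <- list()
  ent <- doc$entities
  ent <- ent[!is.na(ent$smiles) & nzchar(ent$smiles), , drop = FALSE]

  target <- NA_integer_  # row index into ent
  if (!is.na(section$heading)) {
    in_head <- which(ent$block_index == section$heading)
    if (length(in_head)) target <- in_head[length(in_head)]
  }
  if (is.na(target)) {
    in_sec <- which(ent$block_index %in% c(section$heading, blocks))
    if (length(in_sec)) target <- in_sec[1]
  }

  last_par <- if (length(blocks)) blocks[length(blocks)] else NA_integer_
  for (b in blocks) {
    text <- doc$blocks$text[b]
    mentions <- parse_mentions(text)
    for (m in mentions) {
      bound <- FALSE
      # explicit: bracketed group shortly after an entity
      br <- .open_bracket_before(text, m$char_span[1])
      if (!is.na(br)) {
        cand <- which(ent$block_index == b & ent$end <= br &
                        br - ent$end <= window)
        cand <- cand[!vapply(cand, function(j)
          .sentence_break_between(text, ent$end[j], br), logical(1))]
        if (length(cand) > 1L) {
          warning(sprintf(
            "%s: %d explicit candidates within window for mention at [%d,%d); binding to nearest",
            doc$doc_id, length(cand), m$char_span[1], m$char_span[2]))
        }
        if (length(cand)) {
          j <- cand[which.max(ent$end[cand])]
          recs[[length(recs) + 1L]] <- .mention_record(doc, b, m, ent$smiles[j], "explicit")
          bound <- TRUE
        }
      }
      if (!bound && !is.na(last_par) && b == last_par && !is.na(target)) {
        recs[[length(recs) + 1L]] <-
          .mention_record(doc, b, m, ent$smiles[target], "implicit")
        bound <- TRUE
      }
      if (!bound) {
        reason <- if (is.na(target)) "no candidate" else "not in final paragraph"
        unas[[length(unas) + 1L]] <- data.frame(
          doc_id = doc$doc_id, block_index = b,
          start = m$char_span[1], end = m$char_span[2],
          raw_text = m$raw_text, reason = reason, stringsAsFactors = FALSE)
      }
    }
  }
  list(records = .rbind_or_empty(recs, .empty_records()),
       unassociated = .rbind_or_empty(unas, data.frame(
         doc_id = character(0), block_index = integer(0), start = integer(0),
         end = integer(0), raw_text = character(0), reason = character(0),
         stringsAsFactors = FALSE)))
}

.mention_record <- function(doc, block_index, m, smiles, kind) {
  n <- flag_suspicious(normalize_mention(m))
  data.frame(
    smiles = smiles,
    low_c = n$low_c, high_c = n$high_c,
    qualifier = n$qualifier, outcome = n$outcome,
    suspicious = n$suspicious,
    suspicious_reasons = paste(n$suspicious_reasons, collapse = ","),
    raw_text = n$raw_text,
    doc_id = doc$doc_id,
    paragraph_number = doc$blocks$paragraph_number[block_index],
    association_kind = kind,
    stringsAsFactors = FALSE
  )
}

.empty_records <- function() {
  data.frame(smiles = character(0), low_c = numeric(0), high_c = numeric(0),
             qualifier = character(0), outcome = character(0),
             suspicious = logical(0), suspicious_reasons = character(0),
             raw_text = character(0), doc_id = character(0),
             paragraph_number = integer(0), association_kind = character(0),
             stringsAsFactors = FALSE)
}

.rbind_or_empty <- function(lst, empty) {
  if (!length(lst)) empty else do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

#' Extract compound/melting-point records from annotated documents
#'
#' Runs section grouping, mention parsing, normalization, repair,
#' suspicious-value flagging and entity association over one document or a
#' list of documents.
#'
#' @param docs an `annotated_document` or list of them.
#' @param window proximity window for explicit association, in characters.
#' @return a record data frame; unbound mentions are attached as the
#'   `"unassociated"` attribute.
#' @export
extract_records <- function(docs, window = 80) {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  recs <- list(); unas <- list()
  for (doc in docs) {
    for (sec in group_sections(doc)) {
      r <- associate_section(doc, sec, window = window)
      if (nrow(r$records)) recs[[length(recs) + 1L]] <- r$records
      if (nrow(r$unassociated)) unas[[length(unas) + 1L]] <- r$unassociated
    }
  }
  out <- .rbind_or_empty(recs, .empty_records())
  attr(out, "unassociated") <- .rbind_or_empty(unas, data.frame(
    doc_id = character(0), block_index = integer(0), start = integer(0),
    end = integer(0), raw_text = character(0), reason = character(0),
    stringsAsFactors = FALSE))
  out
}

#' Read / write annotated documents as JSON
#'
#' Plain-JSON serialization of the document schema used by
#' [extract_records()].
#'
#' @param docs list of `annotated_document` objects.
#' @param path file path.
#' @return `read_documents` returns a list of `annotated_document`s.
#' @export
write_documents <- function(docs, path) {
  if (inherits(docs, "annotated_document")) docs <- list(docs)
  payload <- lapply(docs, function(d)
    list(doc_id = d$doc_id, blocks = d$blocks, entities = d$entities))
  jsonlite::write_json(payload, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_documents
#' @export
read_documents <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  field <- function(rows, name, cast, default) {
    cast(vapply(rows, function(r)
      if (is.null(r[[name]])) default else r[[name]],
      vector(mode = mode(default), length = 1)))
  }
  lapply(payload, function(d) {
    blk <- d$blocks
    ent <- d$entities
    annotated_document(
      doc_id = d$doc_id,
      blocks = data.frame(
        kind = field(blk, "kind", as.character, NA_character_),
        paragraph_number = field(blk, "paragraph_number", as.integer, NA_real_),
        text = field(blk, "text", as.character, NA_character_),
        stringsAsFactors = FALSE),
      entities = if (length(ent)) data.frame(
        block_index = field(ent, "block_index", as.integer, NA_real_),
        start = field(ent, "start", as.integer, NA_real_),
        end = field(ent, "end", as.integer, NA_real_),
        smiles = field(ent, "smiles", as.character, NA_character_),
        label = field(ent, "label", as.character, NA_character_),
        stringsAsFactors = FALSE) else NULL)
  })
}
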