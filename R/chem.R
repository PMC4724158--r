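# Structure handling: canonicalization, component counting and SDF
# serialization are delegated to ChemmineR / ChemmineOB (Open Babel).

#' Canonical SMILES
#'
#' Canonicalizes a vector of SMILES strings with Open Babel.  Invalid
#' strings yield `NA`.  The canonical string is used throughout the
#' package as the molecule key for deduplication and grouping.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  conv <- function(x) {
    res <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste(x, collapse = "\n"))
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    sub("\t.*$", "", lines)
  }
  got <- tryCatch(conv(smiles[ok]), error = function(e) character(0))
  if (length(got) == sum(ok)) {
    out[ok] <- got
  } else {
    # Open Babel drops invalid entries from batch output; fall back to
    # one-at-a-time conversion to keep the alignment.
    idx <- which(ok)
    for (i in idx) {
      gi <- tryCatch(conv(smiles[i]), error = function(e) character(0))
      out[i] <- if (length(gi) == 1L && nzchar(gi)) gi else NA_character_
    }
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Number of connected components of a SMILES string
#'
#' In SMILES the dot is the disconnection operator, so the number of
#' connected components is one more than the number of dots.
#'
#' @param smiles character vector of SMILES.
#' @return integer vector of component counts.
#' @export
n_components <- function(smiles) {
  lengths(strsplit(as.character(smiles), ".", fixed = TRUE))
}

#' Serialize compound melting-point records to SDF
#'
#' Writes one SDF entry per record with the property fields `MP_RAW`,
#' `MP_LOW_C`, `MP_HIGH_C`, `OUTCOME`, `QUALIFIER`, `SUSPICIOUS`,
#' `PATENT_ID` and `PARAGRAPH_NUM`, so extracted data can be related back
#' to its location in the source document.
#'
#' @param records a record data frame as produced by [extract_records()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_records_sdf <- function(records, file) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(records$smiles))
  ChemmineR::cid(sdf) <- make.unique(as.character(ChemmineR::cid(sdf)), sep = "_")
  ChemmineR::datablock(sdf) <- lapply(seq_len(nrow(records)), function(i) c(
    MP_RAW = as.character(records$raw_text[i]),
    MP_LOW_C = as.character(records$low_c[i]),
    MP_HIGH_C = as.character(records$high_c[i]),
    OUTCOME = as.character(records$outcome[i]),
    QUALIFIER = as.character(records$qualifier[i]),
    SUSPICIOUS = as.character(as.integer(records$suspicious[i])),
    PATENT_ID = as.character(records$doc_id[i]),
    PARAGRAPH_NUM = as.character(records$paragraph_number[i])
  ))
  ChemmineR::write.SDF(sdf, file)
  invisible(file)
}

#' Read compound melting-point records from SDF
#'
#' Inverse of [write_records_sdf()].
#'
#' @param file SDF path.
#' @return a record data frame.
#' @export
read_records_sdf <- function(file) {
  sdf <- ChemmineR::read.SDFset(file)
  smi <- vapply(seq_along(sdf), function(i)
    as.character(ChemmineR::sdf2smiles(sdf[i])), character(1))
  blocks <- ChemmineR::datablock2ma(ChemmineR::datablock(sdf))
  df <- as.data.frame(blocks, stringsAsFactors = FALSE)
  data.frame(
    smiles = smi,
    low_c = as.numeric(df$MP_LOW_C),
    high_c = as.numeric(df$MP_HIGH_C),
    qualifier = df$QUALIFIER,
    outcome = df$OUTCOME,
    suspicious = df$SUSPICIOUS == "1",
    raw_text = df$MP_RAW,
    doc_id = df$PATENT_ID,
    paragraph_number = suppressWarnings(as.integer(df$PARAGRAPH_NUM)),
    stringsAsFactors = FALSE
  )
}
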