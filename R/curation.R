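# Curation of extracted records into a modeling-ready dataset: exclusion of
# suspicious values and mixtures, transitive duplicate elimination at
# |dT| <= 1 degree C, and selection of one representative record per molecule
# near the median of its distinct measurements.

.record_midpoint <- function(records) (records$low_c + records$high_c) / 2

#' Exclude suspicious records, mixtures and unparsable structures
#'
#' Drops records carrying the suspicious-value flag, structures with more
#' than one connected component (mixtures), and SMILES that fail to parse.
#' A `mol_key` column holding the canonical SMILES is added to the
#' retained records so downstream grouping does not re-canonicalize.
#'
#' @param records record data frame (needs `smiles`, `suspicious`).
#' @return list with `records` (retained rows, plus `mol_key`) and
#'   `counts` (`input`, `suspicious_excluded`, `mixtures_excluded`,
#'   `invalid_excluded`, `retained`).
#' @export
exclude_suspicious_and_mixtures <- function(records) {
  stopifnot(is.data.frame(records))
  n_in <- nrow(records)
  susp <- as.logical(records$suspicious)
  records1 <- records[!susp, , drop = FALSE]
  mix <- n_components(records1$smiles) > 1L
  records2 <- records1[!mix, , drop = FALSE]
  key <- canonical_smiles(records2$smiles)
  bad <- is.na(key)
  out <- records2[!bad, , drop = FALSE]
  out$mol_key <- key[!bad]
  list(records = out,
       counts = list(input = n_in,
                     suspicious_excluded = sum(susp),
                     mixtures_excluded = sum(mix),
                     invalid_excluded = sum(bad),
                     retained = nrow(out)))
}

# Single-linkage clusters of sorted values with gap <= delta_t; returns an
# integer cluster id per element of `values` (original order).
.chain_clusters <- function(values, delta_t) {
  ord <- order(values)
  cl_sorted <- cumsum(c(1, diff(values[ord]) > delta_t))
  cl <- integer(length(values))
  cl[ord] <- cl_sorted
  cl
}

#' Eliminate duplicate measurements and pick representative records
#'
#' Within each molecule (canonical-SMILES key), measurement midpoints are
#' merged transitively whenever two values differ by at most `delta_t`
#' degrees C; such merged values are considered full duplicates and only
#' the first-seen record of each cluster is retained.  The remaining
#' distinct values are the molecule's multiple measurements; the single
#' representative record is the one whose midpoint lies nearest their
#' median (even count: mean of the two central values).  Ties are broken
#' toward the lower temperature, then the earlier `doc_id`, so the result
#' is deterministic.  The representative keeps its provenance fields,
#' preserving the link to the originating document.
#'
#' @param records record data frame; a `mol_key` column is used as the
#'   molecule key when present, otherwise canonical SMILES are computed.
#' @param delta_t full-duplicate threshold in degrees C.
#' @return an object of class `curated_dataset`: list with `records` (one
#'   representative per molecule), `groups` (named list of distinct
#'   midpoints per molecule), and `counts`.
#' @export
deduplicate <- function(records, delta_t = 1.0) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(structure(list(records = records, groups = list(),
                          counts = list(input = 0, duplicates_eliminated = 0,
                                        molecules = 0)),
                     class = "curated_dataset"))
  }
  key <- if ("mol_key" %in% names(records)) records$mol_key
         else canonical_smiles(records$smiles)
  mid <- .record_midpoint(records)
  reps <- integer(0)
  groups <- list()
  dup_elim <- 0L
  idx_by_key <- split(seq_along(key), factor(key, levels = unique(key)))
  for (k in names(idx_by_key)) {
    idx <- idx_by_key[[k]]           # first-seen order
    cl <- .chain_clusters(mid[idx], delta_t)
    keep <- vapply(split(seq_along(idx), cl), `[`, integer(1), 1L)
    keep <- keep[order(keep)]
    kept_idx <- idx[keep]
    dup_elim <- dup_elim + length(idx) - length(kept_idx)
    vals <- mid[kept_idx]
    med <- stats::median(vals)
    d <- abs(vals - med)
    cand <- which(d == min(d))
    if (length(cand) > 1L) {
      cand <- cand[order(vals[cand], records$doc_id[kept_idx][cand])][1]
    }
    reps <- c(reps, kept_idx[cand])
    groups[[k]] <- vals
  }
  structure(list(
    records = records[reps, , drop = FALSE],
    groups = groups,
    counts = list(input = nrow(records),
                  duplicates_eliminated = dup_elim,
                  molecules = length(groups))
  ), class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("<curated_dataset> %d molecules from %d records (%d duplicates eliminated)\n",
              x$counts$molecules, x$counts$input, x$counts$duplicates_eliminated))
  invisible(x)
}

#' Absolute pairwise differences of repeated measurements
#'
#' Emits |difference| for every pair of distinct retained measurements of
#' the same molecule; these drive the experimental-accuracy estimate.
#'
#' @param groups named list of distinct measurement values per molecule
#'   (the `groups` field of a [deduplicate()] result).
#' @return numeric vector of absolute pairwise differences.
#' @seealso [duplicate_pairs()] for the (midpoint, difference) pairs used
#'   by the temperature-binned accuracy curve.
#' @export
pairwise_differences <- function(groups) {
  unlist(lapply(groups, function(v) {
    if (length(v) < 2L) return(numeric(0))
    as.numeric(abs(utils::combn(v, 2, FUN = diff)))
  }), use.names = FALSE)
}

#' Pair means and differences of repeated measurements
#'
#' For every pair of distinct measurements of a molecule, returns the pair
#' mean (the temperature at which the disagreement was observed) and the
#' absolute difference.
#'
#' @inheritParams pairwise_differences
#' @return data frame with columns `midpoint` and `delta_t`.
#' @export
duplicate_pairs <- function(groups) {
  out <- lapply(groups, function(v) {
    if (length(v) < 2L) return(NULL)
    cmb <- utils::combn(v, 2)
    data.frame(midpoint = colMeans(cmb), delta_t = abs(cmb[2, ] - cmb[1, ]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(data.frame(midpoint = numeric(0), delta_t = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Drug-like subset of records
#'
#' Keeps records whose interval midpoint lies in the closed interval
#' `[low, high]` degrees C; the default 50--250 degrees C band covers the
#' melting points of about 90 percent of pharmaceutical compounds.
#'
#' @param records record data frame.
#' @param low,high interval bounds in degrees C (closed on both ends).
#' @return the retained rows.
#' @export
drug_like_subset <- function(records, low = 50, high = 250) {
  mid <- .record_midpoint(records)
  records[mid >= low & mid <= high, , drop = FALSE]
}
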