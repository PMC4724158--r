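# Hypergeometric over/under-representation of structural features between a
# subset of records (e.g. compounds that decompose on melting) and the whole
# population.  Feature incidence is binary per molecule, as the
# hypergeometric model requires.

#' Hypergeometric feature enrichment between a subset and its population
#'
#' For each feature with `K` carriers among `N` population records and `k`
#' carriers among the `n` subset records, reports the fold change
#' `(k/n) / (K/N)` and the upper-tail hypergeometric probability of
#' observing at least `k` carriers in `n` draws without replacement.
#' Benjamini-Hochberg q-values are attached; raw p-values are always
#' retained.  Results are sorted by p-value.
#'
#' @param features logical (or 0/1) matrix, records x features, with
#'   column names; incidence is presence, not count.
#' @param subset logical mask over rows (or integer row indices) defining
#'   the subset.
#' @return data frame with columns `feature`, `k`, `n`, `K`, `N`, `fold`,
#'   `p_value`, `q_value`.
#' @export
set_compare <- function(features, subset) {
  features <- as.matrix(features)
  storage.mode(features) <- "logical"
  N <- nrow(features)
  if (is.logical(subset)) {
    stopifnot(length(subset) == N)
    subset <- which(subset)
  }
  if (length(subset) > N) stop("subset larger than population")
  stopifnot(all(subset >= 1), all(subset <= N))
  n <- length(subset)
  K <- colSums(features)
  k <- colSums(features[subset, , drop = FALSE])
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- (k / n) / (K / N)
  out <- data.frame(feature = colnames(features), k = as.integer(k), n = n,
                    K = as.integer(K), N = N, fold = fold, p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Starter SMARTS feature set for decomposition analysis
#'
#' Substructure patterns for the functional groups most associated with
#' thermal decomposition during melting-point determination: carboxylic,
#' phosphonic and alpha-amino acids, primary amines, tetrazoles and
#' nitroso groups.
#'
#' @return named character vector of SMARTS patterns.
#' @export
mp_feature_smarts <- function() {
  c(carboxylic_acid = "[CX3](=O)[OX2H1]",
    phosphonic_acid = "[PX4](=O)([OX2H1])[OX2H1]",
    alpha_amino_acid = "[NX3;H2,H1][CX4][CX3](=O)[OX2H1]",
    primary_amine = "[NX3;H2][CX4]",
    tetrazole = "c1nnn[nH]1",
    nitroso = "[NX2]=[OX1]")
}

#' Binary feature-incidence matrix from SMARTS patterns
#'
#' Matches each pattern against each structure with Open Babel's SMARTS
#' engine.
#'
#' @param smiles character vector of SMILES.
#' @param smarts named character vector of SMARTS patterns
#'   (default [mp_feature_smarts()]).
#' @return logical matrix, molecules x features.
#' @export
feature_matrix <- function(smiles, smarts = mp_feature_smarts()) {
  stopifnot(length(smiles) > 0, length(smarts) > 0, !is.null(names(smarts)))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  out <- vapply(smarts, function(pat)
    ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = FALSE) > 0,
    logical(length(smiles)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(smiles),
                                       dimnames = list(NULL, names(smarts)))
  rownames(out) <- smiles
  out
}
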