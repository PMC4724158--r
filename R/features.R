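# QNPR descriptors: counts of fixed-length character substrings of the
# SMILES line notation, held as a sparse molecule x descriptor matrix
# (Matrix::dgCMatrix).  Splitting is literal, character by character; the
# SMILES should be canonicalized upstream so that descriptors are
# reproducible across depositions of the same structure.

#' QNPR (SMILES-substring) descriptors
#'
#' One column per contiguous substring of length `min_len` to `max_len`
#' occurring in at least `min_freq` molecules of the dataset; the cell
#' value is the (overlapping) occurrence count of the substring in that
#' molecule's SMILES string.
#'
#' @param smiles_list character vector of SMILES (canonical recommended).
#' @param min_len,max_len substring length bounds, in characters.
#' @param min_freq minimum number of molecules containing a substring for
#'   its column to be kept.
#' @return a sparse `dgCMatrix` (molecules x substrings) with the SMILES
#'   as row names and substrings as column names.
#' @export
qnpr_descriptors <- function(smiles_list, min_len = 1, max_len = 3, min_freq = 5) {
  smiles_list <- as.character(smiles_list)
  n <- length(smiles_list)
  if (!n) stop("empty dataset")
  per_mol <- lapply(smiles_list, function(s) {
    nc <- nchar(s)
    subs <- unlist(lapply(min_len:max_len, function(L) {
      if (nc < L) return(character(0))
      starts <- seq_len(nc - L + 1L)
      substring(s, starts, starts + L - 1L)
    }))
    if (!length(subs)) return(integer(0))
    tab <- table(subs)
    stats::setNames(as.integer(tab), names(tab))
  })
  # molecule frequency per substring (presence, not total occurrences)
  molfreq <- table(unlist(lapply(per_mol, names)))
  keep <- sort(names(molfreq)[as.integer(molfreq) >= min_freq])
  if (!length(keep)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, 0),
                                dimnames = list(smiles_list, character(0))))
  }
  ijx <- lapply(seq_len(n), function(i) {
    v <- per_mol[[i]]
    j <- match(names(v), keep)
    ok <- !is.na(j)
    list(i = rep.int(i, sum(ok)), j = j[ok], x = as.numeric(v[ok]))
  })
  Matrix::sparseMatrix(
    i = unlist(lapply(ijx, `[[`, "i")),
    j = unlist(lapply(ijx, `[[`, "j")),
    x = unlist(lapply(ijx, `[[`, "x")),
    dims = c(n, length(keep)),
    dimnames = list(smiles_list, keep))
}

#' Sparseness of a descriptor matrix
#'
#' Average number of zero entries per non-zero entry.
#'
#' @param X a matrix or sparse `Matrix`.
#' @return `(nrow * ncol - nnz) / nnz`.
#' @export
sparseness <- function(X) {
  nnz <- sum(X != 0)
  if (nnz == 0) stop("all-zero matrix")
  (prod(dim(X)) - nnz) / nnz
}

#' Unsupervised descriptor filtering
#'
#' Two target-blind steps applied before modeling: descriptors with
#' `max_nonzero` or fewer non-zero values over the whole set are
#' eliminated, and descriptors inter-correlated with a squared linear
#' correlation above `r2_threshold` are grouped, keeping only the first
#' column (in column order) of each group.  Grouping is greedy: scanning
#' left to right, a column joins the first existing group whose
#' representative it correlates with above the threshold, otherwise it
#' founds a new group.  No target property is consulted, so the selection
#' introduces no bias toward chance correlations.
#'
#' @param X descriptor matrix (dense or sparse), at least 2 rows.
#' @param max_nonzero columns with at most this many non-zero entries are
#'   dropped.
#' @param r2_threshold squared-correlation threshold for grouping.
#' @return list with `X` (the filtered matrix), `group_map` (named
#'   character vector mapping each dropped column to the kept
#'   representative of its group), and `dropped_sparse` (names of columns
#'   removed by the non-zero-count rule).
#' @export
unsupervised_filter <- function(X, max_nonzero = 2, r2_threshold = 0.95) {
  stopifnot(nrow(X) >= 2)
  nz <- Matrix::colSums(X != 0)
  dropped_sparse <- colnames(X)[nz <= max_nonzero]
  X <- X[, nz > max_nonzero, drop = FALSE]
  p <- ncol(X)
  if (p <= 1L) {
    return(list(X = X, group_map = stats::setNames(character(0), character(0)),
                dropped_sparse = dropped_sparse))
  }
  n <- nrow(X)
  mu <- Matrix::colMeans(X)
  xtx <- as.matrix(Matrix::crossprod(X))
  cov <- (xtx - n * tcrossprod(mu)) / (n - 1)
  sd <- sqrt(pmax(diag(cov), 0))
  denom <- tcrossprod(sd)
  cc <- ifelse(denom > 0, cov / denom, 0)
  r2 <- cc^2

  reps <- integer(0)                     # representative column indices
  group_of <- integer(p)
  for (j in seq_len(p)) {
    hit <- if (length(reps)) which(r2[j, reps] > r2_threshold) else integer(0)
    if (length(hit)) {
      group_of[j] <- hit[1]
    } else {
      reps <- c(reps, j)
      group_of[j] <- length(reps)
    }
  }
  kept <- reps
  dropped <- setdiff(seq_len(p), kept)
  group_map <- stats::setNames(colnames(X)[kept[group_of[dropped]]],
                               colnames(X)[dropped])
  list(X = X[, kept, drop = FALSE], group_map = group_map,
       dropped_sparse = dropped_sparse)
}

#' Write / read a sparse descriptor matrix as MatrixMarket
#'
#' The matrix is stored as an `.mtx` file plus two plain-text sidecars
#' (`<file>.cols`, `<file>.rows`) holding the column and row names.
#'
#' @param X sparse descriptor matrix.
#' @param file path of the `.mtx` file.
#' @return `file` (write) or the matrix with dimnames restored (read).
#' @export
write_descriptors_mtx <- function(X, file) {
  Matrix::writeMM(methods::as(methods::as(X, "generalMatrix"), "TsparseMatrix"), file)
  writeLines(colnames(X), paste0(file, ".cols"))
  writeLines(rownames(X), paste0(file, ".rows"))
  invisible(file)
}

#' @rdname write_descriptors_mtx
#' @export
read_descriptors_mtx <- function(file) {
  X <- methods::as(Matrix::readMM(file), "CsparseMatrix")
  dimnames(X) <- list(readLines(paste0(file, ".rows")),
                      readLines(paste0(file, ".cols")))
  X
}
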