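# Experimental reproducibility of repeated melting-point measurements.
# Two independent measurements of the same quantity with per-measurement
# standard deviation sigma differ with variance 2 sigma^2, so sigma is
# estimated from absolute pairwise differences as sqrt(mean(dT^2) / 2).
# The duplicate-elimination step removes pairs with |dT| <= 1 degree C, which
# hollows out the first two histogram bins; the bin correction refills them
# before re-estimating.

#' Estimate measurement reproducibility from pairwise differences
#'
#' @param diffs numeric vector of absolute pairwise differences between
#'   repeated measurements of the same molecules.
#' @return sigma of a single measurement (degrees C), assuming two
#'   independent equal-variance measurements per pair:
#'   `sqrt(mean(diffs^2) / 2)`.
#' @export
estimate_sigma <- function(diffs) {
  if (!length(diffs)) stop("no repeated measurements")
  sqrt(mean(diffs^2) / 2)
}

#' Integer-binned histogram of absolute differences
#'
#' Bin `b` collects differences in `[b, b + 1)`.
#'
#' @param diffs numeric vector of absolute differences.
#' @return named integer vector of counts; names are the bin lower edges.
#' @export
delta_histogram <- function(diffs) {
  if (!length(diffs)) stop("no repeated measurements")
  stopifnot(all(diffs >= 0))
  b <- floor(diffs)
  tab <- table(factor(b, levels = 0:max(b)))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Sigma implied by a binned difference histogram
#'
#' Each bin contributes at its center (`b + 0.5`).
#'
#' @param histogram named count vector as from [delta_histogram()].
#' @return sigma in degrees C.
#' @export
histogram_sigma <- function(histogram) {
  counts <- as.numeric(histogram)
  if (sum(counts) <= 0) stop("empty histogram")
  centers <- as.numeric(names(histogram)) + 0.5
  sqrt(sum(counts * centers^2) / sum(counts) / 2)
}

#' Bin-corrected sigma
#'
#' Duplicate elimination removes same-molecule pairs differing by at most
#' 1 degree C, depleting the dT = 0 and dT = 1 bins.  The correction
#' replaces the counts of bins 0 and 1 each with the mean count observed
#' for the dT in [2, 3] interval (bins 2 and 3), then recomputes sigma
#' from the corrected histogram.
#'
#' @param histogram named count vector as from [delta_histogram()].
#' @return corrected sigma in degrees C.  If bins 2 and 3 are both empty
#'   the correction is skipped with a warning and the uncorrected
#'   histogram sigma is returned.
#' @export
corrected_sigma <- function(histogram) {
  counts <- as.numeric(histogram)
  bins <- as.numeric(names(histogram))
  c23 <- counts[bins %in% c(2, 3)]
  if (!length(c23) || sum(c23) == 0) {
    warning("bins 2 and 3 empty; correction skipped")
    return(histogram_sigma(histogram))
  }
  fill <- mean(c23)
  corrected <- counts
  for (b in c(0, 1)) {
    i <- which(bins == b)
    if (length(i)) corrected[i] <- fill
    else { corrected <- c(fill, corrected); bins <- c(b, bins) }
  }
  names(corrected) <- bins
  histogram_sigma(corrected)
}

#' Full experimental-accuracy estimate
#'
#' Convenience wrapper returning the raw and bin-corrected sigma for a set
#' of pairwise differences.
#'
#' @inheritParams estimate_sigma
#' @return object of class `accuracy_estimate`: list with `sigma_raw`,
#'   `sigma_corrected`, `n_pairs` and `histogram`.
#' @export
accuracy_estimate <- function(diffs) {
  h <- delta_histogram(diffs)
  structure(list(
    sigma_raw = estimate_sigma(diffs),
    sigma_corrected = corrected_sigma(h),
    n_pairs = length(diffs),
    histogram = h
  ), class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("<accuracy_estimate> sigma = %.1f C (raw), %.1f C (bin-corrected), n = %d pairs\n",
              x$sigma_raw, x$sigma_corrected, x$n_pairs))
  invisible(x)
}

#' Temperature-binned accuracy curve
#'
#' Reproducibility as a function of the melting point itself: duplicate
#' pairs are sorted by their pair mean and grouped into adaptive
#' equal-count bins of at least `min_count` pairs; a per-bin sigma is
#' computed from the differences.  Optionally the curve is rescaled by a
#' single global factor so that its count-weighted mean sigma equals
#' `rescale_to`.  Pairs with a mean below 0 degrees C are excluded by
#' default, as sub-zero melting points in mined data are dominated by
#' processing errors.
#'
#' @param pairs data frame with columns `midpoint` and `delta_t`
#'   (see [duplicate_pairs()]).
#' @param min_count minimum number of pairs per bin.
#' @param rescale_to optional target for the count-weighted mean sigma.
#' @param exclude_below_zero drop pairs with `midpoint < 0` first.
#' @return object of class `binned_accuracy`: list with `bin_centers`,
#'   `sigma_per_bin`, `counts` and `min_bin_count`.
#' @export
binned_accuracy <- function(pairs, min_count = 50, rescale_to = NULL,
                            exclude_below_zero = TRUE) {
  stopifnot(is.data.frame(pairs), all(c("midpoint", "delta_t") %in% names(pairs)))
  if (exclude_below_zero) pairs <- pairs[pairs$midpoint >= 0, , drop = FALSE]
  n <- nrow(pairs)
  if (!n) stop("no pairs")
  ord <- order(pairs$midpoint)
  k <- max(1L, n %/% as.integer(min_count))
  bin <- ceiling(seq_len(n) / (n / k))
  mids <- split(pairs$midpoint[ord], bin)
  dts <- split(pairs$delta_t[ord], bin)
  centers <- vapply(mids, mean, numeric(1))
  sigmas <- vapply(dts, function(d) sqrt(mean(d^2) / 2), numeric(1))
  counts <- vapply(dts, length, integer(1))
  if (!is.null(rescale_to)) {
    sigmas <- sigmas * rescale_to / stats::weighted.mean(sigmas, counts)
  }
  structure(list(bin_centers = unname(centers),
                 sigma_per_bin = unname(sigmas),
                 counts = unname(counts),
                 min_bin_count = min_count),
            class = "binned_accuracy")
}

#' @export
print.binned_accuracy <- function(x, ...) {
  cat(sprintf("<binned_accuracy> %d bins (>= %d pairs each), sigma %.1f-%.1f C\n",
              length(x$bin_centers), x$min_bin_count,
              min(x$sigma_per_bin), max(x$sigma_per_bin)))
  invisible(x)
}
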