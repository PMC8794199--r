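# The pipeline's central object: individuals x markers minor-parent dosage.

#' Construct an ancestry matrix
#'
#' Individuals x markers matrix of diploid minor-parent dosage (0, 1, 2, or
#' `NA` for masked/uncalled), with the marker set that labels the columns and
#' optionally the per-entry three-state posterior probabilities from which
#' hard calls were derived.
#'
#' @param dosage integer matrix, rows = individuals, columns = markers;
#'   entries in `{0, 1, 2, NA}`.
#' @param markers a [marker_set()] with one row per column of `dosage`.
#' @param posteriors optional numeric array `dim = c(n, m, 3)` of posterior
#'   probabilities for dosage states 0/1/2; each triple must sum to 1.
#' @return object of class `ancestry_matrix`.
#' @export
ancestry_matrix <- function(dosage, markers, posteriors = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!inherits(markers, "marker_set")) markers <- marker_set(markers)
  if (ncol(dosage) != nrow(markers))
    stop("dosage has ", ncol(dosage), " columns but markers has ",
         nrow(markers), " rows")
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(posteriors)) {
    stopifnot(length(dim(posteriors)) == 3,
              all(dim(posteriors)[1:2] == dim(dosage)), dim(posteriors)[3] == 3)
    sums <- rowSums(matrix(posteriors, ncol = 3))
    if (any(abs(sums[!is.na(sums)] - 1) > 1e-9))
      stop("posterior triples must sum to 1")
  }
  structure(list(dosage = dosage, markers = markers, posteriors = posteriors),
            class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat("<ancestry_matrix> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " markers (",
      round(100 * mean(is.na(x$dosage)), 2), "% missing)\n", sep = "")
  invisible(x)
}

#' Per-marker mean minor-parent ancestry
#'
#' Mean of non-missing dosage/2 across individuals at each marker; `NaN` for
#' markers with no calls.
#'
#' @param am an [ancestry_matrix()].
#' @return numeric vector, one value per marker.
#' @export
site_ancestry <- function(am) {
  colMeans(am$dosage, na.rm = TRUE) / 2
}

#' Per-individual hybrid index
#'
#' Fraction of each individual's genome derived from the minor parent,
#' estimated as the mean of non-missing dosage/2 across markers.
#'
#' @param am an [ancestry_matrix()] or `f2_panel`.
#' @return numeric vector, one value per individual.
#' @export
hybrid_index <- function(am) {
  rowMeans(am$dosage, na.rm = TRUE) / 2
}
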