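#' @useDynLib hybridscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile approx rbinom rpois runif rmultinom density
#'   pchisq pt sd median setNames complete.cases rnorm
#' @importFrom utils read.table write.table head tail
NULL

# ---- GeneticMap --------------------------------------------------------------

#' Construct a genetic map
#'
#' A genetic map is a set of per-chromosome piecewise-linear anchors relating
#' physical position (bp, 0-based) to map position (cM).  Anchors must be
#' strictly increasing in bp and non-decreasing in cM, and every chromosome
#' must start at (0 bp, 0 cM).  Flat stretches (equal cM at successive
#' anchors) are allowed; they represent zero-recombination plateaus common in
#' LD-inferred maps.
#'
#' @param anchors data.frame with columns `chrom`, `pos_bp`, `pos_cM`.
#' @return An object of class `genetic_map`: a named list of per-chromosome
#'   anchor data.frames plus `len_bp` and `len_cM` vectors.
#' @export
genetic_map <- function(anchors) {
  stopifnot(is.data.frame(anchors),
            all(c("chrom", "pos_bp", "pos_cM") %in% names(anchors)))
  chroms <- split(anchors[c("pos_bp", "pos_cM")], anchors$chrom)
  # preserve first-appearance chromosome order
  chroms <- chroms[unique(as.character(anchors$chrom))]
  for (cn in names(chroms)) {
    a <- chroms[[cn]]
    a <- a[order(a$pos_bp), , drop = FALSE]
    if (any(diff(a$pos_bp) <= 0))
      stop("anchors not strictly increasing in bp on chromosome ", cn)
    if (any(diff(a$pos_cM) < 0))
      stop("anchors decreasing in cM on chromosome ", cn)
    if (a$pos_bp[1] != 0 || a$pos_cM[1] != 0)
      stop("first anchor must be (0 bp, 0 cM) on chromosome ", cn)
    rownames(a) <- NULL
    chroms[[cn]] <- a
  }
  structure(list(
    chroms = chroms,
    len_bp = vapply(chroms, function(a) a$pos_bp[nrow(a)], numeric(1)),
    len_cM = vapply(chroms, function(a) a$pos_cM[nrow(a)], numeric(1))
  ), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", length(x$chroms), " chromosome(s), ",
      format(sum(x$len_bp), big.mark = ","), " bp, ",
      round(sum(x$len_cM), 2), " cM\n", sep = "")
  invisible(x)
}

#' Interpolate map position (cM) at physical positions
#'
#' Piecewise-linear interpolation between flanking anchors; exact at anchors
#' and monotone non-decreasing in bp.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome name (length 1).
#' @param pos_bp numeric vector of positions in bp; must lie within
#'   `[0, chromosome length]`.
#' @return numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, chrom, pos_bp) {
  a <- map$chroms[[as.character(chrom)]]
  if (is.null(a)) stop("unknown chromosome: ", chrom)
  if (any(pos_bp < 0 | pos_bp > a$pos_bp[nrow(a)]))
    stop("position out of range on chromosome ", chrom)
  approx(a$pos_bp, a$pos_cM, xout = pos_bp, method = "linear")$y
}

#' Inverse map interpolation: cM to bp
#'
#' On zero-recombination plateaus (several bp mapping to one cM value) the
#' leftmost bp is returned.
#'
#' @inheritParams interpolate_cm
#' @param pos_cM numeric vector of cM positions within `[0, chromosome cM]`.
#' @return numeric vector of bp positions.
#' @export
interpolate_bp <- function(map, chrom, pos_cM) {
  a <- map$chroms[[as.character(chrom)]]
  if (is.null(a)) stop("unknown chromosome: ", chrom)
  if (any(pos_cM < 0 | pos_cM > a$pos_cM[nrow(a)] + 1e-9))
    stop("cM position out of range on chromosome ", chrom)
  approx(a$pos_cM, a$pos_bp, xout = pmin(pos_cM, a$pos_cM[nrow(a)]),
         method = "linear", ties = min)$y
}

# ---- MarkerSet ---------------------------------------------------------------

#' Construct a marker set
#'
#' Ordered ancestry-informative markers.  Markers are sorted and must be
#' unique within a chromosome.
#'
#' @param df data.frame with columns `chrom`, `pos` (bp, 0-based); an optional
#'   `freq_diff` column carries the diagnostic allele-frequency difference.
#' @return data.frame of class `marker_set`, sorted by chromosome (order of
#'   first appearance) then position.
#' @export
marker_set <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "pos") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  ord <- order(match(df$chrom, unique(df$chrom)), df$pos)
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[c("chrom", "pos")])
  if (any(dup)) stop("duplicate marker positions")
  rownames(df) <- NULL
  class(df) <- c("marker_set", "data.frame")
  df
}

#' Thin markers to a minimum spacing
#'
#' Greedy left-to-right retention within each chromosome: a marker is kept iff
#' it lies at least `min_spacing_bp` from the last kept marker.  The default
#' spacing of 395 bp is the genome-wide average spacing of diagnostic sites in
#' the swordtail system this package models.
#'
#' @param markers a [marker_set()].
#' @param min_spacing_bp minimum spacing in bp (> 0).
#' @return thinned [marker_set()].
#' @export
thin_markers <- function(markers, min_spacing_bp = 395) {
  stopifnot(min_spacing_bp > 0)
  keep <- unlist(lapply(split(seq_len(nrow(markers)), markers$chrom), function(idx) {
    pos <- markers$pos[idx]
    k <- logical(length(idx))
    last <- -Inf
    for (j in seq_along(idx)) {
      if (pos[j] - last >= min_spacing_bp) {
        k[j] <- TRUE
        last <- pos[j]
      }
    }
    idx[k]
  }), use.names = FALSE)
  out <- markers[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- AnnotationTrack ---------------------------------------------------------

#' Construct an annotation track
#'
#' A named set of half-open intervals `[start, end)` in 0-based bp
#' coordinates, each carrying a class label (coding, conserved, repeat,
#' inversion, or custom).
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `class` (default `"custom"`).
#' @return data.frame of class `annotation_track`.
#' @export
annotation_track <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$class)) df$class <- rep("custom", nrow(df))
  if (nrow(df) && any(df$start >= df$end)) stop("intervals must have start < end")
  df$chrom <- as.character(df$chrom)
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_track", "data.frame")
  df
}

# Merge overlapping/adjacent intervals (matrix with start, end columns).
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  grp <- cumsum(c(1L, as.integer(start[-1] > cummax(end[-length(end)]))))
  cbind(start = tapply(start, grp, min), end = tapply(end, grp, max))
}

# Total overlap (bp) of each window [ws, we) with a merged, disjoint, sorted
# interval set, via the cumulative coverage function of the set.
overlap_bp <- function(ws, we, ms, me) {
  if (length(ms) == 0L || length(ws) == 0L) return(numeric(length(ws)))
  cum <- c(0, cumsum(me - ms))
  coverage_to <- function(x) {
    i <- findInterval(x, ms)
    ifelse(i == 0, 0,
           cum[pmax(i, 1)] +
             pmin(pmax(x - ms[pmax(i, 1)], 0), (me - ms)[pmax(i, 1)]))
  }
  coverage_to(we) - coverage_to(ws)
}

# ---- WindowGrid --------------------------------------------------------------

#' Tile a genome into non-overlapping windows
#'
#' Windows tile each chromosome left-to-right from 0; the last window per
#' chromosome may be short.  Genetic-distance (cM) windows are materialized as
#' bp intervals via inverse interpolation of the map so they can be used in
#' interval queries; inverse interpolation is exact on the piecewise-linear
#' map.
#'
#' @param map a [genetic_map()].
#' @param unit `"bp"` or `"cM"`.
#' @param size window size in the chosen unit (> 0).
#' @return data.frame of class `window_grid` with columns `chrom`, `start`,
#'   `end` (bp, half-open), `start_cM`, `end_cM`, and attribute `unit`/`size`.
#' @export
make_windows <- function(map, unit = c("bp", "cM"), size) {
  unit <- match.arg(unit)
  stopifnot(size > 0)
  res <- lapply(names(map$chroms), function(cn) {
    Lbp <- map$len_bp[[cn]]
    LcM <- map$len_cM[[cn]]
    nw <- function(L) max(1L, ceiling(L / size - 1e-9))
    if (unit == "bp") {
      s <- (seq_len(nw(Lbp)) - 1) * size
      e <- c(s[-1], Lbp)                   # exact shared boundaries
      data.frame(chrom = cn, start = s, end = e,
                 start_cM = interpolate_cm(map, cn, s),
                 end_cM = interpolate_cm(map, cn, e))
    } else {
      s_cM <- (seq_len(nw(LcM)) - 1) * size
      e_cM <- c(s_cM[-1], LcM)
      data.frame(chrom = cn, start = interpolate_bp(map, cn, s_cM),
                 end = c(interpolate_bp(map, cn, e_cM[-length(e_cM)]), Lbp),
                 start_cM = s_cM, end_cM = e_cM)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, unit = unit, size = size,
            class = c("window_grid", "data.frame"))
}

#' Count annotated basepairs per window
#'
#' Sums intersection lengths of the (merged) intervals of one annotation
#' class with each window.  Merged-interval semantics: overlapping intervals
#' of the class are never double counted.
#'
#' @param track an [annotation_track()].
#' @param grid a [make_windows()] grid.
#' @param class annotation class to count.
#' @return numeric vector of per-window basepair counts, in grid order.
#' @export
count_annotation_bp <- function(track, grid, class) {
  if (!class %in% c("coding", "conserved", "repeat", "inversion", "custom"))
    stop("unknown annotation class: ", class)
  tr <- track[track$class == class, , drop = FALSE]
  out <- numeric(nrow(grid))
  for (cn in unique(grid$chrom)) {
    gi <- which(grid$chrom == cn)
    ti <- tr$chrom == cn
    m <- merge_intervals(tr$start[ti], tr$end[ti])
    out[gi] <- overlap_bp(grid$start[gi], grid$end[gi], m[, "start"], m[, "end"])
  }
  out
}

# Index of the grid window containing each bp position (half-open rule:
# a position exactly at a boundary belongs to the right-hand window).
# Returns NA for positions on chromosomes absent from the grid.
window_index <- function(grid, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (cn in unique(chrom)) {
    gi <- which(grid$chrom == cn)
    if (!length(gi)) next
    sel <- which(chrom == cn)
    j <- findInterval(pos[sel], grid$start[gi])
    ok <- j >= 1 & pos[sel] < grid$end[gi[pmax(j, 1)]]
    idx[sel[ok]] <- gi[j[ok]]
  }
  idx
}
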