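# Detection of minor-parent ancestry deserts and islands, cross-population
# sharing classification, and permutation null schemes.

#' Detection configuration for ancestry deserts and islands
#'
#' Defaults implement the two-step outlier scan this package models: focal
#' sites in the 2.5% genome-wide ancestry tail, expansion to the 5% tail,
#' verification of the 0.05 cM midpoint window against the 10% tail with at
#' least 10 markers and a length above 10 kb, merging of regions closer than
#' 50 kb, and (for islands) a 10% absolute ancestry agreement filter between
#' thinned and unthinned marker sets.  Sharing with another population uses
#' that population's own 10% tail.
#'
#' @param q_focal focal-site quantile (lower tail for deserts).
#' @param q_edge expansion quantile.
#' @param q_window midpoint-window quantile.
#' @param window_size_cM fine-scale window size (cM).
#' @param min_aims minimum markers in the midpoint window.
#' @param min_len minimum region length (bp, strict).
#' @param merge_dist merge regions with gaps below this (bp).
#' @param thinned_diff_max maximum absolute ancestry difference between
#'   thinned and unthinned calls (islands only).
#' @param share_quantile tail used to call a region shared in another
#'   population.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(q_focal = 0.025, q_edge = 0.05, q_window = 0.10,
                             window_size_cM = 0.05, min_aims = 10,
                             min_len = 10e3, merge_dist = 50e3,
                             thinned_diff_max = 0.10, share_quantile = 0.10) {
  stopifnot(q_focal > 0, q_focal <= q_edge, q_edge <= q_window,
            q_window < 0.5)
  structure(list(q_focal = q_focal, q_edge = q_edge, q_window = q_window,
                 window_size_cM = window_size_cM, min_aims = min_aims,
                 min_len = min_len, merge_dist = merge_dist,
                 thinned_diff_max = thinned_diff_max,
                 share_quantile = share_quantile),
            class = "detection_config")
}

#' Empirical ancestry quantile threshold
#'
#' Linear-interpolation (type 7) empirical quantile of per-site mean
#' ancestries.
#'
#' @param site_freq numeric vector of per-site mean minor ancestry.
#' @param q quantile in (0, 1).
#' @return threshold value.
#' @export
site_quantiles <- function(site_freq, q) {
  unname(quantile(site_freq, q, na.rm = TRUE, type = 7))
}

# Orient ancestry so outliers of interest are always in the LOWER tail:
# deserts work on minor ancestry directly, islands on (1 - ancestry).
orient <- function(site_freq, type) {
  if (type == "island") 1 - site_freq else site_freq
}

#' Find raw ancestry outlier regions
#'
#' For every focal site beyond the `q_focal` genome-wide threshold (below it
#' for deserts; symmetrically above the upper tail for islands), expands 5'
#' and 3' through consecutive sites still beyond the `q_edge` threshold.
#' The region boundary is the outermost such site (the first site exceeding
#' the edge threshold is excluded); overlapping expansions from several
#' focal sites coalesce into one region.
#'
#' @param site_freq per-site mean minor ancestry (all sites, genome-wide).
#' @param markers a [marker_set()] aligned with `site_freq`.
#' @param config a [detection_config()].
#' @param type `"desert"` or `"island"`.
#' @return data.frame: `chrom`, `start`, `end` (bp, half-open; end is last
#'   site + 1), `focal_pos` (most extreme focal site), `n_sites`.
#' @export
find_outlier_regions <- function(site_freq, markers, config,
                                 type = c("desert", "island")) {
  type <- match.arg(type)
  v <- orient(site_freq, type)
  thr_focal <- site_quantiles(v, config$q_focal)
  thr_edge <- site_quantiles(v, config$q_edge)
  res <- vector("list", 0)
  # sites at the vector maximum are never "in the lower tail", so a
  # constant landscape yields no outliers even though its quantile ties
  vmax <- max(v, na.rm = TRUE)
  for (cn in unique(markers$chrom)) {
    jj <- which(markers$chrom == cn & !is.na(v))
    if (!length(jj)) next
    vv <- v[jj]
    intail <- vv <= thr_edge & vv < vmax
    r <- rle(intail)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      focal <- run[vv[run] <= thr_focal]
      if (!length(focal)) next
      best <- focal[which.min(vv[focal])]
      res[[length(res) + 1L]] <- data.frame(
        chrom = cn,
        start = markers$pos[jj[run[1]]],
        end = markers$pos[jj[run[length(run)]]] + 1,
        focal_pos = markers$pos[jj[best]],
        n_sites = length(run))
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), focal_pos = numeric(0),
                      n_sites = integer(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Mean ancestry and marker count of fine-scale windows from site values.
window_profile <- function(site_freq, markers, grid) {
  wi <- window_index(grid, markers$chrom, markers$pos)
  ok <- !is.na(wi) & !is.na(site_freq)
  anc <- rep(NA_real_, nrow(grid))
  n <- integer(nrow(grid))
  t1 <- tapply(site_freq[ok], wi[ok], mean)
  t2 <- tapply(rep(1L, sum(ok)), wi[ok], sum)
  anc[as.integer(names(t1))] <- t1
  n[as.integer(names(t2))] <- t2
  list(ancestry = anc, n_aims = n)
}

#' Refine raw outlier regions into region calls
#'
#' Filter order: (1) midpoint-window checks -- the 0.05 cM window containing
#' the region midpoint must fall in the `q_window` tail of the genome-wide
#' window-ancestry distribution, contain at least `min_aims` markers, and
#' the region must be longer than `min_len`; (2) merge regions separated by
#' less than `merge_dist`; (3) drop merged regions not longer than
#' `min_len`; (4) for islands, drop regions whose midpoint-window ancestry
#' differs by more than `thinned_diff_max` (absolute) between unthinned and
#' thinned marker sets.
#'
#' @param raw output of [find_outlier_regions()].
#' @param site_freq per-site ancestry used for detection (unthinned).
#' @param markers the [marker_set()] aligned with `site_freq`.
#' @param grid fine-scale (0.05 cM) [make_windows()] grid.
#' @param config a [detection_config()].
#' @param type `"desert"` or `"island"`.
#' @param thinned_site_freq,thinned_markers optional thinned-call ancestry
#'   for the island agreement filter; skipped when `NULL`.
#' @return data.frame of class `region_call`: `type`, `chrom`, `start`,
#'   `end`, `focal_pos`, `mid_window`, `mid_ancestry`, `mid_n_aims`,
#'   `length`.
#' @export
refine_regions <- function(raw, site_freq, markers, grid, config,
                           type = c("desert", "island"),
                           thinned_site_freq = NULL, thinned_markers = NULL) {
  type <- match.arg(type)
  prof <- window_profile(site_freq, markers, grid)
  v <- orient(prof$ancestry, type)
  thr_window <- site_quantiles(v, config$q_window)

  midpoint_window <- function(reg) {
    window_index(grid, reg$chrom, floor((reg$start + reg$end) / 2))
  }
  # (1) midpoint-window checks + length
  w <- midpoint_window(raw)
  keep <- !is.na(w) & v[pmax(w, 1)] <= thr_window &
    prof$n_aims[pmax(w, 1)] >= config$min_aims &
    (raw$end - raw$start) > config$min_len
  reg <- raw[which(keep), , drop = FALSE]
  # (2) merge close regions per chromosome
  if (nrow(reg) > 1) {
    reg <- reg[order(match(reg$chrom, unique(markers$chrom)), reg$start), ]
    merged <- reg[1, , drop = FALSE]
    for (i in seq_len(nrow(reg))[-1]) {
      last <- nrow(merged)
      if (reg$chrom[i] == merged$chrom[last] &&
          reg$start[i] - merged$end[last] < config$merge_dist) {
        merged$end[last] <- max(merged$end[last], reg$end[i])
        merged$n_sites[last] <- merged$n_sites[last] + reg$n_sites[i]
      } else merged <- rbind(merged, reg[i, ])
    }
    reg <- merged
  }
  # (3) drop short merged regions
  reg <- reg[reg$end - reg$start > config$min_len, , drop = FALSE]
  # recompute midpoint windows on final extents
  w <- midpoint_window(reg)
  reg$mid_window <- w
  reg$mid_ancestry <- prof$ancestry[pmax(w, 1)]
  reg$mid_n_aims <- prof$n_aims[pmax(w, 1)]
  # (4) thinned-vs-unthinned agreement filter (islands)
  if (type == "island" && !is.null(thinned_site_freq)) {
    tprof <- window_profile(thinned_site_freq,
                            thinned_markers %||% markers, grid)
    diff <- abs(reg$mid_ancestry - tprof$ancestry[pmax(w, 1)])
    reg <- reg[!is.na(diff) & diff <= config$thinned_diff_max, , drop = FALSE]
  }
  reg$type <- rep(type, nrow(reg))
  reg$length <- reg$end - reg$start
  rownames(reg) <- NULL
  class(reg) <- c("region_call", "data.frame")
  reg
}

#' Detect ancestry deserts or islands in one step
#'
#' Convenience wrapper chaining [find_outlier_regions()] and
#' [refine_regions()].
#'
#' @inheritParams refine_regions
#' @param map a [genetic_map()]; the fine-scale grid is built from it.
#' @return a `region_call` data.frame.
#' @export
detect_regions <- function(site_freq, markers, map,
                           type = c("desert", "island"),
                           config = detection_config(),
                           thinned_site_freq = NULL, thinned_markers = NULL,
                           grid = NULL) {
  type <- match.arg(type)
  if (is.null(grid)) grid <- make_windows(map, "cM", config$window_size_cM)
  raw <- find_outlier_regions(site_freq, markers, config, type)
  refine_regions(raw, site_freq, markers, grid, config, type,
                 thinned_site_freq, thinned_markers)
}

#' Classify regions as shared with another population
#'
#' A region is shared in population P iff P's fine-scale window containing
#' the region midpoint falls beyond P's own `share_quantile` genome-wide
#' window-ancestry threshold, on the side matching the region type.
#'
#' @param regions a `region_call` data.frame (with `mid_window`).
#' @param other_window_freq the other population's mean minor ancestry per
#'   window of the same grid.
#' @param config a [detection_config()].
#' @return `regions` with a logical `shared` column.
#' @export
classify_shared <- function(regions, other_window_freq, config) {
  out <- regions
  out$shared <- rep(FALSE, nrow(regions))
  for (ty in unique(regions$type)) {
    v <- orient(other_window_freq, ty)
    thr <- site_quantiles(v, config$share_quantile)
    sel <- regions$type == ty
    w <- regions$mid_window[sel]
    # strict inequality so a constant landscape shares nothing
    out$shared[sel] <- !is.na(w) & !is.na(v[pmax(w, 1)]) & v[pmax(w, 1)] < thr
  }
  out
}

shared_count <- function(regions, other_window_freq, config) {
  sum(classify_shared(regions, other_window_freq, config)$shared)
}

# Permutation test statistic: number of outlier windows (share_quantile
# tail, matching side) overlapping any focal region.  Unlike the
# midpoint-based shared classification this accumulates over each region's
# full span, which is what gives the permutation test its power.
overlap_outlier_count <- function(regions, other_window_freq, grid, config) {
  total <- 0L
  region_windows <- attr(regions, "window_cache")
  if (is.null(region_windows))
    region_windows <- lapply(seq_len(nrow(regions)), function(i)
      which(grid$chrom == regions$chrom[i] & grid$end > regions$start[i] &
              grid$start < regions$end[i]))
  for (ty in unique(regions$type)) {
    v <- orient(other_window_freq, ty)
    thr <- site_quantiles(v, config$share_quantile)
    # strict inequality: a constant landscape has no outliers
    w <- unique(unlist(region_windows[regions$type == ty], use.names = FALSE))
    total <- total + sum(!is.na(v[w]) & v[w] < thr)
  }
  total
}

cache_region_windows <- function(regions, grid) {
  attr(regions, "window_cache") <- lapply(seq_len(nrow(regions)), function(i)
    which(grid$chrom == regions$chrom[i] & grid$end > regions$start[i] &
            grid$start < regions$end[i]))
  regions
}

#' Permutation null for cross-population sharing (value shuffle)
#'
#' The test statistic is the number of windows in the other population's
#' `share_quantile` ancestry tail (matching the region type's side) that
#' overlap any focal region.  Null replicates permute the other
#' population's window ancestry values uniformly at random across windows
#' and recount; the empirical p-value for the observed count uses the +1
#' correction.  Shuffling destroys all spatial structure, so this null asks
#' how much overlap is expected if the other population's ancestry
#' landscape were unrelated to the focal one.
#'
#' @param regions a `region_call` data.frame.
#' @param other_window_freq other population's per-window ancestry.
#' @param grid the fine-scale window grid the ancestry is computed on.
#' @param config a [detection_config()].
#' @param n_perm permutation count (default 1000).
#' @param seed optional integer seed.
#' @return list: `observed`, `null` (vector of null counts), `p`.
#' @export
permutation_null_shuffle <- function(regions, other_window_freq, grid, config,
                                     n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- cache_region_windows(regions, grid)
  obs <- overlap_outlier_count(regions, other_window_freq, grid, config)
  null <- if (nrow(regions) == 0) rep(0L, n_perm) else
    replicate(n_perm, overlap_outlier_count(regions,
                                            sample(other_window_freq),
                                            grid, config))
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Permutation null preserving local ancestry structure (block rotation)
#'
#' Null replicates are circular rotations of the genome-wide window-ancestry
#' vector by a fixed set of offsets tiling the genome; autocorrelation
#' between neighbouring windows is preserved exactly.  Default: ~130
#' equally spaced offsets.
#'
#' @inheritParams permutation_null_shuffle
#' @param offsets integer vector of rotation offsets (in windows); default
#'   `n_offsets` equally spaced nonzero offsets (offset 0 would reproduce
#'   the observed count).
#' @param n_offsets number of default offsets.
#' @return list: `observed`, `null`, `offsets`, `p`.
#' @export
permutation_null_blocks <- function(regions, other_window_freq, grid, config,
                                    offsets = NULL, n_offsets = 130) {
  W <- length(other_window_freq)
  if (is.null(offsets))
    offsets <- unique(pmax(1, round(W * seq_len(n_offsets) / (n_offsets + 1))))
  regions <- cache_region_windows(regions, grid)
  obs <- overlap_outlier_count(regions, other_window_freq, grid, config)
  null <- vapply(offsets, function(o) {
    rot <- other_window_freq[((seq_len(W) - 1 + o) %% W) + 1]
    overlap_outlier_count(regions, rot, grid, config)
  }, numeric(1))
  list(observed = obs, null = null, offsets = offsets,
       p = (1 + sum(null >= obs)) / (length(offsets) + 1))
}

#' Matched-window chance-overlap probability for one region
#'
#' Builds all candidate spans of the region's genetic length (consecutive
#' fine-scale windows), keeps those whose annotated coding content is within
#' `tolerance` bp of the region's own, and reports the fraction of matched
#' candidates falling beyond the `share_quantile` ancestry threshold of the
#' other population (threshold computed over all spans).  This null asks how
#' often windows that look like the region also look shared.
#'
#' @param region one row of a `region_call`.
#' @param grid the fine-scale grid.
#' @param coding_bp per-window coding basepairs (from
#'   [count_annotation_bp()]).
#' @param other_window_freq other population's per-window ancestry.
#' @param config a [detection_config()].
#' @param tolerance coding-content tolerance (bp); `Inf` matches everything.
#' @return list: `probability`, `n_candidates`, `span_windows`.
#' @export
matched_window_null <- function(region, grid, coding_bp, other_window_freq,
                                config, tolerance = Inf) {
  w <- region$mid_window
  # genetic length of the region = number of fine-scale windows it overlaps
  ov <- which(grid$chrom == region$chrom & grid$end > region$start &
                grid$start < region$end)
  span <- max(1L, length(ov))
  W <- length(other_window_freq)
  if (span > W) span <- W
  w <- if (length(ov)) ov[1] else w
  # spans of `span` consecutive windows, constrained within chromosomes
  starts <- which(unlist(lapply(split(seq_len(W), grid$chrom), function(idx) {
    seq_along(idx) <= length(idx) - span + 1
  })[unique(grid$chrom)], use.names = FALSE))
  roll <- function(x) {
    cs <- cumsum(c(0, x))
    cs[starts + span] - cs[starts]
  }
  cod <- roll(coding_bp)
  anc <- roll(other_window_freq) / span
  region_cod <- sum(coding_bp[w:min(w + span - 1, W)])
  cand <- abs(cod - region_cod) <= tolerance
  v <- orient(anc, region$type)
  thr <- site_quantiles(v, config$share_quantile)
  list(probability = mean(v[cand] < thr, na.rm = TRUE),
       n_candidates = sum(cand), span_windows = span)
}

#' Bootstrap distribution of the observed shared-region count
#'
#' Resamples regions with replacement and counts shared regions per
#' replicate, giving a sampling envelope for the observed count.
#'
#' @param shared logical vector of per-region shared flags.
#' @param n_boot bootstrap replicates.
#' @param seed optional integer seed.
#' @return integer vector of length `n_boot`.
#' @export
bootstrap_observed_counts <- function(shared, n_boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(shared)) return(rep(0L, n_boot))
  replicate(n_boot, sum(sample(shared, replace = TRUE)))
}

#' Audit that region calls satisfy their configuration
#'
#' Post-hoc check that every emitted region is longer than `min_len`, has at
#' least `min_aims` markers in its midpoint window, and that no two regions
#' on a chromosome are separated by less than `merge_dist`.
#'
#' @param regions a `region_call`.
#' @param config the [detection_config()] used.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
audit_regions <- function(regions, config) {
  stopifnot(all(regions$length > config$min_len),
            all(regions$mid_n_aims >= config$min_aims))
  for (cn in unique(regions$chrom)) {
    r <- regions[regions$chrom == cn, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1 && any(r$start[-1] - r$end[-nrow(r)] < config$merge_dist))
      stop("regions closer than merge_dist on ", cn)
  }
  invisible(TRUE)
}
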