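# Windowed ancestry summaries, Spearman and Spearman-partial correlations,
# thinning/masking controls, chromosome-level statistics, distance profiles.

#' Summarize ancestry and genomic features in windows
#'
#' Per-window mean minor-parent ancestry (mean of non-missing dosage/2,
#' pooled over individuals and markers), marker counts, annotated basepairs,
#' and local recombination rate (window cM span / window Mb span).  Windows
#' with fewer than `min_aims` markers are flagged invalid.
#'
#' @param am an [ancestry_matrix()], or a numeric vector of per-site mean
#'   ancestries (then `markers` must be given).
#' @param grid a [make_windows()] grid.
#' @param map a [genetic_map()].
#' @param tracks optional [annotation_track()] (classes coding / conserved /
#'   repeat are counted when present).
#' @param min_aims minimum ancestry-informative markers per valid window.
#' @param markers marker set, when `am` is a site-ancestry vector.
#' @return data.frame of class `window_summary`: grid columns plus
#'   `ancestry`, `n_aims`, `coding_bp`, `conserved_bp`, `repeat_bp`,
#'   `rec_rate`, `valid`.
#' @export
summarize_windows <- function(am, grid, map, tracks = NULL, min_aims = 1,
                              markers = NULL) {
  if (inherits(am, "ancestry_matrix")) {
    markers <- am$markers
    sf <- site_ancestry(am)
    wt <- colSums(!is.na(am$dosage))
  } else {
    if (is.null(markers)) stop("markers required with a site-ancestry vector")
    sf <- am
    wt <- rep(1, length(sf))
  }
  wi <- window_index(grid, markers$chrom, markers$pos)
  ok <- !is.na(wi) & !is.na(sf)
  num <- den <- naims <- numeric(nrow(grid))
  agg <- function(v, idx) {
    t <- tapply(v, idx, sum)
    out <- numeric(nrow(grid))
    out[as.integer(names(t))] <- t
    out
  }
  num <- agg((sf * wt)[ok], wi[ok])
  den <- agg(wt[ok], wi[ok])
  naims <- agg(rep(1, sum(ok)), wi[ok])
  out <- as.data.frame(grid)
  out$ancestry <- ifelse(den > 0, num / den, NA_real_)
  out$n_aims <- as.integer(naims)
  for (cls in c("coding", "conserved", "repeat")) {
    col <- paste0(sub("repeat", "repeat", cls), "_bp")
    out[[col]] <- if (!is.null(tracks) && any(tracks$class == cls))
      count_annotation_bp(tracks, grid, cls) else 0
  }
  span_bp <- (out$end - out$start) / 1e6
  out$rec_rate <- ifelse(span_bp > 0, (out$end_cM - out$start_cM) / span_bp, NA)
  out$valid <- out$n_aims >= min_aims & !is.na(out$ancestry)
  class(out) <- c("window_summary", "data.frame")
  out
}

# ---- Correlations ------------------------------------------------------------

avg_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' Average-rank handling of ties; p-value from the large-sample t
#' approximation (optionally an exact permutation p for small n).
#'
#' @param x,y numeric vectors; pairs with missing values are dropped.
#' @param permutation_p compute an exact/Monte-Carlo permutation p instead of
#'   the t approximation (intended for n < 30).
#' @param n_perm permutation count when `permutation_p = TRUE`.
#' @return list of class `correlation_result`: `rho`, `p`, `n`, `covariates`.
#' @export
spearman <- function(x, y, permutation_p = FALSE, n_perm = 10000) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant input: Spearman correlation undefined")
  rho <- pearson(avg_rank(x), avg_rank(y))
  p <- if (permutation_p) {
    obs <- abs(rho)
    null <- replicate(n_perm, abs(pearson(avg_rank(x), avg_rank(sample(y)))))
    (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
  } else t_pvalue(rho, n - 2)
  structure(list(rho = rho, p = p, n = n, covariates = character(0)),
            class = "correlation_result")
}

pearson <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

t_pvalue <- function(r, df) {
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(t), df)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("rho = ", signif(x$rho, 4), ", p = ", format(x$p, digits = 3),
      ", n = ", x$n,
      if (length(x$covariates)) paste0(" | ", paste(x$covariates, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Spearman partial correlation
#'
#' All variables are rank-transformed (average ranks); `x` and `y` ranks are
#' then residualized on the covariate ranks by least squares and the Pearson
#' correlation of the residuals is returned, with a t approximation on
#' `n - 2 - k` degrees of freedom.  With no covariates this reduces exactly
#' to [spearman()].  Degenerate projections (e.g. a covariate identical to
#' `y`) return `NA` with a warning rather than a spurious 0.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix / data.frame of covariates (may have 0
#'   columns), or `NULL`.
#' @return a `correlation_result`.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.data.frame(covariates) && ncol(covariates) == 0))
    return(spearman(x, y))
  Z <- as.matrix(covariates)
  ok <- is.finite(x) & is.finite(y) & apply(is.finite(Z), 1, all)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  k <- ncol(Z)
  n <- length(x)
  if (n < k + 3) stop("need at least k + 3 complete rows")
  rx <- avg_rank(x); ry <- avg_rank(y)
  rZ <- cbind(1, apply(Z, 2, avg_rank))
  qr_z <- qr(rZ)
  if (qr_z$rank < ncol(rZ)) stop("collinear covariates")
  ex <- qr.resid(qr_z, rx)
  ey <- qr.resid(qr_z, ry)
  if (sd(ex) < 1e-10 * sd(rx) || sd(ey) < 1e-10 * sd(ry)) {
    warning("degenerate projection: partial correlation undefined")
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          covariates = colnames(Z) %||% paste0("z", 1:k)),
                     class = "correlation_result"))
  }
  rho <- pearson(ex, ey)
  structure(list(rho = rho, p = t_pvalue(rho, n - 2 - k), n = n,
                 covariates = colnames(Z) %||% paste0("z", 1:k)),
            class = "correlation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thin window summaries to a minimum separation
#'
#' Greedy per-chromosome retention (as [thin_markers()]), keeping one window
#' per `min_separation_bp` (default 500 kb, approximately the scale of
#' admixture linkage disequilibrium in young hybrid populations) to control
#' for autocorrelation between nearby windows.
#'
#' @param summaries a `window_summary` data.frame.
#' @param min_separation_bp minimum start-to-start separation (bp).
#' @return thinned `window_summary`.
#' @export
thin_windows <- function(summaries, min_separation_bp = 500e3) {
  keep <- unlist(lapply(split(seq_len(nrow(summaries)), summaries$chrom),
                        function(idx) {
    st <- summaries$start[idx]
    k <- logical(length(idx)); last <- -Inf
    for (j in order(st)) {
      if (st[j] - last >= min_separation_bp) { k[j] <- TRUE; last <- st[j] }
    }
    idx[k]
  }), use.names = FALSE)
  out <- summaries[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Invalidate windows overlapping annotated regions
#'
#' Any-overlap semantics: a window sharing even 1 bp with an interval of the
#' track (typically inversions, where hybrid recombination is suppressed) is
#' flagged invalid.
#'
#' @param summaries a `window_summary`.
#' @param track an [annotation_track()].
#' @return `window_summary` with `valid` updated.
#' @export
exclude_regions <- function(summaries, track) {
  if (!nrow(track)) return(summaries)
  hit <- logical(nrow(summaries))
  for (cn in unique(summaries$chrom)) {
    gi <- which(summaries$chrom == cn)
    ti <- track$chrom == cn
    if (!any(ti)) next
    m <- merge_intervals(track$start[ti], track$end[ti])
    hit[gi] <- overlap_bp(summaries$start[gi], summaries$end[gi],
                          m[, "start"], m[, "end"]) > 0
  }
  summaries$valid <- summaries$valid & !hit
  summaries
}

#' Chromosome-level ancestry statistics
#'
#' Mean minor-parent ancestry per chromosome (weighted by per-window marker
#' counts) and its Spearman correlation with chromosome length and,
#' optionally, gene count.  Shorter chromosomes have higher effective
#' recombination rates, which is expected to leave them with more minor
#' ancestry under polygenic selection against the minor parent.
#'
#' @param summaries a `window_summary`.
#' @param gene_counts optional named vector of genes per chromosome.
#' @return list: `per_chrom` data.frame, `cor_length`, `cor_genes`
#'   (`correlation_result` or `NULL`).
#' @export
chromosome_stats <- function(summaries, gene_counts = NULL) {
  s <- summaries[summaries$valid, , drop = FALSE]
  agg <- lapply(split(s, s$chrom), function(d) data.frame(
    chrom = d$chrom[1],
    ancestry = sum(d$ancestry * d$n_aims) / sum(d$n_aims),
    length_bp = max(d$end)))
  per <- do.call(rbind, agg)
  rownames(per) <- NULL
  if (nrow(per) < 3) stop("need at least 3 chromosomes")
  cor_len <- spearman(per$ancestry, per$length_bp)
  cor_genes <- NULL
  if (!is.null(gene_counts)) {
    per$genes <- as.numeric(gene_counts[per$chrom])
    cor_genes <- spearman(per$ancestry, per$genes)
  }
  list(per_chrom = per, cor_length = cor_len, cor_genes = cor_genes)
}

#' Ancestry as a function of distance to selected sites
#'
#' Computes each valid window's distance (bp, 0 if overlapping) to the
#' nearest site, bins windows by distance (logarithmic edges by default,
#' since selection's footprint decays roughly geometrically with map
#' distance), and returns per-bin mean ancestry with a bootstrap envelope
#' obtained by resampling windows with replacement.
#'
#' @param summaries a `window_summary` (the fine scale, e.g. 10 kb windows).
#' @param sites data.frame with columns `chrom`, `pos` (bp).
#' @param n_boot bootstrap replicates (default 500).
#' @param breaks numeric vector of distance-bin edges, or `NULL` for
#'   logarithmic defaults.
#' @param seed optional integer seed.
#' @return data.frame: `bin_lo`, `bin_hi`, `n_windows`, `mean_ancestry`,
#'   `boot_lo`, `boot_hi` (2.5% / 97.5% envelope).
#' @export
ancestry_by_distance <- function(summaries, sites, n_boot = 500,
                                 breaks = NULL, seed = NULL) {
  stopifnot(nrow(sites) > 0)
  if (!is.null(seed)) set.seed(seed)
  s <- summaries[summaries$valid, , drop = FALSE]
  dist <- rep(NA_real_, nrow(s))
  for (cn in unique(s$chrom)) {
    sp <- sort(sites$pos[sites$chrom == cn])
    gi <- which(s$chrom == cn)
    if (!length(sp)) next
    mid <- (s$start[gi] + s$end[gi]) / 2
    j <- findInterval(mid, sp)
    d_lo <- ifelse(j >= 1, mid - sp[pmax(j, 1)], Inf)
    d_hi <- ifelse(j < length(sp), sp[pmin(j + 1, length(sp))] - mid, Inf)
    d <- pmin(d_lo, d_hi)
    inside <- sp[pmax(j, 1)] >= s$start[gi] & sp[pmax(j, 1)] < s$end[gi] & j >= 1
    nxt <- sp[pmin(j + 1, length(sp))] >= s$start[gi] &
      sp[pmin(j + 1, length(sp))] < s$end[gi] & (j < length(sp))
    d[inside | nxt] <- 0
    dist[gi] <- d
  }
  ok <- is.finite(dist)
  s <- s[ok, , drop = FALSE]; dist <- dist[ok]
  if (is.null(breaks))
    breaks <- c(0, 10^seq(4, ceiling(log10(max(dist + 1))), by = 0.5))
  bin <- cut(dist, breaks, include.lowest = TRUE, right = FALSE)
  bin_means <- function(anc) tapply(anc, bin, mean)
  mm <- bin_means(s$ancestry)
  boot <- replicate(n_boot, {
    idx <- sample.int(nrow(s), replace = TRUE)
    out <- tapply(s$ancestry[idx], bin[idx], mean)
    out[match(names(mm), names(out))]
  })
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             n_windows = as.integer(table(bin)),
             mean_ancestry = as.numeric(mm),
             boot_lo = apply(boot, 1, quantile, 0.025, na.rm = TRUE),
             boot_hi = apply(boot, 1, quantile, 0.975, na.rm = TRUE))
}

#' Mean minor-parent ancestry in regions, relative to the genome
#'
#' Region mean over contained markers (pooled over individuals), normalized
#' by the genome-wide minor-parent fraction.
#'
#' @param am an [ancestry_matrix()].
#' @param regions data.frame with columns `chrom`, `start`, `end` (bp,
#'   half-open).
#' @return data.frame: region columns plus `ancestry`, `ratio`, `n_aims`.
#' @export
region_ancestry_summary <- function(am, regions) {
  sf <- site_ancestry(am)
  wt <- colSums(!is.na(am$dosage))
  genome_mean <- sum(sf * wt, na.rm = TRUE) / sum(wt[!is.na(sf)])
  res <- regions
  res$ancestry <- NA_real_; res$n_aims <- 0L
  for (r in seq_len(nrow(regions))) {
    jj <- which(am$markers$chrom == regions$chrom[r] &
                am$markers$pos >= regions$start[r] &
                am$markers$pos < regions$end[r] & !is.na(sf))
    res$n_aims[r] <- length(jj)
    if (length(jj))
      res$ancestry[r] <- sum(sf[jj] * wt[jj]) / sum(wt[jj])
  }
  res$ratio <- res$ancestry / genome_mean
  res
}
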