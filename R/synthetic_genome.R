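# Synthetic genomes: maps, markers and annotation for simulation studies.

#' Build a synthetic genetic map with heterogeneous recombination
#'
#' Chromosomes are divided into segments of `segment_bp`; each segment draws
#' a recombination rate from a log-normal distribution around `cm_per_mb`
#' (cM/Mb) and the piecewise-linear map accumulates them, rescaled so each
#' chromosome's total genetic length is exactly `chr_cM`.  The default
#' average rate of 4.55 cM/Mb reproduces the fine-mapping scale of the
#' swordtail system (0.05 cM corresponding to ~11 kb on average); `rate_sd`
#' (log-scale SD) controls how heterogeneous the landscape is.
#'
#' @param n_chr number of chromosomes.
#' @param chr_cM genetic length per chromosome (cM), recycled.
#' @param cm_per_mb average recombination rate (cM/Mb).
#' @param rate_sd log-scale standard deviation of segment rates; 0 gives a
#'   uniform map.
#' @param segment_bp segment size for rate heterogeneity.
#' @param seed optional integer seed.
#' @return a [genetic_map()].
#' @export
synthetic_map <- function(n_chr = 2, chr_cM = 25, cm_per_mb = 4.55,
                          rate_sd = 0.7, segment_bp = 250e3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chr_cM <- rep_len(chr_cM, n_chr)
  anchors <- do.call(rbind, lapply(seq_len(n_chr), function(c) {
    len_bp <- round(chr_cM[c] / cm_per_mb * 1e6)
    bounds <- unique(c(seq(0, len_bp, by = segment_bp), len_bp))
    nseg <- length(bounds) - 1
    rate <- exp(rnorm(nseg, 0, rate_sd))
    cm <- cumsum(rate * diff(bounds))
    cm <- c(0, cm / cm[nseg] * chr_cM[c])
    data.frame(chrom = paste0("chr", c), pos_bp = bounds, pos_cM = cm)
  }))
  genetic_map(anchors)
}

#' Place regularly spaced markers on a map
#'
#' Markers every `spacing_bp` along each chromosome (default 395 bp, the
#' average ancestry-informative-site spacing of the system this package
#' models).
#'
#' @param map a [genetic_map()].
#' @param spacing_bp spacing between consecutive markers (bp).
#' @return a [marker_set()].
#' @export
synthetic_markers <- function(map, spacing_bp = 395) {
  marker_set(do.call(rbind, lapply(names(map$chroms), function(cn) {
    pos <- seq(0, map$len_bp[[cn]] - 1, by = spacing_bp)
    data.frame(chrom = cn, pos = pos)
  })))
}

#' Scatter random annotation intervals on a map
#'
#' @param map a [genetic_map()].
#' @param class annotation class label.
#' @param n_per_chr number of intervals per chromosome.
#' @param mean_len mean interval length (bp, exponential).
#' @param seed optional integer seed.
#' @return an [annotation_track()].
#' @export
synthetic_annotation <- function(map, class = "coding", n_per_chr = 50,
                                 mean_len = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  annotation_track(do.call(rbind, lapply(names(map$chroms), function(cn) {
    L <- map$len_bp[[cn]]
    len <- pmax(1, round(stats::rexp(n_per_chr, 1 / mean_len)))
    start <- floor(runif(n_per_chr, 0, pmax(1, L - len)))
    data.frame(chrom = cn, start = start, end = pmin(start + len, L),
               class = class)
  })))
}
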