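# F2 intercross analytics: segregation-distortion scan, viability-selection
# rejection simulation, and the two-locus incompatibility chi-square scan.

#' Exact two-sided binomial p-value
#'
#' Sums the probabilities of all outcomes whose point probability does not
#' exceed that of the observed count (the same convention as
#' `binom.test`, reproduced here so the scan can be vectorized over many
#' markers with a single precomputed pmf).
#'
#' @param k observed successes (vectorized).
#' @param n trials.
#' @param p0 null success probability.
#' @return numeric vector of p-values.
#' @export
exact_binom_p <- function(k, n, p0 = 0.5) {
  pmf <- stats::dbinom(0:n, n, p0)
  # p(k) = sum of pmf over outcomes with pmf <= pmf(k) (with relative slack)
  vapply(k, function(kk) {
    sum(pmf[pmf <= pmf[kk + 1] * (1 + 1e-7)])
  }, numeric(1))
}

#' Segregation-distortion scan of an F2 panel
#'
#' Thins markers to one per `thin_spacing` bp, then tests each retained
#' marker's minor-allele count against the Mendelian expectation of 50%
#' with an exact two-sided binomial test (alleles = 2 x non-missing
#' individuals).  Markers below `alpha` are flagged and contiguous flagged
#' runs are reported as candidate distorter regions.
#'
#' @param panel an `f2_panel` (or [ancestry_matrix()]).
#' @param thin_spacing marker thinning spacing in bp (default 50 kb).
#' @param alpha per-marker significance threshold (default 5e-4,
#'   approximately the 5% tail of ancestry outliers at this design size).
#' @return list: `markers` (data.frame chrom, pos, k_minor, n_alleles, p,
#'   significant), `regions` (contiguous significant runs).
#' @export
segdist_scan <- function(panel, thin_spacing = 50e3, alpha = 5e-4) {
  stopifnot(nrow(panel$dosage) > 0)
  thin <- thin_markers(panel$markers[c("chrom", "pos")], thin_spacing)
  jj <- match(paste(thin$chrom, thin$pos),
              paste(panel$markers$chrom, panel$markers$pos))
  d <- panel$dosage[, jj, drop = FALSE]
  k <- colSums(d, na.rm = TRUE)
  n <- 2L * colSums(!is.na(d))
  res <- data.frame(chrom = thin$chrom, pos = thin$pos,
                    k_minor = k, n_alleles = n, p = NA_real_)
  for (nn in unique(n[n > 0])) {
    sel <- which(n == nn)
    res$p[sel] <- exact_binom_p(k[sel], nn)
  }
  res$significant <- !is.na(res$p) & res$p < alpha
  regions <- NULL
  if (any(res$significant)) {
    r <- rle(paste(res$chrom, res$significant))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    sig <- which(res$significant[starts])
    regions <- data.frame(chrom = res$chrom[starts[sig]],
                          start = res$pos[starts[sig]],
                          end = res$pos[ends[sig]] + 1,
                          n_markers = r$lengths[sig],
                          min_p = vapply(sig, function(i)
                            min(res$p[starts[i]:ends[i]]), numeric(1)))
  } else {
    regions <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_markers = integer(0),
                          min_p = numeric(0))
  }
  list(markers = res, regions = regions)
}

#' Post-selection F2 genotype expectation under viability selection
#'
#' Starting from Mendelian (1/4, 1/2, 1/4) proportions, survival of the
#' disfavored homozygote is `1 - s` and of heterozygotes `1 - h*s`; the
#' renormalized genotype fractions and the resulting frequency of the
#' disfavored allele are returned.
#'
#' @param s selection coefficient in `[0, 1]`.
#' @param h dominance coefficient in `[0, 1]`.
#' @return list: `fractions` (named: disfavored homozygote, heterozygote,
#'   favored homozygote), `allele_freq` (disfavored allele).
#' @export
viability_selection_expectation <- function(s, h) {
  stopifnot(s >= 0, s <= 1, h >= 0, h <= 1)
  w <- c(dis_hom = 0.25 * (1 - s), het = 0.5 * (1 - h * s), fav_hom = 0.25)
  f <- w / sum(w)
  list(fractions = f, allele_freq = unname(f[1] + f[2] / 2))
}

#' Rejection simulation for the selection strength behind distortion
#'
#' Repeatedly draws `s ~ U(0,1)` and `h ~ U(0,1)`, samples `n_individuals`
#' F2 genotypes from the post-selection expectation, and accepts the
#' replicate when its mean ancestry deviates from 50% far enough to be
#' called distorted by the exact binomial rule at `acceptance_alpha` (the
#' same rule the scan applies to data).  The distribution of accepted `s`
#' shows how strong selection must be to produce a detected distorter; the
#' accepted `h` marginal stays close to its prior.
#'
#' @param n_individuals simulated panel size (default 943).
#' @param n_reps replicates (default 10000).
#' @param acceptance_alpha binomial p-value threshold (default 5e-4).
#' @param seed optional integer seed.
#' @return object of class `distortion_fit`: `accepted` (data.frame s, h,
#'   allele_freq, p), `acceptance_rate`, `s_quantiles` (1%, 5%, 25%, 50%,
#'   75%, 95%).
#' @export
segdist_selection_abc <- function(n_individuals = 943, n_reps = 10000,
                                  acceptance_alpha = 5e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- runif(n_reps); h <- runif(n_reps)
  n_alleles <- 2L * n_individuals
  # sample genotype counts from the per-replicate expectation
  w0 <- 0.25 * (1 - s); w1 <- 0.5 * (1 - h * s); w2 <- rep(0.25, n_reps)
  tot <- w0 + w1 + w2
  counts <- vapply(seq_len(n_reps), function(i)
    as.numeric(rmultinom(1, n_individuals, c(w0[i], w1[i], w2[i]) / tot[i])),
    numeric(3))
  k_dis <- 2 * counts[1, ] + counts[2, ]   # disfavored-allele count
  pmf <- stats::dbinom(0:n_alleles, n_alleles, 0.5)
  pvals <- vapply(k_dis, function(kk)
    sum(pmf[pmf <= pmf[kk + 1] * (1 + 1e-7)]), numeric(1))
  acc <- pvals < acceptance_alpha
  if (!any(acc)) stop("no accepted replicates")
  accepted <- data.frame(s = s[acc], h = h[acc],
                         allele_freq = k_dis[acc] / n_alleles, p = pvals[acc])
  structure(list(accepted = accepted, acceptance_rate = mean(acc),
                 s_quantiles = quantile(accepted$s,
                                        c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95))),
            class = "distortion_fit")
}

# ---- Two-locus incompatibility scan -----------------------------------------

#' Expected two-locus genotype table from marginals
#'
#' `E[i, j] = n * (a_i / n) * (b_j / n)`: the independence expectation built
#' from the observed genotype frequencies at each locus.
#'
#' @param counts_a,counts_b length-3 genotype counts at the two loci
#'   (complete cases only; totals must match).
#' @return 3x3 expected-count matrix.
#' @export
two_locus_expected <- function(counts_a, counts_b) {
  n <- sum(counts_a)
  stopifnot(n == sum(counts_b), n > 0)
  outer(counts_a, counts_b) / n
}

#' Two-locus chi-square test (4 degrees of freedom)
#'
#' `chisq = sum (O - E)^2 / E` over cells with `E > 0`; the p-value uses the
#' chi-square distribution with 4 degrees of freedom (the 3x3 table with
#' both marginals estimated).  Cells with zero expectation are excluded and
#' counted.
#'
#' @param observed,expected 3x3 count matrices with equal totals.
#' @return list of class `two_locus_result`: `chisq`, `df`, `p`,
#'   `n_excluded_cells`, `observed`, `expected`.
#' @export
two_locus_chisq <- function(observed, expected) {
  stopifnot(abs(sum(observed) - sum(expected)) < 1e-6, sum(observed) > 0)
  use <- expected > 0
  chisq <- sum((observed[use] - expected[use])^2 / expected[use])
  structure(list(chisq = chisq, df = 4,
                 p = pchisq(chisq, df = 4, lower.tail = FALSE),
                 n_excluded_cells = sum(!use),
                 observed = observed, expected = expected),
            class = "two_locus_result")
}

# Vectorized scan of a focal genotype vector against all columns of G.
# Returns data.frame chisq, p, n (complete cases per pair).
scan_chisq <- function(focal, G) {
  M <- ncol(G)
  okF <- !is.na(focal)
  cnt <- array(0, c(3, 3, M))
  for (g in 0:2) {
    sel <- okF & focal == g
    if (!any(sel)) next
    Gs <- G[sel, , drop = FALSE]
    for (hh in 0:2)
      cnt[g + 1, hh + 1, ] <- colSums(Gs == hh, na.rm = TRUE)
  }
  n <- apply(cnt, 3, sum)
  chisq <- numeric(M)
  for (m in seq_len(M)) {
    o <- cnt[, , m]
    if (n[m] == 0) { chisq[m] <- NA; next }
    e <- outer(rowSums(o), colSums(o)) / n[m]
    use <- e > 0
    chisq[m] <- sum((o[use] - e[use])^2 / e[use])
  }
  data.frame(chisq = chisq, p = pchisq(chisq, 4, lower.tail = FALSE), n = n)
}

#' Genome-wide two-locus incompatibility scan from a focal marker
#'
#' Tests every other marker's 3x3 genotype-combination table against the
#' independence expectation from the pair's marginals (complete cases per
#' pair).  Markers within `exclude_cM` of the focal marker on its own
#' chromosome are reported but flagged `linked` and excluded from
#' genome-wide minimum-p bookkeeping, since linkage to a distorted focal
#' locus inflates the statistic without epistasis.
#'
#' @param panel an `f2_panel` whose marker table has `pos_cM`.
#' @param focal_marker index of the focal marker, or a `chrom`/`pos` pair
#'   as `c(chrom, pos)`.
#' @param exclude_cM linkage exclusion radius (cM) around the focal marker.
#' @return data.frame: `chrom`, `pos`, `chisq`, `p`, `n`, `linked`,
#'   `is_focal`; attribute `min_p` (minimum p over unlinked markers).
#' @export
incompatibility_scan <- function(panel, focal_marker, exclude_cM = 5) {
  mk <- panel$markers
  if (length(focal_marker) == 2 && !is.numeric(focal_marker))
    focal_marker <- which(mk$chrom == focal_marker[1] &
                            mk$pos == as.numeric(focal_marker[2]))[1]
  stopifnot(length(focal_marker) == 1, focal_marker >= 1,
            focal_marker <= nrow(mk))
  focal <- panel$dosage[, focal_marker]
  res <- scan_chisq(focal, panel$dosage)
  out <- data.frame(chrom = mk$chrom, pos = mk$pos, chisq = res$chisq,
                    p = res$p, n = res$n)
  out$linked <- mk$chrom == mk$chrom[focal_marker] &
    !is.null(mk$pos_cM) &
    abs(mk$pos_cM - mk$pos_cM[focal_marker]) <= exclude_cM
  out$is_focal <- seq_len(nrow(mk)) == focal_marker
  usable <- !out$linked & !out$is_focal & !is.na(out$p)
  attr(out, "min_p") <- if (any(usable)) min(out$p[usable]) else NA_real_
  out
}

#' Simulation-based genome-wide false-positive threshold for the scan
#'
#' Per replicate, simulates a focal genotype for every individual as
#' `Binomial(2, hybrid index)` -- preserving each individual's genome-wide
#' ancestry but breaking any true two-locus association -- runs the scan,
#' and records the minimum p over unlinked markers.  The threshold is the
#' `fpr_quantile` quantile of minimum p-values; scans of real data beyond
#' it are genome-wide significant at that false-positive rate.
#'
#' @param panel an `f2_panel` with `hybrid_index`.
#' @param n_reps replicates (default 500).
#' @param fpr_quantile quantile of minimum p-values (default 0.05).
#' @param seed optional integer seed.
#' @return list: `threshold`, `min_p` (per-replicate minima).
#' @export
scan_fpr_threshold <- function(panel, n_reps = 500, fpr_quantile = 0.05,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hi <- panel$hybrid_index %||% hybrid_index(panel)
  n <- length(hi)
  minp <- vapply(seq_len(n_reps), function(r) {
    focal <- rbinom(n, 2, hi)
    res <- scan_chisq(focal, panel$dosage)
    min(res$p, na.rm = TRUE)
  }, numeric(1))
  list(threshold = unname(quantile(minp, fpr_quantile)), min_p = minp)
}
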