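# Post-HMM processing of local ancestry calls: hard-calling, masking,
# Hardy-Weinberg filtering, transition intervals and tract-length masking.

#' Hard-call ancestry states from posterior probabilities
#'
#' A site is assigned the ancestry state whose posterior probability meets
#' `threshold` (inclusive); sites with no state that confident are masked.
#'
#' @param am an [ancestry_matrix()] carrying a `posteriors` array (see
#'   [emit_posteriors()]), or the array itself plus `markers`.
#' @param threshold posterior probability required to assign a state; must
#'   exceed 1/3 (below that the argmax is ambiguous).
#' @param markers marker set, required when `am` is a bare array.
#' @return an [ancestry_matrix()] of hard calls.
#' @export
hard_call <- function(am, threshold = 0.9, markers = NULL) {
  if (threshold <= 1 / 3) stop("threshold must exceed 1/3")
  if (inherits(am, "ancestry_matrix")) {
    post <- am$posteriors
    markers <- am$markers
    if (is.null(post)) stop("no posteriors attached")
  } else post <- am
  n <- dim(post)[1]; m <- dim(post)[2]
  flat <- matrix(post, n * m, 3)
  top <- max.col(flat, ties.method = "first")
  val <- flat[cbind(seq_len(n * m), top)]
  call <- ifelse(!is.na(val) & val >= threshold, top - 1L, NA_integer_)
  ancestry_matrix(matrix(as.integer(call), n, m), markers, posteriors = post)
}

#' Mask markers observed in too few individuals
#'
#' Markers whose fraction of non-missing calls is below
#' `min_present_fraction` are dropped from the matrix (boundary inclusive: a
#' marker present in exactly that fraction is retained).
#'
#' @param am an [ancestry_matrix()].
#' @param min_present_fraction minimum fraction of individuals with a call.
#' @return an [ancestry_matrix()] restricted to retained markers.
#' @export
mask_sites <- function(am, min_present_fraction = 0.25) {
  present <- colMeans(!is.na(am$dosage))
  keep <- present >= min_present_fraction
  subset_markers(am, keep)
}

subset_markers <- function(am, keep) {
  post <- if (!is.null(am$posteriors)) am$posteriors[, keep, , drop = FALSE]
  mk <- am$markers[keep, , drop = FALSE]
  rownames(mk) <- NULL
  class(mk) <- class(am$markers)
  out <- ancestry_matrix(am$dosage[, keep, drop = FALSE], mk, post)
  for (extra in setdiff(names(am), names(out))) out[[extra]] <- am[[extra]]
  class(out) <- class(am)
  out
}

#' Exact Hardy-Weinberg test on ancestry genotype counts
#'
#' Exact conditional test (enumeration over heterozygote counts compatible
#' with the observed allele counts); the two-sided p-value sums the
#' probabilities of all heterozygote counts no more likely than the observed
#' one.  Monomorphic markers return p = 1.
#'
#' @param n0,n1,n2 counts of dosage-0 homozygotes, heterozygotes and
#'   dosage-2 homozygotes.
#' @return exact two-sided p-value.
#' @export
hwe_exact_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1            # minor allele count (orientation irrelevant)
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  # P(n1 = h | allele counts) via log factorials
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (nA + hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(n1, hets)] * (1 + 1e-7)])
}

#' Filter markers out of Hardy-Weinberg equilibrium
#'
#' Applies the exact HWE test per marker to the three ancestry-genotype
#' counts and removes markers with `p < alpha / n_markers` (Bonferroni).
#' Genotyping and ancestry-inference errors inflate apparent ancestry
#' switches, and strong HWE departures flag such markers.
#'
#' @param am an [ancestry_matrix()].
#' @param alpha family-wise significance level before correction
#'   (default 0.1).
#' @param min_n minimum non-missing individuals for a marker to be tested
#'   (untested markers are retained).
#' @return list with `matrix` (filtered [ancestry_matrix()]), `p` (per-marker
#'   exact p-values) and `removed` (logical vector).
#' @export
hwe_filter <- function(am, alpha = 0.1, min_n = 5) {
  d <- am$dosage
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  p <- rep(1, ncol(d))
  tested <- (n0 + n1 + n2) >= min_n
  p[tested] <- mapply(hwe_exact_test, n0[tested], n1[tested], n2[tested])
  removed <- p < alpha / ncol(d)
  list(matrix = subset_markers(am, !removed), p = p, removed = removed)
}

#' Detect ancestry-transition intervals
#'
#' Scans each individual along each chromosome over confidently called sites
#' and emits one interval per change of ancestry state: the interval runs
#' from the last confident site of the old state to the first confident site
#' of the new state.  These intervals localize historical crossover events.
#' Missing (unconfident) sites never terminate the scan; they are skipped.
#'
#' @param am an [ancestry_matrix()] of hard calls.
#' @return data.frame with columns `individual`, `chrom`, `left`, `right`,
#'   `state_from`, `state_to`.
#' @export
detect_transitions <- function(am) {
  d <- am$dosage
  res <- vector("list", 0)
  for (cn in unique(am$markers$chrom)) {
    jj <- which(am$markers$chrom == cn)
    pos <- am$markers$pos[jj]
    for (i in seq_len(nrow(d))) {
      g <- d[i, jj]
      ok <- !is.na(g)
      if (sum(ok) < 2) next
      g2 <- g[ok]; p2 <- pos[ok]
      ch <- which(diff(g2) != 0)
      if (length(ch))
        res[[length(res) + 1L]] <- data.frame(
          individual = i, chrom = cn, left = p2[ch], right = p2[ch + 1],
          state_from = g2[ch], state_to = g2[ch + 1])
    }
  }
  if (!length(res))
    return(data.frame(individual = integer(0), chrom = character(0),
                      left = numeric(0), right = numeric(0),
                      state_from = integer(0), state_to = integer(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Maximal runs of constant non-missing dosage per individual/chromosome,
# with cM spans.  A run's span covers from the midpoint to its flanking runs
# (chromosome ends for terminal runs), so spans partition the chromosome.
dosage_runs <- function(am, map) {
  d <- am$dosage
  out <- vector("list", 0)
  for (cn in unique(am$markers$chrom)) {
    jj <- which(am$markers$chrom == cn)
    cm <- interpolate_cm(map, cn, am$markers$pos[jj])
    LcM <- map$len_cM[[cn]]
    for (i in seq_len(nrow(d))) {
      g <- d[i, jj]
      ok <- which(!is.na(g))
      if (!length(ok)) next
      g2 <- g[ok]; cm2 <- cm[ok]
      r <- rle(g2)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1
      # boundaries between runs at midpoints of flanking confident sites
      bnd <- if (length(r$lengths) > 1)
        (cm2[ends_i[-length(ends_i)]] + cm2[starts_i[-1]]) / 2 else numeric(0)
      start_cM <- c(0, bnd)
      end_cM <- c(bnd, LcM)
      out[[length(out) + 1L]] <- data.frame(
        individual = i, chrom = cn, dosage = r$values,
        start_cM = start_cM, end_cM = end_cM,
        first = jj[ok[starts_i]], last = jj[ok[ends_i]])
    }
  }
  if (!length(out))
    return(data.frame(individual = integer(0), chrom = character(0),
                      dosage = integer(0), start_cM = numeric(0),
                      end_cM = numeric(0), first = integer(0),
                      last = integer(0)))
  do.call(rbind, out)
}

#' Tract lengths by ancestry class
#'
#' Converts maximal runs of identical non-missing dosage into cM spans.
#' Diploid convention: a run of dosage 1 or 2 is a minor-parent tract, a run
#' of dosage 0 a major-parent tract (heterozygous runs count toward the
#' minor class).
#'
#' @param am an [ancestry_matrix()].
#' @param map a [genetic_map()] covering all markers.
#' @return list with numeric vectors `minor` and `major` of tract lengths
#'   (cM).
#' @export
tract_lengths <- function(am, map) {
  runs <- dosage_runs(am, map)
  len <- runs$end_cM - runs$start_cM
  list(minor = len[runs$dosage > 0], major = len[runs$dosage == 0])
}

#' Mask implausibly short ancestry tracts
#'
#' Dosage runs shorter than the class threshold are set to missing: tracts
#' far shorter than expected under the population's age are likely HMM switch
#' errors.  Default thresholds (0.004 cM minor, 0.035 cM major) are the
#' masking rule this package models.
#'
#' @param am an [ancestry_matrix()].
#' @param map a [genetic_map()].
#' @param min_minor_cM,min_major_cM minimum tract length by class (cM).
#' @return an [ancestry_matrix()] with short runs masked.
#' @export
mask_short_tracts <- function(am, map, min_minor_cM = 0.004,
                              min_major_cM = 0.035) {
  runs <- dosage_runs(am, map)
  if (!nrow(runs)) return(am)
  len <- runs$end_cM - runs$start_cM
  thr <- ifelse(runs$dosage > 0, min_minor_cM, min_major_cM)
  bad <- runs[len < thr, , drop = FALSE]
  d <- am$dosage
  for (k in seq_len(nrow(bad)))
    d[bad$individual[k], bad$first[k]:bad$last[k]] <- NA_integer_
  out <- am
  out$dosage <- d
  out
}
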