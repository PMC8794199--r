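# Synthetic-data engine: forward-in-time tract simulation of admixed
# populations, F2 intercross panels, and HMM-like posterior emission.

#' Demographic parameters for the admixture simulator
#'
#' Defaults describe the hybrid-zone system this package models: admixture
#' beginning ~120 generations ago with a strongly asymmetric founding
#' contribution (85% major / 15% minor parent) and limited ongoing migration.
#'
#' @param N hybrid population size (diploid individuals), >= 2.
#' @param T generations since admixture, >= 1.
#' @param m0 initial minor-parent admixture proportion, in (0, 1).
#' @param mig_minor,mig_major per-generation fraction of the population
#'   replaced by pure migrants of each parental species, in `[0, 0.5)`.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(N = 1000, T = 120, m0 = 0.15,
                       mig_minor = 0, mig_major = 0) {
  stopifnot(N >= 2, T >= 1, m0 > 0, m0 < 1,
            mig_minor >= 0, mig_minor < 0.5, mig_major >= 0, mig_major < 0.5)
  structure(list(N = as.integer(N), T = as.integer(T), m0 = m0,
                 mig_minor = mig_minor, mig_major = mig_major),
            class = "sim_params")
}

#' Selection configuration for the admixture simulator
#'
#' Four modes are supported.  `neutral`: no selection.  `dmi_pairs`:
#' epistatic incompatibilities between minor-parent ancestry at one locus and
#' major-parent ancestry at a partner locus; an individual's fitness is the
#' product over pairs of `1 - s * f(a) * f(b)` where `a` is minor-parent
#' dosage at locus 1, `b` major-parent dosage at locus 2, and
#' `f(0) = 0, f(1) = h, f(2) = 1`.  `hybridization_load`: per-site selection
#' against the dosage of the load-carrying parent, fitness product of
#' `1 - s * f(dosage)`.  `single_parent`: identical form against the dosage
#' of a globally disfavored parent.
#'
#' @param mode one of `"neutral"`, `"dmi_pairs"`, `"hybridization_load"`,
#'   `"single_parent"`.
#' @param pairs for `dmi_pairs`: data.frame with columns `chrom1`, `pos1`,
#'   `chrom2`, `pos2` (bp), `s`, `h`.  If `NULL`, `n_sites` random pairs are
#'   placed on the marker set at simulation time.
#' @param sites for load/single-parent modes: data.frame with columns
#'   `chrom`, `pos`, `s`, `h`.  If `NULL`, `n_sites` random sites are placed.
#' @param n_sites number of random pairs/sites to place when `pairs`/`sites`
#'   is `NULL` (default 20, the density used in the simulations this package
#'   emulates).
#' @param s,h selection and dominance coefficients used for random placement.
#' @param target which parent's dosage selection acts on, for load and
#'   single-parent modes: `"minor"` or `"major"`.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(mode = c("neutral", "dmi_pairs",
                                      "hybridization_load", "single_parent"),
                             pairs = NULL, sites = NULL, n_sites = 20,
                             s = 0.1, h = 0.5, target = c("minor", "major")) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  stopifnot(s >= 0, s <= 1, h >= 0, h <= 1)
  if (!is.null(pairs))
    stopifnot(all(pairs$s >= 0 & pairs$s <= 1), all(pairs$h >= 0 & pairs$h <= 1))
  if (!is.null(sites))
    stopifnot(all(sites$s >= 0 & sites$s <= 1), all(sites$h >= 0 & sites$h <= 1))
  structure(list(mode = mode, pairs = pairs, sites = sites,
                 n_sites = as.integer(n_sites), s = s, h = h, target = target),
            class = "selection_config")
}

# Resolve a selection config to the numeric matrix the engine consumes.
# Random placements are drawn from the marker set (so selected loci always
# lie on simulated markers).
resolve_selection <- function(sel, map, markers) {
  chrom_idx <- function(ch) match(as.character(ch), names(map$chroms)) - 1L
  cm_of <- function(ch, pos) {
    vapply(seq_along(pos),
           function(i) interpolate_cm(map, ch[i], pos[i]), numeric(1))
  }
  if (sel$mode == "neutral")
    return(list(mode = 0L, loci = matrix(numeric(0), 0, 6), placed = NULL))
  if (sel$mode == "dmi_pairs") {
    p <- sel$pairs
    if (is.null(p)) {
      idx <- matrix(sample.int(nrow(markers), 2 * sel$n_sites, replace = FALSE),
                    ncol = 2)
      p <- data.frame(chrom1 = markers$chrom[idx[, 1]],
                      pos1 = markers$pos[idx[, 1]],
                      chrom2 = markers$chrom[idx[, 2]],
                      pos2 = markers$pos[idx[, 2]],
                      s = sel$s, h = sel$h)
    }
    loci <- cbind(chrom_idx(p$chrom1), cm_of(p$chrom1, p$pos1),
                  chrom_idx(p$chrom2), cm_of(p$chrom2, p$pos2), p$s, p$h)
    if (anyNA(loci)) stop("selected loci must lie on map chromosomes")
    return(list(mode = 1L, loci = loci, placed = p))
  }
  st <- sel$sites
  if (is.null(st)) {
    idx <- sample.int(nrow(markers), sel$n_sites, replace = FALSE)
    st <- data.frame(chrom = markers$chrom[idx], pos = markers$pos[idx],
                     s = sel$s, h = sel$h)
  }
  loci <- cbind(chrom_idx(st$chrom), cm_of(st$chrom, st$pos), st$s, st$h,
                as.integer(sel$target == "minor"))
  if (anyNA(loci)) stop("selected sites must lie on map chromosomes")
  list(mode = if (sel$mode == "hybridization_load") 2L else 3L,
       loci = loci, placed = st)
}

#' Simulate an admixed hybrid population
#'
#' Forward-in-time Wright-Fisher simulation of ancestry tracts.  Founders are
#' pure minor-parent individuals with probability `m0`, otherwise pure major.
#' Each generation, migrants replace a `Binomial(N, mig)` subset with pure
#' parentals; parents are then sampled with probability proportional to
#' fitness (soft viability selection at constant N), and gametes are formed
#' with per-chromosome crossover counts `~ Poisson(cM length / 100)` and
#' breakpoints uniform in cM (no interference).
#'
#' @param params a [sim_params()].
#' @param sel a [selection_config()] (default neutral).
#' @param map a [genetic_map()].
#' @param markers a [marker_set()] on the map's chromosomes.
#' @param seed optional integer seed.
#' @param return_matrix return the full individuals x markers dosage matrix.
#' @param return_tracts return the haplotype tract table.
#' @return list with components `matrix` (an [ancestry_matrix()], if
#'   requested), `site_freq` (per-marker minor ancestry), `tracts` (if
#'   requested: data.frame individual/haplotype/chrom/start_cM/end_cM/
#'   ancestry), `stats` (tract-based summary statistics: median minor tract
#'   length in cM, mean hybrid index, CV of chromosome-wide ancestry across
#'   individuals), `selection` (the placed selected loci) and `seed`.
#' @export
simulate_admixed_population <- function(params, sel = selection_config(),
                                        map, markers, seed = NULL,
                                        return_matrix = TRUE,
                                        return_tracts = FALSE) {
  stopifnot(inherits(params, "sim_params"), inherits(sel, "selection_config"))
  if (!inherits(markers, "marker_set")) markers <- marker_set(markers)
  if (!all(markers$chrom %in% names(map$chroms)))
    stop("markers lie on chromosomes absent from the map")
  if (!is.null(seed)) set.seed(seed)
  rs <- resolve_selection(sel, map, markers)
  chr_i <- match(markers$chrom, names(map$chroms)) - 1L
  mk_cM <- unlist(lapply(names(map$chroms), function(cn) {
    interpolate_cm(map, cn, markers$pos[markers$chrom == cn])
  }), use.names = FALSE)
  raw <- .wf_simulate_cpp(unname(map$len_cM), params$N, params$T, params$m0,
                          params$mig_minor, params$mig_major,
                          rs$mode, rs$loci, chr_i, mk_cM,
                          return_matrix, TRUE, return_tracts)
  out <- list(site_freq = raw$site_freq, stats = raw$stats,
              selection = rs$placed, seed = seed)
  if (return_matrix) out$matrix <- ancestry_matrix(raw$dosage, markers)
  if (return_tracts) {
    tr <- raw$tracts
    tr$chrom <- names(map$chroms)[tr$chrom]
    tr$ancestry <- c("major", "minor")[tr$ancestry + 1L]
    out$tracts <- tr
  }
  out
}

# ---- F2 intercross panels ----------------------------------------------------

#' Configuration of a simulated F2 intercross
#'
#' @param n_individuals number of surviving F2s to collect (default 943, the
#'   panel size this package models).
#' @param distorters data.frame of single-locus viability distorters with
#'   columns `chrom`, `pos`, `s`, `h`, `disfavored` (`"minor"` or `"major"`:
#'   which homozygote has survival `1 - s`; heterozygotes survive with
#'   `1 - h * s`).
#' @param epistatic list of two-locus incompatibilities; each element a list
#'   with `chrom1`, `pos1`, `chrom2`, `pos2`, `s`, and `penalized`, a
#'   two-column matrix of (dosage at locus 1, dosage at locus 2) combinations
#'   whose survival is `1 - s`.
#' @return object of class `f2_cross_config`.
#' @export
f2_cross_config <- function(n_individuals = 943, distorters = NULL,
                            epistatic = NULL) {
  if (!is.null(distorters))
    stopifnot(all(distorters$s >= 0 & distorters$s <= 1),
              all(distorters$h >= 0 & distorters$h <= 1),
              all(distorters$disfavored %in% c("minor", "major")))
  structure(list(n_individuals = as.integer(n_individuals),
                 distorters = distorters, epistatic = epistatic),
            class = "f2_cross_config")
}

# One F1 gamete's dosage contribution (0/1) at marker cM positions.
f1_gamete <- function(len_cM, mk_cM_by_chr) {
  unlist(lapply(seq_along(len_cM), function(c) {
    L <- len_cM[c]
    k <- rpois(1, L / 100)
    br <- sort(runif(k, 0, L))
    start <- sample(0:1, 1)
    (start + findInterval(mk_cM_by_chr[[c]], br)) %% 2L
  }), use.names = FALSE)
}

#' Simulate an F2 intercross panel under viability selection
#'
#' Each F2 is formed from two independent F1 gametes (the F1 is heterozygous
#' everywhere); crossovers per chromosome are `Poisson(cM/100)`.  Survival
#' probability is the product over configured distorter loci and epistatic
#' pairs of `1 - s`, `1 - h*s`, or 1 according to genotype; rejected
#' individuals are redrawn until `n_individuals` survivors are collected.
#'
#' @param config an [f2_cross_config()].
#' @param map a [genetic_map()].
#' @param markers a [marker_set()].
#' @param seed optional integer seed.
#' @return object of class `f2_panel` (inherits `ancestry_matrix`), with the
#'   marker table augmented by a `pos_cM` column and a `hybrid_index` field.
#' @export
simulate_f2_panel <- function(config, map, markers, seed = NULL) {
  stopifnot(inherits(config, "f2_cross_config"))
  if (!inherits(markers, "marker_set")) markers <- marker_set(markers)
  if (!is.null(seed)) set.seed(seed)
  len_cM <- unname(map$len_cM)
  chr_names <- names(map$chroms)
  mk_cM_by_chr <- lapply(chr_names, function(cn)
    interpolate_cm(map, cn, markers$pos[markers$chrom == cn]))
  mk_cM <- unlist(mk_cM_by_chr, use.names = FALSE)

  survival <- function(G) {
    p <- rep(1, nrow(G))
    for (d in seq_len(NROW(config$distorters))) {
      dd <- config$distorters[d, ]
      j <- which(markers$chrom == dd$chrom & markers$pos == dd$pos)
      if (!length(j)) stop("distorter locus not in marker set")
      g <- G[, j[1]]
      gd <- if (dd$disfavored == "minor") g else 2L - g
      p <- p * ifelse(gd == 2L, 1 - dd$s, ifelse(gd == 1L, 1 - dd$h * dd$s, 1))
    }
    for (ep in config$epistatic) {
      j1 <- which(markers$chrom == ep$chrom1 & markers$pos == ep$pos1)
      j2 <- which(markers$chrom == ep$chrom2 & markers$pos == ep$pos2)
      if (!length(j1) || !length(j2)) stop("epistatic locus not in marker set")
      hit <- paste(G[, j1[1]], G[, j2[1]]) %in%
        paste(ep$penalized[, 1], ep$penalized[, 2])
      p <- p * ifelse(hit, 1 - ep$s, 1)
    }
    p
  }

  n <- config$n_individuals
  kept <- matrix(NA_integer_, 0, length(mk_cM))
  drawn_total <- 0L
  while (nrow(kept) < n) {
    batch <- max(64L, ceiling(1.3 * (n - nrow(kept))))
    G <- t(vapply(seq_len(batch), function(i)
      f1_gamete(len_cM, mk_cM_by_chr) + f1_gamete(len_cM, mk_cM_by_chr),
      integer(length(mk_cM))))
    keep <- runif(batch) < survival(G)
    kept <- rbind(kept, G[keep, , drop = FALSE])
    drawn_total <- drawn_total + batch
    if (drawn_total > 200L * n && nrow(kept) == 0L)
      stop("viability configuration appears lethal: no survivors in ",
           drawn_total, " draws")
  }
  kept <- kept[seq_len(n), , drop = FALSE]
  mk <- markers
  mk$pos_cM <- mk_cM
  am <- ancestry_matrix(kept, mk)
  am$hybrid_index <- hybrid_index(am)
  class(am) <- c("f2_panel", class(am))
  am
}

# ---- HMM-like posterior emission --------------------------------------------

#' Emit HMM-like posterior probabilities for true ancestry calls
#'
#' Emulates the output of a local-ancestry HMM so downstream filters can be
#' exercised on data with known truth.  With probability `1 - error_rate` the
#' true state receives posterior mass drawn from `U(0.9, 1)`; with
#' probability `error_rate` the mass goes to a randomly chosen wrong state,
#' either confidently (`U(0.9, 1)`, half the time) or ambiguously
#' (`U(0.5, 0.9)`).  Rows always sum to 1; missing input entries emit the
#' uninformative triple (1/3, 1/3, 1/3).
#'
#' @param am an [ancestry_matrix()].
#' @param error_rate probability a site's posterior argmax is wrong, in
#'   `[0, 0.5)`.
#' @param seed optional integer seed.
#' @return the input [ancestry_matrix()] with a `posteriors` array attached.
#' @export
emit_posteriors <- function(am, error_rate = 0.02, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  d <- am$dosage
  n <- length(d)
  state <- as.integer(d) + 1L
  err <- runif(n) < error_rate
  shift <- 1L + (runif(n) < 0.5)                  # pick one of the two others
  wrong <- ((state - 1L + shift) %% 3L) + 1L
  top_state <- ifelse(err, wrong, state)
  confident <- !err | runif(n) < 0.5
  top_p <- ifelse(confident, runif(n, 0.9, 1), runif(n, 0.5, 0.9))
  split <- runif(n)                                # share of remainder
  post <- matrix(0, n, 3)
  rest <- 1 - top_p
  # ensure the top state keeps the argmax in the ambiguous case
  r1 <- pmin(rest * split, pmin(top_p, rest) - 1e-9)
  r1 <- pmax(r1, 0)
  ts <- ifelse(is.na(top_state), 1L, top_state)   # placeholder for NA entries
  other <- vapply(seq_len(n), function(i) setdiff(1:3, ts[i]), integer(2))
  post[cbind(seq_len(n), ts)] <- top_p
  post[cbind(seq_len(n), other[1, ])] <- r1
  post[cbind(seq_len(n), other[2, ])] <- rest - r1
  post[is.na(state), ] <- 1 / 3
  am$posteriors <- array(post, dim = c(nrow(d), ncol(d), 3))
  am
}
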