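# Rejection-ABC inference of hybrid-population demographic history.

#' Prior specification for demographic ABC
#'
#' Uniform or log-uniform priors for the admixture-demography parameters:
#' hybrid population size `N`, time since admixture `T` (generations),
#' initial minor-parent proportion `m0`, and per-generation migration rates
#' from each parental species.
#'
#' @param ... named parameter specs, each `list(dist, min, max)` with
#'   `dist` in `{"uniform", "loguniform"}`.  Defaults cover the plausible
#'   range for recently formed hybrid populations.
#' @return object of class `abc_prior`.
#' @export
abc_prior <- function(...) {
  spec <- list(...)
  defaults <- list(
    N = list(dist = "loguniform", min = 100, max = 10000),
    T = list(dist = "uniform", min = 10, max = 300),
    m0 = list(dist = "uniform", min = 0.05, max = 0.95),
    mig_minor = list(dist = "uniform", min = 0, max = 0.05),
    mig_major = list(dist = "uniform", min = 0, max = 0.05))
  for (nm in names(spec)) defaults[[nm]] <- spec[[nm]]
  for (nm in names(defaults)) {
    p <- defaults[[nm]]
    stopifnot(p$dist %in% c("uniform", "loguniform"),
              is.finite(p$min), is.finite(p$max), p$min <= p$max)
    if (p$dist == "loguniform") stopifnot(p$min > 0)
  }
  structure(defaults, class = "abc_prior")
}

sample_prior <- function(prior, n) {
  as.data.frame(lapply(prior, function(p) {
    if (p$min == p$max) rep(p$min, n)
    else if (p$dist == "uniform") runif(n, p$min, p$max)
    else exp(runif(n, log(p$min), log(p$max)))
  }))
}

#' Summary statistics of an ancestry matrix for demographic inference
#'
#' The statistics carrying information about admixture age, proportion and
#' drift: median minor-parent ancestry tract length (cM), mean hybrid index,
#' and either the coefficient of variation of chromosome-wide ancestry
#' across individuals (`mode = "global"`) or the CV of local ancestry in
#' 250 kb windows along the genome (`mode = "local250kb"`).
#'
#' @param am an [ancestry_matrix()].
#' @param map a [genetic_map()].
#' @param mode `"global"` or `"local250kb"`.
#' @return named numeric vector: `median_minor_tract_cM`,
#'   `mean_hybrid_index`, and `cv_chrom_ancestry` or `cv_local_ancestry`.
#' @export
compute_summary_stats <- function(am, map, mode = c("global", "local250kb")) {
  mode <- match.arg(mode)
  stopifnot(nrow(am$dosage) >= 2)
  hi <- hybrid_index(am)
  tl <- tract_lengths(am, map)
  med <- if (length(tl$minor)) median(tl$minor) else NA_real_
  if (mode == "global") {
    cvs <- vapply(names(map$chroms), function(cn) {
      jj <- am$markers$chrom == cn
      if (!any(jj)) return(NA_real_)
      a <- rowMeans(am$dosage[, jj, drop = FALSE], na.rm = TRUE) / 2
      m <- mean(a, na.rm = TRUE)
      if (!is.finite(m) || m == 0) return(NA_real_)
      sd(a, na.rm = TRUE) / m
    }, numeric(1))
    if (all(is.na(cvs))) stop("CV undefined: no chromosome with nonzero mean ancestry")
    c(median_minor_tract_cM = med, mean_hybrid_index = mean(hi),
      cv_chrom_ancestry = mean(cvs, na.rm = TRUE))
  } else {
    grid <- make_windows(map, "bp", 250e3)
    prof <- window_profile(site_ancestry(am), am$markers, grid)
    w <- prof$ancestry[prof$n_aims > 0]
    m <- mean(w, na.rm = TRUE)
    if (!is.finite(m) || m == 0) stop("CV undefined: mean window ancestry is 0")
    c(median_minor_tract_cM = med, mean_hybrid_index = mean(hi),
      cv_local_ancestry = sd(w, na.rm = TRUE) / m)
  }
}

#' Rejection-ABC over the admixture simulator
#'
#' Draws parameters from the prior, simulates an admixed population for
#' each draw, computes summary statistics, and accepts either the `k`
#' nearest draws (`accept_mode = "top_k"`, default k = 500) or all draws
#' within distance `epsilon`.  Distance is the Euclidean norm of
#' component-wise differences standardized by the median absolute deviation
#' of the simulated statistics (a robust scale, so no statistic dominates).
#' Simulations with undefined statistics are excluded and counted.
#'
#' By default statistics come from the simulator's tract-based fast path;
#' supply `sim_fun` to override (it receives one parameter row and must
#' return the named statistics vector).
#'
#' @param observed named numeric vector of observed summary statistics (the
#'   names select which statistics enter the distance).
#' @param prior an [abc_prior()].
#' @param n_sims number of prior draws.
#' @param map,markers genome used by the default simulator.
#' @param accept_mode `"top_k"` or `"epsilon"`.
#' @param k accepted count for `top_k`.
#' @param epsilon distance cutoff for `epsilon`.
#' @param seed optional integer seed.
#' @param sim_fun optional custom simulator `function(params_row) -> stats`.
#' @param table optional precomputed [abc_reference_table()]; when given, no
#'   new simulations are run (the standard design for coverage studies,
#'   where many pseudo-observed datasets are evaluated against one
#'   simulated reference table).
#' @return object of class `abc_posterior`: `accepted` (params + stats +
#'   distance), `n_sims`, `n_degenerate`, `prior`, `observed`.
#' @export
run_rejection <- function(observed, prior, n_sims, map = NULL, markers = NULL,
                          accept_mode = c("top_k", "epsilon"), k = 500,
                          epsilon = NULL, seed = NULL, sim_fun = NULL,
                          table = NULL) {
  accept_mode <- match.arg(accept_mode)
  if (is.null(table)) {
    if (!is.null(seed)) set.seed(seed)
    table <- abc_reference_table(prior, n_sims, map, markers,
                                 sim_fun = sim_fun)
  }
  draws <- table$draws
  stats <- table$stats[, names(observed), drop = FALSE]
  n_sims <- nrow(draws)
  if (accept_mode == "top_k") stopifnot(n_sims >= k)
  ok <- apply(is.finite(stats), 1, all)
  scale <- apply(stats[ok, , drop = FALSE], 2, stats::mad)
  scale[scale == 0 | !is.finite(scale)] <- 1
  dist <- rep(Inf, n_sims)
  dist[ok] <- sqrt(colSums(
    ((t(stats[ok, , drop = FALSE]) - observed) / scale)^2))
  acc <- if (accept_mode == "top_k") order(dist)[seq_len(min(k, sum(ok)))]
         else which(dist <= epsilon)
  accepted <- cbind(draws[acc, , drop = FALSE],
                    stats[acc, , drop = FALSE], distance = dist[acc])
  rownames(accepted) <- NULL
  structure(list(accepted = accepted, n_sims = n_sims,
                 n_degenerate = sum(!ok), prior = prior,
                 observed = observed),
            class = "abc_posterior")
}

#' Simulate an ABC reference table
#'
#' Draws `n_sims` parameter vectors from the prior and simulates the summary
#' statistics for each.  The table can be passed to [run_rejection()] and
#' reused across several observed (or pseudo-observed) datasets.
#'
#' @inheritParams run_rejection
#' @return object of class `abc_reference_table`: `draws` (data.frame) and
#'   `stats` (matrix).
#' @export
abc_reference_table <- function(prior, n_sims, map = NULL, markers = NULL,
                                seed = NULL, sim_fun = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sim_fun)) {
    stopifnot(!is.null(map), !is.null(markers))
    sim_fun <- function(pr) {
      res <- simulate_admixed_population(
        sim_params(N = round(pr$N), T = round(pr$T), m0 = pr$m0,
                   mig_minor = pr$mig_minor, mig_major = pr$mig_major),
        selection_config("neutral"), map, markers,
        return_matrix = FALSE)
      res$stats
    }
  }
  draws <- sample_prior(prior, n_sims)
  stats <- NULL
  for (i in seq_len(n_sims)) {
    s <- sim_fun(draws[i, , drop = FALSE])
    if (is.null(stats))
      stats <- matrix(NA_real_, n_sims, length(s),
                      dimnames = list(NULL, names(s)))
    stats[i, ] <- s
  }
  structure(list(draws = draws, stats = stats, prior = prior),
            class = "abc_reference_table")
}

#' Subset an ABC reference table to its first n simulations
#' @param table an `abc_reference_table`.
#' @param n number of simulations to keep.
#' @return an `abc_reference_table`.
#' @export
head_table <- function(table, n) {
  structure(list(draws = table$draws[seq_len(n), , drop = FALSE],
                 stats = table$stats[seq_len(n), , drop = FALSE],
                 prior = table$prior),
            class = "abc_reference_table")
}

#' MAP estimate and 95% quantile interval for one parameter
#'
#' The MAP is the mode of a Gaussian kernel density (Silverman bandwidth,
#' 512-point grid) over the accepted draws, computed on the log scale for
#' log-uniform parameters; the interval is the 2.5%-97.5% quantile range of
#' the accepted draws.
#'
#' @param posterior an `abc_posterior`, or a numeric vector of draws.
#' @param parameter parameter name (when `posterior` is an `abc_posterior`).
#' @param log_scale compute the KDE on the log scale; default follows the
#'   prior's distribution type when available.
#' @return list: `map`, `lower`, `upper`, `n`.
#' @export
map_estimate <- function(posterior, parameter = NULL, log_scale = NULL) {
  if (inherits(posterior, "abc_posterior")) {
    x <- posterior$accepted[[parameter]]
    if (is.null(log_scale))
      log_scale <- posterior$prior[[parameter]]$dist == "loguniform"
  } else x <- posterior
  if (is.null(log_scale)) log_scale <- FALSE
  stopifnot(length(x) >= 1)
  if (length(unique(x)) == 1)
    return(list(map = x[1], lower = x[1], upper = x[1], n = length(x)))
  z <- if (log_scale) log(x) else x
  d <- density(z, bw = "nrd0", n = 512)
  mode_z <- d$x[which.max(d$y)]
  list(map = if (log_scale) exp(mode_z) else mode_z,
       lower = unname(quantile(x, 0.025)),
       upper = unname(quantile(x, 0.975)),
       n = length(x))
}
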