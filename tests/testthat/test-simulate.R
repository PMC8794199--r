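# Tract-engine properties and F2 panel simulation.

test_that("parameter and config validation rejects invalid inputs", {
  expect_error(sim_params(N = 1), "N")
  expect_error(sim_params(m0 = 0), "m0")
  expect_error(sim_params(mig_minor = 0.6), "mig_minor")
  expect_error(selection_config("dmi_pairs",
                                pairs = data.frame(chrom1 = "c", pos1 = 1,
                                                   chrom2 = "c", pos2 = 2,
                                                   s = 1.5, h = 0)), "s")
})

test_that("neutral drift is a martingale: mean ancestry stays at m0", {
  map <- uniform_map(1e6, 50)
  mk <- synthetic_markers(map, 10e3)
  set.seed(11)
  means <- vapply(1:20, function(r) {
    mean(simulate_admixed_population(sim_params(N = 200, T = 20, m0 = 0.5),
                                     selection_config(), map, mk,
                                     return_matrix = FALSE)$site_freq)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.5), 2 * sd(means) / sqrt(20))
})

test_that("neutral tract lengths match the exponential approximation", {
  # mean minor tract length ~ 100 / ((1 - m0) * T) cM for young populations
  map <- uniform_map(1e7, 300)
  mk <- mk_at(c(0, 1e6))
  set.seed(12)
  res <- simulate_admixed_population(sim_params(N = 2000, T = 10, m0 = 0.5),
                                     selection_config(), map, mk,
                                     return_matrix = FALSE,
                                     return_tracts = TRUE)
  tr <- res$tracts
  minor <- tr[tr$ancestry == "minor", ]
  expect_lt(abs(mean(minor$end_cM - minor$start_cM) - 20) / 20, 0.15)
})

test_that("total cM per haplotype is conserved through generations", {
  map <- toy_map()
  mk <- mk_at(c(1e5, 1.5e6))
  set.seed(13)
  res <- simulate_admixed_population(sim_params(N = 50, T = 40, m0 = 0.3),
                                     selection_config(), map, mk,
                                     return_matrix = FALSE,
                                     return_tracts = TRUE)
  tot <- tapply(res$tracts$end_cM - res$tracts$start_cM,
                list(paste(res$tracts$individual, res$tracts$haplotype),
                     res$tracts$chrom), sum)
  expect_true(all(abs(tot[, "chr1"] - 2.5) < 1e-9))
  expect_true(all(abs(tot[, "chr2"] - 2.0) < 1e-9))
})

test_that("dmi selection removes minor ancestry relative to paired seeds", {
  map <- uniform_map(4e6, 120)
  mk <- synthetic_markers(map, 4000)
  set.seed(14)
  diffs <- vapply(1:12, function(r) {
    seed <- 1400 + r
    sel <- simulate_admixed_population(
      sim_params(N = 300, T = 40, m0 = 0.15),
      selection_config("dmi_pairs", n_sites = 20, s = 0.1), map, mk,
      seed = seed, return_matrix = FALSE)
    neu <- simulate_admixed_population(
      sim_params(N = 300, T = 40, m0 = 0.15),
      selection_config(), map, mk, seed = seed, return_matrix = FALSE)
    mean(sel$site_freq) - mean(neu$site_freq)
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gte(mean(diffs < 0), 0.9)
})

test_that("local-ancestry heterogeneity grows with time since admixture", {
  # Drift accumulates: the variance of per-site mean ancestry along the
  # genome grows with T at fixed N.  (The variance of *individual* hybrid
  # indices instead shrinks with T -- founders are pure, recombination
  # mixes tracts, and the genome-wide admixture fraction is a
  # parent-averaging martingale with tiny step variance -- so local
  # ancestry is the axis on which time since admixture is visible.)
  map <- synthetic_map(10, 50, rate_sd = 0, seed = 150)
  mk <- synthetic_markers(map, 2e5)
  set.seed(15)
  v <- function(T) vapply(1:20, function(r) {
    res <- simulate_admixed_population(sim_params(N = 150, T = T, m0 = 0.5),
                                       selection_config(), map, mk,
                                       return_matrix = FALSE)
    var(res$site_freq)
  }, numeric(1))
  expect_lt(stats::wilcox.test(v(50), v(5), alternative = "greater")$p.value,
            0.01)
})

test_that("migration holds ancestry near the migrant source", {
  map <- uniform_map(1e6, 50)
  mk <- synthetic_markers(map, 10e3)
  set.seed(16)
  res <- simulate_admixed_population(
    sim_params(N = 200, T = 60, m0 = 0.5, mig_major = 0.2),
    selection_config(), map, mk, return_matrix = FALSE)
  expect_lt(mean(res$site_freq), 0.2)
})

test_that("F2 panels are Mendelian without selection", {
  map <- uniform_map(5e6, 100)
  mk <- synthetic_markers(map, 50e3)
  set.seed(17)
  panel <- simulate_f2_panel(f2_cross_config(943), map, mk)
  fr <- table(factor(panel$dosage, 0:2)) / length(panel$dosage)
  expect_true(all(abs(fr - c(0.25, 0.5, 0.25)) < 0.03))
  expect_lt(abs(mean(panel$hybrid_index) - 0.5), 0.02)
})

test_that("a lethal distorter removes its genotype class", {
  map <- uniform_map(1e6, 50)
  mk <- mk_at(c(2e5, 8e5))
  set.seed(18)
  cfg <- f2_cross_config(400, distorters = data.frame(
    chrom = "chr1", pos = 2e5, s = 1, h = 0, disfavored = "minor"))
  panel <- simulate_f2_panel(cfg, map, mk)
  g <- panel$dosage[, 1]
  expect_equal(sum(g == 2), 0)
  fr <- table(factor(g, 0:2)) / length(g)
  expect_lt(abs(fr[[2]] - 2 / 3), 0.06)        # renormalized (1/3, 2/3, 0)
  # a configuration with survival 0 for every genotype errors out
  lethal <- f2_cross_config(50, epistatic = list(list(
    chrom1 = "chr1", pos1 = 2e5, chrom2 = "chr1", pos2 = 8e5, s = 1,
    penalized = as.matrix(expand.grid(0:2, 0:2)))))
  expect_error(simulate_f2_panel(lethal, map, mk_at(c(2e5, 8e5))), "lethal")
})

test_that("an epistatic pair suppresses the penalized genotype combination", {
  map <- genetic_map(data.frame(chrom = c("c1", "c1", "c2", "c2"),
                                pos_bp = c(0, 1e6, 0, 1e6),
                                pos_cM = c(0, 50, 0, 50)))
  mk <- marker_set(data.frame(chrom = c("c1", "c2"), pos = c(5e5, 5e5)))
  set.seed(19)
  cfg <- f2_cross_config(300, epistatic = list(list(
    chrom1 = "c1", pos1 = 5e5, chrom2 = "c2", pos2 = 5e5, s = 1,
    penalized = cbind(2, 2))))
  panel <- simulate_f2_panel(cfg, map, mk)
  expect_equal(sum(panel$dosage[, 1] == 2 & panel$dosage[, 2] == 2), 0)
})

test_that("selection placements land on markers and are reported", {
  map <- uniform_map(1e6, 25)
  mk <- synthetic_markers(map, 5000)
  set.seed(20)
  res <- simulate_admixed_population(
    sim_params(N = 50, T = 5, m0 = 0.3),
    selection_config("single_parent", n_sites = 5, s = 0.2), map, mk,
    return_matrix = FALSE)
  expect_equal(nrow(res$selection), 5)
  expect_true(all(paste(res$selection$chrom, res$selection$pos) %in%
                    paste(mk$chrom, mk$pos)))
})
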