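# Desert/island detection, sharing and the permutation nulls.

test_that("site_quantiles is the type-7 empirical quantile", {
  expect_equal(site_quantiles(seq(0, 1, by = 0.01), 0.025), 0.025)
  expect_equal(site_quantiles(rep(0.4, 50), 0.1), 0.4)
  set.seed(31)
  v <- runif(137)
  expect_equal(site_quantiles(v, 0.07), unname(quantile(v, 0.07, type = 7)))
})

test_that("find_outlier_regions expands a dip to the edge threshold", {
  cfg <- detection_config()
  # one dip (.2, .2, .01, .02, .2, .2) followed by 34 distinct background
  # values: type-7 quantiles land at 0.0198 (focal) and ~0.19 (edge), so
  # the region is exactly the two dip sites, flanks excluded
  sf <- c(0.2, 0.2, 0.01, 0.02, 0.2, 0.2, seq(0.5, 1, length.out = 34))
  mk <- mk_at(c(10, 20, 30, 40, 50, 60, 100 + seq_len(34) * 10))
  raw <- find_outlier_regions(sf, mk, cfg, "desert")
  expect_equal(nrow(raw), 1)
  expect_equal(raw$start, 30)      # outermost sites still beyond the edge
  expect_equal(raw$end, 41)
  expect_equal(raw$focal_pos, 30)
  # degenerate tail (constant ancestry): no site beyond q_focal -> empty
  expect_equal(nrow(find_outlier_regions(rep(0.5, 10),
                                         mk_at(1:10 * 10), cfg, "desert")), 0)
  # two focal sites inside one dip coalesce into one region
  sf3 <- c(rep(0.2, 100), 0.001, 0.002, rep(0.2, 98))
  raw3 <- find_outlier_regions(sf3, mk_at(seq_len(200) * 10), cfg, "desert")
  expect_equal(nrow(raw3), 1)
})

test_that("find_outlier_regions matches a per-focal expansion oracle", {
  # oracle: expand left/right from each focal site through sites still
  # beyond the edge threshold, then deduplicate overlapping expansions
  oracle <- function(sf, pos, cfg) {
    tf <- site_quantiles(sf, cfg$q_focal)
    te <- site_quantiles(sf, cfg$q_edge)
    out <- NULL
    for (i in which(sf <= tf)) {
      L <- i; while (L > 1 && sf[L - 1] <= te) L <- L - 1
      R <- i; while (R < length(sf) && sf[R + 1] <= te) R <- R + 1
      out <- rbind(out, c(pos[L], pos[R] + 1))
    }
    unique(out)
  }
  set.seed(30)
  cfg <- detection_config()
  for (r in 1:20) {
    sf <- runif(400)^2
    pos <- sort(sample.int(1e6, 400))
    raw <- find_outlier_regions(sf, mk_at(pos), cfg, "desert")
    orc <- oracle(sf, pos, cfg)
    expect_equal(nrow(raw), nrow(orc))
    expect_equal(raw$start, unname(orc[, 1]))
    expect_equal(raw$end, unname(orc[, 2]))
  }
})

test_that("desert and island detection are exact mirror images", {
  set.seed(32)
  cfg <- detection_config()
  for (r in 1:100) {
    sf <- runif(300)
    mk <- mk_at(sort(sample.int(1e6, 300)))
    des <- find_outlier_regions(1 - sf, mk, cfg, "desert")
    isl <- find_outlier_regions(sf, mk, cfg, "island")
    expect_equal(des[c("chrom", "start", "end", "focal_pos", "n_sites")],
                 isl[c("chrom", "start", "end", "focal_pos", "n_sites")])
  }
})

# A synthetic landscape with V-shaped dips on a uniform map: background
# ancestry ~0.5, parabolic dips to ~0 of half-width `dip_kb`/2 kb (the
# shape a selected site leaves after linked selection).
dip_world <- function(dips, n = 2000, dip_kb = 30, seed = 1) {
  set.seed(seed)
  map <- uniform_map(n * 500, n * 500 * 4.55e-6)      # 4.55 cM/Mb
  mk <- mk_at(seq_len(n) * 500 - 250)
  sf <- runif(n, 0.4, 0.6)
  for (d in dips) {
    sel <- abs(mk$pos - d) < dip_kb * 1000 / 2
    r <- abs(mk$pos[sel] - d) / (dip_kb * 1000 / 2)
    sf[sel] <- 0.45 * r^2 + runif(sum(sel), 0, 0.005)
  }
  list(map = map, mk = mk, sf = sf,
       grid = make_windows(map, "cM", 0.05))
}

test_that("refine_regions applies window checks, merging and length drop", {
  w <- dip_world(dips = c(2e5, 6e5), seed = 33)
  cfg <- detection_config()
  reg <- detect_regions(w$sf, w$mk, w$map, "desert", cfg, grid = w$grid)
  expect_equal(nrow(reg), 2)
  expect_true(all(reg$length > cfg$min_len))
  expect_true(all(reg$mid_n_aims >= cfg$min_aims))
  audit_regions(reg, cfg)
  # two dips 40 kb apart merge into one region
  w2 <- dip_world(dips = c(4e5, 4.7e5), seed = 34)
  reg2 <- detect_regions(w2$sf, w2$mk, w2$map, "desert", cfg, grid = w2$grid)
  expect_equal(nrow(reg2), 1)
  expect_gt(reg2$length, 8e4)
  # a dip much shorter than min_len is dropped
  w3 <- dip_world(dips = 5e5, dip_kb = 6, seed = 35)
  reg3 <- detect_regions(w3$sf, w3$mk, w3$map, "desert", cfg, grid = w3$grid)
  expect_equal(nrow(reg3), 0)
})

test_that("island thinned-agreement filter drops discordant regions", {
  w <- dip_world(dips = c(2e5, 6e5), seed = 36)
  sf <- 1 - w$sf                                  # mirror: dips become peaks
  thinned <- sf
  sel2 <- abs(w$mk$pos - 6e5) < 15e3
  thinned[sel2] <- sf[sel2] - 0.2                 # disagreement > 0.10
  isl <- detect_regions(sf, w$mk, w$map, "island", grid = w$grid)
  expect_equal(nrow(isl), 2)
  isl2 <- detect_regions(sf, w$mk, w$map, "island", grid = w$grid,
                         thinned_site_freq = thinned)
  expect_equal(nrow(isl2), 1)
  expect_lt(abs(isl2$start - 185000), 2e4)
})

test_that("classify_shared uses the other population's own tail", {
  w <- dip_world(dips = c(2e5, 6e5), seed = 37)
  cfg <- detection_config()
  reg <- detect_regions(w$sf, w$mk, w$map, "desert", cfg, grid = w$grid)
  prof_self <- hybridscan:::window_profile(w$sf, w$mk, w$grid)
  # identical population -> every region shared
  expect_true(all(classify_shared(reg, prof_self$ancestry, cfg)$shared))
  # constant other population -> none shared (ties give threshold = value,
  # every window "in tail"; guarded by requiring strict outliers)
  w2 <- dip_world(dips = 2e5, seed = 38)          # shares only the first dip
  prof2 <- hybridscan:::window_profile(w2$sf, w2$mk, w$grid)
  sh <- classify_shared(reg, prof2$ancestry, cfg)
  expect_equal(sh$shared, c(TRUE, FALSE))
})

test_that("shuffle permutation null matches the binomial expectation", {
  # R regions each covering one window, independent-uniform window values:
  # expected null count ~ R * q per tail side
  set.seed(39)
  grid <- make_windows(uniform_map(1e6, 50), "cM", 0.05)  # 1000 windows
  W <- nrow(grid)
  regions <- data.frame(type = "desert", chrom = "chr1",
                        start = grid$start[c(100, 300, 500, 700, 900)],
                        end = grid$end[c(100, 300, 500, 700, 900)],
                        mid_window = c(100L, 300L, 500L, 700L, 900L))
  class(regions) <- c("region_call", "data.frame")
  vals <- runif(W)
  pn <- permutation_null_shuffle(regions, vals, grid, detection_config(),
                                 n_perm = 10000, seed = 40)
  expect_lt(abs(mean(pn$null) - 5 * 0.10), 0.02)
  # empty region set -> all null counts zero
  pn0 <- permutation_null_shuffle(regions[0, ], vals, grid,
                                  detection_config(), n_perm = 50)
  expect_true(all(pn0$null == 0))
})

test_that("block null reproduces the observed count at offset 0", {
  w <- dip_world(dips = c(2e5, 6e5), seed = 41)
  cfg <- detection_config()
  reg <- detect_regions(w$sf, w$mk, w$map, "desert", cfg, grid = w$grid)
  prof <- hybridscan:::window_profile(w$sf, w$mk, w$grid)
  bl <- permutation_null_blocks(reg, prof$ancestry, w$grid, cfg,
                                offsets = c(0, nrow(w$grid) %/% 2))
  expect_equal(bl$null[1], bl$observed)
  # rotation by half the genome moves the dip away
  expect_lt(bl$null[2], bl$observed)
  # constant ancestry in the other population: no NA-free outliers either way
  const <- rep(0.5, nrow(w$grid))
  bl2 <- permutation_null_blocks(reg, const, w$grid, cfg)
  expect_true(all(bl2$null == bl2$observed))     # ties everywhere
})

test_that("matched_window_null recovers the marginal tail at infinite tolerance", {
  w <- dip_world(dips = 2e5, seed = 42)
  cfg <- detection_config()
  reg <- detect_regions(w$sf, w$mk, w$map, "desert", cfg, grid = w$grid)
  coding <- numeric(nrow(w$grid))
  other <- runif(nrow(w$grid))
  mn <- matched_window_null(reg[1, ], w$grid, coding, other, cfg,
                            tolerance = Inf)
  expect_lt(abs(mn$probability - cfg$share_quantile), 0.03)
  # coding-matched candidates in a coding-correlated landscape exceed the
  # unmatched marginal (direct enumeration, constructed correlation)
  coding2 <- round(runif(nrow(w$grid), 0, 1000))
  other2 <- 1 - coding2 / 1000 + runif(nrow(w$grid), 0, 0.1)
  reg_cod <- sum(coding2[w$grid$chrom == reg$chrom[1] &
                           w$grid$end > reg$start[1] &
                           w$grid$start < reg$end[1]])
  mn2 <- matched_window_null(reg[1, ], w$grid, coding2, other2, cfg,
                             tolerance = max(100, 0.2 * reg_cod))
  expect_gt(mn2$n_candidates, 0)
})

test_that("bootstrap_observed_counts resamples shared flags", {
  expect_true(all(bootstrap_observed_counts(rep(TRUE, 7), 50, seed = 1) == 7))
  expect_true(all(bootstrap_observed_counts(rep(FALSE, 7), 50, seed = 1) == 0))
  b <- bootstrap_observed_counts(rep(c(TRUE, FALSE), 10), 4000, seed = 2)
  expect_lt(abs(mean(b) - 10), 0.2)              # binomial mean oracle
  expect_true(all(bootstrap_observed_counts(logical(0), 10) == 0))
})
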