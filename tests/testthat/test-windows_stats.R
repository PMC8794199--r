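test_that("summarize_windows averages dosage/2 and flags empty windows", {
  map <- uniform_map(300, 0.3)
  g <- make_windows(map, "bp", 100)
  am <- ancestry_matrix(matrix(2L, 3, 4), mk_at(c(10, 50, 110, 150)))
  ws <- summarize_windows(am, g, map)
  expect_equal(ws$ancestry[1:2], c(1, 1))
  expect_false(ws$valid[3])                      # no markers
  # checkerboard 0/2 over 10 markers -> 0.5
  am2 <- ancestry_matrix(matrix(rep(c(0L, 2L), 5), 1), mk_at(1:10 * 9))
  expect_equal(summarize_windows(am2, g, map)$ancestry[1], 0.5)
  # recombination rate: cM span over Mb span (0.1 cM per 1e-4 Mb window)
  expect_equal(ws$rec_rate, rep(1000, 3))
})

test_that("spearman reproduces the closed form and handles errors", {
  expect_equal(spearman(1:5, 1:5 * 2)$rho, 1)
  expect_equal(spearman(1:5, -(1:5))$rho, -1)
  r <- spearman(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)                       # 1 - 6*2/(5*24)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 1:2), "at least 3")
  # closed form 1 - 6*sum(d^2)/(n(n^2-1)) without ties (property)
  set.seed(21)
  for (r in 1:10) {
    x <- sample(100, 30); y <- sample(100, 30)
    d <- rank(x) - rank(y)
    expect_equal(spearman(x, y)$rho, 1 - 6 * sum(d^2) / (30 * (30^2 - 1)))
  }
  # agreement with the stats::cor.test oracle (rho and t-approx p)
  set.seed(22)
  x <- rnorm(40); y <- x + rnorm(40)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(spearman(x, y)$rho, unname(ct$estimate))
})

test_that("spearman permutation p is available for small n", {
  set.seed(23)
  x <- rnorm(12); y <- x + rnorm(12, sd = 0.4)
  p <- spearman(x, y, permutation_p = TRUE, n_perm = 2000)$p
  expect_lt(p, 0.05)
})

test_that("spearman_partial reduces, matches the recursive formula, signals", {
  set.seed(24)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  expect_equal(spearman_partial(x, y, NULL)$rho, spearman(x, y)$rho)
  # recursive-formula oracle on ranks for one covariate
  rho_xy <- spearman(x, y)$rho
  rho_xz <- spearman(x, z)$rho
  rho_yz <- spearman(y, z)$rho
  oracle <- (rho_xy - rho_xz * rho_yz) /
    sqrt((1 - rho_xz^2) * (1 - rho_yz^2))
  expect_equal(spearman_partial(x, y, cbind(z))$rho, oracle,
               tolerance = 1e-10)
  # degenerate projection: covariate identical to y -> NA, not 0
  expect_warning(r <- spearman_partial(x, y, cbind(y)), "degenerate")
  expect_true(is.na(r$rho))
  expect_error(spearman_partial(x, y, cbind(z, z)), "collinear")
  # with independent covariates the partial tracks the plain coefficient
  set.seed(25)
  n <- 400
  x2 <- rnorm(n); y2 <- 0.5 * x2 + rnorm(n); z2 <- matrix(rnorm(2 * n), n)
  expect_lt(abs(spearman_partial(x2, y2, z2)$rho - spearman(x2, y2)$rho),
            0.05)
})

test_that("thin_windows retains one window per separation greedily", {
  ws <- data.frame(chrom = "c", start = c(0, 2e5, 6e5, 1.2e6),
                   end = c(1, 2, 3, 4) * 1e5 + c(0, 2e5, 6e5, 1.2e6))
  th <- thin_windows(ws, 5e5)
  expect_equal(th$start, c(0, 6e5, 1.2e6))
  expect_equal(nrow(thin_windows(ws, 1)), 4)
})

test_that("exclude_regions uses any-overlap semantics", {
  map <- uniform_map(300, 0.3)
  g <- make_windows(map, "bp", 100)
  am <- ancestry_matrix(matrix(1L, 2, 3), mk_at(c(10, 110, 210)))
  ws <- summarize_windows(am, g, map)
  expect_equal(exclude_regions(ws, annotation_track(
    data.frame(chrom = character(0), start = numeric(0),
               end = numeric(0))))$valid, ws$valid)
  inv <- annotation_track(data.frame(chrom = "chr1", start = 99, end = 100,
                                     class = "inversion"))
  ws2 <- exclude_regions(ws, inv)                # 1 bp overlap with window 1
  expect_equal(ws2$valid, c(FALSE, TRUE, TRUE))
  full <- annotation_track(data.frame(chrom = "chr1", start = 100, end = 200,
                                      class = "inversion"))
  expect_false(exclude_regions(ws, full)$valid[2])
})

test_that("chromosome_stats correlates ancestry with length", {
  set.seed(26)
  n_chr <- 24
  lens <- sort(sample(5e5 + 1:n_chr * 1e5))
  ws <- do.call(rbind, lapply(seq_len(n_chr), function(c)
    data.frame(chrom = paste0("c", c), start = 0, end = lens[c],
               ancestry = rank(lens)[c] / n_chr, n_aims = 10, valid = TRUE)))
  cs <- chromosome_stats(ws)
  expect_equal(cs$cor_length$rho, 1)
  ws$ancestry <- 0.5
  expect_error(chromosome_stats(ws), "constant")
  genes <- setNames(sample(100:500, n_chr), paste0("c", seq_len(n_chr)))
  ws$ancestry <- rank(genes) / n_chr
  cs2 <- chromosome_stats(ws, genes)
  expect_equal(cs2$cor_genes$rho, 1)
})

test_that("ancestry_by_distance bins by nearest-site distance", {
  map <- uniform_map(1e6, 1)
  g <- make_windows(map, "bp", 1e4)
  set.seed(27)
  am <- ancestry_matrix(matrix(rbinom(2 * 100, 2, 0.3), 2, 100),
                        mk_at(0:99 * 1e4 + 5000))
  ws <- summarize_windows(am, g, map)
  sites <- data.frame(chrom = "chr1", pos = 5e5)
  prof <- ancestry_by_distance(ws, sites, n_boot = 50,
                               breaks = c(0, 1e5, 5e5, 1e6), seed = 1)
  expect_equal(sum(prof$n_windows), 100)
  # brute-force nearest-site distances
  mid <- (ws$start + ws$end) / 2
  d <- abs(mid - 5e5)
  d[ws$start <= 5e5 & ws$end > 5e5] <- 0
  expect_equal(prof$n_windows[1], sum(d < 1e5))
  # constant ancestry -> flat profile, envelope hugging the constant
  am2 <- ancestry_matrix(matrix(1L, 2, 100), mk_at(0:99 * 1e4 + 5000))
  ws2 <- summarize_windows(am2, g, map)
  prof2 <- ancestry_by_distance(ws2, sites, n_boot = 20,
                                breaks = c(0, 2e5, 6e5), seed = 1)
  expect_true(all(abs(prof2$mean_ancestry - 0.5) < 1e-12))
  expect_true(all(abs(prof2$boot_lo - 0.5) < 1e-12))
})

test_that("region_ancestry_summary normalizes by the genome-wide mean", {
  set.seed(28)
  am <- ancestry_matrix(matrix(rbinom(300, 2, 0.3), 3, 100),
                        mk_at(1:100 * 100))
  whole <- data.frame(chrom = "chr1", start = 0, end = 11000)
  expect_equal(region_ancestry_summary(am, whole)$ratio, 1)
  d <- am$dosage; d[, 1:10] <- 0L
  am2 <- ancestry_matrix(d, am$markers)
  zero <- data.frame(chrom = "chr1", start = 0, end = 1050)
  expect_equal(region_ancestry_summary(am2, zero)$ratio, 0)
  # random region vs direct marker-mean oracle
  reg <- data.frame(chrom = "chr1", start = 2500, end = 7700)
  r <- region_ancestry_summary(am, reg)
  jj <- which(am$markers$pos >= 2500 & am$markers$pos < 7700)
  expect_equal(r$ancestry, mean(am$dosage[, jj]) / 2)
})
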