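# Shared fixtures: tiny maps and matrices built in code.

# A map from explicit anchors; lengths in bp/cM per chromosome.
toy_map <- function() {
  genetic_map(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos_bp = c(0, 1e6, 2e6, 0, 2e6),
    pos_cM = c(0, 0.5, 2.5, 0, 2.0)))
}

# Uniform-rate map: one chromosome, `cm` cM over `bp` basepairs.
uniform_map <- function(bp = 1e6, cm = 1, chrom = "chr1") {
  genetic_map(data.frame(chrom = chrom, pos_bp = c(0, bp), pos_cM = c(0, cm)))
}

# Markers at given positions on one chromosome.
mk_at <- function(pos, chrom = "chr1") {
  marker_set(data.frame(chrom = chrom, pos = pos))
}

# Ancestry matrix from a dosage matrix and marker positions.
am_of <- function(dosage, pos, chrom = "chr1") {
  ancestry_matrix(rbind(dosage), mk_at(pos, chrom))
}

# Random ancestry matrix (n individuals x m markers, iid dosages).
random_am <- function(n, m, map, p = 0.3, chrom = "chr1") {
  pos <- sort(sample.int(map$len_bp[[chrom]] - 1, m))
  ancestry_matrix(matrix(rbinom(n * m, 2, p), n, m), mk_at(pos, chrom))
}

# Brute-force per-basepair annotation count (oracle for count_annotation_bp).
brute_annotation_bp <- function(track, grid, class) {
  vapply(seq_len(nrow(grid)), function(w) {
    bps <- seq(grid$start[w], grid$end[w] - 1)
    covered <- rep(FALSE, length(bps))
    tr <- track[track$class == class & track$chrom == grid$chrom[w], ]
    for (i in seq_len(nrow(tr)))
      covered <- covered | (bps >= tr$start[i] & bps < tr$end[i])
    sum(covered)
  }, numeric(1))
}

# Randomized empirical p from a permutation-null result (uniform under the
# null when the statistic is exchangeable).
randomized_p <- function(null, observed) {
  (sum(null > observed) + runif(1) * (1 + sum(null == observed))) /
    (length(null) + 1)
}
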