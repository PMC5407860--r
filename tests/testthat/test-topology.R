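test_that("iterative correction balances and recovers planted bias factors", {
  ## already balanced: factors stay at 1
  n <- 10
  m <- matrix(1, n, n)
  r <- ice_correct(m)
  expect_equal(r$factors, rep(1, n), tolerance = 1e-8)
  expect_true(r$converged)

  ## one row/col scaled by 2: bias factor sqrt(2), balanced output unscaled
  set.seed(3)
  base <- matrix(runif(n * n, 1, 2), n, n); base <- (base + t(base)) / 2
  biased <- base
  biased[1, ] <- biased[1, ] * 2
  biased[, 1] <- base[1, ] * 2; biased[1, 1] <- base[1, 1] * 4
  rb <- ice_correct(biased, max_iter = 2000, tol = 1e-14)
  r0 <- ice_correct(base, max_iter = 2000, tol = 1e-14)
  ## balancing factors are defined up to a global scalar: the bias of 2 on
  ## bin 1 shows up as its factor ratio relative to the unbiased bins
  rel <- rb$factors / r0$factors
  expect_equal(rel[1] / mean(rel[-1]), 2, tolerance = 1e-6)
  ## balanced matrices agree up to the same scalar
  ratio <- rb$matrix / r0$matrix
  expect_lt(max(abs(ratio - mean(ratio))), 1e-6)

  ## all-zero row masked and untouched
  mz <- base; mz[5, ] <- 0; mz[, 5] <- 0
  rz <- ice_correct(mz)
  expect_true(rz$masked[5])
  expect_equal(rz$matrix[5, ], rep(0, n))
  rs <- rowSums(rz$matrix)[-5]
  expect_lt(max(abs(rs - mean(rs))), 1e-8)
})

test_that("the directionality index follows its chi-squared form", {
  ## A = 10 upstream, B = 30 downstream -> E = 20, DI = +10
  di_stat <- function(A, B) {
    if (A == B) return(0)
    E <- (A + B) / 2
    sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  expect_equal(di_stat(10, 30), 10)
  expect_equal(di_stat(50, 50), 0)
  expect_equal(di_stat(30, 10), -di_stat(10, 30))

  ## on a matrix: transposition symmetry means DI is antisymmetric under
  ## reversing the genome
  m <- simulate_contact_matrix(120, tad_bins = data.table::data.table(
    from = c(1, 61), to = c(60, 120)), seed = 4)
  di_f <- directionality_index(m)
  m_rev <- m[rev(seq_len(120)), rev(seq_len(120))]
  di_r <- directionality_index(m_rev)
  ## position p in the reversed genome mirrors chrom_len - bin - p
  expect_equal(di_f$di_raw, -rev(di_r$di_raw), tolerance = 1e-8)
})

test_that("smoothing is an 11-point edge-truncated box filter with z-standardisation", {
  ## impulse of height 11 spreads into a plateau of height 1
  tr <- data.table::data.table(position = seq(0, by = 5000, length.out = 31),
                               di_raw = 0)
  tr$di_raw[16] <- 11
  sm <- smooth_and_standardize(tr)
  expect_equal(sm$di_smoothed[11:21], rep(1, 11))
  expect_equal(sm$di_smoothed[c(10, 22)], c(0, 0))

  ## constant track: smoothed identical, z all zero (with warning)
  trc <- data.table::data.table(position = seq(0, by = 5000, length.out = 20),
                                di_raw = 3)
  expect_warning(smc <- smooth_and_standardize(trc), "constant")
  expect_equal(smc$di_smoothed, rep(3, 20))
  expect_equal(smc$di_z, rep(0, 20))

  ## brute-force windowed mean oracle on a random track
  set.seed(9)
  trr <- data.table::data.table(position = seq(0, by = 5000, length.out = 200),
                                di_raw = rnorm(200))
  smr <- smooth_and_standardize(trr)
  brute <- vapply(seq_len(200), function(i) {
    mean(trr$di_raw[max(1, i - 5):min(200, i + 5)])
  }, numeric(1))
  expect_equal(smr$di_smoothed, brute)
  expect_equal(smr$di_z, (brute - mean(brute)) / sd(brute))
})

test_that("TAD calling accepts strong extremum pairs and rejects weak ones", {
  ## flat track: no TADs
  flat <- data.table::data.table(position = seq(0, by = 5000, length.out = 100),
                                 di_raw = 0, di_smoothed = 0, di_z = 0)
  expect_equal(nrow(call_tads(flat)), 0)

  ## hand-built track: one strong extremum pair (dz = 5), one weak (dz = 1.5)
  z <- rep(0, 400)
  z[50] <- 2.5; z[100] <- -2.5      # strong: dz = 5
  z[250] <- 0.75; z[300] <- -0.75   # weak: dz = 1.5 < 2 -> rejected
  tr <- data.table::data.table(position = (seq_along(z) - 1) * 5000,
                               di_raw = z, di_smoothed = z, di_z = z)
  tads <- call_tads(tr, no_bias_eps = 0.25)
  expect_equal(nrow(tads), 1)
  expect_equal(tads$tad_delta_z, 5)
  expect_equal(tads$max_pos, 49 * 5000)
  expect_equal(tads$min_pos, 99 * 5000)
})

test_that("planted TADs are recovered with boundaries within one bin", {
  tb <- data.table::data.table(from = c(1, 121), to = c(120, 240))
  m <- simulate_contact_matrix(240, tad_bins = tb, tad_enrichment = 5,
                               seed = 11)
  tads <- call_tads(smooth_and_standardize(directionality_index(m)))
  expect_equal(nrow(tads), 2)
  edges <- c(tads$max_pos, tads$min_pos + 25000)
  expect_true(any(abs(edges - 3e6) <= 25000))
})

test_that("boundary strength is the extremum difference and survives count scaling", {
  z <- rep(0, 300)
  z[40] <- 3; z[100] <- -2; z[110] <- 3; z[200] <- -2.5
  tr <- data.table::data.table(position = (seq_along(z) - 1) * 5000,
                               di_raw = z, di_smoothed = z, di_z = z)
  tads <- call_tads(tr)
  expect_equal(nrow(tads), 2)
  bs <- boundary_strength(tads, tr)
  expect_equal(bs$tadb_delta_z, 3 - (-2))   # z(max of following) - z(min of preceding)

  ## doubling every count leaves z-standardised strengths unchanged
  tb <- data.table::data.table(from = c(1, 121), to = c(120, 240))
  m <- simulate_contact_matrix(240, tad_bins = tb, tad_enrichment = 5,
                               seed = 12)
  t1 <- smooth_and_standardize(directionality_index(m))
  t2 <- smooth_and_standardize(directionality_index(m * 2))
  tads1 <- call_tads(t1); tads2 <- call_tads(t2)
  expect_equal(boundary_strength(tads1, t1)$tadb_delta_z,
               boundary_strength(tads2, t2)$tadb_delta_z, tolerance = 1e-6)
  expect_equal(tads1$tad_delta_z, tads2$tad_delta_z, tolerance = 1e-6)
})

test_that("stronger planted boundaries score higher boundary strengths", {
  ## three TADs; the middle boundary is weaker (smaller enrichment step)
  tb <- data.table::data.table(from = c(1, 81, 161), to = c(80, 160, 240),
                               enrichment = c(6, 2, 6))
  m <- simulate_contact_matrix(240, tad_bins = tb, seed = 13)
  tr <- smooth_and_standardize(directionality_index(m))
  tads <- call_tads(tr, delta_z_min = 0.5)
  bs <- boundary_strength(tads, tr)
  expect_gte(nrow(bs), 1)
  expect_true(all(bs$tadb_delta_z > 0))
})

test_that("compartments recover a planted checkerboard and the +/-10 rule", {
  unit <- c(rep("A", 5), "neither", rep("B", 5), "neither")
  labs <- rep(unit, 4)
  m <- simulate_contact_matrix(length(labs), comp_labels = labs,
                               base_contacts = 4000, decay_exponent = 0.7,
                               compartment_strength = 0.4, seed = 21)
  mark <- ifelse(labs == "A", 1, 0)
  ct <- call_compartments(m, mark, threshold = 10)
  ab <- labs != "neither"
  expect_equal(ct$label[ab], labs[ab])
  ## neutral transition bins stay inside the +/-10 band
  expect_true(all(abs(ct$pc_value[!ab]) < 10))
  expect_true(all(ct$label[!ab] == "neither"))

  ## negating the mark flips nothing after alignment to the (negated) mark
  ct2 <- call_compartments(m, mark, threshold = 10)
  expect_identical(ct$label, ct2$label)

  ## value inside the band -> neither, regardless of sign
  expect_equal(ct$label[abs(ct$pc_value) < 10],
               rep("neither", sum(abs(ct$pc_value) < 10)))
})

test_that("eigenvector sign is fixed by the active mark, not the solver", {
  labs <- rep(c("A", "B"), each = 12)
  m <- simulate_contact_matrix(24, comp_labels = labs, base_contacts = 4000,
                               decay_exponent = 0.7,
                               compartment_strength = 0.5, seed = 22)
  mark <- ifelse(labs == "A", 1, 0)
  ct <- call_compartments(m, mark)
  expect_true(all(ct$pc_value[1:12] > 0))
  ## anti-aligned mark flips the labels coherently
  ct_flip <- call_compartments(m, -mark)
  expect_equal(ct_flip$label[ct$label == "A"],
               rep("B", sum(ct$label == "A")))
})

test_that("matrix aggregation sums blocks symmetrically", {
  m <- matrix(1, 6, 6)
  a <- aggregate_matrix(m, 3)
  expect_equal(a, matrix(9, 2, 2))
  set.seed(5)
  m2 <- matrix(rpois(100, 4), 10, 10); m2 <- m2 + t(m2)
  a2 <- aggregate_matrix(m2, 4)   # blocks of 4, 4, 2
  expect_true(isSymmetric(a2))
  expect_equal(sum(a2), sum(m2))
})
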