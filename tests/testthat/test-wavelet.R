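test_that("wavelet specs satisfy the admissibility invariants", {
  haar <- make_wavelet("haar")
  expect_equal(haar$lowpass, c(1, 1) / sqrt(2), tolerance = 1e-15)
  expect_equal(sort(abs(haar$highpass)), c(1, 1) / sqrt(2), tolerance = 1e-15)
  for (nm in c("haar", "db2", "db4")) {
    w <- make_wavelet(nm)
    expect_lt(abs(sum(w$highpass)), 1e-10)
    expect_lt(abs(sum(w$lowpass) - sqrt(2)), 1e-10)
    expect_equal(sum(w$lowpass^2), 1, tolerance = 1e-12)
  }
  expect_error(make_wavelet("coif17"), "supported wavelets")
})

test_that("the 1-D analysis step matches the convolve-and-decimate oracle", {
  w <- make_wavelet("haar")
  got <- dwt_step(c(1, 2, 3, 4), w)
  expect_equal(got$approx, c(3, 7) / sqrt(2), tolerance = 1e-12)
  expect_equal(got$detail, c(-1, -1) / sqrt(2), tolerance = 1e-12)
  set.seed(14)
  for (nm in c("haar", "db2", "db4")) {
    w <- make_wavelet(nm)
    x <- rnorm(32)
    got <- dwt_step(x, w)
    want <- oracle_dwt_step(x, w$lowpass, w$highpass)
    expect_equal(got$approx, want$approx, tolerance = 1e-12)
    expect_equal(got$detail, want$detail, tolerance = 1e-12)
  }
})

test_that("constant images are annihilated by all detail bands", {
  dec <- fdwt2(matrix(5, 8, 8), "haar", 1)
  expect_true(all(abs(unlist(dec$details)) < 1e-12))
  expect_true(all(abs(dec$approximation - 10) < 1e-12))
  dec3 <- fdwt2(matrix(2.5, 16, 16), "db2", 2)
  expect_true(all(abs(unlist(dec3$details)) < 1e-10))
})

test_that("fdwt2 rejects impossible depths", {
  expect_error(fdwt2(matrix(0, 8, 8), "haar", 4), "\\[1, 3\\]")
})

test_that("the 2-D transform is invertible and energy-preserving", {
  set.seed(15)
  for (nm in c("haar", "db2", "db4")) {
    for (J in 1:3) {
      x <- matrix(rnorm(32 * 32), 32, 32)
      dec <- fdwt2(x, nm, J)
      expect_lt(max(abs(ifdwt2(dec) - x)), 1e-8)
      energy <- sum(dec$approximation^2) + sum(unlist(dec$details)^2)
      expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-6)
    }
  }
})

test_that("reconstruction is linear: zeroed smooth band subtracts it", {
  set.seed(16)
  x <- matrix(rnorm(16 * 16), 16, 16)
  dec <- fdwt2(x, "haar", 2)
  smooth_only <- dec
  for (j in 1:2) {
    smooth_only$details[[j]] <- lapply(smooth_only$details[[j]],
                                       function(m) m * 0)
  }
  no_smooth <- dec
  no_smooth$approximation <- dec$approximation * 0
  expect_lt(max(abs(ifdwt2(no_smooth) - (x - ifdwt2(smooth_only)))), 1e-10)
  zero <- fdwt2(matrix(0, 8, 8), "haar", 1)
  expect_true(all(ifdwt2(zero) == 0))
})

test_that("subband statistics match a brute-force recomputation", {
  dec0 <- fdwt2(matrix(0, 8, 8), "haar", 1)
  s0 <- subband_statistics(dec0)
  expect_true(all(as.numeric(s0) == 0))

  # forced arithmetic on a hand-built subband
  v <- c(1, -1, 1, -1)
  expect_equal(mean(abs(v)), 1)
  expect_equal(mean(v^2), 1)

  set.seed(17)
  dec <- fdwt2(matrix(rnorm(256), 16, 16), "db2", 2)
  st <- subband_statistics(dec)
  expect_equal(ncol(st), (3 * 2 + 1) * 4)
  for (band in c("horizontal", "vertical", "diagonal")) {
    coef <- as.vector(dec$details[[2]][[band]])
    expect_equal(st[[sprintf("L2_%s_mean", band)]], mean(abs(coef)))
    expect_equal(st[[sprintf("L2_%s_sd", band)]], sd(coef))
    expect_equal(st[[sprintf("L2_%s_energy", band)]], mean(coef^2))
    counts <- tabulate(pmin(64, floor(abs(coef) / max(abs(coef)) * 64) + 1), 64)
    p <- counts[counts > 0] / sum(counts)
    expect_equal(st[[sprintf("L2_%s_entropy", band)]], -sum(p * log2(p)))
  }
})

test_that("feature extraction is shaped, ordered and deterministic", {
  set1 <- make_tiny_set(5, 32, 1, seed = 18)
  feats <- extract_features(set1, "haar", 2)
  expect_equal(dim(feats), c(10, 2 + 28))
  expect_equal(feats$id, set1$id)

  dup <- set1[c(1, 1, 2), ]
  fd <- extract_features(dup, "haar", 2)
  expect_identical(fd[1, -1], fd[2, -1])

  f2 <- extract_features(set1, "haar", 2)
  expect_identical(feats, f2)
})

test_that("band-energy features separate the two synthetic classes", {
  feats <- extract_features(make_tiny_set(10, 64, 1, seed = 19), "haar", 3)
  energy_cols <- grep("L1_.*_energy", names(feats), value = TRUE)
  gaps <- vapply(energy_cols, function(cl) {
    a <- feats[[cl]][feats$label == 0]
    b <- feats[[cl]][feats$label == 1]
    abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
  }, numeric(1))
  expect_gt(max(gaps), 1)  # effect size above 1 on at least one energy band
})
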