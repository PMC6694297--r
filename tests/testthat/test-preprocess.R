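test_that("discard_initial drops volumes and motion rows in lockstep", {
  mask <- array(TRUE, c(3, 3, 2))
  vs <- volume_series(matrix(rnorm(18 * 600), 18, 600), mask, tr = 2)
  motion <- matrix(rnorm(600 * 6), 600, 6)
  out <- discard_initial(vs, motion, 5)
  expect_equal(ncol(out$vs$mat), 595)
  expect_equal(nrow(out$motion), 595)
  expect_equal(out$vs$mat, vs$mat[, 6:600])
  expect_equal(out$motion, motion[6:600, ])

  ident <- discard_initial(vs, motion, 0)
  expect_identical(ident$vs$mat, vs$mat)

  vs5 <- volume_series(matrix(rnorm(18 * 5), 18, 5), mask, tr = 2)
  expect_error(discard_initial(vs5, NULL, 5), "n_discard")
  expect_error(discard_initial(vs, motion[1:10, ], 5), "motion")
})

test_that("spatial smoothing is identity at fwhm 0 and conserves interior mass", {
  mask <- array(TRUE, c(19, 19, 13))
  mat <- matrix(rnorm(prod(dim(mask)) * 3), ncol = 3)
  vs <- volume_series(mat, mask, tr = 2)
  expect_identical(smooth_spatial(vs, 0), vs)

  # deep-interior impulse (beyond twice the kernel half-width from any
  # edge): smoothing redistributes but conserves total mass
  imp <- matrix(0, prod(dim(mask)), 1)
  centre <- 10L + (10L - 1L) * 19L + (7L - 1L) * 19L * 19L  # voxel (10,10,7)
  imp[centre, 1] <- 7.5
  vs_imp <- volume_series(imp, mask, tr = 2)
  sm <- smooth_spatial(vs_imp, 1.2, c(0.4, 0.4, 0.6))
  expect_lt(max(sm$mat), 7.5)          # actually spread out
  expect_equal(sum(sm$mat), 7.5, tolerance = 1e-6)

  expect_error(smooth_spatial(vs, 1.2, c(0, 0.4, 0.6)), "positive")
})

test_that("smoothing kernel sigma follows the FWHM identity", {
  # fwhm 1.2 mm on 0.4 mm voxels -> sigma = 1.2/2.3548/0.4 voxels; check the
  # impulse response against an analytic separable Gaussian (renormalised)
  n <- 21
  mask <- array(TRUE, c(n, 1, 1))
  imp <- matrix(0, n, 1)
  imp[11, 1] <- 1
  vs <- volume_series(imp, mask, tr = 2)
  sm <- smooth_spatial(vs, 1.2, c(0.4, 0.4, 0.6))
  sig <- 1.2 / (2 * sqrt(2 * log(2))) / 0.4
  half <- ceiling(3 * sig)
  k <- exp(-((-half):half)^2 / (2 * sig^2))
  k <- k / sum(k)
  expect_equal(sm$mat[(11 - half):(11 + half), 1], k, tolerance = 1e-10)
})

test_that("nuisance regression matches the closed-form OLS oracle", {
  set.seed(42)
  for (rep in 1:10) {
    V <- sample(5:50, 1)
    Tn <- sample(20:50, 1)
    ts <- matrix(rnorm(V * Tn), V, Tn)
    motion <- matrix(rnorm(Tn * 6), Tn, 6)
    res <- regress_nuisance(ts, motion, detrend_order = 1)
    X <- attr(res, "design")
    # independent oracle: explicit normal equations per voxel
    H <- X %*% solve(crossprod(X)) %*% t(X)
    oracle <- ts - ts %*% t(H)
    expect_equal(unclass(res)[, ], oracle, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # residuals orthogonal to all regressors
    expect_lt(max(abs(res %*% X)) / max(abs(ts)), 1e-8)
  }
})

test_that("nuisance regression removes exactly-spanned signals", {
  Tn <- 60
  motion <- matrix(rnorm(Tn * 6), Tn, 6)
  ts <- rbind(motion[, 3] * 2.5,              # a motion column
              3 + 2 * seq_len(Tn) / Tn)       # a linear trend
  res <- regress_nuisance(ts, motion, detrend_order = 1)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("rank-deficient nuisance designs drop columns with a warning", {
  Tn <- 40
  motion <- matrix(rnorm(Tn * 6), Tn, 6)
  motion[, 6] <- motion[, 1]                  # duplicated column
  ts <- matrix(rnorm(5 * Tn), 5, Tn)
  expect_warning(res <- regress_nuisance(ts, motion), "collinear")
  expect_lt(max(abs(res %*% attr(res, "design"))) / max(abs(ts)), 1e-8)
})

test_that("voxelwise z-scoring standardises, zeroes constants, idempotent", {
  m <- rbind(c(1, 2, 3), c(4, 4, 4), rnorm(3))
  z <- zscore_voxelwise(m)
  expect_equal(mean(z[1, ]), 0, tolerance = 1e-10)
  expect_equal(sd(z[1, ]), 1, tolerance = 1e-10)
  expect_equal(z[2, ], c(0, 0, 0))
  expect_equal(attr(z, "constant_rows"), 2L)
  z2 <- zscore_voxelwise(unclass(z))
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("band-pass keeps passband sinusoids, rejects stopband and DC", {
  tr <- 2
  Tn <- 300
  tt <- seq_len(Tn) * tr
  inband <- matrix(sin(2 * pi * 0.05 * tt), 1)
  out <- bandpass(inband, tr, 0.01, 0.1)
  expect_gte(var(out[1, ]) / var(inband[1, ]), 0.9)

  stopb <- matrix(sin(2 * pi * 0.2 * tt), 1)
  out2 <- bandpass(stopb, tr, 0.01, 0.1)
  expect_lte(var(out2[1, ]) / var(stopb[1, ]), 0.1)

  const <- matrix(rep(3.7, Tn), 1)
  out3 <- bandpass(const, tr, 0.01, 0.1)
  expect_lt(max(abs(out3)), 1e-3 * 3.7)

  expect_error(bandpass(inband, tr, 0.01, 0.3), "Nyquist")
})

test_that("preprocess_series applies the fixed stage order and leaves the mask grid intact", {
  des <- small_design(seed = 4)
  tr <- ground_truth(des, networks = c("a", "b"),
                     amp_slope = matrix(0, 2, 2))
  acq <- synthesize_subject(tr, des, group = 0, age = 8, seed = 7)
  pv <- preprocess_series(acq$vs, acq$motion, n_discard = 5, fwhm_mm = 1.2,
                          voxel_size_mm = des$voxel_size_mm)
  expect_equal(ncol(pv$mat), des$n_volumes - 5)
  expect_equal(nrow(pv$mat), sum(tr$mask))
  # voxel means ~0 after detrend + z-score + band-pass (DC removed)
  expect_lt(max(abs(rowMeans(pv$mat))), 0.05)
})
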