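make_series <- function(arr4, voxel_mm = c(1, 1, 1), TR = 10)
  volume_series(arr4, voxel_mm, TR_s = TR, TA_s = 1)

test_that("Gaussian smoothing matches the closed-form kernel and preserves constants", {
  arr <- array(rnorm(6 * 6 * 6 * 2), dim = c(6, 6, 6, 2))
  ser <- make_series(arr)
  expect_identical(smooth_volumes(ser, 0)$data, arr)

  const <- make_series(array(7, dim = c(6, 6, 6, 1)))
  expect_equal(smooth_volumes(const, 2)$data,
               array(7, dim = c(6, 6, 6, 1)), tolerance = 1e-12)

  # point impulse away from edges: centre/neighbour ratio of the separable
  # Gaussian with SD = 2 / 2.3548 = 0.849 voxels
  imp <- array(0, dim = c(11, 11, 11, 1))
  imp[6, 6, 6, 1] <- 1
  sm <- smooth_volumes(make_series(imp), 2)$data
  sd_vox <- 2 / (2 * sqrt(2 * log(2)))
  expect_equal(sm[6, 6, 6, 1] / sm[7, 6, 6, 1],
               exp(0) / exp(-1 / (2 * sd_vox^2)), tolerance = 1e-10)
  # separability: diagonal neighbour = product of axis factors
  expect_equal(sm[7, 7, 6, 1] / sm[6, 6, 6, 1],
               exp(-1 / (2 * sd_vox^2))^2, tolerance = 1e-10)
  expect_error(smooth_volumes(ser, -1), ">= 0")
})

test_that("global scaling maps every volume's in-brain mean to exactly 100", {
  arr <- array(0, dim = c(4, 4, 1, 2))
  arr[, , , 1] <- 250
  arr[, , , 2] <- 250 + rnorm(16, sd = 5)
  ser <- global_scale(make_series(arr))
  expect_equal(mean(ser$data[, , , 1]), 100)
  expect_equal(mean(ser$data[, , , 2]), 100)
  expect_equal(ser$data[, , , 1], arr[, , , 1] * 0.4, tolerance = 1e-12)

  # already at mean 100: unchanged
  arr2 <- array(100, dim = c(4, 4, 1, 1))
  expect_equal(global_scale(make_series(arr2))$data, arr2)

  # two volumes with means 200 and 50 both end at exactly 100
  arr3 <- array(c(rep(200, 16), rep(50, 16)), dim = c(4, 4, 1, 2))
  out3 <- global_scale(make_series(arr3))
  expect_equal(unique(as.vector(out3$data)), 100)

  neg <- array(-5, dim = c(2, 2, 1, 1))
  expect_error(global_scale(make_series(neg)), "non-positive|no in-brain")
})

test_that("design matrix has balanced indicators and period-limited drift columns", {
  sched <- make_schedule(540, rate_conditions()$label, seed = 1)
  X <- build_design(sched, 300)
  cc <- attr(X, "condition_cols")
  expect_equal(unname(colSums(X[, cc])), rep(45, 6))
  # indicators are mutually orthogonal
  G <- crossprod(X[, cc])
  expect_equal(unname(G - diag(diag(G))), matrix(0, 6, 6))
  # DCT count: ceil(2*5400/300) - 1 = 35 drift columns, all with period > 300 s
  expect_equal(sum(grepl("drift", colnames(X))), 35)
  expect_equal(qr(X)$rank, ncol(X))

  # cutoff at least twice the session length: no drift at all
  sched20 <- make_schedule(20, "a", seed = 1)
  expect_equal(sum(grepl("drift", colnames(build_design(sched20, 400)))), 0)
  # 20 volumes at TR 10 (200 s session), cutoff 300 s: a single drift column
  expect_equal(sum(grepl("drift", colnames(build_design(sched20, 300)))), 1)

  # collinear design is refused with the offending column named
  bad <- sched20
  bad$condition <- rep("a", 20)   # condition indicator == constant
  expect_error(build_design(bad, 300), "rank deficient.*constant|constant.*rank")
})

test_that("voxel-wise GLM equals the brute-force normal-equations oracle", {
  # single-voxel toy fixture: 8 volumes, one condition
  y <- c(99.2, 101.5, 100.1, 102.3, 98.7, 101.9, 100.4, 101.1)
  sched <- make_schedule(8, "a", seed = 2, TR_s = 10)
  X <- build_design(sched, 1e6)
  ser <- make_series(array(rep(y, each = 1), dim = c(1, 1, 1, 8)))
  sm <- fit_glm(ser, X)
  oracle <- ols_oracle(unclass(X)[, , drop = FALSE], y, test_cols = 1)
  expect_equal(sm$beta[1, 1], oracle$beta[1], tolerance = 1e-10)
  expect_equal(sm$t[1, 1], oracle$t[1], tolerance = 1e-10)
  expect_equal(sm$F[1], oracle$F, tolerance = 1e-10)
  expect_equal(sm$df, oracle$df)

  # property: random <= 10-volume fixtures, several voxels, vs oracle
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(c(6, 8, 10), 1)
    schedr <- make_schedule(n, "a", seed = rep)
    Xr <- build_design(schedr, 1e6)
    Y <- matrix(100 + rnorm(n * 3), n, 3)
    serr <- make_series(array(t(Y), dim = c(3, 1, 1, n)))
    smr <- fit_glm(serr, Xr)
    for (vx in 1:3) {
      o <- ols_oracle(unclass(Xr)[, , drop = FALSE], Y[, vx], test_cols = 1)
      expect_equal(smr$beta[vx, 1], o$beta[1], tolerance = 1e-10)
      expect_equal(smr$t[vx, 1], o$t[1], tolerance = 1e-10)
      expect_equal(smr$F[vx], o$F, tolerance = 1e-10)
    }
  }
})

test_that("noiseless simulated betas equal the injected response amplitudes", {
  surf <- small_surface()
  truth <- small_truth()
  conds <- rate_conditions()
  sched <- make_schedule(36, conds$label, seed = 3)
  ser <- simulate_sparse_experiment(truth, surf$mesh, sched, conds,
                                    noise_params(sd = 0))
  # series is already at the scaled level (baseline 100), so betas are in
  # percent units without further scaling
  sm <- fit_glm(ser, build_design(sched))
  pref <- audtopo:::voxel_tuning(surf$mesh, truth$rate_hz, 2)
  active <- which(!is.na(pref))
  expected <- sapply(conds$value_hz, function(v)
    tuning_response(v, pref[active], 1.5))
  expect_equal(unname(sm$beta[active, ]), unname(expected), tolerance = 1e-8)

  # through per-volume global scaling, betas keep a per-condition offset
  # that cancels in all voxel differences
  # (exact to first order; second-order terms are O(response^2 / 100))
  sms <- fit_glm(global_scale(ser), build_design(sched))
  d_raw <- sweep(sm$beta[active, ], 2, colMeans(sm$beta[active, ]))
  d_scl <- sweep(sms$beta[active, ], 2, colMeans(sms$beta[active, ]))
  expect_lt(max(abs(d_scl - d_raw)), 0.01)
})

test_that("scaling the raw series leaves scaled-analysis betas and t-values unchanged", {
  surf <- small_surface()
  truth <- small_truth()
  conds <- rate_conditions()
  sched <- make_schedule(24, conds$label, seed = 4)
  ser <- simulate_sparse_experiment(truth, surf$mesh, sched, conds,
                                    noise_params(sd = 2, seed = 9))
  ser2 <- ser
  ser2$data <- ser$data * 3.7
  X <- build_design(sched)
  sm1 <- fit_glm(global_scale(ser), X)
  sm2 <- fit_glm(global_scale(ser2), X)
  expect_equal(sm1$beta, sm2$beta, tolerance = 1e-10)
  expect_equal(sm1$t, sm2$t, tolerance = 1e-10)
})

test_that("slow drifts are absorbed by the cosine regressors", {
  surf <- small_surface()
  truth <- small_truth()
  conds <- rate_conditions()
  sched <- make_schedule(540, conds$label, seed = 6)  # 5400 s session
  ser <- simulate_sparse_experiment(truth, surf$mesh, sched, conds,
                                    noise_params(sd = 0))
  X <- build_design(sched, 300)
  sm0 <- fit_glm(ser, X)
  pref <- audtopo:::voxel_tuning(surf$mesh, truth$rate_hz, 2)
  active <- which(!is.na(pref))
  add_drift <- function(ser, drift) {
    ser$data <- ser$data + rep(drift, each = prod(dim(ser$data)[1:3]))
    ser
  }
  # a 600 s cosine on the session's cosine grid lies in the drift basis
  # (period 2T/k with k = 18 < 35) and is absorbed exactly
  t0 <- seq_len(540) - 0.5
  drift_basis <- 5 * cos(pi * 18 * t0 / 540)
  smd <- fit_glm(add_drift(ser, drift_basis), X)
  expect_lt(max(abs(smd$beta[active, ] - sm0$beta[active, ])), 1e-8)
  # arbitrary phase adds a sine component whose truncated cosine expansion
  # leaks slightly at the session edges; the effect on condition betas
  # stays below 2% of the drift amplitude
  drift_any <- 5 * cos(2 * pi * (t0 * 10) / 600 + 0.8)
  smd2 <- fit_glm(add_drift(ser, drift_any), X)
  expect_lt(max(abs(smd2$beta[active, ] - sm0$beta[active, ])), 0.02 * 5)
})

test_that("omnibus mask is monotone in alpha and handles degenerate voxels", {
  surf <- small_surface()
  truth <- small_truth()
  conds <- rate_conditions()
  sched <- make_schedule(24, conds$label, seed = 8)
  ser <- simulate_sparse_experiment(truth, surf$mesh, sched, conds,
                                    noise_params(sd = 0))
  sm <- fit_glm(ser, build_design(sched))
  pref <- audtopo:::voxel_tuning(surf$mesh, truth$rate_hz, 2)

  m_all <- omnibus_mask(sm, alpha = 1, correction = "none")
  # noiseless responding voxels are always in the mask
  expect_true(all(m_all[!is.na(array(pref, dim = sm$dim))]))
  # pure-baseline voxels with zero variance are excluded
  expect_true(all(!m_all[is.na(array(pref, dim = sm$dim))]))

  m1 <- omnibus_mask(sm, alpha = 0.001)
  m2 <- omnibus_mask(sm, alpha = 0.01)
  expect_true(all(!m1 | m2))          # mask(0.001) subset of mask(0.01)
  mb <- omnibus_mask(sm, alpha = 0.001, correction = "bonferroni")
  expect_true(all(!mb | m1))          # bonferroni is stricter
  expect_error(omnibus_mask(sm, alpha = 0), "alpha")
  expect_error(omnibus_mask(sm, alpha = 1.5), "alpha")
})
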