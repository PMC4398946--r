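test_that("sheet triangulation has the expected regular-grid structure", {
  surf <- make_surface(sheet_spec(c(20, 30), 1))
  expect_equal(nrow(surf$mesh$vertices), 21 * 31)
  expect_equal(nrow(surf$mesh$triangles), 2 * 20 * 30)

  small <- make_surface(sheet_spec(c(10, 10), 5))
  expect_equal(nrow(small$mesh$vertices), 9)
  expect_equal(nrow(small$mesh$triangles), 8)

  # no degenerate triangles
  v <- surf$mesh$vertices
  tr <- surf$mesh$triangles
  areas <- vapply(seq_len(nrow(tr)), function(i) {
    a <- v[tr[i, 2], ] - v[tr[i, 1], ]
    b <- v[tr[i, 3], ] - v[tr[i, 1], ]
    sqrt(sum(c(a[2] * b[3] - a[3] * b[2],
               a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])^2)) / 2
  }, numeric(1))
  expect_true(all(areas > 0))

  expect_error(sheet_spec(c(10, 10), 7), "divide")
  expect_error(sheet_spec(c(2, 10), 2), "vertices per side")
  expect_error(sheet_spec(c(10, 10), 0), "> 0")
})

test_that("every named auditory field is non-empty and connected", {
  for (surf in list(small_surface(), default_surface(),
                    make_surface(sheet_spec(c(10, 10), 5)))) {
    adj <- mesh_adjacency(surf$mesh)
    for (f in field_levels()) {
      idx <- which(surf$parcellation == f)
      expect_gt(length(idx), 0, label = sprintf("field %s size", f))
      expect_true(is_connected(idx, adj), label = sprintf("field %s connected", f))
    }
  }
})

test_that("planted rate map follows the concentric exponential-decay law", {
  surf <- default_surface()
  p <- topo_params()
  truth <- make_ground_truth(surf$mesh, surf$parcellation, p)
  uv <- cbind(surf$mesh$vertices[, 1], abs(surf$mesh$vertices[, 2]))
  d <- sqrt((uv[, 1] - truth$centre[1])^2 + (uv[, 2] - truth$centre[2])^2)
  expected <- pmin(pmax(p$rate_max_hz * 2^(-d / p$rate_decay_mm),
                        p$rate_min_hz), p$rate_max_hz)
  expect_equal(truth$rate_hz, expected, tolerance = 1e-12)

  # one halving per decay length; max rate at (hypothetical) centre
  expect_equal(p$rate_max_hz * 2^(-p$rate_decay_mm / p$rate_decay_mm),
               p$rate_max_hz / 2)
  # concentricity: closer vertex never prefers a slower rate
  ord <- order(d)
  expect_true(all(diff(truth$rate_hz[ord]) <= 1e-12))
  # ranges
  expect_true(all(truth$rate_hz >= 0.5 & truth$rate_hz <= 128))
  expect_true(all(truth$freq_hz >= 500 & truth$freq_hz <= 16000))
  expect_error(make_ground_truth(surf$mesh, surf$parcellation,
                                 topo_params(rate_decay_mm = -1)),
               "invalid parameter")
})

test_that("planted A1 gradient directions and relative angle match the configured study layout", {
  surf <- default_surface()
  truth <- make_ground_truth(surf$mesh, surf$parcellation)
  co <- flatten_field(surf$mesh, surf$parcellation, "A1")
  ff <- fit_gradient(co, log2(truth$freq_hz))
  rf <- fit_gradient(co, log2(truth$rate_hz))
  expect_equal(ff$direction_deg, 165, tolerance = 1e-6)
  # concentric curvature perturbs the rate direction slightly
  expect_lt(abs(rf$direction_deg - 53), 3)
  expect_lt(abs(relative_angle(ff$direction_deg, rf$direction_deg) - 112), 3)
})

test_that("tonotopic gradient reverses exactly at the A1/R and R/RT borders", {
  surf <- default_surface()
  truth <- make_ground_truth(surf$mesh, surf$parcellation)
  parc <- surf$parcellation
  uv <- cbind(surf$mesh$vertices[, 1], abs(surf$mesh$vertices[, 2]))
  # walk an anterior path at fixed lateral position through the core band
  lat <- sort(unique(uv[, 2]))
  lcore <- lat[which.min(abs(lat - 0.4 * max(lat)))]
  on_path <- which(abs(uv[, 2] - lcore) < 1e-9)
  on_path <- on_path[order(uv[on_path, 1])]
  labs <- as.character(parc[on_path])
  lf <- log2(truth$freq_hz[on_path])
  dsign <- sign(diff(lf))
  crossings <- which(labs[-1] != labs[-length(labs)])
  # within-field steps share a constant sign; it flips at each core border
  for (f in c("A1", "R", "RT")) {
    steps <- which(labs[-length(labs)] == f & labs[-1] == f)
    expect_true(length(unique(dsign[steps])) == 1,
                label = sprintf("monotone within %s", f))
  }
  a1r <- crossings[labs[crossings] == "A1" & labs[crossings + 1] == "R"]
  rrt <- crossings[labs[crossings] == "R" & labs[crossings + 1] == "RT"]
  sgn_of <- function(f) {
    steps <- which(labs[-length(labs)] == f & labs[-1] == f)
    unique(dsign[steps])
  }
  expect_equal(sgn_of("A1"), -sgn_of("R"))
  expect_equal(sgn_of("R"), -sgn_of("RT"))
  expect_true(length(a1r) == 1 && length(rrt) == 1)
})

test_that("sparse schedules alternate baseline and balance conditions", {
  rates <- rate_conditions()$label
  sched <- make_schedule(540, rates, seed = 1)
  counts <- table(sched$condition)
  expect_equal(unname(counts[["baseline"]]), 270)
  for (r in rates) expect_equal(unname(counts[[r]]), 45)
  # every other volume (starting with the first) is baseline
  expect_true(all(sched$condition[seq(1, 539, 2)] == "baseline"))
  expect_true(all(sched$condition[seq(2, 540, 2)] != "baseline"))

  freqs <- frequency_conditions()$label
  expect_equal(unname(table(make_schedule(720, freqs, 1)$condition)[freqs]),
               rep(120, 3), ignore_attr = TRUE)

  tiny <- make_schedule(4, "a", seed = 3)
  expect_equal(tiny$condition, c("baseline", "a", "baseline", "a"))

  expect_error(make_schedule(541, rates), "even")
  expect_error(make_schedule(540, rates[1:4]), "balanced")
  expect_identical(make_schedule(540, rates, seed = 7),
                   make_schedule(540, rates, seed = 7))
  expect_false(identical(make_schedule(540, rates, seed = 7)$condition,
                         make_schedule(540, rates, seed = 8)$condition))
})

test_that("noiseless sparse simulation reproduces the tuning model exactly", {
  surf <- small_surface()
  truth <- small_truth()
  conds <- rate_conditions()
  sched <- make_schedule(24, conds$label, seed = 5)
  # pin every vertex to prefer 32 Hz so the peak condition is exact
  truth32 <- truth
  truth32$rate_hz[] <- 32
  ser <- simulate_sparse_experiment(truth32, surf$mesh, sched, conds,
                                    noise_params(sd = 0))
  m <- matrix(ser$data, ncol = 24)
  pref <- rep(NA_real_, nrow(m))
  active <- rowSums(m != 100) > 0
  at32 <- which(sched$condition == "32")
  base <- which(sched$condition == "baseline")
  # peak of the tuning curve: exactly baseline * (1 + a/100)
  expect_equal(unique(as.vector(m[active, at32])), 100 * (1 + 1 / 100))
  # baseline volumes: exactly the baseline level, for every voxel
  expect_true(all(m[, base] == 100))
  # energy accounting: mean over baseline volumes equals baseline exactly
  expect_equal(mean(m[, base]), 100)

  # off-peak conditions follow the log2-Gaussian tuning curve
  at8 <- which(sched$condition == "8")[1]
  expect_equal(unique(as.vector(m[active, at8])),
               100 * (1 + tuning_response(8, 32, 1.5) / 100))

  # seed contract: bit-identical series
  n <- noise_params(sd = 3, seed = 42)
  s1 <- simulate_sparse_experiment(truth, surf$mesh, sched, conds, n)
  s2 <- simulate_sparse_experiment(truth, surf$mesh, sched, conds, n)
  expect_identical(s1$data, s2$data)

  # condition outside the simulated tuning domain: warning and no response
  weird <- structure(data.frame(label = "a", value_hz = 0.01,
                                stringsAsFactors = FALSE), feature = "rate")
  schedw <- make_schedule(4, "a", seed = 1)
  expect_warning(
    serw <- simulate_sparse_experiment(truth, surf$mesh, schedw, weird,
                                       noise_params(sd = 0)),
    "outside simulated tuning domain")
  expect_true(all(serw$data == 100))
})

test_that("phase-run timing places responses at the stimulus blocks", {
  surf <- small_surface()
  truth <- small_truth()
  # TR-aligned timing, no haemodynamic dispersion: onset volume arithmetic
  tm <- phase_timing(TR_s = 2, n_volumes = 225, hemodynamic_delay_s = 0)
  truth500 <- truth; truth500$freq_hz[] <- 500
  ser <- simulate_phase_runs(truth500, surf$mesh, tm, "low_to_high",
                             noise_params(sd = 0))
  m <- matrix(ser$data, ncol = tm$n_volumes)
  vox <- which(rowSums(m != 100) > 0)[1]
  expect_equal(which(m[vox, ] > 100)[1] - 1L, floor(0 / tm$TR_s))

  truth2k <- truth; truth2k$freq_hz[] <- 2000  # middle of the ladder, k = 4
  s_lh <- simulate_phase_runs(truth2k, surf$mesh, tm, "low_to_high",
                              noise_params(sd = 0))
  s_hl <- simulate_phase_runs(truth2k, surf$mesh, tm, "high_to_low",
                              noise_params(sd = 0))
  # symmetry of the middle step: identical responses in both directions
  expect_equal(s_lh$data, s_hl$data)
  # onset volume for block onset 8 s at TR 2 s
  m4 <- matrix(s_lh$data, ncol = tm$n_volumes)
  vox <- which(rowSums(m4 != 100) > 0)[1]
  expect_equal(which(m4[vox, ] > 100)[1] - 1L, floor(8 / tm$TR_s))

  # lowest frequency: low-to-high onset 16 s earlier than high-to-low
  s0_lh <- simulate_phase_runs(truth500, surf$mesh, tm, "low_to_high",
                               noise_params(sd = 0))
  s0_hl <- simulate_phase_runs(truth500, surf$mesh, tm, "high_to_low",
                               noise_params(sd = 0))
  mlh <- matrix(s0_lh$data, ncol = tm$n_volumes)
  mhl <- matrix(s0_hl$data, ncol = tm$n_volumes)
  on_lh <- (which(mlh[vox, ] > 100)[1] - 1L) * tm$TR_s
  on_hl <- (which(mhl[vox, ] > 100)[1] - 1L) * tm$TR_s
  expect_equal(on_hl - on_lh, 16)

  expect_error(phase_timing(n_volumes = 100), "shorter")
})

test_that("right-hemisphere sheets are mirror images with consistent parcellation", {
  L <- make_surface(sheet_spec(c(16, 12), 2, hemisphere = "left",
                               grid_margin_mm = 2, n_slices = 5))
  R <- make_surface(sheet_spec(c(16, 12), 2, hemisphere = "right",
                               grid_margin_mm = 2, n_slices = 5))
  expect_equal(L$mesh$vertices[, 2], -R$mesh$vertices[, 2])
  expect_identical(as.character(L$parcellation), as.character(R$parcellation))
  expect_equal(as.numeric(L$mesh$vertices %*% L$mesh$axes$lateral),
               as.numeric(R$mesh$vertices %*% R$mesh$axes$lateral))
})
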