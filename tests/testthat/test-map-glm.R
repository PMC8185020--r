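test_that("Gaussian smoothing reproduces the closed-form kernel", {
  expect_equal(gaussian_smooth(array(1:27, c(3, 3, 3)), fwhm = 0),
               array(1:27, c(3, 3, 3)))

  gs <- c(31, 31, 31)
  delta <- array(0, gs); delta[16, 16, 16] <- 1
  fwhm <- 6
  out <- gaussian_smooth(delta, fwhm, voxel_mm = c(1, 1, 1))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, fwhm / 2.3548, tolerance = 1e-4)
  # discrete normalized kernel along one axis through the center
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  # separable kernel: profile through the center matches the 1D Gaussian
  expect_equal(out[16 + (-3:3), 16, 16] / out[16, 16, 16],
               k[r + 1 + (-3:3)] / k[r + 1], tolerance = 0.01,
               ignore_attr = TRUE)
  # interior delta: mass conserved
  expect_lt(abs(sum(out) - 1), 1e-6)
  # anisotropic voxels scale sigma per axis
  out2 <- gaussian_smooth(delta, fwhm, voxel_mm = c(1, 1, 2))
  expect_gt(out2[16, 16, 17], out[16, 16, 17])
})

test_that("high-pass filtering removes slow and keeps fast components", {
  tr <- 2; n <- 185
  t_s <- (seq_len(n) - 1) * tr
  drift <- 5 * t_s / max(t_s)
  hp <- highpass(drift, 0.01, tr)
  expect_lt(max(abs(hp)), 0.05 * diff(range(drift)))

  fast <- sin(2 * pi * 0.05 * t_s)
  hp2 <- highpass(fast, 0.01, tr)
  amp_ratio <- (diff(range(hp2)) / 2) / 1
  expect_gt(amp_ratio, 0.95)
  expect_lt(amp_ratio, 1.05)

  expect_equal(max(abs(highpass(rep(4, n), 0.01, tr))), 0, tolerance = 1e-10)
  expect_error(highpass(fast, 0.3, tr), class = "rtnf_config_error")

  # matrix input filters columns independently
  m <- cbind(drift, fast)
  hm <- highpass(m, 0.01, tr)
  expect_equal(hm[, 2], hp2)
})

test_that("motion exclusion applies the printed quartile fence", {
  task <- condition_boxcar <- as.numeric(schedule_frames(build_parallel_schedule())$condition == "think")
  n <- length(task)
  set.seed(4)
  # all subjects with identical correlation: IQR 0, nobody strictly above
  same <- replicate(6, 0.3 * task + rnorm(n, sd = 1e-8), simplify = FALSE)
  rec <- motion_exclude(same, task)
  expect_false(any(rec$excluded))

  # one strong task-coupled mover among 20
  quiet <- replicate(19, rnorm(n), simplify = FALSE)
  mover <- 2 * task + rnorm(n, sd = 0.3)
  rec2 <- motion_exclude(c(quiet, list(mover)), task)
  expect_equal(which(rec2$excluded), 20L)
  expect_equal(sum(rec2$excluded), 1L)

  # constant displacement cannot be correlated: flagged for review
  rec3 <- motion_exclude(c(quiet[1:4], list(rep(0.2, n))), task)
  expect_true(rec3$manual_review[5])
  expect_false(rec3$excluded[5])

  expect_error(motion_exclude(quiet[1:3], task), class = "rtnf_data_error")
})

test_that("motion coupling in the simulator drives the exclusion rule", {
  s <- build_parallel_schedule()
  task <- as.numeric(schedule_frames(s)$condition == "think")
  runs <- lapply(1:20, function(i) {
    coupling <- if (i == 7) 8 else 0
    r <- simulate_roi_run(s, sim_params(motion_coupling = coupling), seed = 200 + i)
    r$displacement
  })
  rec <- motion_exclude(runs, task)
  expect_true(rec$excluded[7])
  expect_equal(which.max(rec$event_correlation), 7L)
  # the printed Q1 + 1.5*IQR fence is aggressive; the outlier must fall,
  # and only a small minority of ordinary subjects may join it
  expect_lte(sum(rec$excluded), 4L)
})

test_that("LSA design separates think repetitions and scales contrasts", {
  dp <- rtnf:::lsa_design(build_parallel_schedule())
  expect_equal(sum(grepl("^think_", dp$condition_cols)), 6)
  ds <- rtnf:::lsa_design(build_serial_schedule())
  expect_equal(sum(grepl("^think_", ds$condition_cols)), 8)
  expect_true("feedback" %in% ds$condition_cols)

  cs <- rtnf:::lsa_contrasts(ds$condition_cols, "serial")
  for (cw in cs) {
    expect_equal(sum(cw[cw > 0]), 1)       # positive weights sum to 1
    expect_equal(unname(cw["count"]), -1)  # count as control condition
  }
  expect_equal(names(cs), c("think", "feedback", "overall"))
})

test_that("voxelwise first-level betas equal brute-force per-voxel OLS", {
  gs <- c(6, 6, 6)
  mask <- cube_mask(gs, c(2, 2, 2), c(4, 4, 4))
  vr <- simulate_volume_run(gs, list(list(mask = mask, amplitudes = c(think = 3))),
                            build_parallel_schedule(),
                            sim_params(noise_sd = 0.3, drift_amplitude = 0,
                                       global_sd = 0), seed = 5)
  fl <- first_level_lsa(vr)
  X <- fl$design$X
  vox <- cbind(c(3, 1, 6), c(3, 2, 5), c(3, 4, 1))
  for (j in 1:3) {
    v <- vox[j, ]
    y <- vr$vol[v[1], v[2], v[3], ]
    bf <- solve(crossprod(X), crossprod(X, y))
    col <- which(which(vr$mask) == ((v[3] - 1) * 36 + (v[2] - 1) * 6 + v[1]))
    expect_lt(max(abs(fl$betas[, col] - bf)), 1e-8)
  }
  # the statistic peaks inside the active cube
  expect_true(which.max(fl$think$z$values) %in% which(mask))
})

test_that("averaged per-repetition think betas equal the combined regressor beta", {
  gs <- c(4, 4, 4)
  mask <- cube_mask(gs, c(1, 1, 1), c(2, 2, 2))
  vr <- simulate_volume_run(gs, list(list(mask = mask, amplitudes = c(think = 2))),
                            build_serial_schedule(), quiet_params(), seed = 6)
  fl <- first_level_lsa(vr, use_motion = FALSE)
  think_rows <- grep("^think_", rownames(fl$betas))
  lsa_mean <- colMeans(fl$betas[think_rows, , drop = FALSE])

  # combined single think regressor model on the same data
  sched <- vr$schedule
  hrf <- double_gamma_hrf(dt = 2)
  comb <- rtnf:::convolve_hrf(as.numeric(schedule_frames(sched)$condition == "think"), hrf)
  cnt <- rtnf:::convolve_hrf(as.numeric(schedule_frames(sched)$condition == "count"), hrf)
  fb <- rtnf:::convolve_hrf(
    as.numeric(schedule_frames(sched)$condition %in% c("feedback_think", "feedback_count")), hrf)
  X1 <- cbind(think = comb, count = cnt, feedback = fb, intercept = 1)
  Y <- t(matrix(vr$vol, nrow = prod(gs), ncol = 185)[as.vector(vr$mask), ])
  b1 <- qr.coef(qr(X1), Y)
  expect_lt(max(abs(lsa_mean - b1["think", ])), 1e-6)
})

test_that("group one-sample maps behave at the extremes and under the null", {
  gs <- c(11, 11, 11)
  # identical nonzero maps: zero between-subject variance -> capped z
  const <- lapply(1:5, function(i) grid_statmap(gs, function(x, y, z) 0.5,
                                                stat_type = "contrast"))
  gz <- group_one_sample(const)
  expect_true(all(gz$values > 8))

  # sign flip of all inputs negates the map
  maps <- effect_subject_maps(6, gs, seed = 8)
  neg <- lapply(maps, function(m) statmap(-m$values, stat_type = "contrast"))
  z1 <- group_one_sample(maps)
  z2 <- group_one_sample(neg)
  expect_equal(z2$values, -z1$values, tolerance = 1e-10)

  # null calibration over >= 1000 voxels
  null_maps <- effect_subject_maps(12, gs, seed = 9)
  zn <- group_one_sample(null_maps)
  frac <- mean(abs(zn$values) > 1.96)
  expect_lt(abs(frac - 0.05), 0.02)
  expect_lt(abs(mean(zn$values)), 0.1)
  expect_lt(abs(var(as.vector(zn$values)) - 1), 0.2)

  expect_error(group_one_sample(maps[1:2]), class = "rtnf_data_error")
})

test_that("first-level null z statistics are approximately standard normal", {
  gs <- c(11, 11, 11)
  vr <- simulate_volume_run(gs, list(),
                            build_parallel_schedule(),
                            sim_params(noise_sd = 0.5, ar1_coef = 0,
                                       drift_amplitude = 0, global_sd = 0),
                            seed = 10)
  fl <- first_level_lsa(vr, use_motion = FALSE)
  z <- as.vector(fl$think$z$values)
  expect_gte(length(z), 1000)
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(var(z) - 1), 0.2)
})
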