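test_that("with all signal sources off the run is constant at baseline", {
  s <- build_serial_schedule()
  r <- simulate_roi_run(s, quiet_params(think = 0), seed = 1)
  expect_true(all(r$target == 1000))
  expect_true(all(r$background == 1000))
})

test_that("positive think amplitude raises late-think target intensity", {
  p <- build_parallel_schedule()
  r <- simulate_roi_run(p, quiet_params(think = 2), seed = 1)
  late_think <- r$condition == "think" & r$time_s >= 60
  base <- r$condition == "baseline"
  expect_gt(mean(r$target[late_think]), mean(r$target[base]))
  expect_true(all(r$background == 1000))  # no background amplitude
})

test_that("identical seeds and params give bit-identical runs", {
  s <- build_serial_schedule()
  pars <- sim_params()
  a <- simulate_roi_run(s, pars, seed = 99)
  b <- simulate_roi_run(s, pars, seed = 99)
  expect_identical(a$target, b$target)
  expect_identical(a$background, b$background)
  expect_identical(a$displacement, b$displacement)
  c2 <- simulate_roi_run(s, pars, seed = 100)
  expect_false(identical(a$target, c2$target))
})

test_that("baseline intensity rescaling leaves FS and TE unchanged", {
  s <- build_serial_schedule()
  for (mult in c(0.5, 40)) {
    p1 <- sim_params(noise_sd = 0.5)
    p2 <- sim_params(baseline_intensity = 1000 * mult, noise_sd = 0.5)
    r1 <- simulate_roi_run(s, p1, seed = 11)
    r2 <- simulate_roi_run(s, p2, seed = 11)
    expect_equal(r2$target, r1$target * mult, tolerance = 1e-12)
    tr1 <- run_feedback_loop(r1)
    tr2 <- run_feedback_loop(r2)
    expect_equal(tr2$fs, tr1$fs, tolerance = 1e-10)
    expect_equal(roi_efficiency(r2)$te, roi_efficiency(r1)$te, tolerance = 1e-10)
  }
})

test_that("null runs produce zero-mean feedback over replicates", {
  s <- build_serial_schedule()
  pars <- sim_params(amplitudes = list(target = c(think = 0),
                                       background = numeric()))
  means <- vapply(1:200, function(i) {
    r <- simulate_roi_run(s, pars, seed = 3000 + i)
    tr <- run_feedback_loop(r)
    mean(tr$fs[tr$display])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("simulate_subject tracks the injected best run", {
  s <- build_serial_schedule()
  expect_error(simulate_subject(s, rep(1, 5)), class = "rtnf_config_error")

  sub <- simulate_subject(s, rep(1.5, 18), quiet_params(), seed = 1)
  expect_equal(sub$truth_index, 1L)            # earliest on ties
  expect_length(sub$runs, 18)

  ramp <- simulate_subject(s, seq(0, 3, length.out = 18), quiet_params(), seed = 1)
  expect_equal(ramp$truth_index, 18L)
  ss <- subject_summary(ramp)
  expect_equal(ss$metr_index, 18L)
  expect_equal(ss$group, "serial")
  expect_length(ss$te_per_run[[1]], 18)
  expect_equal(max(ss$te_per_run[[1]]), ss$metr_te)
})

test_that("group design delivers the requested TE distributions", {
  des <- simulate_group(n_parallel = 10, n_serial = 10, seed = 5)
  expect_equal(nrow(des), 20)
  expect_equal(sum(des$group == "parallel"), 10)
  # degenerate SD with noise-free runs: every estimated TE sits at the
  # group mean up to the calibration's small amplitude nonlinearity
  des0 <- simulate_group(te_sd = c(parallel = 0, serial = 0),
                         params = quiet_params(), seed = 5)
  beh0 <- estimate_group(des0)
  expect_lt(max(abs(beh0$te[beh0$group == "parallel"] - 1.27)), 0.1)
  expect_lt(max(abs(beh0$te[beh0$group == "serial"] - 2.3)), 0.1)
  expect_error(simulate_group(te_sd = c(parallel = -1, serial = 1)),
               class = "rtnf_config_error")
})

test_that("template sets are numerous, unit-variance and near-decorrelated", {
  ts <- make_template_set(c(14, 14, 14), n_templates = 20, seed = 2)
  expect_equal(dim(ts$maps)[4], 20)
  M <- matrix(ts$maps, ncol = 20)
  cc <- cor(M)
  offdiag <- abs(cc[upper.tri(cc)])
  expect_lt(mean(offdiag), 0.2)
  expect_equal(diag(cc), rep(1, 20))
})

test_that("probabilistic atlas profiles form a sub-partition", {
  at <- make_probabilistic_atlas(c(10, 10, 10), n_regions = 4, seed = 3)
  expect_equal(dim(at$prob)[4], 4)
  expect_true(all(at$prob >= 0 & at$prob <= 1))
  sums <- apply(at$prob, 1:3, sum)
  expect_true(all(sums <= 1 + 1e-12))
})

test_that("volume runs place activation where the layout says", {
  gs <- c(6, 6, 6)
  mask <- cube_mask(gs, c(2, 2, 2), c(4, 4, 4))
  vr <- simulate_volume_run(gs, list(list(mask = mask, amplitudes = c(think = 3))),
                            build_parallel_schedule(), quiet_params(), seed = 2)
  expect_equal(dim(vr$vol), c(gs, 185))
  fl <- first_level_lsa(vr, use_motion = FALSE)
  expect_true(which.max(fl$think$z$values) %in% which(mask))
  expect_error(
    simulate_volume_run(gs, list(list(mask = array(TRUE, c(2, 2, 2)),
                                      amplitudes = c(think = 1))),
                        build_parallel_schedule()),
    class = "rtnf_config_error")
})
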