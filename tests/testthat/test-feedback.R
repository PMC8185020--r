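test_that("baseline windows come from the preceding reference block", {
  s <- build_serial_schedule()
  p <- build_parallel_schedule()

  # serial cycle 2 feedback_think (onset 90 s, frame 45): 5 volumes of
  # cycle 1's feedback_count block (70-80 s -> frames 35..39)
  w <- baseline_for_frame(s, 45)
  expect_equal(w$indices, 35:39)
  expect_equal(w$source, "reference_block")

  # parallel cycle 2 think (onset 100 s, frame 50): last 10 volumes of
  # cycle 1's count block (70-100 s -> frames 40..49)
  w2 <- baseline_for_frame(p, 50)
  expect_equal(w2$indices, 40:49)
  expect_length(w2$indices, 10)

  # first cycle falls back to the tail of the initial baseline
  w3 <- baseline_for_frame(p, 25)
  expect_equal(w3$indices, 15:24)
  expect_equal(w3$source, "initial_baseline")
  w4 <- baseline_for_frame(s, 25)   # cycle 1 feedback_think
  expect_equal(w4$indices, 15:19)

  # non-display frames are rejected
  expect_error(baseline_for_frame(p, 0), class = "rtnf_data_error")
  expect_error(baseline_for_frame(s, 20), class = "rtnf_data_error")  # think
})

test_that("percent signal change and FS are the stated arithmetic", {
  expect_equal(percent_signal_change(102, 100), 2)
  expect_equal(percent_signal_change(100, 100), 0)
  expect_equal(percent_signal_change(95, 100), -5)
  expect_error(percent_signal_change(100, 0), class = "rtnf_data_error")
  expect_equal(feedback_signal(2, 1), 1)
  expect_equal(feedback_signal(0, 0), 0)
})

test_that("thermometer quantizer is a clamped 21-level linear map", {
  expect_equal(quantize_thermometer(0), 10L)
  expect_equal(quantize_thermometer(2, fs_max = 2), 20L)
  expect_equal(quantize_thermometer(5, fs_max = 2), 20L)
  expect_equal(quantize_thermometer(-2, fs_max = 2), 0L)
  expect_equal(quantize_thermometer(-9, fs_max = 2), 0L)

  fs <- seq(-4, 4, length.out = 10001)
  expect_equal(length(unique(quantize_thermometer(fs, fs_max = 2))), 21L)

  # monotonicity over random inputs
  set.seed(11)
  x <- sort(runif(500, -5, 5))
  lev <- quantize_thermometer(x)
  expect_true(all(diff(lev) >= 0))

  expect_error(quantize_thermometer(0, fs_max = 0), class = "rtnf_config_error")
})

test_that("feedback loop is null on constant runs and cancels shared global factors", {
  s <- build_serial_schedule()
  r <- simulate_roi_run(s, quiet_params(think = 0), seed = 1)
  tr <- run_feedback_loop(r)
  expect_true(all(tr$fs[tr$display] == 0))
  expect_true(all(tr$level[tr$display] == 10L))
  expect_true(all(is.na(tr$fs[!tr$display])))
  expect_gt(sum(tr$display), 0)

  # target = A*g_t, background = B*g_t for arbitrary positive g_t -> FS = 0
  set.seed(2)
  g <- exp(cumsum(rnorm(185, sd = 0.01)))
  run <- tibble::tibble(target = 800 * g, background = 1200 * g)
  tr2 <- run_feedback_loop(run, s)
  expect_equal(max(abs(tr2$fs[tr2$display])), 0)

  p <- build_parallel_schedule()
  run_p <- tibble::tibble(target = 500 * g, background = 900 * g)
  tr3 <- run_feedback_loop(run_p, p)
  expect_equal(max(abs(tr3$fs[tr3$display])), 0)
})

test_that("FS is invariant to rescaling either ROI's baseline intensity", {
  s <- build_serial_schedule()
  r <- simulate_roi_run(s, sim_params(noise_sd = 0.4), seed = 3)
  tr <- run_feedback_loop(r)
  r2 <- r
  r2$target <- r$target * 3.7
  r2$background <- r$background * 0.2
  tr2 <- run_feedback_loop(r2, s)
  expect_equal(tr2$fs, tr$fs, tolerance = 1e-12)
})

test_that("feedback reflects injected activation", {
  # noise-free serial run with 2% think amplitude: mean FS during
  # feedback_think frames is positive and near the injected amplitude
  s <- build_serial_schedule()
  rs <- simulate_roi_run(s, quiet_params(think = 2), seed = 4)
  trs <- run_feedback_loop(rs)
  m <- mean(trs$fs[trs$condition == "feedback_think"])
  expect_gte(m, 1.0)
  expect_lte(m, 2.2)

  # noise-free parallel run: mean level over think display frames > 10
  p <- build_parallel_schedule()
  rp <- simulate_roi_run(p, quiet_params(think = 2), seed = 5)
  trp <- run_feedback_loop(rp)
  expect_gt(mean(trp$level[trp$condition == "think"]), 10)
})

test_that("FS at a frame depends only on the frame and its baseline window", {
  p <- build_parallel_schedule()
  r <- simulate_roi_run(p, sim_params(noise_sd = 0.5), seed = 6)
  tr <- run_feedback_loop(r)
  frame <- 52L                       # cycle 2 think; window frames 40..49
  win <- baseline_for_frame(p, frame)$indices
  r2 <- r
  touch <- setdiff(seq_len(185) - 1L, c(win, frame))
  r2$target[touch + 1L] <- r2$target[touch + 1L] + 50
  r2$background[touch + 1L] <- r2$background[touch + 1L] * 1.1
  tr2 <- run_feedback_loop(r2, p)
  expect_equal(tr2$fs[frame + 1L], tr$fs[frame + 1L])
})

test_that("display shift delays presentation without changing computation", {
  p <- build_parallel_schedule()
  r <- simulate_roi_run(p, quiet_params(), seed = 7)
  tr <- run_feedback_loop(r, display_shift = 5)
  expect_equal(tr$fs_displayed[-(1:5)], tr$fs[seq_len(180)])
})
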