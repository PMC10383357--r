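test_that("arming needs the pinch and the index tip on the start dot", {
  shp <- display_truth("M")
  cfg <- session_config(radius = 20)
  s0 <- new_session(shp, cfg)

  on_start <- try_arm(s0, 0, pinched_frame(shp$start[1], shp$start[2]))
  expect_equal(on_start$phase, "TRACING")
  expect_equal(on_start$start_time, 0)

  far <- try_arm(s0, 0, pinched_frame(shp$start[1] + 100, shp$start[2]))
  expect_equal(far$phase, "IDLE")

  open_grip <- try_arm(s0, 0, pinched_frame(shp$start[1], shp$start[2],
                                            open_pinch = TRUE))
  expect_equal(open_grip$phase, "IDLE")

  expect_error(session_step(s0, 0.1, pinched_frame(0, 0)),
               class = "solwrite_state_error")
})

test_that("step fails immediately on out-of-bounds, grip loss and hand loss", {
  shp <- display_truth("M")
  cfg <- session_config(radius = 20)
  armed <- try_arm(new_session(shp, cfg), 0,
                   pinched_frame(shp$start[1], shp$start[2]))

  off <- session_step(armed, 1 / 60,
                      pinched_frame(shp$start[1] + 50, shp$start[2] + 50))
  expect_equal(off$phase, "FAILED")
  expect_equal(off$fail_reason, "out_of_bounds")

  open <- session_step(armed, 1 / 60,
                       pinched_frame(shp$start[1], shp$start[2],
                                     open_pinch = TRUE))
  expect_equal(open$phase, "FAILED")
  expect_equal(open$fail_reason, "grip_lost")

  # a momentary detection gap is tolerated, a long one is not
  ok <- session_step(armed, 0.2, pinched_frame(shp$start[1], shp$start[2]))
  expect_equal(ok$phase, "TRACING")
  gone <- session_step(armed, 0.3, pinched_frame(shp$start[1], shp$start[2]))
  expect_equal(gone$phase, "FAILED")
  expect_equal(gone$fail_reason, "hand_lost")

  expect_error(session_step(ok, 0.2, pinched_frame(0, 0)),
               class = "solwrite_stream_error")
})

test_that("a noiseless trace completes with drawn length near the perimeter", {
  shp <- display_truth("M")
  fr <- simulate_trajectory("M", duration = 15, seed = 1)
  s <- run_session(shp, fr, session_config(radius = 20))
  expect_equal(s$phase, "COMPLETED")
  expect_equal(s$drawn_length, shp$perimeter, tolerance = 0.05)
  expect_equal(length(s$deviations), length(s$trace_x))
  r <- finalize(s)
  expect_equal(r$outcome, "completed")
  expect_lt(abs(r$elapsed - 15), 1)
})

test_that("completion needs both the length match and the end vicinity", {
  shp <- display_truth("rectangle")
  cfg <- session_config(radius = 20)
  s <- new_session(shp, cfg)
  s$drawn_length <- shp$perimeter
  expect_true(completion_check(s, shp$end))
  expect_false(completion_check(s, shp$end + c(200, 0)))
  # closed shape: sitting on the shared start/end dot with almost nothing
  # drawn must not complete (the length condition is the safety step)
  s$drawn_length <- 0.05 * shp$perimeter
  expect_false(completion_check(s, shp$end))
})

test_that("partial traces time out with the covered fraction", {
  shp <- display_truth("M")
  fr <- half_trace("M", fraction = 0.5, seed = 2)
  s <- run_session(shp, fr, session_config(radius = 20))
  expect_equal(s$phase, "TIMED_OUT")
  expect_equal(fraction_traced(s), 0.5, tolerance = 0.05)
  r <- finalize(s)
  expect_equal(r$outcome, "partial")
  expect_equal(r$elapsed, 60)
  # no movement at all: fraction 0
  idle <- stream_of(seq(0, 61, by = 1 / 60),
                    rep(shp$start[1], 61 * 60 + 2),
                    rep(shp$start[2], 61 * 60 + 2))
  s0 <- run_session(shp, idle, session_config(radius = 20))
  expect_equal(s0$phase, "TIMED_OUT")
  expect_equal(fraction_traced(s0), 0)
})

test_that("noiseless traces complete across speeds and shapes", {
  for (nm in c("M", "triangle")) {
    shp <- display_truth(nm)
    for (speed in c(100, 250, 400)) {
      fr <- simulate_trajectory(nm, speed = speed, seed = 3)
      s <- run_session(shp, fr, session_config(radius = 20))
      expect_equal(s$phase, "COMPLETED",
                   label = sprintf("%s at %d px/s", nm, speed))
    }
  }
})

test_that("replay is deterministic and terminal phases are absorbing", {
  shp <- display_truth("Pi")
  fr <- simulate_trajectory("Pi", duration = 20, tremor_sigma = 3, seed = 9,
                            radius = 40)
  cfg <- session_config(radius = 40)
  s1 <- run_session(shp, fr, cfg)
  s2 <- run_session(shp, fr, cfg)
  expect_identical(glance(s1), glance(s2))
  expect_identical(s1$deviations, s2$deviations)
  expect_error(session_step(s1, max(fr$t) + 1, pinched_frame(0, 0)),
               class = "solwrite_state_error")
  expect_error(finalize(new_session(shp, cfg)), class = "solwrite_state_error")
})
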