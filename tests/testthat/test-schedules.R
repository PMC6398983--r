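test_that("schedule evaluation is piecewise, right-continuous and 0 outside", {
  step <- make_step(50, t_on = 0, t_off = 48)
  expect_equal(evaluate_schedule(step, 1), 50)
  expect_equal(evaluate_schedule(step, -1), 0)
  expect_equal(evaluate_schedule(step, 100), 0)
  expect_equal(evaluate_schedule(step, 0), 50)   # right-continuous at onset

  ramp <- make_ramp(30, 10, 10)
  # 5th stair of 3 ng/ml increments covers [4, 5): 15 ng/ml
  expect_equal(evaluate_schedule(ramp, 4.5), 15)
  expect_equal(evaluate_schedule(ramp, 9.5), 30) # last stair
  expect_equal(evaluate_schedule(ramp, 4), 15)   # stair boundary: new level
  expect_equal(evaluate_schedule(ramp, -1), 0)

  lin <- ligand_schedule(data.frame(t_start = 0, t_end = 10, c_start = 0,
                                    c_end = 30, interpolation = "linear"))
  expect_equal(evaluate_schedule(lin, 5), 15)
})

test_that("invalid segment geometry is rejected at construction", {
  bad_overlap <- data.frame(t_start = c(0, 3), t_end = c(5, 8),
                            c_start = 1, c_end = 1,
                            interpolation = "constant")
  expect_error(ligand_schedule(bad_overlap), "overlap")
  bad_gap <- data.frame(t_start = c(0, 6), t_end = c(5, 8),
                        c_start = 1, c_end = 1, interpolation = "constant")
  expect_error(ligand_schedule(bad_gap), "contiguous")
  expect_error(ligand_schedule(data.frame(t_start = 0, t_end = 5,
                                          c_start = -1, c_end = 1,
                                          interpolation = "constant")),
               ">= 0")
  expect_error(make_ramp(-5, 10), "> 0")
  expect_error(make_ramp(30, 0), "> 0")
  expect_error(make_ramp(30, 10, 0), ">= 1")
})

test_that("a one-step ramp equals a delayed full-dose step", {
  ramp1 <- make_ramp(30, 10, 1)
  tt <- seq(-1, 12, by = 0.25)
  expect_equal(evaluate_schedule(ramp1, tt),
               ifelse(tt >= 0 & tt <= 10, 30, 0))
})

test_that("pulse trains carry the stated durations, gaps and exposure", {
  pt <- make_pulse_train(30, 0, c(6, 10, 8), 5)
  seg <- pt$segments
  on <- seg[seg$c_start > 0, ]
  expect_equal(on$t_end - on$t_start, c(6, 10, 8))
  expect_equal(on$t_start, c(0, 11, 26))
  expect_equal(integrate_schedule(pt), 30 * 24)
  expect_equal(integrate_schedule(make_step(30, t_off = 34)), 30 * 34)
})
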