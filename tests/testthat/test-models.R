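grid12 <- seq(0, 12, by = 0.01)

test_that("feedback model is at steady state without ligand and overshoots with it", {
  p <- feedback_params()
  none <- make_step(0, t_off = 12, name = "none")
  tr0 <- simulate_feedback(p, none, grid12)
  expect_equal(tr0$S, rep(p$S0, length(grid12)), tolerance = 1e-8)

  tr <- simulate_feedback(p, make_step(50, t_off = 12), grid12)
  plateau <- mean(tr$S[tr$t >= 10])
  expect_gt(max(tr$S), plateau + 0.1)       # overshoot ...
  expect_gt(plateau, p$S0 + 0.01)           # ... then plateau above S0
})

test_that("feedback peak excess is non-decreasing in step dose", {
  p <- feedback_params()
  peaks <- vapply(c(1, 5, 10, 50), function(d)
    max(simulate_feedback(p, make_step(d, t_off = 12), grid12)$S) - p$S0,
    numeric(1))
  expect_false(is.unsorted(peaks))
})

test_that("receptor model matches its closed-form limits", {
  p <- receptor_params(s = 10, d_i = 0.1, d_a = 1, k_b = 10)
  none <- make_step(0, t_off = 12, name = "none")
  tr0 <- simulate_receptor_depletion(p, none, grid12)
  expect_equal(max(abs(tr0$S)), 0, tolerance = 1e-8)

  # saturating step, fast binding: adapted fraction of peak -> d_i / d_a
  grid40 <- seq(0, 40, by = 0.01)
  tr <- simulate_receptor_depletion(p, make_step(200, t_off = 40), grid40)
  m <- adaptation_metrics(tr)
  expect_equal(m$baseline_fraction, p$d_i / p$d_a, tolerance = 0.05)

  # after removal, responsiveness (receptor pool) recovers at rate d_i:
  # a re-challenge after gap g gives peak2/peak1 = 1 - exp(-d_i g),
  # so 90% recovery takes ln(10)/d_i
  peak_after_gap <- function(gap) {
    sched <- ligand_schedule(data.frame(
      t_start = c(0, 2, 2 + gap), t_end = c(2, 2 + gap, 4 + gap),
      c_start = c(200, 0, 200), c_end = c(200, 0, 200),
      interpolation = "constant"))
    gr <- seq(0, 4 + gap, by = 0.01)
    tr2 <- simulate_receptor_depletion(p, sched, gr)
    c(max(tr2$S[tr2$t <= 2]), max(tr2$S[tr2$t >= 2 + gap]))
  }
  g90 <- log(10) / p$d_i
  pk <- peak_after_gap(g90)
  expect_equal(pk[2] / pk[1], 0.9, tolerance = 0.03)
})

test_that("ligand depletion gives dose-dependent duration with closed-form crossing", {
  p <- depletion_params(u = 0.15, L_thresh = 1)
  grid <- seq(0, 40, by = 0.01)
  # u -> 0: sustained over the whole grid
  p0 <- depletion_params(u = 1e-9, L_thresh = 1)
  tr0 <- simulate_ligand_depletion(p0, 10, grid)
  expect_gt(min(tr0$S[tr0$t >= 2]), p0$S0 + 0.9 * p0$alpha / p0$gamma * 0.9)

  d10 <- halfmax_duration(simulate_ligand_depletion(p, 10, grid))
  d50 <- halfmax_duration(simulate_ligand_depletion(p, 50, grid))
  expect_lt(d10, d50)

  # ligand crosses L_thresh at ln(L0/L_thresh)/u
  tr <- simulate_ligand_depletion(p, 10, grid)
  L <- attr(tr, "ligand")
  t_cross <- tr$t[which(L < p$L_thresh)[1]]
  expect_equal(t_cross, log(10 / p$L_thresh) / p$u, tolerance = 0.01)
})

test_that("target-gene kinetics separate adaptive and sustained classes", {
  p <- feedback_params()
  traj <- simulate_feedback(p, make_step(50, t_off = 24), seq(0, 24, 0.01))
  # no signal -> no transcription
  flat <- signal_trajectory(seq(0, 24, 0.01), rep(p$S0, 2401), S0 = p$S0)
  expect_equal(max(simulate_target_gene(gene_params("adaptive"), flat)$m), 0)

  sus <- simulate_target_gene(gene_params("sustained"), traj)
  # plateau maintained to the end of the window
  expect_gt(sus$m[nrow(sus)], 0.8 * max(sus$m))

  ada <- simulate_target_gene(gene_params("adaptive"), traj)
  expect_lt(ada$m[nrow(ada)], 0.5 * max(ada$m))  # peaks then decays

  # pathway inhibition: mRNA halves after ln(2)/delta_m
  g <- gene_params("sustained", delta_m = 0.2)
  inh <- simulate_target_gene(g, traj, t_inh = 12)
  m_at <- function(tt) inh$m[which.min(abs(inh$t - tt))]
  expect_equal(m_at(12 + log(2) / g$delta_m), m_at(12) / 2, tolerance = 0.01)
})

test_that("qPCR normalization is log2 relative to the reference gene", {
  expect_equal(normalize_ct(20, 20), 0)
  expect_equal(normalize_ct(18, 20), 2)
  expect_equal(normalize_ct(23.32, 20), -3.32)
})

test_that("adaptive-solver trajectories match the RK4 reference integrator", {
  p <- feedback_params()
  sched <- make_step(50, t_off = 12)
  coarse <- c(0, 6, 12)
  tr <- simulate_feedback(p, sched, seq(0, 12, 0.01), rtol = 1e-8)
  rhs <- function(t, y) {
    L <- evaluate_schedule(sched, t)
    O <- L / (L + p$K_L)
    c(p$alpha * O / (1 + y[2] / p$K_I) - p$gamma * (y[1] - p$S0),
      p$beta * (y[1] - p$S0) - p$delta * y[2])
  }
  # reference: fixed-step RK4 at 10x finer than a fine grid
  ref <- integrate_rk4(rhs, c(p$S0, 0), seq(0, 12, 0.01),
                       breaks = schedule_breakpoints(sched), refine = 10)
  at <- function(tt) which(abs(seq(0, 12, 0.01) - tt) < 1e-9)
  for (tt in coarse[-1]) {
    i <- at(tt)
    expect_equal(tr$S[i], ref[i, 1], tolerance = 1e-4)
  }
})
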