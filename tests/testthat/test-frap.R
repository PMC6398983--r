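test_that("fully-free model recovers the kinetic ratio; sequestration lowers it", {
  free <- shuttling_params(k_out = 0.02, f_ns = 0, f_cs = 0, bleach_eff = 1)
  # long trace so the final-10% plateau readout is fully equilibrated
  tr <- simulate_frap(free, duration = 60 + 60 * 25 / (free$k_in + free$k_out))
  f <- fit_recovery(tr)
  expect_equal(f$R_prime, f$R, tolerance = 1e-5)

  seq1 <- shuttling_params(k_out = 0.02, f_ns = 0.3, f_cs = 0.4,
                           bleach_eff = 1)
  f1 <- fit_recovery(simulate_frap(seq1))
  expect_lt(f1$R_prime, f1$R)

  # R' strictly decreasing in f_cs at fixed other parameters
  rp <- vapply(c(0.1, 0.3, 0.5, 0.7), function(fcs)
    fit_recovery(simulate_frap(shuttling_params(k_out = 0.02, f_ns = 0.3,
                                                f_cs = fcs)))$R_prime,
    numeric(1))
  expect_true(all(diff(rp) < 0))
})

test_that("no-bleach traces are flat and flagged", {
  tr <- simulate_frap(shuttling_params(k_out = 0.02, bleach_eff = 0))
  expect_equal(max(tr$I_nuc) - min(tr$I_nuc), 0, tolerance = 1e-12)
  f <- fit_recovery(tr)
  expect_equal(f$flag, "no bleach detected")
  expect_equal(f$A, 0)
})

test_that("total fluorescence is conserved after the bleach", {
  p <- shuttling_params(k_out = 0.03, f_ns = 0.2, f_cs = 0.5,
                        bleach_eff = 0.7)
  tr <- simulate_frap(p)
  tot <- tr$I_nuc + tr$I_cyt
  post <- tr$t >= attr(tr, "t_bleach")
  expect_equal(max(tot[post]) - min(tot[post]), 0, tolerance = 1e-12)
})

test_that("recovery rate reflects kinetics, not bleach depth", {
  ks <- vapply(c(0.3, 0.6, 0.9), function(b)
    fit_recovery(simulate_frap(shuttling_params(k_out = 0.05,
                                                f_ns = 0.2, f_cs = 0.2,
                                                bleach_eff = b)))$k,
    numeric(1))
  expect_equal(max(ks) - min(ks), 0, tolerance = 1e-6)
})

test_that("exponential fits recover a noiseless synthetic recovery exactly", {
  tt <- seq(0, 200, by = 2)
  A <- 0.30; k <- 0.05; I_inf <- 1.2
  I_nuc <- c(rep(I_inf, 15), I_inf - A * exp(-k * (tt[tt <= 170])))
  trace <- data.frame(t = c(tt[1:15] - 30, tt[tt <= 170] + 30),
                      I_nuc = I_nuc, I_cyt = 1)
  trace$t <- trace$t - min(trace$t)
  f <- fit_recovery(trace, t_bleach = 30)
  expect_equal(f$A, A, tolerance = 1e-6)
  expect_equal(f$k, k * 60, tolerance = 1e-6)  # reported per minute
})

test_that("fitted recovery rate equals the exchange eigenvalue k_in + k_out", {
  p <- shuttling_params(k_out = 0.07, f_ns = 0.25, f_cs = 0.35,
                        bleach_eff = 0.8)
  f <- fit_recovery(simulate_frap(p, dt = 2))
  expect_equal(f$k, p$k_in + p$k_out, tolerance = 0.02 * (p$k_in + p$k_out))

  # independent oracle: matrix exponential of the 2x2 exchange system
  skip_if_not_installed("Matrix")
  # state x = (N_free, C_free): dN/dt = -k_out N + k_in C, dC/dt = the rest
  km <- matrix(c(-p$k_out, p$k_in, p$k_out, -p$k_in), 2, 2, byrow = TRUE)
  ev <- sort(Re(eigen(km)$values))
  expect_equal(-ev[1], p$k_in + p$k_out, tolerance = 1e-10)
  x0 <- c(0.2, 0.8)
  dtm <- 1.5
  xs <- t(vapply(0:40, function(n)
    as.numeric(as.matrix(Matrix::expm(km * dtm * n)) %*% x0), numeric(2)))
  # nuclear pool relaxes as a single exponential with the same rate
  dev <- xs[, 1] - sum(x0) * p$k_in / (p$k_in + p$k_out)
  rate <- -stats::coef(stats::lm(log(abs(dev[1:20])) ~ I(dtm * (0:19))))[2]
  expect_equal(unname(rate), p$k_in + p$k_out, tolerance = 1e-6)
})

test_that("sequestration inference is exact without noise and honest with it", {
  # zero-sequestration ensemble: estimates ~ (0, 0), k_out = k - k_in
  free <- shuttling_params(k_out = 0.05, f_ns = 0, f_cs = 0)
  ens0 <- generate_frap_ensemble(free, n_cells = 12, jitter_cv = 0,
                                 noise_sd = 0, seed = 11)
  # truth sits on the [0,1] boundary, so tiny numerical undershoot is clipped
  est0 <- suppressWarnings(
    infer_sequestration(lapply(ens0$traces, fit_recovery)))
  expect_equal(est0$f_ns_hat, 0, tolerance = 1e-4)
  expect_equal(est0$f_cs_hat, 0, tolerance = 1e-4)
  expect_equal(est0$k_out_hat, 0.05, tolerance = 1e-5)

  # a noiseless single cell reproduces simulate_frap exactly
  one <- generate_frap_ensemble(free, n_cells = 1, jitter_cv = 0,
                                noise_sd = 0, seed = 1)
  ref <- simulate_frap(free, duration = 60 + 60 * 5 / (free$k_in + free$k_out))
  expect_equal(one$traces[[1]]$I_nuc, ref$I_nuc)

  # round-trip at (f_ns = 0.3, f_cs = 0.4, k_out = 0.02), n = 20, fixed seed:
  # recovery within 1 propagated SE of the realized ensemble means
  p <- shuttling_params(k_out = 0.02, f_ns = 0.3, f_cs = 0.4)
  ens <- generate_frap_ensemble(p, n_cells = 20, seed = 5)
  est <- infer_sequestration(lapply(ens$traces, fit_recovery))
  expect_lt(abs(est$f_ns_hat - ens$truth$mean_f_ns), est$se_f_ns)
  expect_lt(abs(est$f_cs_hat - ens$truth$mean_f_cs), est$se_f_cs)
  expect_lt(abs(est$k_out_hat - ens$truth$mean_k_out), est$se_k_out)
})

test_that("two-condition comparisons preserve the programmed ordering", {
  # condition B: lower nuclear, higher cytoplasmic sequestration, equal k_out
  pA <- shuttling_params(k_out = 0.025, f_ns = 0.20, f_cs = 0.15)
  pB <- shuttling_params(k_out = 0.025, f_ns = 0.05, f_cs = 0.45)
  eA <- infer_sequestration(lapply(
    generate_frap_ensemble(pA, n_cells = 15, seed = 21)$traces, fit_recovery))
  eB <- infer_sequestration(lapply(
    generate_frap_ensemble(pB, n_cells = 15, seed = 22)$traces, fit_recovery))
  expect_lt(eB$f_ns_hat, eA$f_ns_hat)
  expect_gt(eB$f_cs_hat, eA$f_cs_hat)
  expect_equal(eB$k_out_hat, eA$k_out_hat, tolerance = 0.15)
})

test_that("degenerate shuttling parameters are rejected", {
  expect_error(shuttling_params(f_ns = 1.2), "\\[0, 1\\)")
  expect_error(shuttling_params(k_out = -1), "> 0")
  expect_error(simulate_frap(shuttling_params(), duration = 100),
               "duration")
})
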