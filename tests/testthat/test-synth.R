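test_that("trajectory ensembles obey the noise and seed contracts", {
  p <- feedback_params()
  traj <- simulate_feedback(p, make_step(50, t_off = 12), seq(0, 12, 0.05))
  # zero noise: all cells identical to the model solution
  e0 <- generate_trajectories(traj, n_cells = 5, noise_cv = 0, obs_sd = 0,
                              seed = 1)
  expect_equal(e0$cells[3, ], traj$S, ignore_attr = TRUE)

  # n = 700, cv = 0.2: ensemble mean close to the model solution everywhere
  e <- generate_trajectories(traj, n_cells = 700, noise_cv = 0.2,
                             obs_sd = 0.05, seed = 2)
  sem <- apply(e$cells, 2, sd) / sqrt(nrow(e$cells))
  z <- abs(e$mean - traj$S) / sem
  expect_lt(max(z), 4)
  # the shared per-cell amplitude factors correlate deviations across time,
  # so the within-2-SEM fraction fluctuates well below the pointwise 95%
  expect_gt(mean(z < 2), 0.75)

  # seed contract: identical seeds identical, different seeds different but
  # with matching ensemble means
  e2 <- generate_trajectories(traj, n_cells = 700, noise_cv = 0.2,
                              obs_sd = 0.05, seed = 2)
  expect_identical(e$cells, e2$cells)
  e3 <- generate_trajectories(traj, n_cells = 700, noise_cv = 0.2,
                              obs_sd = 0.05, seed = 3)
  expect_false(identical(e$cells, e3$cells))
  expect_equal(mean(e3$mean - e$mean), 0, tolerance = 0.02)
})

test_that("ensemble-mean error shrinks as one over the square root of n", {
  p <- feedback_params()
  traj <- simulate_feedback(p, make_step(50, t_off = 12), seq(0, 12, 0.1))
  rmse <- vapply(c(10, 100, 1000), function(n) {
    devs <- vapply(1:8, function(rep) {
      e <- generate_trajectories(traj, n_cells = n, noise_cv = 0.2,
                                 obs_sd = 0.05, seed = 1000 * n + rep)
      sqrt(mean((e$mean - traj$S)^2))
    }, numeric(1))
    mean(devs)
  }, numeric(1))
  expect_equal(rmse[1] / rmse[2], sqrt(10), tolerance = 0.5)
  expect_equal(rmse[2] / rmse[3], sqrt(10), tolerance = 0.5)
})

test_that("frap ensembles expose realized ground truth and are reproducible", {
  p <- shuttling_params(k_out = 0.03, f_ns = 0.2, f_cs = 0.3)
  e1 <- generate_frap_ensemble(p, n_cells = 12, seed = 4)
  e2 <- generate_frap_ensemble(p, n_cells = 12, seed = 4)
  expect_identical(e1$traces, e2$traces)
  expect_equal(nrow(e1$truth$cells), 12)
  expect_equal(e1$truth$mean_k_out, mean(e1$truth$cells$k_out))
})

test_that("colony generator emits programmed truth and restricts the interior", {
  col <- generate_colony(colony_params(), seed = 42)
  expect_equal(col$truth$wave_velocity, 10)
  expect_equal(col$truth$wave_onset, 25)

  # interior stays at baseline between restriction and wave onset:
  # center below half the edge value
  k <- col$kymographs$SMAD4
  mid <- k$t > 14 & k$t < 25
  center <- rowMeans(k$matrix[mid, k$r_centers < 80, drop = FALSE])
  edge <- rowMeans(k$matrix[mid, k$r_centers > 310, drop = FALSE])
  expect_true(all(center < 0.5 * edge))

  # bit-reproducibility
  col2 <- generate_colony(colony_params(), seed = 42)
  expect_identical(col$kymographs$SMAD4$matrix, col2$kymographs$SMAD4$matrix)

  # near-zero velocity: the front stays put after onset
  slow <- colony_params(wave_velocity = 1e-9)
  cs <- generate_colony(slow, seed = 1)
  ks <- cs$kymographs$SMAD4
  keep <- ks$t >= 12
  ft <- track_front(suppressWarnings(normalize_channel(
    kymograph(ks$matrix[keep, ], ks$r_centers, ks$t[keep]), "minmax")),
    window = c(26, 40))
  expect_equal(ft$velocity, 0, tolerance = 0.3)
})

test_that("pSMAD1 stays at the edge while SMAD2/3 carries the wave", {
  col <- generate_colony(colony_params(), seed = 8)
  tsel <- col$kymographs$pSMAD1$t >= 26
  trim <- function(kym) kymograph(kym$matrix[tsel, ], kym$r_centers,
                                  kym$t[tsel], channel = kym$channel)
  ft_p <- track_front(suppressWarnings(
    normalize_channel(trim(col$kymographs$pSMAD1), "minmax")),
    window = c(26, 40))
  ft_s <- track_front(suppressWarnings(
    normalize_channel(trim(col$kymographs$`SMAD2/3`), "minmax")),
    window = c(26, 40))
  expect_lt(abs(ft_p$velocity), 1)        # edge channel: stationary front
  expect_equal(ft_s$velocity, 10, tolerance = 1)  # wave channel moves inward
})
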