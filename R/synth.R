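#' Single-cell trajectory ensemble with known ground truth
#'
#' Emulates live-cell reporter ensembles: every cell follows the shared model
#' solution with a per-cell multiplicative lognormal amplitude factor applied
#' to the excess over baseline (mean 1, coefficient of variation `noise_cv`)
#' plus additive Gaussian observation noise. The ensemble mean converges to
#' the model solution as the number of cells grows.
#'
#' @param traj a [signal_trajectory()] (the shared model solution).
#' @param n_cells ensemble size (the live-imaging experiments this emulates
#'   measured on the order of 700 cells per condition).
#' @param noise_cv CV of the per-cell amplitude factor.
#' @param obs_sd additive observation noise (ratio units).
#' @param seed RNG seed (required; output is bit-reproducible).
#' @return list with `t`, `cells` (n_cells x time matrix), `mean` (ensemble
#'   mean) and `truth` (sidecar: the model solution and parameters).
#' @export
generate_trajectories <- function(traj, n_cells = 700, noise_cv = 0.2,
                                  obs_sd = 0.05, seed) {
  stopifnot(inherits(traj, "signal_trajectory"))
  set.seed(seed)
  S0 <- attr(traj, "S0")
  exc <- traj$S - S0
  sdlog <- sqrt(log(1 + noise_cv^2))
  amp <- if (noise_cv > 0)
    stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  else rep(1, n_cells)
  cells <- outer(amp, exc) + S0
  if (obs_sd > 0)
    cells <- cells + matrix(stats::rnorm(length(cells), 0, obs_sd),
                            nrow = n_cells)
  list(t = traj$t, cells = cells, mean = colMeans(cells),
       truth = list(model = as.data.frame(traj), S0 = S0,
                    noise_cv = noise_cv, obs_sd = obs_sd, seed = seed,
                    n_cells = n_cells))
}

#' Rendering parameters for synthetic cell-field images
#'
#' Cells are disks (nucleus, visible in both the signal and the
#' nuclear-marker channel) surrounded by a cytoplasmic ring in the signal
#' channel. Intensities are chosen so the noiseless background-subtracted
#' nuclear:cytoplasmic ratio equals each cell's ground-truth value:
#' nucleus `bg + ratio * cyt_excess`, ring `bg + cyt_excess`, background
#' `bg`. Per-pixel shot noise is Poisson on the intensity; read noise is
#' Gaussian with standard deviation `read_noise_frac` of the dynamic range.
#'
#' @param n_cells number of cells to place.
#' @param field_px image size `c(rows, cols)` in pixels.
#' @param nucleus_radius_px,ring_width_px cell geometry (pixels).
#' @param pixel_size micrometres per pixel.
#' @param bg,cyt_excess,dapi_level intensity levels (photon-ish units).
#' @param poisson apply shot noise.
#' @param read_noise_frac Gaussian read noise as a fraction of dynamic range.
#' @param max_attempts placement attempts before giving up on non-overlap.
#' @return an object of class `render_params`.
#' @export
render_params <- function(n_cells = 200, field_px = c(384, 384),
                          nucleus_radius_px = 4, ring_width_px = 3,
                          pixel_size = 1, bg = 100, cyt_excess = 200,
                          dapi_level = 500, poisson = TRUE,
                          read_noise_frac = 0.01, max_attempts = 20000) {
  structure(as.list(environment()), class = "render_params")
}

# non-overlapping centers in a rectangular field or a centred disc (px units)
place_centers <- function(n, field_px, min_dist, max_attempts,
                          disc_radius = NULL) {
  centers <- matrix(numeric(0), 0, 2)
  margin <- min_dist / 2 + 1
  attempts <- 0
  while (nrow(centers) < n && attempts < max_attempts) {
    attempts <- attempts + 1
    cand <- c(stats::runif(1, margin, field_px[1] - margin),
              stats::runif(1, margin, field_px[2] - margin))
    if (!is.null(disc_radius)) {
      d0 <- sqrt(sum((cand - field_px / 2)^2))
      if (d0 > disc_radius - margin) next
    }
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      if (min(d) < min_dist) next
    }
    centers <- rbind(centers, cand)
  }
  if (nrow(centers) < n)
    warning("placed only ", nrow(centers), " of ", n,
            " cells without overlap", call. = FALSE)
  centers
}

#' Render a synthetic cell field with ground truth
#'
#' @param ratios per-cell ground-truth nuclear:cytoplasmic ratios (recycled
#'   to `n_cells` if length 1).
#' @param render a [render_params()].
#' @param seed RNG seed (placement and noise; bit-reproducible).
#' @param centers optional pre-chosen centers (pixel coordinates, n x 2);
#'   skips random placement.
#' @return list with `channels` (named list of `signal` and `dapi` matrices),
#'   `truth` (data.frame `cell_id`, `x`, `y` in micrometres, `ratio`) and
#'   `render` (the parameters).
#' @export
render_cell_field <- function(ratios, render = render_params(), seed,
                              centers = NULL) {
  stopifnot(inherits(render, "render_params"))
  set.seed(seed)
  p <- render
  if (is.null(centers)) {
    min_dist <- 2 * (p$nucleus_radius_px + p$ring_width_px) + 1
    centers <- place_centers(p$n_cells, p$field_px, min_dist, p$max_attempts)
  }
  n <- nrow(centers)
  ratios <- if (n == 0) numeric(0) else rep_len(ratios, n)
  sig <- matrix(p$bg, p$field_px[1], p$field_px[2])
  dapi <- matrix(p$bg / 5, p$field_px[1], p$field_px[2])
  r_n <- p$nucleus_radius_px
  r_o <- r_n + p$ring_width_px
  for (i in seq_len(n)) {
    # paint inside a local window only
    ri <- max(1, floor(centers[i, 1] - r_o)):min(p$field_px[1],
                                                 ceiling(centers[i, 1] + r_o))
    ci <- max(1, floor(centers[i, 2] - r_o)):min(p$field_px[2],
                                                 ceiling(centers[i, 2] + r_o))
    d2 <- outer((ri - centers[i, 1])^2, (ci - centers[i, 2])^2, `+`)
    ring <- d2 <= r_o^2 & d2 > r_n^2
    nuc <- d2 <= r_n^2
    sig[ri, ci][ring] <- p$bg + p$cyt_excess
    sig[ri, ci][nuc] <- p$bg + ratios[i] * p$cyt_excess
    dapi[ri, ci][nuc] <- p$dapi_level
  }
  if (p$poisson) {
    sig[] <- stats::rpois(length(sig), sig)
    dapi[] <- stats::rpois(length(dapi), dapi)
  }
  if (p$read_noise_frac > 0) {
    sig <- sig + stats::rnorm(length(sig),
                              sd = p$read_noise_frac * max(c(ratios, 1)) *
                                p$cyt_excess)
    dapi <- dapi + stats::rnorm(length(dapi),
                                sd = p$read_noise_frac * p$dapi_level)
  }
  truth <- data.frame(cell_id = seq_len(n),
                      x = centers[, 1] * p$pixel_size,
                      y = centers[, 2] * p$pixel_size,
                      ratio = ratios[seq_len(n)])
  list(channels = list(signal = sig, dapi = dapi), truth = truth,
       render = p)
}

#' FRAP trace ensemble with per-cell parameter jitter
#'
#' Each cell's shuttling parameters are jittered around the condition values
#' (multiplicative lognormal with CV `jitter_cv` on `k_out`, `f_ns`, `f_cs`;
#' import rate shared), a trace is simulated with [simulate_frap()], and
#' Gaussian measurement noise is added to both channels. The sidecar records
#' the realized per-cell parameters and their means — the ground truth of the
#' generated ensemble for round-trip tests.
#'
#' @param params condition-level [shuttling_params()].
#' @param n_cells ensemble size (>= 12 in the experiments this emulates).
#' @param jitter_cv CV of the per-cell parameter jitter.
#' @param noise_sd measurement noise (units of pre-bleach cytoplasmic
#'   intensity).
#' @param dt sampling interval (seconds).
#' @param seed RNG seed.
#' @param condition label carried on the traces.
#' @return list with `traces` (list of `frap_trace`) and `truth` (sidecar:
#'   per-cell parameter data.frame plus realized means).
#' @export
generate_frap_ensemble <- function(params, n_cells = 20, jitter_cv = 0.05,
                                   noise_sd = 0.01, dt = 5, seed,
                                   condition = "untreated") {
  stopifnot(inherits(params, "shuttling_params"))
  set.seed(seed)
  sdlog <- sqrt(log(1 + jitter_cv^2))
  jit <- function(x, n) if (jitter_cv > 0)
    x * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) else rep(x, n)
  k_out_i <- jit(params$k_out, n_cells)
  f_ns_i <- pmin(jit(params$f_ns, n_cells), 0.95)
  f_cs_i <- pmin(jit(params$f_cs, n_cells), 0.95)
  duration <- 60 + 60 * 5 / (params$k_in + min(k_out_i, params$k_out))
  traces <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    pi <- shuttling_params(k_out = k_out_i[i], f_ns = f_ns_i[i],
                           f_cs = f_cs_i[i],
                           bleach_eff = params$bleach_eff,
                           k_in = params$k_in)
    tr <- simulate_frap(pi, duration = duration, dt = dt, t_bleach = 60,
                        condition = condition)
    if (noise_sd > 0) {
      tr$I_nuc <- tr$I_nuc + stats::rnorm(nrow(tr), 0, noise_sd)
      tr$I_cyt <- tr$I_cyt + stats::rnorm(nrow(tr), 0, noise_sd)
    }
    traces[[i]] <- tr
  }
  cells <- data.frame(cell_id = seq_len(n_cells), k_out = k_out_i,
                      f_ns = f_ns_i, f_cs = f_cs_i)
  list(traces = traces,
       truth = list(cells = cells,
                    mean_k_out = mean(k_out_i), mean_f_ns = mean(f_ns_i),
                    mean_f_cs = mean(f_cs_i), k_in = params$k_in,
                    bleach_eff = params$bleach_eff, condition = condition,
                    seed = seed))
}

#' Micropattern colony dynamics parameters
#'
#' Phenomenological space-time program of signaling in a BMP4-treated
#' micropatterned colony:
#' 1. a uniform response rising over the first hour everywhere;
#' 2. restriction of the response to an edge band: the interior decays so
#'   that the inner-half mean falls below half the edge-band mean by
#'   `edge_restriction_time` (the 0.5-crossing is programmed at
#'   `restriction_margin` of that time so restriction is complete by the
#'   stated time even under colony-to-colony variability);
#' 3. from `wave_onset`, a logistic front of increased signal travels inward
#'   at `wave_velocity` from the inner boundary of the edge domain
#'   (`colony_radius - wave_start_offset`).
#'
#' Channel composition: SMAD4 carries both the edge component and the wave
#' (combined saturatingly), pSMAD1 the edge component only, SMAD2/3 the wave
#' only, and BRA accumulates with first-order gene kinetics behind the wave.
#'
#' Noise model: each of `n_colonies` colonies gets a shared lognormal
#' amplitude factor (CV `colony_cv`) plus independent per-bin lognormal noise
#' (CV `bin_cv`, the cell-sampling error of a ~40-cell annulus); the emitted
#' kymographs are colony averages.
#'
#' @param colony_diameter micrometres (700 for the live-imaging colonies).
#' @param uniform_phase_end hours of uniform response.
#' @param edge_restriction_time hours by which the response is restricted to
#'   the edge.
#' @param edge_band_width micrometres.
#' @param wave_onset hours at which the inward wave starts.
#' @param wave_velocity micrometres/hr.
#' @param wave_start_offset micrometres inward of the rim where the wave
#'   front originates.
#' @param front_width 10-90% width of the logistic wavefront (micrometres).
#' @param amp peak excess of the programmed response (ratio units over a
#'   baseline of 1).
#' @param rise_tau hours, initial response rise time.
#' @param restriction_margin fraction of `edge_restriction_time` at which the
#'   interior/edge ratio is programmed to cross 0.5.
#' @param t_max,dt time grid (hours).
#' @param bin_width radial bin width (micrometres).
#' @param n_colonies colonies averaged per kymograph.
#' @param colony_cv,bin_cv noise parameters (see above).
#' @return an object of class `colony_params`.
#' @export
colony_params <- function(colony_diameter = 700, uniform_phase_end = 6,
                          edge_restriction_time = 12, edge_band_width = 40,
                          wave_onset = 25, wave_velocity = 10,
                          wave_start_offset = 50, front_width = 40,
                          amp = 3, rise_tau = 1, restriction_margin = 0.85,
                          t_max = 42, dt = 0.5, bin_width = 20,
                          n_colonies = 4, colony_cv = 0.2, bin_cv = 0.03) {
  stopifnot(colony_diameter > 0, wave_velocity > 0,
            uniform_phase_end > 0, edge_restriction_time > uniform_phase_end,
            edge_restriction_time < wave_onset, wave_onset < t_max)
  structure(as.list(environment()), class = "colony_params")
}

# logistic scale giving a 10-90% width `w`
logistic_scale <- function(w) w / (2 * log(9))

# deterministic space-time field of one channel; r in um, t in hours
colony_field <- function(params, channel, r, t) {
  p <- params
  n <- max(length(r), length(t))
  r <- rep_len(r, n); t <- rep_len(t, n)
  R <- p$colony_diameter / 2
  s_b <- logistic_scale(p$edge_band_width)
  s_w <- logistic_scale(p$front_width)
  r_b <- R - p$edge_band_width
  g <- stats::plogis((r - r_b) / s_b)
  rise <- 1 - exp(-t / p$rise_tau)
  x <- ifelse(t <= p$uniform_phase_end, 1,
              exp(-(t - p$uniform_phase_end) / restriction_tau(p)))
  u_B <- rise * (g + (1 - g) * x)
  r_front <- pmax(R - p$wave_start_offset -
                    p$wave_velocity * (t - p$wave_onset), 0)
  u_W <- ifelse(t >= p$wave_onset,
                stats::plogis((r - r_front) / s_w), 0)
  u <- switch(channel,
              SMAD4 = 1 - (1 - u_B) * (1 - u_W),
              pSMAD1 = u_B,
              `SMAD2/3` = u_W,
              stop("unknown channel: ", channel))
  1 + p$amp * u
}

# inner-half / edge-band bin index sets on the generator's radial grid
colony_bins <- function(params) {
  R <- params$colony_diameter / 2
  r <- seq(params$bin_width / 2, R, by = params$bin_width)
  list(r = r, inner = r <= R / 2, edge = r >= R - params$edge_band_width)
}

# interior decay time constant such that the inner-half / edge-band ratio of
# the programmed field crosses 0.5 at restriction_margin*edge_restriction_time
restriction_tau <- function(params) {
  p <- params
  b <- colony_bins(p)
  s_b <- logistic_scale(p$edge_band_width)
  r_b <- p$colony_diameter / 2 - p$edge_band_width
  g <- stats::plogis((b$r - r_b) / s_b)
  g_in <- mean(g[b$inner]); g_e <- mean(g[b$edge])
  x_star <- (0.5 * p$amp * g_e - p$amp * g_in - 0.5) /
    (p$amp * (1 - g_in) - 0.5 * p$amp * (1 - g_e))
  if (x_star <= 0 || x_star >= 1)
    stop("restriction crossing infeasible for these colony parameters")
  (p$restriction_margin * p$edge_restriction_time - p$uniform_phase_end) /
    log(1 / x_star)
}

#' Generate synthetic colony kymographs with ground truth
#'
#' Evaluates the programmed space-time field (see [colony_params()]) on the
#' radial-bin/time grid for each channel, simulates `n_colonies` noisy
#' colonies and averages them, and accumulates the BRA channel with
#' first-order gene kinetics behind the wavefront (normalized at export to
#' the maximum of the latest time, the BRA convention). Emits a ground-truth
#' sidecar with the programmed onset, velocity, restriction time and front
#' positions; closure tests read only the sidecar.
#'
#' @param params a [colony_params()].
#' @param seed RNG seed (bit-reproducible output).
#' @param channels which channels to emit.
#' @return list with `kymographs` (named list of raw [kymograph()]s; BRA is
#'   bra_rule-normalized) and `truth` (sidecar list).
#' @export
generate_colony <- function(params = colony_params(), seed,
                            channels = c("SMAD4", "pSMAD1", "SMAD2/3",
                                         "BRA")) {
  stopifnot(inherits(params, "colony_params"))
  set.seed(seed)
  p <- params
  b <- colony_bins(p)
  t <- seq(0, p$t_max, by = p$dt)
  R <- p$colony_diameter / 2
  noisy <- function(mat) {
    sdc <- sqrt(log(1 + p$colony_cv^2))
    sdb <- sqrt(log(1 + p$bin_cv^2))
    acc <- 0
    for (k in seq_len(p$n_colonies)) {
      ampf <- stats::rlnorm(1, -sdc^2 / 2, sdc)
      bin_noise <- matrix(stats::rlnorm(length(mat), -sdb^2 / 2, sdb),
                          nrow = nrow(mat))
      acc <- acc + 1 + (mat - 1) * ampf * bin_noise
    }
    acc / p$n_colonies
  }
  kyms <- list()
  for (ch in intersect(channels, c("SMAD4", "pSMAD1", "SMAD2/3"))) {
    clean <- outer(t, b$r, function(tt, rr) colony_field(p, ch, rr, tt))
    kyms[[ch]] <- kymograph(noisy(clean), b$r, t, channel = ch)
  }
  if ("BRA" %in% channels) {
    uW <- (outer(t, b$r, function(tt, rr)
      colony_field(p, "SMAD2/3", rr, tt)) - 1) / p$amp
    bra <- bra_accumulate(uW, t)
    kyms[["BRA"]] <- normalize_channel(
      kymograph(noisy(1 + p$amp * bra) - 1, b$r, t, channel = "BRA"),
      "bra_rule")
  }
  truth <- list(
    colony_radius = R, bin_width = p$bin_width,
    wave_onset = p$wave_onset, wave_velocity = p$wave_velocity,
    wave_origin = R - p$wave_start_offset,
    edge_restriction_time = p$restriction_margin * p$edge_restriction_time,
    uniform_phase_end = p$uniform_phase_end,
    edge_halfmax_radius = R - p$edge_band_width,
    front_position = data.frame(
      t = t, r_front = pmax(R - p$wave_start_offset -
                              p$wave_velocity * (t - p$wave_onset), 0) *
        (t >= p$wave_onset) + (R - p$edge_band_width) * (t < p$wave_onset)),
    seed = seed)
  list(kymographs = kyms, truth = truth)
}

# first-order BRA gene kinetics driven by the wave occupancy u in [0,1]:
# db/dt = a * h(max(u - theta, 0)) - delta * b, stepped exactly between rows
bra_accumulate <- function(u, t, a = 1, delta = 0.15, theta = 0.3,
                           K_m = 0.2) {
  x <- pmax(u - theta, 0)
  h <- x / (x + K_m)
  out <- matrix(0, nrow(u), ncol(u))
  for (i in seq_len(nrow(u) - 1)) {
    dtau <- t[i + 1] - t[i]
    e <- exp(-delta * dtau)
    out[i + 1, ] <- out[i, ] * e + (a / delta) * h[i, ] * (1 - e)
  }
  out
}

#' Render and segment one colony frame
#'
#' Places `n_cells` in the colony disc once (cells do not move), then for a
#' given time evaluates the programmed SMAD4 field at each cell's radius,
#' applies a persistent per-cell lognormal amplitude factor, renders the
#' field with [render_cell_field()] and returns the channels plus truth.
#' Used by the full imaging-pipeline closure.
#'
#' @param params a [colony_params()].
#' @param n_cells cells per colony.
#' @param img_px image size (square, pixels).
#' @param cell_cv per-cell amplitude CV.
#' @param seed RNG seed.
#' @return list with `centers` (pixel coordinates), `cell_amp`, `render`
#'   (a [render_params()]), `pixel_size`, and function `frame(t, seed)`
#'   rendering the channels at time `t`.
#' @export
colony_renderer <- function(params = colony_params(), n_cells = 330,
                            img_px = 256, cell_cv = 0.2, seed) {
  set.seed(seed)
  p <- params
  pixel_size <- p$colony_diameter / (img_px - 6)
  rp <- render_params(n_cells = n_cells, field_px = c(img_px, img_px),
                      nucleus_radius_px = 2, ring_width_px = 2,
                      pixel_size = pixel_size)
  min_dist <- 2 * (rp$nucleus_radius_px + rp$ring_width_px) + 1
  centers <- place_centers(n_cells, rp$field_px, min_dist, rp$max_attempts,
                           disc_radius = (img_px - 6) / 2)
  sdlog <- sqrt(log(1 + cell_cv^2))
  amp <- stats::rlnorm(nrow(centers), -sdlog^2 / 2, sdlog)
  r_um <- sqrt((centers[, 1] - img_px / 2)^2 +
                 (centers[, 2] - img_px / 2)^2) * pixel_size
  frame <- function(t, seed) {
    v <- colony_field(p, "SMAD4", r_um, t)
    ratios <- 1 + (v - 1) * amp
    render_cell_field(ratios, render = rp, seed = seed, centers = centers)
  }
  list(centers = centers, cell_amp = amp, render = rp,
       pixel_size = pixel_size, center_um = rep(img_px / 2 * pixel_size, 2),
       frame = frame)
}

#' Earliest time by which the interior signal is edge-restricted
#'
#' The earliest time after which the mean raw signal over the inner half of
#' the colony stays below `threshold` times the mean over the edge band,
#' until wave onset.
#'
#' @param kym a raw (unnormalized) [kymograph()].
#' @param edge_band_width micrometres defining the edge band.
#' @param wave_onset hours; the condition must hold from the reported time to
#'   this time.
#' @param threshold interior/edge ratio defining "restricted".
#' @return hours (`NA` if the interior never restricts before onset).
#' @export
edge_restriction_time <- function(kym, edge_band_width = 40, wave_onset = 25,
                                  threshold = 0.5) {
  stopifnot(inherits(kym, "kymograph"))
  R <- max(kym$r_centers)
  inner <- kym$r_centers <= R / 2
  edge <- kym$r_centers >= R - edge_band_width
  ratio <- rowMeans(kym$matrix[, inner, drop = FALSE], na.rm = TRUE) /
    rowMeans(kym$matrix[, edge, drop = FALSE], na.rm = TRUE)
  pre <- which(kym$t < wave_onset)
  below <- ratio[pre] < threshold
  if (!any(below)) return(NA_real_)
  # last pre-onset index that is NOT below, plus one step
  bad <- which(!below)
  idx <- if (length(bad) == 0) 1L else max(bad) + 1L
  if (idx > length(pre)) return(NA_real_)
  kym$t[pre[idx]]
}
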