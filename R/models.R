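#' Parameters of the negative-feedback signaling model
#'
#' Two-variable model of the Activin/Nodal-like adaptive SMAD4 response. The
#' signal S (nuclear:cytoplasmic ratio units) is driven by receptor occupancy
#' and repressed by a downstream inhibitor I produced in proportion to the
#' signaling excess:
#'
#' \deqn{dS/dt = \alpha\, O(L) / (1 + I/K_I) - \gamma (S - S_0)}
#' \deqn{dI/dt = \beta (S - S_0) - \delta I}
#'
#' with occupancy \eqn{O(L) = L / (L + K_L)}. With no ligand the unique steady
#' state is \eqn{S = S_0, I = 0}; a sustained step produces an overshoot that
#' relaxes to a plateau above \eqn{S_0} maintained by continued exposure. The
#' adaptation timescale is set by the inhibitor decay rate \eqn{\delta} and is
#' therefore independent of dose.
#'
#' The default values are the shipped calibration (see
#' `analysis/00_calibrate_feedback.R`): a saturating 50 ng/ml step yields
#' peak excess 1.0 ratio units and a late plateau at 20% of the peak excess,
#' and two saturating pulses 5 hr apart re-trigger to >= 85% of the first
#' peak.
#'
#' @param alpha max activation rate (ratio units/hr).
#' @param K_L half-saturating ligand dose (ng/ml).
#' @param gamma signal relaxation rate (1/hr).
#' @param beta inhibitor production rate (1/hr per ratio-unit excess).
#' @param delta inhibitor decay rate (1/hr).
#' @param K_I inhibitor half-inhibition scale (dimensionless).
#' @param S0 pre-stimulus signal level (ratio units).
#' @return an object of class `feedback_params`.
#' @export
feedback_params <- function(alpha = 106.6854327084,
                            K_L = 20,
                            gamma = 6,
                            beta = 265.6387434472,
                            delta = 0.85,
                            K_I = 1,
                            S0 = 1) {
  p <- list(alpha = alpha, K_L = K_L, gamma = gamma, beta = beta,
            delta = delta, K_I = K_I, S0 = S0)
  if (any(unlist(p[c("alpha", "K_L", "gamma", "beta", "delta", "K_I")]) <= 0))
    stop("all feedback model rates and scales must be > 0")
  if (S0 < 0) stop("S0 must be >= 0")
  structure(p, class = "feedback_params")
}

#' SMAD2/3 variant of the feedback model
#'
#' The receptor-specific SMAD2/3 channel adapts less deeply than SMAD4 (to
#' about 60% of peak rather than 20%). It is modeled as the same feedback
#' system with a weaker feedback (larger `K_I`), calibrated so a saturating
#' step yields baseline fraction 0.60.
#'
#' @return an object of class `feedback_params`.
#' @export
smad23_params <- function() {
  feedback_params(K_I = 1208.2707018275)
}

#' Parameters of the receptor-depletion model
#'
#' Alternative (rejected) mechanism in which adaptation is caused by
#' degradation of ligand-bound receptors:
#'
#' \deqn{dR/dt = s - d_i R - k_b L R, \quad dR^*/dt = k_b L R - d_a R^*}
#'
#' with signal proportional to active receptor \eqn{R^*}. At saturating
#' ligand the adapted fraction of the peak approaches \eqn{d_i / d_a}: the
#' magnitude of adaptation is governed by the ratio of the degradation rates
#' of active and inactive receptors, and the same rates set the recovery
#' timescale — strong adaptation forces slow recovery, which is the argument
#' against this mechanism.
#'
#' @param s receptor synthesis rate (molecules/hr).
#' @param d_i inactive-receptor degradation rate (1/hr).
#' @param d_a active-receptor degradation rate (1/hr).
#' @param k_b ligand-binding rate constant (1/(ng/ml)/hr).
#' @param rho signal per active receptor (ratio units/molecule).
#' @return an object of class `receptor_params`.
#' @export
receptor_params <- function(s = 10, d_i = 0.1, d_a = 1, k_b = 1, rho = 0.01) {
  p <- list(s = s, d_i = d_i, d_a = d_a, k_b = k_b, rho = rho)
  if (any(unlist(p) <= 0)) stop("all receptor model parameters must be > 0")
  structure(p, class = "receptor_params")
}

#' Parameters of the ligand-depletion model
#'
#' BMP-like sustained response whose duration is dose-dependent because the
#' cells deplete the ligand: within each media segment the concentration
#' decays exponentially at uptake rate `u` from the concentration set by the
#' last media change. The response follows a switch-like occupancy
#' \eqn{O(L) = L^h / (L^h + L_{thresh}^h)} relaxed at rate `gamma`:
#'
#' \deqn{dS/dt = \alpha\, O(L(t)) - \gamma (S - S_0)}
#'
#' Signaling is sustained while `L` is well above `L_thresh` and declines when
#' `L` approaches it, so the duration of half-maximal signaling grows with
#' \eqn{\log(L_0/L_{thresh})/u}.
#'
#' @param u ligand uptake/depletion rate (1/hr).
#' @param L_thresh response threshold dose (ng/ml).
#' @param hill Hill coefficient of the switch-like occupancy.
#' @param alpha response gain (ratio units/hr).
#' @param gamma signal relaxation rate (1/hr).
#' @param S0 pre-stimulus signal level (ratio units).
#' @return an object of class `depletion_params`.
#' @export
depletion_params <- function(u = 0.15, L_thresh = 1, hill = 4,
                             alpha = 3, gamma = 3, S0 = 1) {
  p <- list(u = u, L_thresh = L_thresh, hill = hill, alpha = alpha,
            gamma = gamma, S0 = S0)
  if (any(unlist(p[c("u", "L_thresh", "hill", "alpha", "gamma")]) <= 0))
    stop("all ligand-depletion parameters must be > 0")
  structure(p, class = "depletion_params")
}

#' Build a signal trajectory object
#'
#' @param t strictly increasing time grid (hours).
#' @param S signal values (nuc:cyt ratio units), same length as `t`.
#' @param channel readout name (e.g. "SMAD4", "SMAD2/3", "pSMAD1").
#' @param schedule_name,model_name provenance labels.
#' @param params parameter snapshot (list).
#' @param S0 pre-stimulus level used by [adaptation_metrics()].
#' @param t_on stimulus onset time (hours).
#' @return an object of class `signal_trajectory` (a data.frame with columns
#'   `t` and `S` plus metadata attributes).
#' @export
signal_trajectory <- function(t, S, channel = "SMAD4",
                              schedule_name = "", model_name = "",
                              params = list(), S0 = 0, t_on = t[1]) {
  if (length(t) != length(S)) stop("t and S must have equal length")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(S < -1e-9)) stop("signal values must be >= 0")
  structure(data.frame(t = t, S = pmax(S, 0)),
            channel = channel, schedule_name = schedule_name,
            model_name = model_name, params = params, S0 = S0, t_on = t_on,
            class = c("signal_trajectory", "data.frame"))
}

# Integrate an ODE right-hand side with lsoda, restarting at every schedule
# breakpoint so the adaptive solver never smooths a media-change
# discontinuity. `rhs(t, y)` returns dy/dt. Output at `t_grid` exactly.
integrate_piecewise <- function(rhs, y0, t_grid, breaks = numeric(0),
                                rtol = 1e-6, atol = 1e-9) {
  stopifnot(all(diff(t_grid) > 0))
  breaks <- breaks[breaks > t_grid[1] & breaks < t_grid[length(t_grid)]]
  edges <- sort(unique(c(t_grid[1], breaks, t_grid[length(t_grid)])))
  out_t <- numeric(0)
  out_y <- NULL
  y <- y0
  f <- function(t, y, parms) list(rhs(t, y))
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    tt <- sort(unique(c(a, t_grid[t_grid > a & t_grid < b], b)))
    sol <- tryCatch(
      deSolve::lsoda(y, tt, f, parms = NULL, rtol = rtol, atol = atol),
      warning = function(w) stop("ODE integration failed on [", a, ", ", b,
                                 "] hr: ", conditionMessage(w), call. = FALSE))
    keep <- sol[, 1] %in% t_grid
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
    y <- as.numeric(sol[nrow(sol), -1])
  }
  dup <- duplicated(out_t)
  list(t = out_t[!dup], y = out_y[!dup, , drop = FALSE])
}

#' Fixed-step fourth-order Runge-Kutta reference integrator
#'
#' Independent reference used to validate the adaptive-step solutions: a
#' classical RK4 scheme with `refine` fixed sub-steps per output interval,
#' restarted at schedule breakpoints. Not intended for production use.
#'
#' @param rhs function `(t, y)` returning dy/dt.
#' @param y0 initial state.
#' @param t_grid output times (hours).
#' @param breaks discontinuity times to land on exactly.
#' @param refine sub-steps per output interval.
#' @return matrix of states, one row per element of `t_grid`.
#' @export
integrate_rk4 <- function(rhs, y0, t_grid, breaks = numeric(0), refine = 10) {
  stopifnot(all(diff(t_grid) > 0), refine >= 1)
  y <- y0
  out <- matrix(NA_real_, length(t_grid), length(y0))
  out[1, ] <- y0
  step_to <- function(y, a, b, n) {
    h <- (b - a) / n
    for (k in seq_len(n)) {
      t <- a + (k - 1) * h
      k1 <- rhs(t, y)
      k2 <- rhs(t + h / 2, y + h / 2 * k1)
      k3 <- rhs(t + h / 2, y + h / 2 * k2)
      k4 <- rhs(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  for (i in seq_len(length(t_grid) - 1)) {
    a <- t_grid[i]; b <- t_grid[i + 1]
    inner <- sort(unique(c(a, breaks[breaks > a & breaks < b], b)))
    for (j in seq_len(length(inner) - 1))
      y <- step_to(y, inner[j], inner[j + 1], refine)
    out[i + 1, ] <- y
  }
  out
}

#' Simulate the negative-feedback model under a ligand schedule
#'
#' @param params a [feedback_params()].
#' @param schedule a [ligand_schedule()].
#' @param t_grid increasing time grid (hours); the initial condition is the
#'   pre-stimulus steady state `(S0, 0)`.
#' @param channel readout label carried on the trajectory.
#' @param rtol relative tolerance of the stiff-capable adaptive solver.
#' @return a [signal_trajectory()].
#' @export
simulate_feedback <- function(params, schedule, t_grid,
                              channel = "SMAD4", rtol = 1e-6) {
  stopifnot(inherits(params, "feedback_params"),
            inherits(schedule, "ligand_schedule"))
  p <- unclass(params)
  rhs <- function(t, y) {
    L <- evaluate_schedule(schedule, t)
    O <- L / (L + p$K_L)
    c(p$alpha * O / (1 + y[2] / p$K_I) - p$gamma * (y[1] - p$S0),
      p$beta * (y[1] - p$S0) - p$delta * y[2])
  }
  sol <- integrate_piecewise(rhs, c(p$S0, 0), t_grid,
                             breaks = schedule_breakpoints(schedule),
                             rtol = rtol)
  t_on <- stimulus_onset(schedule)
  signal_trajectory(sol$t, sol$y[, 1], channel = channel,
                    schedule_name = schedule$name, model_name = "feedback",
                    params = p, S0 = p$S0, t_on = t_on)
}

#' Simulate the receptor-depletion model under a ligand schedule
#'
#' @inheritParams simulate_feedback
#' @param params a [receptor_params()].
#' @return a [signal_trajectory()] with `S = rho * R*` and `S0 = 0`.
#' @export
simulate_receptor_depletion <- function(params, schedule, t_grid,
                                        channel = "SMAD4", rtol = 1e-6) {
  stopifnot(inherits(params, "receptor_params"),
            inherits(schedule, "ligand_schedule"))
  p <- unclass(params)
  rhs <- function(t, y) {
    L <- evaluate_schedule(schedule, t)
    c(p$s - p$d_i * y[1] - p$k_b * L * y[1],
      p$k_b * L * y[1] - p$d_a * y[2])
  }
  sol <- integrate_piecewise(rhs, c(p$s / p$d_i, 0), t_grid,
                             breaks = schedule_breakpoints(schedule),
                             rtol = rtol)
  signal_trajectory(sol$t, p$rho * sol$y[, 2], channel = channel,
                    schedule_name = schedule$name,
                    model_name = "receptor_depletion", params = p, S0 = 0,
                    t_on = stimulus_onset(schedule))
}

#' Simulate the ligand-depletion (BMP-like) model
#'
#' Ligand decays exponentially at uptake rate `u` from the level set by each
#' media change; concentration is reset at every schedule breakpoint. A bare
#' initial dose can be given instead of a schedule.
#'
#' @param params a [depletion_params()].
#' @param schedule a [ligand_schedule()], or a single number interpreted as an
#'   initial dose L0 applied at t = 0 and never replenished.
#' @param t_grid increasing time grid (hours).
#' @param channel readout label.
#' @param rtol solver relative tolerance.
#' @return a [signal_trajectory()]; the realized (depleting) ligand curve is
#'   attached as attribute `ligand`.
#' @export
simulate_ligand_depletion <- function(params, schedule, t_grid,
                                      channel = "SMAD4", rtol = 1e-6) {
  stopifnot(inherits(params, "depletion_params"))
  if (is.numeric(schedule) && length(schedule) == 1) {
    schedule <- make_step(schedule, t_on = t_grid[1],
                          t_off = t_grid[length(t_grid)],
                          name = sprintf("bolus_%gng", schedule))
  }
  stopifnot(inherits(schedule, "ligand_schedule"))
  p <- unclass(params)
  seg <- schedule$segments
  # concentration at time t: level set at the start of the active segment,
  # decayed exponentially since that media change
  Lfun <- function(t) {
    L <- numeric(length(t))
    for (i in seq_len(nrow(seg))) {
      last <- i == nrow(seg)
      sel <- t >= seg$t_start[i] &
        (if (last) t <= seg$t_end[i] else t < seg$t_end[i])
      L[sel] <- seg$c_start[i] * exp(-p$u * (t[sel] - seg$t_start[i]))
    }
    L
  }
  rhs <- function(t, y) {
    L <- Lfun(t)
    O <- L^p$hill / (L^p$hill + p$L_thresh^p$hill)
    p$alpha * O - p$gamma * (y[1] - p$S0)
  }
  sol <- integrate_piecewise(rhs, p$S0, t_grid,
                             breaks = schedule_breakpoints(schedule),
                             rtol = rtol)
  traj <- signal_trajectory(sol$t, sol$y[, 1], channel = channel,
                            schedule_name = schedule$name,
                            model_name = "ligand_depletion", params = p,
                            S0 = p$S0, t_on = stimulus_onset(schedule))
  attr(traj, "ligand") <- Lfun(sol$t)
  traj
}

# first time at which the schedule becomes positive (stimulus onset)
stimulus_onset <- function(schedule) {
  seg <- schedule$segments
  on <- seg$t_start[seg$c_start > 0 | seg$c_end > 0]
  if (length(on) == 0) seg$t_start[1] else min(on)
}

#' Target-gene transcription parameters
#'
#' First-order mRNA kinetics driven by signaling excess above a threshold:
#' \deqn{dm/dt = a\, h(\max(S - \theta, 0)) - \delta_m m,\quad
#'       h(x) = x / (x + K_m).}
#' Adaptive-class genes have `theta` above the adapted baseline excess so they
#' respond only to the transient peak; sustained-class genes have `theta`
#' below it and stay transcribed from the maintained baseline.
#'
#' @param mode `"adaptive"` or `"sustained"` (label only; the threshold does
#'   the work).
#' @param a max transcription rate (1/hr).
#' @param theta signal threshold (excess over `S0`, ratio units).
#' @param delta_m mRNA decay rate (1/hr).
#' @param K_m half-saturation of the transcription response (ratio units).
#' @return an object of class `gene_params`.
#' @export
gene_params <- function(mode = c("adaptive", "sustained"), a = 1,
                        theta = if (match.arg(mode) == "adaptive") 0.5 else 0.05,
                        delta_m = 0.2, K_m = 0.1) {
  mode <- match.arg(mode)
  if (delta_m <= 0) stop("delta_m must be > 0")
  if (a <= 0 || K_m <= 0) stop("a and K_m must be > 0")
  structure(list(mode = mode, a = a, theta = theta, delta_m = delta_m,
                 K_m = K_m), class = "gene_params")
}

#' Simulate target-gene mRNA driven by a signal trajectory
#'
#' The trajectory is interpolated linearly between grid points. Setting
#' `t_inh` clamps the signal to its pre-stimulus level from that time on
#' (small-molecule pathway inhibition), after which mRNA decays exponentially
#' at `delta_m`.
#'
#' @param gene a [gene_params()].
#' @param traj a [signal_trajectory()].
#' @param t_inh optional pathway-inhibition time (hours).
#' @param m0 initial mRNA level.
#' @return data.frame with columns `t` and `m`.
#' @export
simulate_target_gene <- function(gene, traj, t_inh = Inf, m0 = 0) {
  stopifnot(inherits(gene, "gene_params"),
            inherits(traj, "signal_trajectory"))
  S0 <- attr(traj, "S0")
  Sfun <- stats::approxfun(traj$t, traj$S, rule = 2)
  rhs <- function(t, y) {
    S <- if (t >= t_inh) S0 else Sfun(t)
    x <- max(S - S0 - gene$theta, 0)
    gene$a * x / (x + gene$K_m) - gene$delta_m * y[1]
  }
  breaks <- if (is.finite(t_inh)) t_inh else numeric(0)
  sol <- integrate_piecewise(rhs, m0, traj$t, breaks = breaks)
  data.frame(t = sol$t, m = sol$y[, 1])
}

#' Reference-gene normalized qPCR expression
#'
#' Relative expression on a log2 scale from raw cycle-threshold values,
#' normalized to a reference gene (ATP5O in the experiments this mirrors):
#' `-(ct_target - ct_reference)`, i.e. each cycle earlier is a doubling.
#'
#' @param ct_target,ct_reference threshold cycles.
#' @return log2 expression relative to the reference.
#' @examples
#' normalize_ct(18, 20)  # 4-fold higher than reference -> +2
#' @export
normalize_ct <- function(ct_target, ct_reference) {
  -(ct_target - ct_reference)
}
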