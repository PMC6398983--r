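#' Adaptation metrics of a signal trajectory
#'
#' Quantifies a response relative to the pre-stimulus level `S0`:
#' * `peak`: maximum excess over `S0`, and `peak_time` (hours);
#' * `baseline`: mean signal over the final 10% of the window (the late
#'   plateau), reported in ratio units;
#' * `baseline_fraction`: `(baseline - S0) / peak` — 0.20 means the response
#'   adapts to 20% of its peak;
#' * `adaptation_timescale`: time from the peak until the excess over the
#'   baseline first falls to 1/e of the peak-to-baseline excess.
#'
#' Monotone non-decreasing (sustained) trajectories get `baseline_fraction
#' = 1` and an infinite timescale. A flat trajectory (no excess above `S0`)
#' is flagged `"no response"` with `NA` metrics. An adapting trajectory whose
#' window is shorter than 4 adaptation timescales after stimulus onset raises
#' a "window too short" error, since its baseline cannot be read reliably.
#'
#' @param traj a [signal_trajectory()].
#' @param S0 pre-stimulus level; defaults to the trajectory attribute.
#' @param t_on stimulus onset; defaults to the trajectory attribute.
#' @param response_tol minimum peak excess counted as a response.
#' @return list of class `adaptation_metrics` with fields `peak`,
#'   `peak_time`, `baseline`, `baseline_fraction`, `adaptation_timescale`,
#'   `flag` (one of "ok", "no response") and `class` (sustained / adaptive /
#'   intermediate).
#' @export
adaptation_metrics <- function(traj, S0 = attr(traj, "S0"),
                               t_on = attr(traj, "t_on"),
                               response_tol = 1e-6) {
  stopifnot(is.data.frame(traj), all(c("t", "S") %in% names(traj)))
  if (is.null(S0)) stop("S0 must be supplied or carried by the trajectory")
  if (is.null(t_on)) t_on <- traj$t[1]
  t <- traj$t; S <- traj$S
  exc <- S - S0
  peak <- max(exc)
  out <- list(peak = peak, peak_time = t[which.max(exc)],
              baseline = NA_real_, baseline_fraction = NA_real_,
              adaptation_timescale = NA_real_, flag = "ok",
              class = NA_character_)
  if (peak < response_tol) {
    out$flag <- "no response"
    return(structure(out, class = "adaptation_metrics"))
  }
  n_tail <- max(ceiling(0.1 * length(t)), 1L)
  baseline <- mean(S[seq.int(length(t) - n_tail + 1L, length(t))])
  out$baseline <- baseline
  post <- which(t >= t_on)
  monotone <- all(diff(S[post]) >= -response_tol)
  if (monotone) {
    out$baseline_fraction <- 1
    out$adaptation_timescale <- Inf
  } else {
    out$baseline_fraction <- (baseline - S0) / peak
    i_pk <- which.max(exc)
    target <- baseline + (S[i_pk] - baseline) / exp(1)
    after <- which(t > t[i_pk] & S <= target)
    out$adaptation_timescale <-
      if (length(after) == 0) Inf else t[after[1]] - t[i_pk]
    if (is.finite(out$adaptation_timescale) &&
        out$baseline_fraction < 0.8 &&
        (t[length(t)] - t_on) < 4 * out$adaptation_timescale)
      stop("window too short: trajectory must cover >= 4 adaptation ",
           "timescales after stimulus onset")
  }
  out$class <- classify_response(out$baseline_fraction)
  structure(out, class = "adaptation_metrics")
}

#' Classify a response by its baseline fraction
#'
#' Sentinel thresholds: `baseline_fraction >= 0.8` is sustained, `<= 0.5`
#' adaptive, in between intermediate.
#'
#' @param baseline_fraction dimensionless, from [adaptation_metrics()].
#' @return one of `"sustained"`, `"adaptive"`, `"intermediate"`.
#' @export
classify_response <- function(baseline_fraction) {
  if (is.na(baseline_fraction)) return(NA_character_)
  if (baseline_fraction >= 0.8) "sustained"
  else if (baseline_fraction <= 0.5) "adaptive"
  else "intermediate"
}

#' @export
print.adaptation_metrics <- function(x, ...) {
  cat("adaptation metrics:", x$flag, "\n")
  if (x$flag == "ok")
    cat(sprintf(
      "  peak excess %.4g at %.3g hr; baseline %.4g; fraction %.3g (%s); timescale %.3g hr\n",
      x$peak, x$peak_time, x$baseline, x$baseline_fraction, x$class,
      x$adaptation_timescale))
  invisible(x)
}

#' Duration of half-maximal signaling
#'
#' Length of time the excess over `S0` stays at or above half its maximum —
#' the duration readout used for dose-dependent BMP response decline.
#'
#' @param traj a [signal_trajectory()].
#' @param S0 pre-stimulus level; defaults to the trajectory attribute.
#' @return hours (0 if there is no response).
#' @export
halfmax_duration <- function(traj, S0 = attr(traj, "S0")) {
  exc <- traj$S - S0
  pk <- max(exc)
  if (pk <= 0) return(0)
  above <- exc >= pk / 2
  if (!any(above)) return(0)
  diff(range(traj$t[above]))
}
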