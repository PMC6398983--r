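#' Construct a piecewise ligand schedule
#'
#' A ligand schedule describes extracellular ligand concentration over time as
#' an ordered set of contiguous, non-overlapping segments. Each segment spans
#' `[t_start, t_end)` hours and carries the concentration from `c_start` to
#' `c_end` ng/ml, either as a constant (`c_start` held, media-change style) or
#' by linear interpolation. Outside the covered span the concentration is 0.
#'
#' @param segments data.frame with columns `t_start`, `t_end` (hours),
#'   `c_start`, `c_end` (ng/ml) and `interpolation` (`"constant"` or
#'   `"linear"`). Segments must be contiguous and ordered.
#' @param name character label for the schedule.
#' @return An object of class `ligand_schedule`.
#' @examples
#' sched <- ligand_schedule(data.frame(
#'   t_start = 0, t_end = 48, c_start = 50, c_end = 50,
#'   interpolation = "constant"), name = "step50")
#' evaluate_schedule(sched, c(-1, 1, 50))
#' @export
ligand_schedule <- function(segments, name = "schedule") {
  req <- c("t_start", "t_end", "c_start", "c_end", "interpolation")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    stop("`segments` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  segments <- segments[order(segments$t_start), req, drop = FALSE]
  if (any(segments$t_end <= segments$t_start))
    stop("each segment needs t_end > t_start")
  if (any(segments$c_start < 0) || any(segments$c_end < 0))
    stop("ligand concentrations must be >= 0")
  if (!all(segments$interpolation %in% c("constant", "linear")))
    stop("interpolation must be 'constant' or 'linear'")
  if (nrow(segments) > 1) {
    gap <- segments$t_start[-1] - segments$t_end[-nrow(segments)]
    if (any(gap < -1e-9)) stop("segments overlap")
    if (any(abs(gap) > 1e-9)) stop("segments must be contiguous")
  }
  structure(list(segments = segments, name = name),
            class = "ligand_schedule")
}

#' @export
print.ligand_schedule <- function(x, ...) {
  cat("ligand schedule '", x$name, "': ", nrow(x$segments),
      " segment(s), span ", min(x$segments$t_start), "-",
      max(x$segments$t_end), " hr\n", sep = "")
  invisible(x)
}

#' Evaluate a ligand schedule at given times
#'
#' Right-continuous at step discontinuities: at a breakpoint the segment
#' starting there wins. Returns 0 ng/ml outside the covered span.
#'
#' @param schedule a [ligand_schedule()].
#' @param t numeric vector of times (hours).
#' @return numeric vector of concentrations (ng/ml).
#' @export
evaluate_schedule <- function(schedule, t) {
  stopifnot(inherits(schedule, "ligand_schedule"), all(is.finite(t)))
  seg <- schedule$segments
  out <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    # half-open [t_start, t_end) gives right-continuity; the final segment
    # is closed at its right end so the span endpoint evaluates to its value
    last <- i == nrow(seg)
    sel <- t >= seg$t_start[i] & (if (last) t <= seg$t_end[i] else t < seg$t_end[i])
    if (!any(sel)) next
    if (seg$interpolation[i] == "constant") {
      out[sel] <- seg$c_start[i]
    } else {
      f <- (t[sel] - seg$t_start[i]) / (seg$t_end[i] - seg$t_start[i])
      out[sel] <- seg$c_start[i] + f * (seg$c_end[i] - seg$c_start[i])
    }
  }
  out
}

#' Times at which a schedule is discontinuous or changes slope
#'
#' Used by the integrators to split the time axis so that the adaptive solver
#' never steps across a media change.
#'
#' @param schedule a [ligand_schedule()].
#' @return sorted numeric vector of breakpoint times (hours).
#' @export
schedule_breakpoints <- function(schedule) {
  sort(unique(c(schedule$segments$t_start, schedule$segments$t_end)))
}

#' Step stimulation schedule
#'
#' @param dose ng/ml, held from `t_on` to `t_off`.
#' @param t_on,t_off hours.
#' @param name label.
#' @return a [ligand_schedule()].
#' @export
make_step <- function(dose, t_on = 0, t_off = 48,
                      name = sprintf("step_%gng", dose)) {
  if (dose < 0) stop("dose must be >= 0")
  ligand_schedule(data.frame(t_start = t_on, t_end = t_off, c_start = dose,
                             c_end = dose, interpolation = "constant"),
                  name = name)
}

#' Staircase ramp schedule
#'
#' Experimental concentration ramps are realized as hourly media changes, so a
#' ramp is a staircase of `n_steps` equal increments, each held for
#' `duration / n_steps` hours, ending at `final_dose`. After the staircase the
#' final dose is optionally held until `hold_until`.
#'
#' @param final_dose ng/ml reached by the last stair.
#' @param duration hours over which the staircase rises.
#' @param n_steps number of equal increments (default one per hour).
#' @param hold_until if greater than `duration`, the final dose is held as an
#'   extra constant segment up to this time (hours).
#' @param name label.
#' @return a [ligand_schedule()].
#' @export
make_ramp <- function(final_dose, duration, n_steps = round(duration),
                      hold_until = duration,
                      name = sprintf("ramp_%gng_%ghr_%dsteps",
                                     final_dose, duration, n_steps)) {
  if (final_dose <= 0) stop("final_dose must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) stop("n_steps must be >= 1")
  h <- duration / n_steps
  lev <- final_dose * seq_len(n_steps) / n_steps
  seg <- data.frame(t_start = h * (seq_len(n_steps) - 1),
                    t_end = h * seq_len(n_steps),
                    c_start = lev, c_end = lev, interpolation = "constant")
  if (hold_until > duration)
    seg <- rbind(seg, data.frame(t_start = duration, t_end = hold_until,
                                 c_start = final_dose, c_end = final_dose,
                                 interpolation = "constant"))
  ligand_schedule(seg, name = name)
}

#' Pulse-train schedule
#'
#' Alternating high/low ligand pulses. The defaults are the three-pulse
#' protocol used for Activin: pulses of 6, 10 and 8 hours at 30 ng/ml with
#' 5-hour gaps at the low dose.
#'
#' @param high,low ng/ml during pulses and gaps.
#' @param pulse_durations hours, one per pulse.
#' @param gap hours between consecutive pulses.
#' @param name label.
#' @return a [ligand_schedule()].
#' @export
make_pulse_train <- function(high = 30, low = 0,
                             pulse_durations = c(6, 10, 8), gap = 5,
                             name = "pulse_train") {
  stopifnot(high >= 0, low >= 0, gap >= 0, all(pulse_durations > 0))
  t <- 0
  rows <- list()
  for (i in seq_along(pulse_durations)) {
    rows[[length(rows) + 1L]] <- data.frame(
      t_start = t, t_end = t + pulse_durations[i], c_start = high,
      c_end = high, interpolation = "constant")
    t <- t + pulse_durations[i]
    if (i < length(pulse_durations) && gap > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        t_start = t, t_end = t + gap, c_start = low, c_end = low,
        interpolation = "constant")
      t <- t + gap
    }
  }
  ligand_schedule(do.call(rbind, rows), name = name)
}

#' Integrated ligand exposure of a schedule
#'
#' @param schedule a [ligand_schedule()].
#' @return integral of concentration over the covered span (ng/ml x hr).
#' @export
integrate_schedule <- function(schedule) {
  seg <- schedule$segments
  sum((seg$t_end - seg$t_start) * (seg$c_start + seg$c_end) / 2)
}
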