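#' Shuttling / sequestration parameters for FRAP simulation
#'
#' Two-compartment model of a nucleocytoplasmic shuttling protein with
#' sequestered sub-populations. Free molecules exchange with import rate
#' `k_in` (cytoplasm to nucleus) and export rate `k_out`; a fraction `f_ns` of
#' nuclear molecules and `f_cs` of cytoplasmic molecules are sequestered —
#' mobile within their compartment but unable to cross on the recovery
#' timescale. Production and degradation are slow compared to shuttling, so
#' recovery after bleaching comes only from redistribution of unbleached
#' molecules.
#'
#' The pre-bleach free pools are at kinetic steady state,
#' `k_in * C_free = k_out * N_free`, which fixes the pre-bleach
#' nuclear:cytoplasmic intensity ratio:
#' \deqn{R = \frac{k_{in} (1 - f_{cs})}{k_{out} (1 - f_{ns})}.}
#' Compartments are book-kept in intensity units with the effective volume
#' ratio folded into R; cytoplasmic intensity is normalized to 1.
#'
#' `k_in` is fixed at 0.04/min by convention throughout the package; all
#' export rates are relative to that convention.
#'
#' @param k_out nuclear export rate of free molecules (1/min).
#' @param f_ns fraction of nuclear molecules sequestered, in \[0, 1).
#' @param f_cs fraction of cytoplasmic molecules sequestered, in \[0, 1).
#' @param bleach_eff fraction of nuclear fluorescence destroyed at the bleach.
#' @param k_in nuclear import rate (1/min), fixed convention.
#' @return an object of class `shuttling_params` with the derived pre-bleach
#'   ratio `R`.
#' @export
shuttling_params <- function(k_out = 0.04, f_ns = 0, f_cs = 0,
                             bleach_eff = 0.8, k_in = 0.04) {
  if (k_in <= 0 || k_out <= 0) stop("k_in and k_out must be > 0")
  if (f_ns < 0 || f_ns >= 1 || f_cs < 0 || f_cs >= 1)
    stop("sequestered fractions must be in [0, 1)")
  if (bleach_eff < 0 || bleach_eff > 1)
    stop("bleach_eff must be in [0, 1]")
  R <- k_in * (1 - f_cs) / (k_out * (1 - f_ns))
  structure(list(k_in = k_in, k_out = k_out, f_ns = f_ns, f_cs = f_cs,
                 bleach_eff = bleach_eff, R = R),
            class = "shuttling_params")
}

#' Simulate a FRAP trace
#'
#' Starts from the pre-bleach steady state (nuclear intensity `R`, cytoplasmic
#' intensity 1). At `t_bleach` all nuclear fluorescent amounts — free and
#' sequestered — are multiplied by `(1 - bleach_eff)`. Afterwards only the
#' free pools exchange (linear two-compartment kinetics, solved in closed
#' form); sequestered fluorescence is immobile between compartments and there
#' is no production or degradation, so total fluorescence is conserved
#' post-bleach. Nuclear fluorescence recovers as a single exponential with
#' rate `k_in + k_out` (per minute).
#'
#' @param params a [shuttling_params()].
#' @param duration trace length (seconds); must cover at least
#'   `5 / (k_in + k_out)` of recovery.
#' @param dt sampling interval (seconds).
#' @param t_bleach bleach time (seconds).
#' @param condition label (e.g. "untreated", "peak", "adapted").
#' @return object of class `frap_trace`: data.frame `t`, `I_nuc`, `I_cyt`
#'   with attributes `t_bleach`, `condition`, `params`.
#' @export
simulate_frap <- function(params, duration = NULL, dt = 5, t_bleach = 60,
                          condition = "untreated") {
  stopifnot(inherits(params, "shuttling_params"))
  p <- params
  k_min <- p$k_in + p$k_out            # 1/min
  if (is.null(duration)) duration <- t_bleach + 60 * 5 / k_min
  if ((duration - t_bleach) * k_min / 60 < 5)
    stop("duration must cover >= 5 / (k_in + k_out) after the bleach")
  t <- seq(0, duration, by = dt)
  R <- p$R
  N_seq <- p$f_ns * R; N_free0 <- (1 - p$f_ns) * R
  C_seq <- p$f_cs;     C_free0 <- 1 - p$f_cs
  b <- p$bleach_eff
  # post-bleach free pools: total free T redistributes with nuclear share
  # k_in / (k_in + k_out); relaxation rate k_in + k_out
  Tfree <- (1 - b) * N_free0 + C_free0
  N_inf <- Tfree * p$k_in / k_min
  k_s <- k_min / 60                    # 1/s
  post <- t >= t_bleach
  N_free <- ifelse(post,
                   N_inf + ((1 - b) * N_free0 - N_inf) *
                     exp(-k_s * (t - t_bleach)),
                   N_free0)
  I_nuc <- ifelse(post, (1 - b) * N_seq, N_seq) + N_free
  I_cyt <- C_seq + ifelse(post, Tfree - N_free, C_free0)
  structure(data.frame(t = t, I_nuc = I_nuc, I_cyt = I_cyt),
            t_bleach = t_bleach, condition = condition, params = unclass(p),
            class = c("frap_trace", "data.frame"))
}

#' Fit an exponential recovery to a FRAP trace
#'
#' Least-squares fit of `I_nuc(t) = I_inf - A * exp(-k * (t - t_bleach))` on
#' the post-bleach samples, after normalizing intensities by the pre-bleach
#' cytoplasmic mean (so `A` and `I_inf` are in units of pre-bleach cytoplasmic
#' intensity). Also reads out:
#' * `R`: pre-bleach nuclear:cytoplasmic mean ratio;
#' * `R_prime`: ratio over the final 10% of the trace (robust empirical
#'   plateau readout; the difference from the fitted-plateau ratio is logged
#'   in `diag_R_prime_fit`);
#' * `bleach_depth`: `1 - (I_inf - A) / R`, the fitted fractional drop of
#'   nuclear intensity at the bleach.
#'
#' Fits with non-positive rate or relative SE(k) above 100% are flagged
#' `"fit failure"`; traces with no detectable intensity drop are flagged
#' `"no bleach detected"`. Flagged records are excluded downstream.
#'
#' @param trace a [simulate_frap()] trace or data.frame with `t`, `I_nuc`,
#'   `I_cyt` plus a `t_bleach` attribute (or explicit argument).
#' @param t_bleach bleach time (seconds) if not carried by the trace.
#' @return list of class `frap_fit`: `A`, `k` (1/min), `I_inf`, `R`,
#'   `R_prime`, `bleach_depth`, standard errors `se_A`, `se_k`, `se_R`,
#'   `se_bleach`, `flag`, `condition`.
#' @export
fit_recovery <- function(trace, t_bleach = attr(trace, "t_bleach")) {
  stopifnot(is.data.frame(trace), all(c("t", "I_nuc", "I_cyt") %in% names(trace)))
  if (is.null(t_bleach)) stop("t_bleach must be supplied or carried by trace")
  pre <- trace$t < t_bleach
  post <- !pre
  if (sum(post) < 10)
    stop("need >= 10 post-bleach samples to fit a recovery")
  C_pre <- mean(trace$I_cyt[pre])
  ratio_pre <- trace$I_nuc[pre] / trace$I_cyt[pre]
  R <- mean(ratio_pre)
  se_R <- stats::sd(ratio_pre) / sqrt(sum(pre))
  y <- trace$I_nuc[post] / C_pre
  tt <- trace$t[post] - min(trace$t[post])
  n_tail <- max(ceiling(0.1 * nrow(trace)), 2L)
  tail_idx <- seq.int(nrow(trace) - n_tail + 1L, nrow(trace))
  R_prime <- mean(trace$I_nuc[tail_idx] / trace$I_cyt[tail_idx])

  res <- list(A = NA_real_, k = NA_real_, I_inf = NA_real_, R = R,
              R_prime = R_prime, bleach_depth = NA_real_,
              se_A = NA_real_, se_k = NA_real_, se_R = se_R,
              se_bleach = NA_real_, diag_R_prime_fit = NA_real_,
              flag = "ok", condition = attr(trace, "condition"))

  drop0 <- R - y[1]
  noise <- stats::sd(y - stats::filter(y, rep(1 / 5, 5), sides = 2),
                     na.rm = TRUE)
  if (!is.finite(drop0) || drop0 <= max(3 * noise, 1e-9)) {
    res$flag <- "no bleach detected"
    res$A <- 0
    return(structure(res, class = "frap_fit"))
  }

  I_inf0 <- mean(y[seq.int(max(1, length(y) - 9), length(y))])
  A0 <- max(I_inf0 - y[1], 1e-6)
  half <- which(y >= I_inf0 - A0 / 2)[1]
  k0 <- log(2) / max(tt[half], diff(range(tt)) / 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I_inf - A * exp(-k * tt),
                      start = list(I_inf = I_inf0, A = A0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res$flag <- "fit failure"
    return(structure(res, class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, 3), names(cf)))
  res$A <- unname(cf["A"]); res$I_inf <- unname(cf["I_inf"])
  res$k <- unname(cf["k"]) * 60                 # 1/s -> 1/min
  res$se_A <- unname(se["A"]); res$se_k <- unname(se["k"]) * 60
  res$bleach_depth <- 1 - (res$I_inf - res$A) / R
  # first-order SE of the bleach depth from fit SEs and var(R)
  res$se_bleach <- sqrt(((se["I_inf"]^2 + se["A"]^2) / R^2) +
                          ((res$I_inf - res$A)^2 / R^4) * se_R^2)
  res$se_bleach <- unname(res$se_bleach)
  I_cyt_inf <- mean(trace$I_cyt[tail_idx]) / C_pre
  res$diag_R_prime_fit <- res$I_inf / I_cyt_inf - R_prime
  if (!is.finite(res$k) || res$k <= 0 ||
      (is.finite(res$se_k) && res$se_k / res$k > 1))
    res$flag <- "fit failure"
  structure(res, class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "frap fit [%s]: A=%.4g (se %.2g), k=%.4g/min (se %.2g), R=%.3g, R'=%.3g\n",
    x$flag, x$A, x$se_A, x$k, x$se_k, x$R, x$R_prime))
  invisible(x)
}

# closed-form inversion of the sequestration model from condition-level
# measured quantities: recovery amplitude A (units of pre-bleach cytoplasmic
# intensity), recovery rate k (1/min), pre-bleach ratio R, bleach depth b.
# Derived from the forward model:
#   A = (1 - f_ns) R k_out b / k  =>  f_ns = 1 - A k / (R k_out b)
#   steady state k_in (1 - f_cs) = k_out (1 - f_ns) R
invert_sequestration <- function(A, k, R, b, k_in) {
  k_out <- unname(k - k_in)
  f_ns <- unname(1 - A * k / (R * k_out * b))
  f_cs <- unname(1 - (k_out / k_in) * (1 - f_ns) * R)
  c(f_ns = f_ns, f_cs = f_cs, k_out = k_out)
}

#' Infer sequestration fractions and export rate from FRAP fits
#'
#' Maps per-condition means of the measured quantities (recovery amplitude
#' `A`, recovery rate `k`, pre-bleach ratio `R` and bleach depth) through the
#' closed-form inversion of the sequestration model to estimates of the
#' nuclear and cytoplasmic sequestered fractions and the nuclear export rate.
#' The import rate is fixed by convention (`k_in = 0.04`/min), so export
#' rates directly reflect the measured exchange rates `k = k_in + k_out`.
#' Standard errors of the means are propagated to first order (delta method,
#' numerical gradient, independence across the measured quantities).
#'
#' Flagged fits (`"fit failure"`, `"no bleach detected"`) are excluded with a
#' message. Estimates outside `[0, 1]` are clipped and flagged `"boundary"`.
#'
#' @param fits list of [fit_recovery()] results (one per cell), or a list of
#'   such lists keyed by condition.
#' @param k_in fixed nuclear import rate (1/min).
#' @return for a single condition, a list of class `sequestration_estimate`
#'   with `f_ns_hat`, `f_cs_hat`, `k_out_hat`, their SEs, `n_cells`,
#'   `n_excluded` and `flag`; for multiple conditions, a named list of these.
#' @export
infer_sequestration <- function(fits, k_in = 0.04) {
  if (length(fits) > 0 && !inherits(fits[[1]], "frap_fit"))
    return(lapply(fits, infer_sequestration, k_in = k_in))
  ok <- vapply(fits, function(f) identical(f$flag, "ok"), logical(1))
  n_exc <- sum(!ok)
  if (n_exc > 0)
    message(n_exc, " flagged fit(s) excluded from sequestration inference")
  fits <- fits[ok]
  if (length(fits) < 3) stop("need >= 3 usable fits per condition")
  grab <- function(fld) vapply(fits, `[[`, numeric(1), fld)
  m <- c(A = mean(grab("A")), k = mean(grab("k")), R = mean(grab("R")),
         b = mean(grab("bleach_depth")))
  se <- c(A = stats::sd(grab("A")), k = stats::sd(grab("k")),
          R = stats::sd(grab("R")), b = stats::sd(grab("bleach_depth"))) /
    sqrt(length(fits))
  if (m["k"] <= k_in)
    stop("mean recovery rate below the fixed import rate; cannot invert")
  est <- invert_sequestration(m["A"], m["k"], m["R"], m["b"], k_in)
  # delta method with numerical gradients, no covariance terms
  grad <- matrix(0, 3, 4, dimnames = list(names(est), names(m)))
  for (j in seq_along(m)) {
    h <- max(abs(m[j]), 1e-3) * 1e-6
    mp <- m; mp[j] <- mp[j] + h
    grad[, j] <- (invert_sequestration(mp["A"], mp["k"], mp["R"], mp["b"],
                                       k_in) - est) / h
  }
  se_est <- sqrt((grad^2) %*% (se^2))[, 1]
  flag <- "ok"
  for (f in c("f_ns", "f_cs")) {
    if (est[f] < 0 || est[f] > 1) {
      est[f] <- min(max(est[f], 0), 1)
      flag <- "boundary"
      warning("inferred ", f, " outside [0, 1]; clipped", call. = FALSE)
    }
  }
  structure(list(f_ns_hat = unname(est["f_ns"]), f_cs_hat = unname(est["f_cs"]),
                 k_out_hat = unname(est["k_out"]),
                 se_f_ns = unname(se_est["f_ns"]),
                 se_f_cs = unname(se_est["f_cs"]),
                 se_k_out = unname(se_est["k_out"]),
                 n_cells = length(fits), n_excluded = n_exc, flag = flag,
                 k_in = k_in),
            class = "sequestration_estimate")
}

#' @export
print.sequestration_estimate <- function(x, ...) {
  cat(sprintf(
    "sequestration estimate (n=%d, %s): f_ns=%.3f+/-%.3f f_cs=%.3f+/-%.3f k_out=%.4f+/-%.4f /min\n",
    x$n_cells, x$flag, x$f_ns_hat, x$se_f_ns, x$f_cs_hat, x$se_f_cs,
    x$k_out_hat, x$se_k_out))
  invisible(x)
}
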