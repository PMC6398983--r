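#!/usr/bin/env Rscript

# Calibration of the negative-feedback model defaults shipped in
# feedback_params() / smad23_params(). Run only to re-derive them; the
# package's defaults are frozen copies of this script's output.
#
# Structural choices fixed first:
#   gamma = 6 /hr  : signal relaxation; sets the rise
#   delta = 0.85/hr: inhibitor decay; sets both the adaptation timescale and
#                    the refractory recovery, and must be fast enough that a
#                    second saturating pulse 5 hr after the first recovers
#                    >= 85% of the peak
#   K_L  = 20 ng/ml: half-saturating dose, large enough that hourly staircase
#                    increments are sensed sub-saturatingly (ramp responses
#                    strongly attenuated relative to steps)
#   K_I = 1, S0 = 1
# Then (alpha, beta) are solved by Newton iteration so a 50 ng/ml step over a
# 12 hr window yields peak excess 1.0 ratio units with a late plateau at 20%
# of it, and the SMAD2/3 variant's K_I is solved so the same protocol yields
# a 60% plateau.

suppressPackageStartupMessages(library(smaddyn))

grid <- seq(0, 12, by = 0.01)
sched <- make_step(50, t_off = 12)

measure <- function(p) {
  m <- adaptation_metrics(simulate_feedback(p, sched, grid, rtol = 1e-8))
  c(bf = m$baseline_fraction, peak = m$peak)
}

resid <- function(x) {
  p <- feedback_params(alpha = x[1], beta = x[2])
  m <- measure(p)
  c(m[["bf"]] - 0.20, m[["peak"]] - 1.0)
}

x <- c(100, 250)
for (i in 1:40) {
  r0 <- resid(x)
  if (max(abs(r0)) < 1e-12) break
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    xp <- x; xp[j] <- xp[j] * (1 + 1e-6)
    J[, j] <- (resid(xp) - r0) / (x[j] * 1e-6)
  }
  x <- x - solve(J, r0)
}
cat(sprintf("alpha = %.10f\nbeta  = %.10f\n", x[1], x[2]))
cat("residuals:", resid(x), "\n")

bf23 <- function(KI) {
  p <- feedback_params(alpha = x[1], beta = x[2], K_I = KI)
  measure(p)[["bf"]] - 0.60
}
KI23 <- uniroot(bf23, c(1.01, 5000), tol = 1e-12)$root
cat(sprintf("SMAD2/3 K_I = %.10f\n", KI23))

# verification against the shipped defaults
cat("\nshipped defaults reproduce the calibration:\n")
cat("  SMAD4 baseline fraction:", measure(feedback_params())[["bf"]], "\n")
cat("  SMAD2/3 baseline fraction:", measure(smad23_params())[["bf"]], "\n")
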