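# Experiment drivers reproducing the in-silico analyses end to end. Each
# driver is deterministic given its seed, returns a structured report, and
# optionally writes CSV/JSON outputs (with the spec and seed embedded) into
# `out_dir`.

write_report <- function(report, out_dir, name) {
  if (is.null(out_dir)) return(invisible(report))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.data.frame(x))
      utils::write.csv(x, file.path(out_dir, paste0(name, "_", nm, ".csv")),
                       row.names = FALSE)
  }
  scalars <- report[!vapply(report, is.data.frame, logical(1))]
  jsonlite::write_json(scalars, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Step versus staircase-ramp comparison
#'
#' Simulates a sudden step and a staircase ramp to the same final dose for
#' the negative-feedback (Activin-like) and ligand-depletion (BMP-like)
#' models and reports the peak-excess ratio (ramp/step) and late-time ratio
#' per model. Rate-sensing shows up as a low peak ratio for the adaptive
#' model; concentration-sensing as a late-time ratio near 1 for the depletion
#' model.
#'
#' @param final_dose ng/ml; @param ramp_duration hours; @param n_steps stairs.
#' @param window total simulated hours.
#' @param out_dir optional output directory.
#' @return list with per-model peak/late ratios and the trajectories.
#' @export
run_step_vs_ramp <- function(final_dose = 30, ramp_duration = 10,
                             n_steps = 10, window = 24, out_dir = NULL) {
  grid <- seq(0, window, by = 0.01)
  step <- make_step(final_dose, t_off = window)
  ramp <- make_ramp(final_dose, ramp_duration, n_steps, hold_until = window)
  # compare late-time signal over the two hours after the ramp completes,
  # when both conditions have reached the same dose
  late <- function(traj) mean(traj$S[traj$t >= ramp_duration &
                                       traj$t <= ramp_duration + 2])
  fb <- feedback_params(); dp <- depletion_params()
  fb_step <- simulate_feedback(fb, step, grid)
  fb_ramp <- simulate_feedback(fb, ramp, grid)
  dp_step <- simulate_ligand_depletion(dp, step, grid)
  dp_ramp <- simulate_ligand_depletion(dp, ramp, grid)
  pk <- function(traj) max(traj$S) - attr(traj, "S0")
  report <- list(
    spec = list(final_dose = final_dose, ramp_duration = ramp_duration,
                n_steps = n_steps, window = window),
    feedback_peak_ratio = pk(fb_ramp) / pk(fb_step),
    feedback_late_ratio = (late(fb_ramp) - fb$S0) / (late(fb_step) - fb$S0),
    depletion_peak_ratio = pk(dp_ramp) / pk(dp_step),
    depletion_late_ratio = (late(dp_ramp) - dp$S0) / (late(dp_step) - dp$S0),
    trajectories = data.frame(
      t = rep(grid, 4),
      S = c(fb_step$S, fb_ramp$S, dp_step$S, dp_ramp$S),
      model = rep(c("feedback", "feedback", "depletion", "depletion"),
                  each = length(grid)),
      schedule = rep(c("step", "ramp", "step", "ramp"), each = length(grid))))
  write_report(report, out_dir, "step_vs_ramp")
}

#' Dose-response series with adaptation metrics and target-gene output
#'
#' Simulates the feedback model across a dose series, reports per-dose
#' adaptation metrics, and integrates a sustained-class target gene (whose
#' terminal level tracks the dose-dependent maintained baseline) and an
#' adaptive-class gene (peak-responsive).
#'
#' @param doses ng/ml.
#' @param window hours.
#' @param out_dir optional output directory.
#' @return list with the dose table.
#' @export
run_dose_response <- function(doses = c(1, 2.5, 5, 10, 25, 50),
                              window = 12, out_dir = NULL) {
  grid <- seq(0, window, by = 0.01)
  fb <- feedback_params()
  rows <- lapply(doses, function(d) {
    traj <- simulate_feedback(fb, make_step(d, t_off = window), grid)
    m <- adaptation_metrics(traj)
    sus <- simulate_target_gene(gene_params("sustained"), traj)
    ada <- simulate_target_gene(gene_params("adaptive"), traj)
    data.frame(dose = d, peak = m$peak, peak_time = m$peak_time,
               baseline_fraction = m$baseline_fraction,
               adaptation_timescale = m$adaptation_timescale,
               class = m$class,
               sustained_gene_terminal = sus$m[nrow(sus)],
               adaptive_gene_peak = max(ada$m))
  })
  tab <- do.call(rbind, rows)
  ts <- tab$adaptation_timescale[is.finite(tab$adaptation_timescale)]
  report <- list(spec = list(doses = doses, window = window),
                 dose_table = tab,
                 peak_monotone = !is.unsorted(tab$peak),
                 timescale_cv = stats::sd(ts) / mean(ts),
                 gene_monotone = !is.unsorted(tab$sustained_gene_terminal))
  write_report(report, out_dir, "dose_response")
}

#' Pulse-train protocol versus sustained and no-ligand controls
#'
#' The three-pulse Activin protocol (6, 10 and 8 hr pulses at 30 ng/ml with
#' 5 hr gaps), a sustained 30 ng/ml condition and a no-ligand condition with
#' media changes at the same times (modeled as schedule breakpoints with no
#' concentration change). Reports per-pulse peak excesses, integrated
#' adaptive-gene output per condition, and integrated ligand exposure.
#'
#' @param high ng/ml during pulses.
#' @param pulse_durations,gap hours.
#' @param out_dir optional output directory.
#' @return list report.
#' @export
run_pulse_train <- function(high = 30, pulse_durations = c(6, 10, 8),
                            gap = 5, out_dir = NULL) {
  total <- sum(pulse_durations) + gap * (length(pulse_durations) - 1)
  grid <- seq(0, total, by = 0.01)
  fb <- feedback_params()
  pulses <- make_pulse_train(high, 0, pulse_durations, gap)
  sustained <- make_step(high, t_off = total, name = "sustained")
  none <- ligand_schedule(data.frame(t_start = 0, t_end = total, c_start = 0,
                                     c_end = 0, interpolation = "constant"),
                          name = "no_ligand")
  tr_p <- simulate_feedback(fb, pulses, grid)
  tr_s <- simulate_feedback(fb, sustained, grid)
  tr_0 <- simulate_feedback(fb, none, grid)
  seg <- pulses$segments
  on <- seg[seg$c_start > 0, ]
  peak_in <- function(traj, a, b) {
    w <- traj$t >= a & traj$t <= b
    max(traj$S[w]) - attr(traj, "S0")
  }
  pulse_peaks <- mapply(peak_in, a = on$t_start, b = on$t_end,
                        MoreArgs = list(traj = tr_p))
  # count distinct response peaks in the sustained condition: local maxima of
  # the excess above half the global peak
  n_peaks <- function(traj) {
    exc <- traj$S - attr(traj, "S0")
    big <- exc > max(exc) / 2
    sum(diff(c(FALSE, big)) == 1)
  }
  gene <- gene_params("adaptive")
  auc <- function(traj) {
    m <- simulate_target_gene(gene, traj)
    sum(diff(m$t) * (utils::head(m$m, -1) + utils::tail(m$m, -1)) / 2)
  }
  report <- list(
    spec = list(high = high, pulse_durations = pulse_durations, gap = gap),
    pulse_peaks = data.frame(pulse = seq_along(pulse_peaks),
                             peak_excess = as.numeric(pulse_peaks)),
    sustained_n_peaks = n_peaks(tr_s),
    pulses_n_peaks = n_peaks(tr_p),
    no_ligand_max_excess = max(tr_0$S) - fb$S0,
    gene_auc_pulses = auc(tr_p),
    gene_auc_sustained = auc(tr_s),
    ligand_exposure_pulses = integrate_schedule(pulses),
    ligand_exposure_sustained = integrate_schedule(sustained))
  write_report(report, out_dir, "pulse_train")
}

# programmed shuttling parameters for the three FRAP conditions; the peak
# state has slower export and less cytoplasmic sequestration than untreated,
# the adapted state keeps the slow export (kinetics are not restored) but has
# lower nuclear and higher cytoplasmic sequestration than the peak state
frap_condition_params <- function() {
  list(untreated = shuttling_params(k_out = 0.06, f_ns = 0.20, f_cs = 0.30),
       peak = shuttling_params(k_out = 0.025, f_ns = 0.20, f_cs = 0.15),
       adapted = shuttling_params(k_out = 0.025, f_ns = 0.05, f_cs = 0.45))
}

#' FRAP condition comparison (untreated / peak / adapted)
#'
#' Generates FRAP ensembles for the three conditions with programmed
#' parameter shifts, fits every recovery, runs the sequestration inference,
#' and reports the estimates alongside the sidecar truth.
#'
#' @param n_cells cells per condition.
#' @param seed RNG seed.
#' @param conditions named list of [shuttling_params()] (defaults to the
#'   programmed shifts).
#' @param out_dir optional output directory.
#' @return list with `estimates`, `truth`, `rates` and the fit table.
#' @export
run_frap_conditions <- function(n_cells = 20, seed = 1,
                                conditions = frap_condition_params(),
                                out_dir = NULL) {
  ests <- list(); truths <- list(); fit_rows <- list()
  for (i in seq_along(conditions)) {
    nm <- names(conditions)[i]
    ens <- generate_frap_ensemble(conditions[[nm]], n_cells = n_cells,
                                  seed = seed + i, condition = nm)
    fits <- lapply(ens$traces, fit_recovery)
    ests[[nm]] <- infer_sequestration(fits)
    truths[[nm]] <- ens$truth
    fit_rows[[nm]] <- data.frame(
      condition = nm,
      A = vapply(fits, `[[`, numeric(1), "A"),
      k = vapply(fits, `[[`, numeric(1), "k"),
      R = vapply(fits, `[[`, numeric(1), "R"),
      R_prime = vapply(fits, `[[`, numeric(1), "R_prime"),
      flag = vapply(fits, `[[`, character(1), "flag"))
  }
  est_tab <- do.call(rbind, lapply(names(ests), function(nm) {
    e <- ests[[nm]]
    data.frame(condition = nm, f_ns = e$f_ns_hat, se_f_ns = e$se_f_ns,
               f_cs = e$f_cs_hat, se_f_cs = e$se_f_cs,
               k_out = e$k_out_hat, se_k_out = e$se_k_out,
               n_cells = e$n_cells)
  }))
  rates <- vapply(fit_rows, function(d) mean(d$k[d$flag == "ok"]), numeric(1))
  report <- list(spec = list(n_cells = n_cells, seed = seed),
                 estimates = est_tab,
                 mean_recovery_rate = as.list(rates),
                 truth = do.call(rbind, lapply(names(truths), function(nm)
                   data.frame(condition = nm,
                              k_out = truths[[nm]]$mean_k_out,
                              f_ns = truths[[nm]]$mean_f_ns,
                              f_cs = truths[[nm]]$mean_f_cs))),
                 fits = do.call(rbind, fit_rows))
  report$estimates_obj <- ests
  write_report(report[names(report) != "estimates_obj"], out_dir,
               "frap_conditions")
  report
}

#' Colony wave analysis: kymographs, normalization, front tracking
#'
#' Generates the synthetic colony, normalizes each channel by its convention
#' (minmax for SMAD4 tracking and SMAD2/3 and pSMAD1; the pSMAD1-anchored
#' rule for SMAD4 display; BRA already bra_rule-normalized at export), tracks
#' the half-maximum fronts, and reports wave velocity, onset, the edge
#' restriction time, pSMAD1 front stationarity, and the BRA domain boundary
#' relative to the SMAD2/3 front. Front tracking starts at the edge
#' restriction time: before the pattern is edge-restricted the colony
#' responds uniformly and a half-maximum front is not defined.
#'
#' With `render = TRUE` the same analysis is additionally run through the
#' full imaging pipeline: rendered frames, watershed segmentation, per-cell
#' measurement, radial profiles, kymograph assembly.
#'
#' @param params a [colony_params()].
#' @param seed RNG seed.
#' @param render also run the rendered-image closure.
#' @param frames_t frame times for the rendered path (hours).
#' @param n_cells,img_px rendered-colony geometry.
#' @param out_dir optional output directory.
#' @return list report (see fields in the description); rendered-path results
#'   under `$rendered`.
#' @export
run_colony_wave <- function(params = colony_params(), seed = 1,
                            render = FALSE, frames_t = seq(0.5, 40, by = 1),
                            n_cells = 330, img_px = 256, out_dir = NULL) {
  colony <- generate_colony(params, seed = seed)
  kyms <- colony$kymographs
  t_min <- params$edge_restriction_time
  trim <- function(kym) kymograph(kym$matrix[kym$t >= t_min, , drop = FALSE],
                                  kym$r_centers, kym$t[kym$t >= t_min],
                                  channel = kym$channel,
                                  normalization = kym$normalization)
  norm_track <- function(ch) track_front(
    suppressWarnings(normalize_channel(trim(kyms[[ch]]), "minmax")))
  ft_smad4 <- norm_track("SMAD4")
  ft_psmad1 <- norm_track("pSMAD1")
  ft_smad23 <- norm_track("SMAD2/3")
  smad4_disp <- suppressWarnings(
    normalize_channel(trim(kyms[["SMAD4"]]), "smad4_rule",
                      auxiliary = trim(kyms[["pSMAD1"]])))
  restr <- edge_restriction_time(kyms[["SMAD4"]],
                                 edge_band_width = params$edge_band_width,
                                 wave_onset = params$wave_onset)
  bin <- params$bin_width
  ps_track <- ft_psmad1$track
  ps_move <- diff(range(ps_track$r_half[ps_track$t >= params$wave_onset &
                                          !is.na(ps_track$r_half)]))
  t_last <- max(kyms[["BRA"]]$t)
  bra_prof <- structure(
    data.frame(r_center = kyms[["BRA"]]$r_centers,
               value = kyms[["BRA"]]$matrix[length(kyms[["BRA"]]$t), ]),
    class = c("radial_profile", "data.frame"))
  bra_dom <- expression_domain(bra_prof, 0.20)
  s23_final <- ft_smad23$track$r_half[ft_smad23$track$t == t_last]
  report <- list(
    spec = list(seed = seed, render = render),
    velocity = ft_smad4$velocity,
    onset = ft_smad4$onset,
    edge_restriction = restr,
    psmad1_front_movement = ps_move,
    psmad1_stationary = is.finite(ps_move) && ps_move < 2 * bin,
    bra_inner_boundary = bra_dom$inner_boundary,
    smad23_final_front = if (length(s23_final)) s23_final else NA_real_,
    truth = colony$truth[c("wave_onset", "wave_velocity",
                           "edge_restriction_time")],
    track = ft_smad4$track)
  if (render) {
    rend <- colony_renderer(params, n_cells = n_cells, img_px = img_px,
                            seed = seed + 1000)
    profs <- vector("list", length(frames_t))
    for (i in seq_along(frames_t)) {
      fr <- rend$frame(frames_t[i], seed = seed + 2000 + i)
      img <- segment_fixture(fr$channels, pixel_size = rend$pixel_size,
                             ring_width = 2)
      cells <- measure_cells(img, channel = "signal")
      profs[[i]] <- radial_profile(cells, center = rend$center_um,
                                   bin_width = params$bin_width,
                                   r_max = params$colony_diameter / 2)
    }
    kym_r <- as_kymograph(profs, frames_t, channel = "SMAD4")
    keep <- kym_r$t >= t_min
    kym_rt <- kymograph(kym_r$matrix[keep, , drop = FALSE], kym_r$r_centers,
                        kym_r$t[keep], channel = "SMAD4")
    ft_r <- track_front(suppressWarnings(normalize_channel(kym_rt, "minmax")))
    report$rendered <- list(
      velocity = ft_r$velocity, onset = ft_r$onset,
      edge_restriction = edge_restriction_time(
        kym_r, edge_band_width = params$edge_band_width,
        wave_onset = params$wave_onset),
      n_frames = length(frames_t), img_px = img_px)
  }
  write_report(report, out_dir, "colony_wave")
  report
}
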