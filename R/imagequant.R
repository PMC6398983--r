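#' Bundle intensity channels with segmentation masks
#'
#' @param intensity a matrix, or named list of matrices (channels), all the
#'   same dimension.
#' @param nuclear_labels integer matrix of nuclear labels (0 = background).
#' @param cyto_labels integer matrix of cytoplasm labels matched to the
#'   nuclear label set.
#' @param background_mask logical matrix marking background pixels.
#' @param pixel_size micrometres per pixel.
#' @return object of class `labeled_image`.
#' @export
labeled_image <- function(intensity, nuclear_labels, cyto_labels,
                          background_mask, pixel_size = 1) {
  if (is.matrix(intensity)) intensity <- list(signal = intensity)
  d <- dim(intensity[[1]])
  ok <- vapply(intensity, function(m) identical(dim(m), d), logical(1))
  if (!all(ok) || !identical(dim(nuclear_labels), d) ||
      !identical(dim(cyto_labels), d) || !identical(dim(background_mask), d))
    stop("all channels and masks must share the same dimensions")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  nl <- sort(unique(nuclear_labels[nuclear_labels > 0]))
  cl <- sort(unique(cyto_labels[cyto_labels > 0]))
  if (!setequal(nl, cl))
    stop("nuclear and cytoplasm label sets disagree")
  if (any(nuclear_labels > 0 & cyto_labels > 0) ||
      any((nuclear_labels > 0 | cyto_labels > 0) & background_mask))
    stop("masks must be mutually exclusive per pixel")
  structure(list(intensity = intensity, nuclear_labels = nuclear_labels,
                 cyto_labels = cyto_labels, background_mask = background_mask,
                 pixel_size = pixel_size),
            class = "labeled_image")
}

#' Per-cell background-subtracted intensity measurements
#'
#' For each cell, the mean intensity over its nuclear and cytoplasmic masks
#' and the mean over the background mask give the signaling readout
#' `nc_ratio = (nuc_mean - bg_mean) / (cyt_mean - bg_mean)`. Cells whose
#' background-subtracted cytoplasmic mean is not positive cannot yield a
#' ratio; they are excluded with a logged count. If a `dapi` channel is
#' present, `nuc_norm = nuc_mean / dapi_mean` is added for nuclear-only
#' markers (DAPI-normalized nuclear intensity).
#'
#' @param img a [labeled_image()].
#' @param channel which intensity channel to measure.
#' @return data.frame with one row per retained cell: `cell_id`, `nuc_mean`,
#'   `cyt_mean`, `bg_mean`, `nc_ratio`, centroid `x`, `y` (micrometres) and
#'   optionally `nuc_norm`; the number of excluded cells is attached as
#'   attribute `n_excluded`.
#' @export
measure_cells <- function(img, channel = 1) {
  stopifnot(inherits(img, "labeled_image"))
  inten <- img$intensity[[channel]]
  if (is.null(inten)) stop("channel not found")
  if (!any(img$background_mask)) stop("background mask is empty")
  if (!any(img$nuclear_labels > 0)) stop("nuclear mask is empty")
  if (!any(img$cyto_labels > 0)) stop("cytoplasm mask is empty")
  bg <- mean(inten[img$background_mask])
  nuc_sel <- img$nuclear_labels > 0
  cyt_sel <- img$cyto_labels > 0
  nuc <- tapply(inten[nuc_sel], img$nuclear_labels[nuc_sel], mean)
  cyt <- tapply(inten[cyt_sel], img$cyto_labels[cyt_sel], mean)
  ids <- as.integer(names(nuc))
  cyt <- cyt[names(nuc)]
  rows <- row(img$nuclear_labels)[nuc_sel]
  cols <- col(img$nuclear_labels)[nuc_sel]
  cx <- tapply(rows, img$nuclear_labels[nuc_sel], mean) * img$pixel_size
  cy <- tapply(cols, img$nuclear_labels[nuc_sel], mean) * img$pixel_size
  out <- data.frame(cell_id = ids,
                    nuc_mean = as.numeric(nuc), cyt_mean = as.numeric(cyt),
                    bg_mean = bg,
                    nc_ratio = (as.numeric(nuc) - bg) /
                      (as.numeric(cyt) - bg),
                    x = as.numeric(cx), y = as.numeric(cy))
  if ("dapi" %in% names(img$intensity) && !identical(channel, "dapi")) {
    dapi <- img$intensity[["dapi"]]
    dmean <- tapply(dapi[nuc_sel], img$nuclear_labels[nuc_sel], mean)
    out$nuc_norm <- out$nuc_mean / as.numeric(dmean[names(nuc)])
  }
  bad <- (out$cyt_mean - out$bg_mean) <= 0
  if (any(bad))
    message(sum(bad), " cell(s) with non-positive cytoplasmic excess excluded")
  out <- out[!bad, , drop = FALSE]
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Radial profile of per-cell measurements around a colony center
#'
#' Cells are binned by distance from the center into contiguous annuli of
#' width `bin_width`; the profile is the per-annulus mean of `value_col`.
#' Empty annuli carry `NA`, never zero.
#'
#' @param cells data.frame from [measure_cells()] (needs `x`, `y` and the
#'   value column).
#' @param center colony center `c(x, y)` in micrometres.
#' @param bin_width annulus width (micrometres), 20 by default.
#' @param r_max outer radius; defaults to the furthest cell.
#' @param value_col measurement column (default `nc_ratio`).
#' @return object of class `radial_profile`: data.frame `r_center`, `value`,
#'   `n_cells`.
#' @export
radial_profile <- function(cells, center, bin_width = 20, r_max = NULL,
                           value_col = "nc_ratio") {
  stopifnot(all(c("x", "y", value_col) %in% names(cells)))
  r <- sqrt((cells$x - center[1])^2 + (cells$y - center[2])^2)
  if (is.null(r_max)) r_max <- max(r)
  edges <- seq(0, r_max + bin_width, by = bin_width)
  idx <- findInterval(r, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  val <- rep(NA_real_, nb); n <- integer(nb)
  agg <- tapply(cells[[value_col]], idx, mean)
  cnt <- table(idx)
  val[as.integer(names(agg))] <- as.numeric(agg)
  n[as.integer(names(cnt))] <- as.integer(cnt)
  structure(data.frame(r_center = edges[-length(edges)] + bin_width / 2,
                       value = val, n_cells = n),
            bin_width = bin_width, class = c("radial_profile", "data.frame"))
}

#' Assemble a kymograph from radial profiles over time
#'
#' @param profiles list of [radial_profile()]s sharing bin centers.
#' @param t times (hours), one per profile.
#' @param channel label.
#' @return object of class `kymograph`: list with `t`, `r_centers`, `matrix`
#'   (`value[t, r]`), `channel`, `normalization`.
#' @export
as_kymograph <- function(profiles, t, channel = "SMAD4") {
  stopifnot(length(profiles) == length(t))
  r <- profiles[[1]]$r_center
  mat <- do.call(rbind, lapply(profiles, function(p) {
    stopifnot(isTRUE(all.equal(p$r_center, r)))
    p$value
  }))
  kymograph(mat, r, t, channel = channel)
}

#' Kymograph container
#'
#' @param mat matrix `value[t, r]`.
#' @param r_centers radial bin centers (micrometres).
#' @param t times (hours).
#' @param channel label.
#' @param normalization one of "raw", "minmax", "smad4_rule", "bra_rule".
#' @return object of class `kymograph`.
#' @export
kymograph <- function(mat, r_centers, t, channel = "SMAD4",
                      normalization = "raw") {
  if (!identical(dim(mat), c(length(t), length(r_centers))))
    stop("matrix must be length(t) x length(r_centers)")
  structure(list(t = t, r_centers = r_centers, matrix = mat,
                 channel = channel, normalization = normalization),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph [%s, %s]: %d times x %d radial bins, r up to %g um\n",
              x$channel, x$normalization, length(x$t), length(x$r_centers),
              max(x$r_centers)))
  invisible(x)
}

# innermost level-crossing of one radial profile row, moving inward from the
# colony edge; linear interpolation between bin centers; NA when no crossing
innermost_crossing <- function(r, v, level) {
  ok <- !is.na(v)
  r <- r[ok]; v <- v[ok]
  if (length(r) < 2) return(NA_real_)
  s <- v - level
  cross <- which(s[-length(s)] * s[-1] <= 0 & (s[-length(s)] != 0 | s[-1] != 0))
  if (length(cross) == 0) return(NA_real_)
  i <- cross[1]  # bins ordered by increasing r, so first crossing is innermost
  r[i] + (level - v[i]) * (r[i + 1] - r[i]) / (v[i + 1] - v[i])
}

#' Normalize a kymograph channel
#'
#' Three conventions are supported, mirroring how the different readouts are
#' scaled for display and front tracking:
#' * `minmax`: each time row is scaled to have its lowest level 0 and highest
#'   1 (used for SMAD1/pSMAD1 and SMAD2/3, whose extreme levels are similar at
#'   each time while their spatial distribution varies). Idempotent; a
#'   constant row is set to 0 with a warning.
#' * `smad4_rule`: each row is shifted by its minimum and scaled so the
#'   maximum over all positions interior to the most interior half-maximum of
#'   the auxiliary pSMAD1 kymograph (at that time) equals 1 — that position
#'   reflects the peak of Nodal-dependent SMAD4 signaling.
#' * `bra_rule`: BRA levels change substantially over time, so the whole
#'   matrix is scaled to the maximum of the latest time row.
#'
#' @param kym a [kymograph()].
#' @param rule `"minmax"`, `"smad4_rule"` or `"bra_rule"`.
#' @param auxiliary the pSMAD1 [kymograph()] (required by `smad4_rule`).
#' @return a normalized [kymograph()].
#' @export
normalize_channel <- function(kym, rule = c("minmax", "smad4_rule", "bra_rule"),
                              auxiliary = NULL) {
  stopifnot(inherits(kym, "kymograph"))
  rule <- match.arg(rule)
  m <- kym$matrix
  if (rule == "minmax") {
    for (i in seq_len(nrow(m))) {
      rng <- range(m[i, ], na.rm = TRUE)
      if (diff(rng) < .Machine$double.eps * 100) {
        warning("constant kymograph row at t = ", kym$t[i], " set to 0",
                call. = FALSE)
        m[i, ] <- 0
      } else m[i, ] <- (m[i, ] - rng[1]) / diff(rng)
    }
  } else if (rule == "smad4_rule") {
    if (!inherits(auxiliary, "kymograph"))
      stop("smad4_rule requires the pSMAD1 kymograph as `auxiliary`")
    aux <- normalize_channel(auxiliary, "minmax")
    for (i in seq_len(nrow(m))) {
      r_half <- innermost_crossing(aux$r_centers, aux$matrix[i, ], 0.5)
      interior <- if (is.na(r_half)) rep(TRUE, ncol(m)) else
        kym$r_centers < r_half
      lo <- min(m[i, ], na.rm = TRUE)
      hi <- max(m[i, interior], na.rm = TRUE)
      if (!is.finite(hi) || hi - lo < .Machine$double.eps * 100) {
        warning("degenerate smad4_rule row at t = ", kym$t[i], call. = FALSE)
        m[i, ] <- 0
      } else m[i, ] <- (m[i, ] - lo) / (hi - lo)
    }
  } else { # bra_rule
    hi <- max(m[nrow(m), ], na.rm = TRUE)
    if (hi <= 0) stop("bra_rule: final time row has no positive values")
    m <- m / hi
  }
  kymograph(m, kym$r_centers, kym$t, channel = kym$channel,
            normalization = rule)
}

#' Track the half-maximum wavefront in a kymograph
#'
#' For every time row, the innermost radius where the linearly interpolated
#' profile crosses `level`, moving inward from the colony edge. The wave
#' velocity is the negated slope of a least-squares line fitted to the
#' half-maximum position over `window`; the onset time is the first time the
#' half-maximum position moves inward of the edge zone (outermost
#' `edge_zone_frac` of the radius) by more than one radial bin. Rows without a
#' crossing yield `NA` and are dropped from the velocity fit.
#'
#' @param kym a [kymograph()], normalized per row to \[0, 1\] (or give
#'   `level` in absolute units).
#' @param level crossing level (fraction of the row range for normalized
#'   kymographs).
#' @param window `c(t_start, t_end)` hours for the velocity fit.
#' @param edge_zone_frac outermost fraction of the radius treated as "at the
#'   edge" for onset detection.
#' @return object of class `front_track`: list with data.frame `track`
#'   (`t`, `r_half`), `velocity` (micrometres/hr), `onset` (hours, `NA` if the
#'   front never leaves the edge zone), `window`, `level`.
#' @export
track_front <- function(kym, level = 0.5, window = c(25, 40),
                        edge_zone_frac = 0.1) {
  stopifnot(inherits(kym, "kymograph"))
  r_half <- vapply(seq_along(kym$t), function(i)
    innermost_crossing(kym$r_centers, kym$matrix[i, ], level), numeric(1))
  track <- data.frame(t = kym$t, r_half = r_half)
  r_max <- max(kym$r_centers)
  bin <- if (length(kym$r_centers) > 1) diff(kym$r_centers[1:2]) else 0
  thresh <- (1 - edge_zone_frac) * r_max - bin
  inside <- !is.na(r_half) & r_half < thresh
  onset <- if (any(inside)) kym$t[which(inside)[1]] else NA_real_
  sel <- kym$t >= window[1] & kym$t <= window[2] & !is.na(r_half)
  velocity <- if (sum(sel) >= 2) {
    -unname(stats::coef(stats::lm(r_half[sel] ~ kym$t[sel]))[2])
  } else NA_real_
  structure(list(track = track, velocity = velocity, onset = onset,
                 window = window, level = level, channel = kym$channel),
            class = "front_track")
}

#' @export
print.front_track <- function(x, ...) {
  cat(sprintf(
    "front track [%s]: velocity %.3g um/hr over %g-%g hr, onset %.3g hr\n",
    x$channel, x$velocity, x$window[1], x$window[2], x$onset))
  invisible(x)
}

#' Expression domain of a radial profile at a fractional threshold
#'
#' Contiguous radial interval(s) where the profile is at least
#' `threshold_fraction` of its maximum (the convention used for the BRA
#' expression domain, threshold 20% of maximal expression).
#'
#' @param profile a [radial_profile()] (or data.frame with `r_center`,
#'   `value`).
#' @param threshold_fraction fraction of the profile maximum.
#' @return list with `intervals` (data.frame `r_inner`, `r_outer` in
#'   micrometres), `inner_boundary` (innermost extent of the outermost
#'   domain), and `flag` (`"ok"` or `"empty"`).
#' @export
expression_domain <- function(profile, threshold_fraction = 0.20) {
  v <- profile$value; r <- profile$r_center
  ok <- !is.na(v)
  if (!any(ok) || max(v[ok]) <= 0)
    return(list(intervals = data.frame(r_inner = numeric(0),
                                       r_outer = numeric(0)),
                inner_boundary = NA_real_, flag = "empty"))
  thr <- threshold_fraction * max(v[ok])
  above <- !is.na(v) & v >= thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  bw <- if (length(r) > 1) diff(r[1:2]) else 0
  ints <- data.frame(r_inner = pmax(r[starts[keep]] - bw / 2, 0),
                     r_outer = r[ends[keep]] + bw / 2)
  list(intervals = ints,
       inner_boundary = ints$r_inner[nrow(ints)],
       flag = "ok")
}

#' Segment a synthetic nuclear-marker image into a labeled image
#'
#' Otsu threshold on the nuclear-marker channel, distance-map watershed to
#' split touching nuclei, a fixed-width dilation ring per nucleus for the
#' cytoplasm (assigned to the nearest nucleus by propagation, never
#' overlapping other nuclei), and everything beyond any ring as background.
#'
#' @param intensity named list of channel matrices; must include `dapi`
#'   (nuclear marker).
#' @param pixel_size micrometres per pixel.
#' @param ring_width cytoplasm ring width (pixels).
#' @param bg_margin extra dilation (pixels) separating the background mask
#'   from the outermost cytoplasm, so cells wider than the measured ring do
#'   not leak into the background estimate.
#' @return a [labeled_image()] carrying all input channels; a blank image
#'   yields zero labels without error.
#' @export
segment_fixture <- function(intensity, pixel_size = 1, ring_width = 2,
                            bg_margin = 3) {
  if (is.matrix(intensity)) intensity <- list(dapi = intensity)
  if (!"dapi" %in% names(intensity))
    stop("a 'dapi' nuclear-marker channel is required")
  dapi <- intensity[["dapi"]]
  rng <- range(dapi)
  img <- EBImage::Image((dapi - rng[1]) / max(diff(rng), .Machine$double.eps))
  thr <- tryCatch(EBImage::otsu(img), error = function(e) NA_real_)
  bw <- if (is.na(thr) || diff(rng) <= 0) img > 1 else img > thr
  if (!any(bw)) {
    z <- matrix(0L, nrow(dapi), ncol(dapi))
    return(labeled_image(intensity, z, z,
                         matrix(TRUE, nrow(dapi), ncol(dapi)), pixel_size))
  }
  labels <- EBImage::watershed(EBImage::distmap(bw), tolerance = 1, ext = 1)
  brush <- EBImage::makeBrush(2 * ring_width + 1, shape = "disc")
  grown <- EBImage::dilate(bw, brush)
  prop <- EBImage::propagate(img * 0, seeds = labels, mask = grown)
  nuc <- imageData(labels)
  storage.mode(nuc) <- "integer"
  cyto <- imageData(prop)
  storage.mode(cyto) <- "integer"
  cyto[nuc > 0] <- 0L
  # a nucleus whose ring was swallowed by neighbours has no cytoplasm; drop it
  orphan <- setdiff(unique(nuc[nuc > 0]), unique(cyto[cyto > 0]))
  if (length(orphan) > 0) nuc[nuc %in% orphan] <- 0L
  excl <- EBImage::dilate(bw, EBImage::makeBrush(
    2 * (ring_width + bg_margin) + 1, shape = "disc"))
  background <- !(as.logical(excl) | nuc > 0)
  dim(background) <- dim(nuc)
  labeled_image(intensity, nuc, cyto, background, pixel_size)
}

# re-export of the EBImage accessor used above without attaching EBImage
imageData <- function(x) EBImage::imageData(x)
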