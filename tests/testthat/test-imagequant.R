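# small hand-built labeled image: one cell, uniform compartment intensities
tiny_image <- function(nuc = 30, cyt = 20, bg = 10) {
  inten <- matrix(bg, 10, 10)
  nl <- matrix(0L, 10, 10); cl <- matrix(0L, 10, 10)
  nl[4:6, 4:6] <- 1L
  cl[3, 3:7] <- 1L; cl[7, 3:7] <- 1L; cl[4:6, 3] <- 1L; cl[4:6, 7] <- 1L
  inten[nl == 1L] <- nuc
  inten[cl == 1L] <- cyt
  bgm <- nl == 0L & cl == 0L
  labeled_image(inten, nl, cl, bgm, pixel_size = 1)
}

test_that("nc_ratio is the background-subtracted nuclear over cytoplasmic mean", {
  m <- measure_cells(tiny_image(30, 20, 10))
  expect_equal(m$nc_ratio, 2)
  m1 <- measure_cells(tiny_image(20, 20, 0))
  expect_equal(m1$nc_ratio, 1)
  # non-positive cytoplasmic excess: excluded with a logged count
  expect_message(m2 <- measure_cells(tiny_image(30, 10, 10)), "excluded")
  expect_equal(nrow(m2), 0)
  expect_equal(attr(m2, "n_excluded"), 1)
})

test_that("nc_ratio is invariant to intensity offset and positive scaling", {
  img <- tiny_image(35, 22, 9)
  base <- measure_cells(img)$nc_ratio
  off <- img; off$intensity$signal <- img$intensity$signal + 57
  expect_equal(measure_cells(off)$nc_ratio, base)
  sc <- img; sc$intensity$signal <- img$intensity$signal * 3.7
  expect_equal(measure_cells(sc)$nc_ratio, base)
})

test_that("radial profiles bin annulus means and mark empty bins as missing", {
  cells <- data.frame(x = c(0, 30, 50, 90), y = 0,
                      nc_ratio = c(1, 1, 2, 2))
  pr <- radial_profile(cells, center = c(0, 0), bin_width = 20, r_max = 100)
  expect_equal(pr$value[1], 1)           # r in [0,20): the cells at 0
  expect_true(is.na(pr$value[4]))        # empty annulus [60,80) is NA
  expect_equal(pr$value[3], 2)
  # constant values give a constant profile over occupied bins
  cells$nc_ratio <- 3
  pr2 <- radial_profile(cells, c(0, 0), 20, r_max = 100)
  expect_true(all(pr2$value[!is.na(pr2$value)] == 3))
  # single cell: exactly one non-missing bin
  pr3 <- radial_profile(cells[1, ], c(0, 0), 20, r_max = 100)
  expect_equal(sum(!is.na(pr3$value)), 1)
})

test_that("edge/interior populations show a step at the placement radius", {
  set.seed(1)
  th <- runif(300, 0, 2 * pi)
  r <- c(runif(150, 0, 150), runif(150, 250, 350))
  cells <- data.frame(x = 350 + r * cos(th), y = 350 + r * sin(th),
                      nc_ratio = c(rep(1, 150), rep(2, 150)))
  pr <- radial_profile(cells, c(350, 350), 20, r_max = 350)
  inner <- pr$value[pr$r_center < 140]
  outer <- pr$value[pr$r_center > 260 & pr$r_center < 340]
  expect_true(all(inner[!is.na(inner)] == 1))
  expect_true(all(outer[!is.na(outer)] == 2))
})

test_that("kymograph normalization rules behave as specified", {
  m <- rbind(c(1, 3, 5), c(2, 2, 2), c(0, 4, 8))
  k <- kymograph(m, c(10, 30, 50), c(0, 1, 2), channel = "SMAD2/3")
  expect_warning(n <- normalize_channel(k, "minmax"), "constant")
  expect_equal(n$matrix[1, ], c(0, 0.5, 1))
  expect_equal(n$matrix[2, ], c(0, 0, 0))
  # idempotent on already-normalized rows
  n2 <- suppressWarnings(normalize_channel(n, "minmax"))
  expect_equal(n2$matrix[c(1, 3), ], n$matrix[c(1, 3), ])

  # bra_rule: everything scaled by the max of the latest time row
  kb <- kymograph(rbind(c(1, 2), c(2, 4)), c(10, 30), c(0, 48),
                  channel = "BRA")
  nb <- normalize_channel(kb, "bra_rule")
  expect_equal(max(nb$matrix[2, ]), 1)
  expect_equal(nb$matrix[1, ], c(0.25, 0.5))

  # smad4_rule: unity at the interior maximum inward of the pSMAD1 half-max
  r <- seq(10, 350, by = 20)
  smad4_row <- exp(-((r - 250)^2) / (2 * 30^2))      # interior max at 250
  psmad1_row <- stats::plogis((r - 300) / 5)         # half-max at 300
  ks <- kymograph(rbind(smad4_row), r, 0, channel = "SMAD4")
  ka <- kymograph(rbind(psmad1_row), r, 0, channel = "pSMAD1")
  ns <- normalize_channel(ks, "smad4_rule", auxiliary = ka)
  expect_equal(unname(ns$matrix[1, which(r == 250)]), 1)
  expect_error(normalize_channel(ks, "smad4_rule"), "auxiliary")
})

test_that("front tracking recovers programmed motion", {
  r <- seq(10, 350, by = 20)
  # static profile: velocity 0
  prof <- stats::plogis((r - 200) / 10)
  ks <- kymograph(matrix(rep(prof, 10), nrow = 10, byrow = TRUE), r, 1:10)
  ft <- track_front(ks, window = c(1, 10))
  expect_equal(ft$velocity, 0, tolerance = 1e-10)

  # exact translation by 7 um per frame at 1 frame/hr
  tt <- 0:15
  mat <- t(vapply(tt, function(i) stats::plogis((r - (300 - 7 * i)) / 10),
                  numeric(length(r))))
  kt <- kymograph(mat, r, tt)
  ft2 <- track_front(kt, window = c(0, 15))
  expect_equal(ft2$velocity, 7, tolerance = 0.01 * 7)
})

test_that("expression domains follow the fractional threshold", {
  r <- seq(0.5, 349.5, by = 1)
  tri <- structure(data.frame(r_center = r, value = r / 350),
                   class = c("radial_profile", "data.frame"))
  dom <- expression_domain(tri, 0.20)
  expect_equal(dom$inner_boundary, 70, tolerance = 1)
  const <- structure(data.frame(r_center = r, value = rep(1, length(r))),
                     class = c("radial_profile", "data.frame"))
  expect_equal(expression_domain(const)$inner_boundary, 0)
  zero <- structure(data.frame(r_center = r, value = rep(0, length(r))),
                    class = c("radial_profile", "data.frame"))
  expect_equal(expression_domain(zero)$flag, "empty")
})

test_that("watershed segmentation labels synthetic nuclei correctly", {
  # k well-separated nuclei -> exactly k labels
  rf <- render_cell_field(1.5, render_params(n_cells = 25, field_px = c(200, 200)),
                          seed = 9)
  img <- segment_fixture(rf$channels)
  expect_equal(length(unique(img$nuclear_labels[img$nuclear_labels > 0])), 25)

  # blank image: zero labels, no error
  blank <- segment_fixture(list(dapi = matrix(0, 50, 50)))
  expect_equal(sum(blank$nuclear_labels), 0)

  # two touching nuclei split by the watershed
  d <- matrix(0, 60, 60)
  rr <- row(d); cc <- col(d)
  d[(rr - 30)^2 + (cc - 24)^2 <= 36] <- 1
  d[(rr - 30)^2 + (cc - 36)^2 <= 36] <- 1
  img2 <- segment_fixture(list(dapi = d), ring_width = 1)
  expect_equal(length(unique(img2$nuclear_labels[img2$nuclear_labels > 0])), 2)
})

test_that("rendered-field measurement closes on the ground truth", {
  # noiseless closure is exact
  rf0 <- render_cell_field(2.0, render_params(n_cells = 40, poisson = FALSE,
                                              read_noise_frac = 0), seed = 4)
  c0 <- measure_cells(segment_fixture(rf0$channels), "signal")
  expect_equal(c0$nc_ratio, rep(2, nrow(c0)), tolerance = 1e-12)

  # 200 cells with calibrated noise: mean recovered ratio within 2%
  rf <- render_cell_field(1.5, render_params(n_cells = 200), seed = 3)
  cells <- measure_cells(segment_fixture(rf$channels), "signal")
  expect_equal(mean(cells$nc_ratio), 1.5, tolerance = 0.02)

  # zero cells: blank image and empty truth table
  rfz <- render_cell_field(numeric(0), render_params(n_cells = 0), seed = 1)
  expect_equal(nrow(rfz$truth), 0)
  expect_equal(sd(rfz$channels$dapi) < 30, TRUE)
})

test_that("radial profiles of rendered colonies are rotation invariant", {
  params <- colony_params()
  rend <- colony_renderer(params, n_cells = 300, img_px = 256, seed = 77)
  th <- pi / 5
  ctr <- 128
  rot <- rend$centers
  rot[, 1] <- ctr + cos(th) * (rend$centers[, 1] - ctr) -
    sin(th) * (rend$centers[, 2] - ctr)
  rot[, 2] <- ctr + sin(th) * (rend$centers[, 1] - ctr) +
    cos(th) * (rend$centers[, 2] - ctr)
  prof_of <- function(centers, seed) {
    v <- smaddyn:::colony_field(params, "SMAD4",
                                sqrt((centers[, 1] - ctr)^2 +
                                       (centers[, 2] - ctr)^2) *
                                  rend$pixel_size, 30)
    fr <- render_cell_field(v, rend$render, seed = seed, centers = centers)
    cells <- measure_cells(segment_fixture(fr$channels,
                                           pixel_size = rend$pixel_size),
                           "signal")
    radial_profile(cells, rend$center_um, 20, r_max = 350)
  }
  p1 <- prof_of(rend$centers, 500)
  p2 <- prof_of(rot, 501)
  sel <- !is.na(p1$value) & !is.na(p2$value) & p1$n_cells > 3 & p2$n_cells > 3
  expect_equal(p1$value[sel], p2$value[sel], tolerance = 0.02)
})
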