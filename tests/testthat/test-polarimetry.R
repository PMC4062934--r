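make_uniform_stack <- function(intensity_fun, angles = seq(0, 120, 20),
                               dim = c(6L, 6L)) {
  frames <- lapply(angles, function(th)
    matrix(intensity_fun(th * pi / 180), dim[1], dim[2]))
  frame_stack(frames, angles)
}

test_that("least-squares Stokes estimates match the closed-form oracle", {
  # all-constant frames: unpolarized light, polarizer transmits half
  st <- make_uniform_stack(function(th) 7)
  sk <- estimate_stokes(st)
  expect_equal(sk$s0[1, 1], 14, tolerance = 1e-12)
  expect_equal(sk$s1[1, 1], 0, tolerance = 1e-12)
  expect_equal(sk$s2[1, 1], 0, tolerance = 1e-12)

  # AoP 0 definition: I = (1 + cos 2 theta)/2 -> (1, 1, 0)
  sk0 <- estimate_stokes(make_uniform_stack(function(th)
    0.5 * (1 + cos(2 * th))))
  expect_equal(c(sk0$s0[1, 1], sk0$s1[1, 1], sk0$s2[1, 1]), c(1, 1, 0),
               tolerance = 1e-12)

  # AoP 30, DoLP 1: compare against the three-point closed form at
  # 0/60/120 degrees, zero residual, exact recovery
  f <- function(th) 0.5 * (1 + cos(2 * (th - pi / 6)))
  sk30 <- estimate_stokes(make_uniform_stack(f))
  oracle <- three_point_stokes(f(0), f(pi / 3), f(2 * pi / 3))
  expect_equal(sk30$s0[1, 1], oracle$s0, tolerance = 1e-9)
  expect_equal(sk30$s1[1, 1], oracle$s1, tolerance = 1e-9)
  expect_equal(sk30$s2[1, 1], oracle$s2, tolerance = 1e-9)
  expect_lt(max(sk30$residual_rms), 1e-10)
  mp <- compute_maps(sk30)
  expect_equal(mp$aop_deg[1, 1], 30, tolerance = 1e-9)
  expect_equal(mp$dolp[1, 1], 1, tolerance = 1e-9)

  expect_error(estimate_stokes(
    frame_stack(list(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2)),
                c(0, 90, 180))))
})

test_that("least squares equals the three-point formulas on random noiseless pixels", {
  set.seed(101)
  for (rep in 1:20) {
    s0 <- runif(1, 0.5, 3); d <- runif(1); phi <- runif(1, 0, pi)
    f <- function(th) 0.5 * s0 * (1 + d * cos(2 * (th - phi)))
    angles <- c(0, 60, 120, sort(runif(3, 0, 180)))  # contains 0/60/120
    sk <- estimate_stokes(make_uniform_stack(f, angles, c(2L, 2L)))
    oracle <- three_point_stokes(f(0), f(pi / 3), f(2 * pi / 3))
    expect_equal(sk$s0[1, 1], oracle$s0, tolerance = 1e-9)
    expect_equal(sk$s1[1, 1], oracle$s1, tolerance = 1e-9)
    expect_equal(sk$s2[1, 1], oracle$s2, tolerance = 1e-9)
  }
})

test_that("maps implement the AoP/DoLP formulas and flag degenerate pixels", {
  mk <- function(s0, s1, s2) {
    structure(list(s0 = matrix(s0, 1, 1), s1 = matrix(s1, 1, 1),
                   s2 = matrix(s2, 1, 1),
                   residual_rms = matrix(0, 1, 1),
                   valid = matrix(TRUE, 1, 1)),
              class = "stokes_image")
  }
  m1 <- compute_maps(mk(1, 1, 0))
  expect_equal(m1$aop_deg[1, 1], 0); expect_equal(m1$dolp[1, 1], 1)
  m2 <- compute_maps(mk(1, 0, 1))
  expect_equal(m2$aop_deg[1, 1], 45); expect_equal(m2$dolp[1, 1], 1)
  m3 <- compute_maps(mk(1, -0.5, 0))
  expect_equal(m3$aop_deg[1, 1], 90); expect_equal(m3$dolp[1, 1], 0.5)

  # unpolarized pixel: below dolp_min, flagged but never NaN
  m4 <- compute_maps(mk(1, 0, 0))
  expect_false(m4$valid[1, 1])
  expect_true(is.na(m4$aop_deg[1, 1]))
  expect_equal(m4$dolp[1, 1], 0)

  # s0 at zero: flagged, no division blow-up
  m5 <- compute_maps(mk(0, 0, 0))
  expect_false(m5$valid[1, 1])
  expect_false(any(is.nan(m5$dolp)))

  # dolp clipped to [0, 1] (noise can push sqrt(s1^2+s2^2) above s0)
  m6 <- compute_maps(mk(1, 1.2, 0.3))
  expect_equal(m6$dolp[1, 1], 1)
})

test_that("AoP/DoLP are scale invariant and AoP is angle-shift equivariant", {
  f <- function(th) 0.5 * 2 * (1 + 0.7 * cos(2 * (th - 1.1)))
  st <- make_uniform_stack(f)
  base <- compute_maps(estimate_stokes(st))
  skb <- estimate_stokes(st)

  k <- 3.7
  st_k <- frame_stack(lapply(st$frames, function(fr) k * fr), st$angles_deg)
  sk_k <- estimate_stokes(st_k)
  mk <- compute_maps(sk_k)
  expect_equal(sk_k$s0, k * skb$s0, tolerance = 1e-9)
  expect_equal(mk$aop_deg, base$aop_deg, tolerance = 1e-9)
  expect_equal(mk$dolp, base$dolp, tolerance = 1e-9)

  # adding delta to every analyzer angle shifts recovered AoP by delta
  for (delta in c(10, 77.5, 150)) {
    st_d <- frame_stack(st$frames, st$angles_deg + delta)
    md <- compute_maps(estimate_stokes(st_d))
    expect_equal(md$aop_deg[1, 1],
                 (base$aop_deg[1, 1] + delta) %% 180, tolerance = 1e-9)
    expect_equal(md$dolp[1, 1], base$dolp[1, 1], tolerance = 1e-9)
  }
})

test_that("ring summaries use axial circular statistics", {
  pat <- make_target_pattern("contrast", image_size = c(80L, 80L),
                             outer_ring = list(inner_radius_px = 24,
                                               outer_radius_px = 36,
                                               aop_deg = 0, dolp = 1,
                                               radiance = 40000),
                             inner_ring = list(outer_radius_px = 23,
                                               aop_deg = 0, dolp = 1,
                                               radiance = 40000))
  # synthetic maps with rings at 10 and 80 degrees: axial distance 70
  m <- petalpol:::region_masks(pat)
  aop <- matrix(NA_real_, 80, 80); dolp <- matrix(0, 80, 80)
  aop[m$inner] <- 10; dolp[m$inner] <- 1
  aop[m$outer] <- 80; dolp[m$outer] <- 1
  maps <- petalpol:::new_polarization_maps(aop, dolp, !m$background)
  rs <- ring_summary(maps, pat)
  expect_equal(rs$aop_difference_deg, axial_distance_oracle(10, 80))
  expect_equal(rs$aop_difference_deg, 70)

  # axial mean handles the 0/180 wrap: angles straddling zero
  aop[m$inner] <- ifelse(seq_along(aop[m$inner]) %% 2 == 0, 178, 2)
  maps2 <- petalpol:::new_polarization_maps(aop, dolp, !m$background)
  rs2 <- ring_summary(maps2, pat)
  expect_lt(axial_distance_oracle(rs2$rings$aop_deg[1], 0), 1e-6)

  # empty ring mask errors
  novalid <- petalpol:::new_polarization_maps(aop, dolp,
                                              matrix(FALSE, 80, 80))
  expect_error(ring_summary(novalid, pat), "empty ring")
})

test_that("false colour is DoLP-weighted, cyclic in hue, and invertible", {
  aop <- matrix(c(0, 90, 179.999, 45), 2, 2)
  dolp <- matrix(c(1, 1, 1, 0), 2, 2)
  valid <- matrix(c(TRUE, TRUE, TRUE, TRUE), 2, 2)
  maps <- petalpol:::new_polarization_maps(aop, dolp, valid)

  img <- false_color(maps, "aop_weighted")
  # d = 0 pixel renders black even when valid
  expect_equal(img[2, 2, ], c(0, 0, 0))
  # 0 and ~180 degrees share a hue (cyclic colormap)
  expect_equal(img[1, 1, ], img[1, 2, ], tolerance = 0.05)
  # hue round trip: decode 90 degrees back from the rendered colour
  px <- img[2, 1, ]
  hue <- grDevices::rgb2hsv(px[1] * 255, px[2] * 255, px[3] * 255)[1, 1]
  expect_equal(unname(hue) * 180, 90, tolerance = 2)

  # invalid pixels are black in every mode
  maps$valid[1, 1] <- FALSE
  for (mode in c("aop", "dolp", "aop_weighted"))
    expect_equal(false_color(maps, mode)[1, 1, ], c(0, 0, 0))
  expect_error(false_color(maps, "rainbow"))

  leg <- aop_color_legend(16)
  expect_equal(nrow(leg), 16)
})

test_that("full pipeline recovers ground truth end to end", {
  geom <- list(image_size = c(120L, 120L),
               outer_ring = list(inner_radius_px = 34, outer_radius_px = 52,
                                 aop_deg = 0, dolp = 1, radiance = 40000),
               inner_ring = list(outer_radius_px = 33, aop_deg = 0,
                                 dolp = 1, radiance = 40000))
  for (kind in c("contrast", "plain")) {
    pat <- do.call(make_target_pattern,
                   c(list(kind = kind, outer_aop_deg = 20, dolp = 0.9),
                     geom))
    st <- render_stack(pat, acquisition_config())
    maps <- compute_maps(estimate_stokes(dark_subtract(st)))
    gt <- ground_truth_maps(pat)
    ring <- gt$valid
    expect_lt(max(abs(maps$dolp[ring] - gt$dolp[ring])), 1e-6)
    dd <- vapply(which(ring), function(i)
      axial_distance_oracle(maps$aop_deg[i], gt$aop_deg[i]), numeric(1))
    expect_lt(max(dd), 1e-6)
    rs <- ring_summary(maps, pat)
    expect_equal(rs$aop_difference_deg,
                 if (kind == "contrast") 90 else 0, tolerance = 1e-6)
  }

  # low noise: per-ring errors stay small
  pat <- do.call(make_target_pattern, c(list(kind = "contrast"), geom))
  cfg <- acquisition_config(read_noise_sd = 655, seed = 3)
  maps <- compute_maps(estimate_stokes(dark_subtract(render_stack(pat, cfg))))
  rs <- ring_summary(maps, pat)
  expect_lt(abs(rs$aop_difference_deg - 90), 1)
  expect_lt(abs(rs$rings$dolp[1] - 1), 0.05)
})

test_that("maps survive a 32-bit TIFF round trip with recorded scales", {
  f <- function(th) 0.5 * 1000 * (1 + 0.6 * cos(2 * (th - 0.4)))
  sk <- estimate_stokes(make_uniform_stack(f))
  mp <- compute_maps(sk)
  dir <- withr::local_tempdir()
  write_maps(sk, mp, dir)
  back <- read_maps(dir)
  expect_equal(back$s0, sk$s0, tolerance = 1e-6)
  expect_equal(back$s1, sk$s1, tolerance = 1e-5)
  expect_equal(back$dolp, mp$dolp, tolerance = 1e-6)
})
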