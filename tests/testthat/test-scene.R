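test_that("contrast and plain targets set perpendicular / parallel ring AoPs", {
  con <- make_target_pattern("contrast")
  expect_equal(con$outer_ring$aop_deg, 0)
  expect_equal(con$inner_ring$aop_deg, 90)

  pla <- make_target_pattern("plain")
  expect_equal(pla$inner_ring$aop_deg, pla$outer_ring$aop_deg)

  rot <- make_target_pattern("contrast", outer_aop_deg = 10)
  expect_equal(rot$inner_ring$aop_deg, 100)

  wrap <- make_target_pattern("contrast", outer_aop_deg = 135)
  expect_equal(wrap$inner_ring$aop_deg, 45)  # 225 wraps into [0, 180)

  expect_error(make_target_pattern("stripes"))
})

test_that("scene pattern invariants reject degenerate geometry", {
  expect_error(scene_pattern(inner_ring = list(outer_radius_px = 150,
                                               aop_deg = 0, dolp = 1,
                                               radiance = 1000)),
               "degenerate")
  expect_error(scene_pattern(inner_ring = list(outer_radius_px = 120,
                                               aop_deg = 0, dolp = 1.4,
                                               radiance = 1000)),
               "dolp")
  expect_error(scene_pattern(background = list(dolp = 0, radiance = -3)))
})

test_that("noiseless renderer evaluates the polarizer forward model exactly", {
  # single fully polarized region filling a tiny image: d=1, phi=0, R=1
  pat <- scene_pattern(image_size = c(8L, 8L), center = c(4.5, 4.5),
                       outer_ring = list(inner_radius_px = 3,
                                         outer_radius_px = 4,
                                         aop_deg = 0, dolp = 1,
                                         radiance = 1),
                       inner_ring = list(outer_radius_px = 2, aop_deg = 0,
                                         dolp = 1, radiance = 1),
                       background = list(dolp = 0, radiance = 1))
  cfg <- acquisition_config(analyzer_angles_deg = c(0, 60, 90, 120),
                            dark_level = 0)
  st <- render_stack(pat, cfg)
  m <- petalpol:::region_masks(pat)
  # Malus maximum: parallel analyzer transmits everything
  expect_equal(st$frames[[1]][m$inner], rep(1, sum(m$inner)))
  # crossed analyzer extinguishes
  expect_equal(st$frames[[3]][m$inner], rep(0, sum(m$inner)))
  # unpolarized background transmits half at every analyzer angle
  for (f in st$frames)
    expect_equal(f[m$background], rep(0.5, sum(m$background)))
})

test_that("frame intensities have period 180 degrees and renders are seed-reproducible", {
  pat <- make_target_pattern("contrast", outer_aop_deg = 25, dolp = 0.8,
                             image_size = c(60L, 60L),
                             outer_ring = list(inner_radius_px = 18,
                                               outer_radius_px = 27,
                                               aop_deg = 0, dolp = 1,
                                               radiance = 40000),
                             inner_ring = list(outer_radius_px = 17,
                                               aop_deg = 0, dolp = 1,
                                               radiance = 40000))
  a <- render_stack(pat, acquisition_config(c(0, 35, 70, 105)))
  b <- render_stack(pat, acquisition_config(c(180, 215, 250, 285)))
  for (k in seq_along(a$frames))
    expect_equal(a$frames[[k]], b$frames[[k]], tolerance = 1e-12)

  cfg <- acquisition_config(read_noise_sd = 50, shot_noise = TRUE,
                            gain = 2, seed = 99)
  pat2 <- make_target_pattern("contrast", image_size = c(40L, 40L),
                              outer_ring = list(inner_radius_px = 12,
                                                outer_radius_px = 18,
                                                aop_deg = 0, dolp = 1,
                                                radiance = 30000),
                              inner_ring = list(outer_radius_px = 11,
                                                aop_deg = 0, dolp = 1,
                                                radiance = 30000))
  r1 <- render_stack(pat2, cfg); r2 <- render_stack(pat2, cfg)
  expect_identical(r1$frames, r2$frames)
  # noiseless render is a deterministic function of the pattern
  cfg0 <- acquisition_config()
  expect_identical(render_stack(pat2, cfg0)$frames,
                   render_stack(pat2, cfg0)$frames)
})

test_that("ground-truth maps echo the pattern and flag the background", {
  con <- make_target_pattern("contrast")
  gt <- ground_truth_maps(con)
  m <- petalpol:::region_masks(con)
  expect_true(all(gt$aop_deg[m$inner] == 90))
  expect_true(all(gt$dolp[m$inner] == 1))
  expect_true(all(gt$dolp[m$background] == 0))
  expect_true(all(!gt$valid[m$background]))
  expect_true(all(is.na(gt$aop_deg[m$background])))

  pla <- make_target_pattern("plain")
  gtp <- ground_truth_maps(pla)
  ring <- m$inner | m$outer
  expect_equal(unique(gtp$aop_deg[ring]), 0)
})

test_that("acquisition config rejects degenerate angle sets", {
  expect_error(acquisition_config(c(0, 90)), "3 analyzer angles")
  expect_error(acquisition_config(c(0, 90, 180)), "3 analyzer angles")
  expect_silent(acquisition_config(c(0, 60, 120)))
})

test_that("simulated choices follow the marginal logistic learning curve", {
  # chance level when all parameters are zero
  tab0 <- simulate_choices(n_bees = 50, n_trials = 100, beta0 = 0,
                           beta1 = 0, sigma_b = 0, sigma_s = 0, seed = 11)
  expect_equal(mean(tab0$correct), 0.5,
               tolerance = 3 * sqrt(0.25 / 5000) / 0.5)

  # closed-form logistic mean at beta0 = 5 (10^4 Bernoulli draws)
  tab5 <- simulate_choices(n_bees = 100, n_trials = 100, beta0 = 5,
                           beta1 = 0, sigma_b = 0, sigma_s = 0, seed = 12)
  p <- plogis(5)
  expect_equal(mean(tab5$correct), p,
               tolerance = 3 * sqrt(p * (1 - p) / 1e4) / p)

  # with heterogeneity: per-trial frequencies track the Gauss-Hermite
  # marginal curve within 3 binomial SEs
  nb <- 600
  tab <- simulate_choices(n_bees = nb, n_trials = 100, beta0 = 0.3,
                          beta1 = 1.2, sigma_b = 0.8, sigma_s = 0.6,
                          seed = 13)
  for (tr in c(1, 25, 50, 75, 100)) {
    x <- (tr - 1) / 99
    p_true <- marginal_correct_prob(x, 0.3, 1.2, 0.8, 0.6)
    p_emp <- mean(tab$correct[tab$trial == tr])
    expect_lt(abs(p_emp - p_true),
              3 * sqrt(p_true * (1 - p_true) / nb) + 1e-9)
  }
})

test_that("choice simulator honours its contract", {
  tab <- simulate_choices(n_bees = 3, seed = 5)
  expect_equal(unname(table(tab$bee_id)), rep(100L, 3), ignore_attr = TRUE)
  expect_true(all(tab$correct %in% 0:1))
  expect_error(simulate_choices(sigma_b = -1), "non-negative")

  # condition labels drawn for intensity-contrast sessions
  tabc <- simulate_choices(n_bees = 4, n_trials = 50,
                           conditions = c("darker", "lighter"), seed = 6)
  expect_true(all(tabc$condition %in% c("darker", "lighter")))
  # same seed, same table
  expect_identical(simulate_choices(n_bees = 4, seed = 8),
                   simulate_choices(n_bees = 4, seed = 8))
})
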