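test_that("design strategies remove whole passages as documented", {
  ds <- noisy_dataset()
  for (kind in c("drop-first", "drop-last", "skip", "drop-middle-block")) {
    expect_identical(apply_strategy(ds, design_strategy(kind, 0)), ds)
  }
  # skip stride 2 on 16 passages: 6 retained, 30 per-passage measurements
  sk <- apply_strategy(ds, design_strategy("skip", 2))
  expect_identical(sort(unique(sk$passage)), c(5L, 8L, 11L, 14L, 17L, 20L))
  expect_identical(nrow(unique(sk[, c("passage", "marker")])), 30L)
  # drop-first 3: earliest three passages absent
  df3 <- apply_strategy(ds, design_strategy("drop-first", 3))
  expect_identical(sort(unique(df3$passage)), 8:20)
  # drop-last 6 keeps the earliest ten
  dl6 <- apply_strategy(ds, design_strategy("drop-last", 6))
  expect_identical(sort(unique(dl6$passage)), 5:14)
  # middle block of 6 removed symmetrically
  dm6 <- apply_strategy(ds, design_strategy("drop-middle-block", 6))
  expect_identical(sort(unique(dm6$passage)),
                   c(5L, 6L, 7L, 8L, 9L, 16L, 17L, 18L, 19L, 20L))
  # replicate rows follow their passage
  expect_identical(nrow(sk), 6L * 5L * 3L)
  expect_error(apply_strategy(ds, design_strategy("drop-first", 15)),
               "fewer than 2")
  expect_error(design_strategy("drop-first", -1), "non-negative")
})

test_that("a k = 0 strategy has exactly zero design error", {
  ds <- noiseless_dataset()
  baseline <- fit_ga(ds, ga = ga_tiny(), seed = 3)
  for (kind in c("drop-first", "drop-last", "skip", "drop-middle-block")) {
    e <- design_strategy_error(ds, design_strategy(kind, 0),
                               baseline = baseline)
    expect_identical(as.numeric(e), 0)
  }
})

test_that("sensitivity surfaces are zero at the generating parameters", {
  ref <- ref_set()
  ds <- noiseless_dataset()
  # 2-D grid over the division ladder endpoints, bracketing the optimum
  fv <- ref$params$div_ladder[1] * c(0.25, 0.5, 1, 2, 4)
  lv <- ref$params$div_ladder[50] * c(0.25, 0.5, 1, 2, 4)
  gr <- sensitivity_grid(ref$params, ref$mparams, ds, pair = "div",
                         first_values = fv, last_values = lv)
  expect_equal(gr$increase_pct[3, 3], 0)
  expect_true(all(gr$increase_pct >= 0, na.rm = TRUE))
  expect_equal(unname(gr$argmin), c(fv[3], lv[3]))
  # the optimum is a decreasing ladder: first endpoint above the last
  expect_gt(gr$argmin[["first"]], gr$argmin[["last"]])

  sc <- sensitivity_scan(ref$params, ref$mparams, ds, "m_GS",
                         values = ref$params$m_GS * c(0.5, 1, 2))
  expect_equal(sc$increase_pct[2], 0)
  expect_equal(attr(sc, "argmin"), ref$params$m_GS)
})

test_that("removing the G-to-S route costs little; accelerating it costs more", {
  ref <- ref_set()
  ds <- noisy_dataset()
  sc <- sensitivity_scan(ref$params, ref$mparams, ds, "m_GS",
                         values = c(0, ref$params$m_GS,
                                    10 * ref$params$m_GS))
  expect_true(all(is.finite(sc$increase_pct)))
  expect_lt(sc$increase_pct[1], sc$increase_pct[3])
  # fraction parameters have weak leverage: finite error at both extremes
  for (pn in c("frac_P_gH2AX", "frac_G_Ki67", "frac_G_gH2AX")) {
    sf <- sensitivity_scan(ref$params, ref$mparams, ds, pn,
                           values = c(0, 1))
    expect_true(all(is.finite(sf$increase_pct)))
  }
})

test_that("the growth-arrest peak locator interpolates and flags no-peak", {
  # toy parabola with a known vertex at t = 100
  tt <- seq(0, 200, by = 10)
  tr <- fake_trajectory(tt, G = 0.25 - ((tt - 100) / 400)^2, TP = 1)
  expect_equal(peak_growth_arrest_time(tr), 100, tolerance = 1e-6)
  # off-grid vertex at t = 103
  tr2 <- fake_trajectory(tt, G = 0.25 - ((tt - 103) / 400)^2, TP = 1)
  expect_equal(peak_growth_arrest_time(tr2), 103, tolerance = 1e-6)
  # monotone fraction: classed no-peak condition
  tr3 <- fake_trajectory(tt, G = tt / 1000, TP = 1)
  expect_error(peak_growth_arrest_time(tr3), class = "senodyn_no_peak")
})

test_that("the peak vanishes when growth-arrested cells stop feeding senescence", {
  ref <- ref_set()
  p0 <- ref$params
  p0$m_GS <- 0
  tr <- simulate_population(p0, 5000, seq(0, 5000, by = 5))
  base_peak <- peak_growth_arrest_time(reference_trajectory())
  res <- tryCatch(peak_growth_arrest_time(tr), error = function(e) e)
  if (inherits(res, "senodyn_no_peak")) {
    succeed("no interior peak without the G-to-S transition")
  } else {
    expect_gt(res, base_peak)  # never an earlier artefact
  }
})

test_that("time to a senescent-fraction threshold responds to the right rates", {
  ref <- ref_set()
  expect_identical(time_to_senescence_fraction(ref$params, 0), 0)
  t85 <- time_to_senescence_fraction(ref$params, 0.85, horizon = 10000)
  expect_true(is.finite(t85) && t85 > 0 && t85 < 10000)
  # crossing is located between the bracketing grid points
  tr <- simulate_population(ref$params, 10000,
                            c(floor(t85), ceiling(t85)))
  expect_lt(tr$S[1] / tr$TP[1], 0.85)
  expect_gte(tr$S[2] / tr$TP[2], 0.85 - 1e-6)
  # proliferation rate moves the clock far more than the apoptosis rate
  p_div <- ref$params; p_div$div_ladder <- 2 * p_div$div_ladder
  p_apo <- ref$params; p_apo$apo_ladder <- 2 * p_apo$apo_ladder
  d_div <- abs(time_to_senescence_fraction(p_div, 0.85, 10000) - t85)
  d_apo <- abs(time_to_senescence_fraction(p_apo, 0.85, 10000) - t85)
  expect_gt(d_div, d_apo)
  # unreachable threshold signals a classed condition with the final fraction
  pz <- model_parameters(rep(0, 4), rep(0, 4), rep(0, 4), rep(0, 4), 0, 0)
  err <- tryCatch(time_to_senescence_fraction(pz, 0.5, horizon = 500),
                  error = function(e) e)
  expect_s3_class(err, "senodyn_not_reached")
  expect_equal(err$final_fraction, 0)
  expect_error(time_to_senescence_fraction(ref$params, 1), "threshold")
})
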