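test_that("straight-tube viscous drop matches the Poiseuille closed form", {
  # D = 3 mm, L = 50 mm, V = 300 mm/s: 32 mu L V / D^2 = 186.7 Pa = 1.400 mmHg
  fit <- mufr(straight_case(), mode = "angio_only")
  dp <- max(fit$pressure$dp_mmhg)
  expect_equal(dp, 186.6667 / MMHG, tolerance = 1e-4)
  expect_equal(dp, 1.400, tolerance = 1e-3)
  expect_equal(max(fit$pressure$separation_mmhg), 0)
  expect_equal(fit$distal_value, (90 - 1.40014) / 90, tolerance = 1e-5)
  expect_equal(fit$distal_value, 0.9844, tolerance = 1e-4)
  expect_equal(fit$curve$value[1], 1)
})

test_that("separation term matches the Borda-Carnot closed form", {
  # 50% DS: A 7.0686 -> 1.7671 mm^2 at Q = 2120.6 mm^3/s, full recovery
  pa <- octmufr:::borda_carnot(2120.575e-9, 1.7671e-6, 7.0686e-6, 1060, 1)
  expect_equal(pa, 429.3, tolerance = 1e-3)
  expect_equal(pa / MMHG, 3.221, tolerance = 1e-3)

  # through the profile machinery: abrupt 50% stenosis in a 3 mm tube
  s <- seq(0, 50, by = 0.2)
  d <- ifelse(s >= 20 & s < 30, 1.5, 3)
  case <- vessel_case(angio_profile(s, d),
                      timi_frame_count = 15 * 50 / (300 / 1.33),
                      distal_eval_s = 50)
  fit <- mufr(case, mode = "angio_only")
  expect_equal(nrow(fit$pressure$lesions), 1L)
  expect_equal(fit$pressure$lesions$dp_sep_mmhg, 3.221, tolerance = 0.03)
})

test_that("no flow means no pressure drop", {
  case <- straight_case(v_h = 1e-6)
  fit <- mufr(case, mode = "angio_only",
              config = mufr_config(hyperemic_multiplier = 1e-6))
  expect_lte(max(fit$pressure$dp_mmhg), 1e-9)
  expect_equal(fit$distal_value, 1, tolerance = 1e-9)
})

test_that("viscous delta scales linearly and separation quadratically in Q", {
  s <- seq(0, 50, by = 0.2)
  d <- 3 * (1 - 0.5 * exp(-(s - 25)^2 / (2 * 2^2)))
  mk <- function(v_h) vessel_case(angio_profile(s, d),
                                  timi_frame_count = 15 * 50 / (v_h / 1.33),
                                  distal_eval_s = 50)
  f1 <- mufr(mk(150), "angio_only")
  f2 <- mufr(mk(300), "angio_only")
  expect_equal(max(f2$pressure$viscous_mmhg) / max(f1$pressure$viscous_mmhg),
               2, tolerance = 1e-6)
  expect_equal(max(f2$pressure$separation_mmhg) /
                 max(f1$pressure$separation_mmhg), 4, tolerance = 1e-3)
})

test_that("grid integration matches the closed-form conical viscous integral", {
  s <- seq(0, 40, by = 0.2)
  d <- 3.2 - 0.015 * s                     # cone 3.2 -> 2.6 mm
  case <- vessel_case(angio_profile(s, d),
                      timi_frame_count = 15 * 40 / (300 / 1.33),
                      distal_eval_s = 40)
  fit <- mufr(case, "angio_only")
  q <- fit$flow$inlet_flow * 1e-9
  exact <- cone_viscous(q, 3.2e-3, 2.6e-3, 40e-3)
  expect_equal(max(fit$pressure$viscous_mmhg) * MMHG, exact,
               tolerance = 5e-3)
})

test_that("pullback curves are monotone and stenoses strictly lower them", {
  for (seed in c(6, 17, 31)) {
    cs <- make_case(random_vessel_spec(seed))
    fit <- mufr(cs$case, "fused")
    expect_true(all(diff(fit$curve$value) <= 1e-12))
    expect_true(all(fit$curve$value > 0 & fit$curve$value <= 1))
  }
  base <- lesion_spec(8, severity = 0)
  spec <- lesion_spec(8, severity = 0.5)
  v0 <- mufr(make_case(base)$case, "fused")$distal_value
  v1 <- mufr(make_case(spec)$case, "fused")$distal_value
  expect_lt(v1, v0)
})

test_that("halving the grid step changes the distal value by < 1e-4", {
  for (seed in c(3, 46)) {
    cs <- make_case(random_vessel_spec(seed))
    d1 <- mufr(cs$case, "fused", mufr_config(grid_step = 0.1))$distal_value
    d2 <- mufr(cs$case, "fused", mufr_config(grid_step = 0.05))$distal_value
    expect_lt(abs(d1 - d2), 1e-4)
  }
})

test_that("fused mode reproduces angio-only mode on consistent OCT", {
  for (seed in c(2, 9, 27)) {
    spec <- lesion_spec(seed, severity = 0.45, with_media = FALSE)
    cs <- make_case(spec)
    vf <- mufr(cs$case, "fused")$distal_value
    va <- mufr(cs$case, "angio_only")$distal_value
    expect_lte(abs(vf - va), 1e-3)
  }
})

test_that("segment deltas telescope over the pullback", {
  cs <- make_case(lesion_spec(12, severity = 0.5))
  fit <- mufr(cs$case, "fused")
  smax <- max(fit$curve$s_mm)
  expect_equal(delta_over_segment(fit, 0, smax), 1 - fit$curve$value[nrow(fit$curve)],
               tolerance = 1e-9)
  expect_equal(delta_over_segment(fit, 10, 10), 0)
  expect_gte(delta_over_segment(fit, 5, 30), 0)
  expect_error(delta_over_segment(fit, -1, 10), "s1")
  expect_error(delta_over_segment(fit, 0, smax + 5), "s1")
  # uniform tube: a tenth of the vessel takes a tenth of the viscous delta
  ft <- mufr(straight_case(), "angio_only")
  expect_equal(delta_over_segment(ft, 10, 15),
               delta_over_segment(ft, 0, 50) / 10, tolerance = 1e-6)
})

test_that("a distal value exactly at the cutoff classifies positive", {
  cs <- make_case(lesion_spec(12, severity = 0.5))
  v <- mufr(cs$case, "fused")$distal_value
  at <- mufr(cs$case, "fused", mufr_config(cutoff = v))
  expect_true(at$classification$ffr_positive)
  below <- mufr(cs$case, "fused", mufr_config(cutoff = v - 1e-6))
  expect_false(below$classification$ffr_positive)
})
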