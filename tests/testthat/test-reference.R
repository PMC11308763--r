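test_that("Murray mother diameter follows the fractal law", {
  expect_equal(murray_mother_diameter(c(3, 2), 3), 35^(1/3), tolerance = 1e-9)
  expect_equal(murray_mother_diameter(c(3, 2), 3), 3.271, tolerance = 1e-3)
  expect_equal(murray_mother_diameter(2.4, 2.55), 2.4)
  expect_equal(murray_distal_diameter(35^(1/3), 2, 3), 3, tolerance = 1e-9)
  expect_error(murray_mother_diameter(numeric()), "daughter")
  expect_error(murray_mother_diameter(c(3, -1)), "> 0")
  expect_error(murray_distal_diameter(2, 3), "smaller")
})

test_that("Murray mother diameter is monotone in each daughter", {
  set.seed(1)
  for (k in 1:20) {
    d <- runif(3, 0.5, 4)
    eps <- 1e-6
    for (j in 1:3) {
      d2 <- d; d2[j] <- d[j] + eps
      expect_gt(murray_mother_diameter(d2), murray_mother_diameter(d))
    }
  }
})

test_that("healthy-point detection keeps constant vessels and drops lesions", {
  s <- seq(0, 40, by = 0.2)
  flat <- as_fused_geometry(angio_profile(s, rep(3, length(s))))
  expect_true(all(detect_healthy_points(flat)))

  dip <- 3 * (1 - 0.5 * exp(-(s - 20)^2 / (2 * 2^2)))
  gd <- as_fused_geometry(angio_profile(s, dip))
  h <- detect_healthy_points(gd)
  expect_false(any(h[abs(s - 20) < 2]))        # lesion core excluded
  expect_true(all(h[s < 10 | s > 30]))          # shoulders retained
  expect_error(detect_healthy_points(flat[0, ]), "empty")
})

test_that("media plaque-burden rule takes precedence where media exists", {
  s <- seq(0, 20, by = 0.5)
  g <- as_fused_geometry(angio_profile(s, rep(3, length(s))))
  g$media_area_mm2 <- g$lumen_area_mm2          # plaque burden 0
  expect_true(all(detect_healthy_points(g)))
  g$media_area_mm2 <- g$lumen_area_mm2 / 0.5    # burden 0.5 > 0.4
  expect_false(any(detect_healthy_points(g)))
})

test_that("reference fit is exact on a straight vessel", {
  s <- seq(0, 50, by = 0.2)
  g <- as_fused_geometry(angio_profile(s, rep(3, length(s))))
  ref <- fit_reference(g, detect_healthy_points(g))
  expect_equal(predict(ref, c(0, 25, 50)), rep(3, 3), tolerance = 1e-9)
})

test_that("reference steps down across a bifurcation per Murray's law", {
  s <- seq(0, 40, by = 0.2)
  d <- ifelse(s < 20, 35^(1/3), 3)              # 3.271 -> 3.0, sb 2.0
  g <- as_fused_geometry(angio_profile(s, d))
  bif <- data.frame(s_mm = 20, sb_diameter_mm = 2)
  ref <- fit_reference(g, detect_healthy_points(g, bifurcations = bif), bif)
  expect_equal(predict(ref, 10), 35^(1/3), tolerance = 1e-3)
  expect_equal(predict(ref, 30), 3, tolerance = 1e-3)
  e <- ref$murray_exponent
  dpx <- predict(ref, 20, side = "proximal")
  ddist <- predict(ref, 20, side = "distal")
  expect_lte(abs(dpx^e - (ddist^e + 2^e)) / dpx^e, 1e-6)
})

test_that("a fully diseased segment inherits the Murray-propagated reference", {
  s <- seq(0, 40, by = 0.2)
  d_ref <- ifelse(s < 20, 35^(1/3), 3)
  d <- d_ref * ifelse(s >= 20, 0.55, 1)         # distal segment all diseased
  g <- as_fused_geometry(angio_profile(s, d))
  bif <- data.frame(s_mm = 20, sb_diameter_mm = 2)
  healthy <- detect_healthy_points(g, bifurcations = bif)
  healthy[s >= 20] <- FALSE
  ref <- fit_reference(g, healthy, bif)
  expect_equal(predict(ref, 30), 3, tolerance = 5e-3)
  expect_error(fit_reference(g, rep(FALSE, nrow(g)), bif),
               "underdetermined")
})

test_that("Murray conservation holds at every fitted step", {
  for (seed in c(2, 7, 21)) {
    cs <- make_case(random_vessel_spec(seed))
    fit <- mufr(cs$case, "fused")
    ref <- fit$reference
    e <- ref$murray_exponent
    for (j in seq_along(ref$step_positions)) {
      b <- ref$step_positions[j]
      dpx <- predict(ref, b, side = "proximal")
      dd <- predict(ref, b, side = "distal")
      expect_lte(abs(dpx^e - (dd^e + ref$sb_diameters[j]^e)) / dpx^e, 1e-6)
    }
  }
})

test_that("reference is invariant to adding a pure stenosis", {
  set.seed(9)
  s <- seq(0, 50, by = 0.2)
  base <- 3.4 - 0.015 * s
  g0 <- as_fused_geometry(angio_profile(s, base))
  ref0 <- fit_reference(g0, detect_healthy_points(g0))
  d1 <- base * (1 - 0.55 * exp(-(s - 25)^2 / (2 * 2.5^2)))
  g1 <- as_fused_geometry(angio_profile(s, d1))
  ref1 <- fit_reference(g1, detect_healthy_points(g1))
  outside <- s < 15 | s > 35
  expect_lte(max(abs(predict(ref0, s[outside]) - predict(ref1, s[outside]))),
             0.05)
})

test_that("percent stenosis reports DS%, AS% and the MLA", {
  s <- seq(0, 40, by = 0.1)
  d <- 3 * (1 - 0.5 * exp(-(s - 20)^2 / (2 * 2^2)))
  g <- as_fused_geometry(angio_profile(s, d))
  ref <- fit_reference(g, detect_healthy_points(g))
  ps <- percent_stenosis(g, ref)
  expect_equal(ps$ds_percent, 50, tolerance = 0.5)
  expect_equal(ps$as_percent, 75, tolerance = 1)   # 1 - 0.5^2
  expect_equal(ps$s_mla, 20, tolerance = 0.2)

  flat <- as_fused_geometry(angio_profile(s, 3 - 0.01 * s))
  reff <- fit_reference(flat, detect_healthy_points(flat))
  psf <- percent_stenosis(flat, reff)
  expect_lte(psf$ds_percent, 1)
  expect_equal(psf$s_mla, 40)                      # global area minimum
})

test_that("taper recovery stays within 0.05 mm RMS on healthy vessels", {
  for (seed in c(4, 11)) {
    set.seed(seed)
    inlet <- runif(1, 2.8, 3.8); taper <- runif(1, 0.005, 0.025)
    spec <- vessel_spec(length = 50, inlet_diameter = inlet, taper = taper,
                        oct_coverage = NULL, seed = seed)
    cs <- make_case(spec)
    fit <- mufr(cs$case, "angio_only")
    s <- seq(0, 50, by = 0.5)
    rms <- sqrt(mean((predict(fit$reference, s) - (inlet - taper * s))^2))
    expect_lte(rms, 0.05)
  }
})
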