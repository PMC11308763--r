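test_that("landmark mapping interpolates exactly and extrapolates linearly", {
  m <- build_mapping(data.frame(oct_mm = c(10, 30), s_mm = c(32, 53)))
  expect_equal(predict(m, 20), 42.5)
  expect_equal(predict(m, c(10, 30)), c(32, 53))      # exact at landmarks
  expect_equal(predict(m, 0), 32 - 10 * 21 / 20)      # linear extrapolation
  ident <- build_mapping(data.frame(oct_mm = c(0, 54), s_mm = c(0, 54)))
  expect_equal(predict(ident, 17.3), 17.3)
  expect_error(build_mapping(data.frame(oct_mm = 10, s_mm = 32)), "2 landmark")
  expect_error(build_mapping(data.frame(oct_mm = c(10, 30), s_mm = c(32, 30))),
               "monotone")
})

test_that("mapping inverse round-trips to 1e-9", {
  m <- build_mapping(data.frame(oct_mm = c(0, 12, 30, 44),
                                s_mm = c(3, 16, 35, 51)))
  x <- seq(-2, 46, by = 0.37)
  expect_lte(max(abs(predict(m, predict(m, x), inverse = TRUE) - x)), 1e-9)
})

test_that("fusion cross-fades linearly at the junctions", {
  s <- seq(0, 60, by = 0.2)
  angio <- angio_profile(s, rep(3, length(s)))
  n_f <- 100                                          # frames 0..99, 0.2 mm
  oct <- oct_pullback(rep(pi, n_f), frame_spacing = 0.2)
  m <- build_mapping(data.frame(oct_mm = c(0, 19.8), s_mm = c(20, 39.8)))
  fg <- fuse_geometry(angio, oct, m, blend_window = 1)
  at <- function(x) approx(fg$s_mm, fg$d_mm, x)$y
  expect_equal(at(19), 3)
  expect_equal(at(20), 2.5)                 # mid-ramp at the junction
  expect_equal(at(21), 2)
  expect_equal(at(30), 2)
  expect_equal(at(38.8), 2)                 # distal junction at 39.8
  expect_equal(at(39.8), 2.5)
  expect_equal(at(40.8), 3)
  expect_true(all(fg$source[fg$s_mm < 19 | fg$s_mm > 40.9] == "angio"))
  expect_true(all(fg$source[fg$s_mm > 21 & fg$s_mm < 38.7] == "oct"))
})

test_that("zero blend window yields a step; fusion stays local", {
  s <- seq(0, 60, by = 0.2)
  angio <- angio_profile(s, rep(3, length(s)))
  oct <- oct_pullback(rep(pi, 100), frame_spacing = 0.2)
  m <- build_mapping(data.frame(oct_mm = c(0, 19.8), s_mm = c(20, 39.8)))
  fg0 <- fuse_geometry(angio, oct, m, blend_window = 0)
  expect_equal(fg0$d_mm[fg0$s_mm == 19.8], 3)   # last pure angio sample
  expect_equal(fg0$d_mm[fg0$s_mm >= 20 & fg0$s_mm <= 39.8], rep(2, 100))
  # locality: samples beyond the blend window are bit-identical to angio
  fg1 <- fuse_geometry(angio, oct, m, blend_window = 1)
  far <- fg1[fg1$s_mm < 19 | fg1$s_mm > 40.8, ]
  ref <- angio[angio$s_mm < 19 | angio$s_mm > 40.8, ]
  expect_identical(far$d_mm, ref$d_mm)
  expect_identical(far$s_mm, ref$s_mm)
})

test_that("consistent OCT areas reproduce the angiographic profile", {
  s <- seq(0, 60, by = 0.2)
  # constant caliber: identical for any blend window
  angio_c <- angio_profile(s, rep(3, length(s)))
  oct_c <- oct_pullback(rep(pi * 9 / 4, 100), frame_spacing = 0.2)
  m <- build_mapping(data.frame(oct_mm = c(0, 19.8), s_mm = c(20, 39.8)))
  for (w in c(0, 1, 2)) {
    fg <- fuse_geometry(angio_c, oct_c, m, blend_window = w)
    expect_lte(max(abs(approx(fg$s_mm, fg$d_mm, s)$y - 3)), 1e-9)
  }
  # tapered caliber: exact without blending; within taper x window with it
  # (the cross-fade extrapolates the OCT value across the junction)
  d <- 3.4 - 0.02 * s
  angio_t <- angio_profile(s, d)
  s_f <- seq(20, 39.8, by = 0.2)
  oct_t <- oct_pullback(pi * (3.4 - 0.02 * s_f)^2 / 4, frame_spacing = 0.2)
  fg0 <- fuse_geometry(angio_t, oct_t, m, blend_window = 0)
  expect_lte(max(abs(approx(fg0$s_mm, fg0$d_mm, s)$y - d)), 1e-9)
  fg1 <- fuse_geometry(angio_t, oct_t, m, blend_window = 1)
  expect_lte(max(abs(approx(fg1$s_mm, fg1$d_mm, s)$y - d)), 0.02 * 1)
})

test_that("disjoint OCT interval and bad windows are rejected", {
  s <- seq(0, 30, by = 0.2)
  angio <- angio_profile(s, rep(3, length(s)))
  oct <- oct_pullback(rep(pi, 20), frame_spacing = 0.2)
  m <- build_mapping(data.frame(oct_mm = c(0, 3.8), s_mm = c(50, 53.8)))
  expect_error(fuse_geometry(angio, oct, m), "disjoint")
  m2 <- build_mapping(data.frame(oct_mm = c(0, 3.8), s_mm = c(10, 13.8)))
  expect_error(fuse_geometry(angio, oct, m2, blend_window = -1),
               "blend_window")
})
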