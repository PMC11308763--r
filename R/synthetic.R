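# Seeded generator of synthetic vessel cases with known ground truth from
# a fine-grid oracle, plus cohort generation for diagnostics testing.

#' Specification of a synthetic vessel
#'
#' The true reference diameter is a linear taper with Murray-law
#' step-downs at the bifurcations; stenoses are Gaussian diameter dips
#' `d(s) = d_ref(s) * (1 - severity * exp(-(s - c)^2 / (2 w^2)))`, so
#' severity maps directly to true DS%.  Angiographic diameters and OCT
#' lumen areas carry independent Gaussian measurement noise.
#'
#' @param length Vessel length, mm.
#' @param inlet_diameter Reference diameter at the ostium, mm.
#' @param taper Reference taper, mm diameter lost per mm.
#' @param stenoses Data frame `center` (mm), `width` (Gaussian sigma, mm),
#'   `severity` (fraction of reference diameter, in [0, 0.95)), or `NULL`.
#' @param bifurcations Data frame `s` (mm), `sb_diameter` (ostial
#'   diameter of the side branch, mm), or `NULL`.
#' @param oct_coverage Interval `[start, end]` on the centerline covered
#'   by the pullback, mm; `NULL` for angio-only cases.
#' @param angio_noise_sd SD of diameter measurement noise, mm.
#' @param oct_noise_sd SD of OCT lumen-area noise, mm^2.
#' @param contrast_velocity True contrast-front velocity used to derive
#'   the TIMI frame count, mm/s.
#' @param with_media Emit OCT media areas (at the true reference size)?
#' @param angio_spacing Angiographic sample spacing, mm.
#' @param distal_eval_s Distal evaluation position, mm.
#' @param murray_exponent Fractal exponent of the true step-downs.
#' @param seed Integer seed; the whole case is deterministic given it.
#' @return A list of class `"vessel_spec"`.
#' @export
vessel_spec <- function(length = 50, inlet_diameter = 3.2, taper = 0.015,
                        stenoses = NULL, bifurcations = NULL,
                        oct_coverage = c(2, min(length - 2, 56)),
                        angio_noise_sd = 0, oct_noise_sd = 0,
                        contrast_velocity = 225, with_media = TRUE,
                        angio_spacing = 0.2,
                        distal_eval_s = length,
                        murray_exponent = 3, seed = 1L) {
  if (is.null(stenoses))
    stenoses <- data.frame(center = numeric(), width = numeric(),
                           severity = numeric())
  if (is.null(bifurcations))
    bifurcations <- data.frame(s = numeric(), sb_diameter = numeric())
  spec <- structure(list(length = length, inlet_diameter = inlet_diameter,
                         taper = taper, stenoses = as.data.frame(stenoses),
                         bifurcations = as.data.frame(bifurcations),
                         oct_coverage = oct_coverage,
                         angio_noise_sd = angio_noise_sd,
                         oct_noise_sd = oct_noise_sd,
                         contrast_velocity = contrast_velocity,
                         with_media = with_media,
                         angio_spacing = angio_spacing,
                         distal_eval_s = distal_eval_s,
                         murray_exponent = murray_exponent,
                         seed = as.integer(seed)),
                    class = "vessel_spec")
  if (length <= 0 || inlet_diameter <= 0 || taper < 0)
    stop("vessel_spec: invalid geometry", call. = FALSE)
  st <- spec$stenoses
  if (nrow(st) && (any(st$severity < 0) || any(st$severity >= 0.95)))
    stop("vessel_spec: severity must be in [0, 0.95)", call. = FALSE)
  if (nrow(st) && (any(st$center <= 0) || any(st$center >= length)))
    stop("vessel_spec: stenoses must lie inside the vessel", call. = FALSE)
  if (!is.null(oct_coverage)) {
    if (oct_coverage[1L] < 0 || oct_coverage[2L] > length ||
        diff(oct_coverage) <= 0)
      stop("vessel_spec: oct_coverage must be an interval inside [0, length]",
           call. = FALSE)
  }
  if (spec$distal_eval_s > length)
    stop("vessel_spec: distal_eval_s beyond the vessel", call. = FALSE)
  spec
}

# True reference diameter function of a spec (vectorised over s).  The
# anatomical caliber steps down smoothly across each branch ostium (a
# linear transition as wide as the side branch); the Murray factors
# themselves are exact step-downs.
truth_reference <- function(spec) {
  e <- spec$murray_exponent
  bif <- spec$bifurcations[order(spec$bifurcations$s), , drop = FALSE]
  base <- function(s) spec$inlet_diameter - spec$taper * s
  fac <- rep(1, nrow(bif) + 1L)
  for (j in seq_len(nrow(bif))) {
    dpx <- fac[j] * base(bif$s[j])
    if (bif$sb_diameter[j] >= dpx)
      stop("vessel_spec: side branch larger than the mother vessel",
           call. = FALSE)
    fac[j + 1L] <- fac[j] *
      (dpx^e - bif$sb_diameter[j]^e)^(1 / e) / dpx
  }
  factor_at <- function(s) {
    if (!nrow(bif)) return(rep(1, length(s)))
    h <- bif$sb_diameter / 2
    kx <- c(min(0, bif$s[1L] - h[1L] - 1),
            as.vector(rbind(bif$s - h, bif$s + h)),
            spec$length + 1)
    ky <- rep(fac, each = 2L)
    approx(kx, ky, s, rule = 2)$y
  }
  list(fn = function(s) factor_at(s) * base(s),
       factors = fac, bif = bif)
}

# True lumen diameter (reference times the Gaussian dips).
truth_diameter <- function(spec) {
  ref <- truth_reference(spec)$fn
  st <- spec$stenoses
  function(s) {
    dip <- rep(0, length(s))
    for (k in seq_len(nrow(st)))
      dip <- dip + st$severity[k] *
        exp(-(s - st$center[k])^2 / (2 * st$width[k]^2))
    ref(s) * (1 - pmin(dip, 0.95))
  }
}

# Truth-based reference_function / flow_model objects for the oracle.
truth_objects <- function(spec, config) {
  tr <- truth_reference(spec)
  bif <- tr$bif
  segs <- data.frame(
    s_start = c(0, bif$s), s_end = c(bif$s, spec$length),
    a = tr$factors * spec$inlet_diameter,
    b = -tr$factors * spec$taper)
  ref <- structure(list(segments = segs, step_positions = bif$s,
                        sb_diameters = bif$sb_diameter,
                        murray_exponent = spec$murray_exponent,
                        trend = c(spec$inlet_diameter, -spec$taper),
                        factors = tr$factors,
                        floor = 1e-6, domain = c(0, spec$length)),
                   class = "reference_function")
  v_h <- hyperemic_velocity(spec$contrast_velocity,
                            config$hyperemic_multiplier,
                            config$velocity_cap)
  q0 <- v_h * pi * predict(ref, 0)^2 / 4
  q <- numeric(nrow(bif) + 1L); q[1L] <- q0
  branches <- data.frame(s_mm = numeric(), sb_diameter_mm = numeric(),
                         fraction = numeric(), q_mm3_s = numeric())
  for (j in seq_len(nrow(bif))) {
    fr <- flow_division(c(predict(ref, bif$s[j]), bif$sb_diameter[j]),
                        spec$murray_exponent)
    q[j + 1L] <- q[j] * fr[1L]
    branches[j, ] <- list(bif$s[j], bif$sb_diameter[j], fr[2L],
                          q[j] * fr[2L])
  }
  flow <- structure(list(contrast_velocity = spec$contrast_velocity,
                         hyperemic_velocity = v_h, inlet_flow = q0,
                         segments = data.frame(s_start = c(0, bif$s),
                                               s_end = c(bif$s, spec$length),
                                               q_mm3_s = q),
                         branches = branches,
                         multiplier = config$hyperemic_multiplier),
                    class = "flow_model")
  list(ref = ref, flow = flow)
}

#' Fine-grid ground-truth oracle for a synthetic vessel
#'
#' Evaluates the pressure-loss model on the true (noise-free) geometry at
#' a fine grid (default 0.01 mm), with the true reference and true flow
#' split, bypassing sampling, coregistration, healthy-point detection and
#' reference fitting.
#'
#' @param spec A [vessel_spec()].
#' @param grid_step Oracle grid step, mm.
#' @param config A [mufr_config()].
#' @return List: `curve` (`s_mm`, `value`), `distal_value`, `ds_percent`,
#'   `as_percent`, `mla_mm2`.
#' @export
oracle_pullback <- function(spec, grid_step = 0.01,
                            config = mufr_config()) {
  to <- truth_objects(spec, config)
  s <- seq(0, spec$length, by = grid_step)
  d <- truth_diameter(spec)(s)
  geom <- data.frame(s_mm = s, d_mm = d, lumen_area_mm2 = pi * d^2 / 4,
                     media_area_mm2 = NA_real_, source = "angio")
  class(geom) <- c("fused_geometry", "data.frame")
  cfg <- config
  cfg$grid_step <- grid_step
  pp <- pressure_drop_profile(geom, to$ref, to$flow, cfg)
  pa <- config$aortic_pressure
  value <- pmax((pa - pp$dp_mmhg) / pa, 1e-6)
  dref <- predict(to$ref, s)
  ratio <- d / dref
  ia <- which.min(geom$lumen_area_mm2)
  list(curve = data.frame(s_mm = pp$s_mm, value = value),
       distal_value = approx(pp$s_mm, value, spec$distal_eval_s,
                             rule = 2)$y,
       ds_percent = max(0, (1 - min(ratio)) * 100),
       as_percent = max(0, (1 - geom$lumen_area_mm2[ia] /
                              (pi * dref[ia]^2 / 4)) * 100),
       mla_mm2 = geom$lumen_area_mm2[ia])
}

#' Generate a synthetic vessel case with ground truth
#'
#' Deterministic given `spec$seed`.  Angiographic samples are the true
#' diameters plus Gaussian noise; OCT lumen areas are `pi d^2 / 4` plus
#' noise on the covered interval, with media areas at the true reference
#' size when `with_media`; landmarks are placed at the coverage ends and
#' at each bifurcation inside the coverage (the true pullback-to-
#' centerline mapping is the identity plus the coverage offset); the TIMI
#' frame count is derived from the assumed true contrast velocity.
#'
#' @param spec A [vessel_spec()].
#' @param config A [mufr_config()] (for the oracle).
#' @return List: `case` (a [vessel_case()]), `truth` (the
#'   [oracle_pullback()] result plus the true mapping and spec).
#' @export
make_case <- function(spec, config = mufr_config()) {
  stopifnot(inherits(spec, "vessel_spec"))
  set.seed(spec$seed)
  d_true <- truth_diameter(spec)
  d_ref <- truth_reference(spec)$fn

  s_a <- seq(0, spec$length, by = spec$angio_spacing)
  if (spec$length - s_a[length(s_a)] > 1e-9) s_a <- c(s_a, spec$length)
  d_a <- d_true(s_a) + rnorm(length(s_a), 0, spec$angio_noise_sd)
  d_a <- pmax(d_a, 0.15 * d_ref(s_a))
  angio <- angio_profile(s_a, d_a)

  constants <- acquisition_constants()
  oct <- NULL
  landmarks <- NULL
  if (!is.null(spec$oct_coverage)) {
    a <- spec$oct_coverage[1L]; b <- spec$oct_coverage[2L]
    sp <- constants$oct_frame_spacing
    pb <- seq(0, b - a, by = sp)
    s_f <- a + pb
    lum <- pi * d_true(s_f)^2 / 4 + rnorm(length(s_f), 0, spec$oct_noise_sd)
    lum <- pmax(lum, 0.05 * pi * d_ref(s_f)^2 / 4)
    med <- if (spec$with_media) pmax(pi * d_ref(s_f)^2 / 4, lum)
    else rep(NA_real_, length(s_f))
    bs <- spec$bifurcations$s
    sb_flag <- vapply(s_f, function(x) any(abs(x - bs) < sp / 2),
                      logical(1L))
    oct <- oct_pullback(lum, med, sb_flag, frame_spacing = sp)
    lm_s <- c(a, bs[bs > a + 0.5 & bs < b - 0.5], max(s_f))
    lm_s <- sort(unique(round(lm_s, 9)))
    landmarks <- data.frame(oct_mm = lm_s - a, s_mm = lm_s)
  }

  bif <- if (nrow(spec$bifurcations))
    data.frame(s_mm = spec$bifurcations$s,
               sb_diameter_mm = spec$bifurcations$sb_diameter)
  else NULL

  timi <- spec$distal_eval_s / spec$contrast_velocity * constants$cine_fps
  case <- vessel_case(angio = angio, oct = oct, bifurcations = bif,
                      landmarks = landmarks, timi_frame_count = timi,
                      constants = constants,
                      distal_eval_s = spec$distal_eval_s)
  truth <- oracle_pullback(spec, config = config)
  truth$mapping_offset <- if (is.null(spec$oct_coverage)) NA_real_
  else spec$oct_coverage[1L]
  truth$spec <- spec
  list(case = case, truth = truth)
}

#' Draw a random synthetic vessel specification
#'
#' Samples vessel length, inlet size, taper, 0-2 bifurcations, 1-2
#' Gaussian stenoses and an OCT coverage window from ranges typical of
#' FFR-interrogated coronary arteries.  Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param angio_noise_sd,oct_noise_sd Measurement noise SDs passed on to
#'   the spec.
#' @return A [vessel_spec()].
#' @export
random_vessel_spec <- function(seed, angio_noise_sd = 0, oct_noise_sd = 0) {
  set.seed(seed)
  len <- runif(1, 40, 70)
  inlet <- runif(1, 2.8, 3.8)
  taper <- runif(1, 0.005, 0.025)
  nbif <- sample(0:2, 1L)
  bifs <- NULL
  if (nbif > 0) {
    bs <- sort(runif(nbif, 0.25 * len, 0.75 * len))
    while (nbif == 2L && diff(bs) < 8) bs <- sort(runif(2, 0.25 * len,
                                                        0.75 * len))
    # resolve side-branch sizes against the running reference
    fac <- 1
    sbd <- numeric(nbif)
    for (j in seq_len(nbif)) {
      dpx <- fac * (inlet - taper * bs[j])
      sbd[j] <- runif(1, 0.4, 0.7) * dpx
      fac <- fac * ((dpx^3 - sbd[j]^3)^(1 / 3)) / dpx
    }
    bifs <- data.frame(s = bs, sb_diameter = sbd)
  }
  nsten <- sample(1:2, 1L)
  widths <- runif(nsten, 1.5, 4)
  centers <- runif(nsten, 0.2 * len, 0.9 * len)
  if (nsten == 2L) {
    # tandem lesions are separated by normal segments: keep the dips apart
    ok <- FALSE
    for (try in 1:50) {
      if (abs(diff(centers)) >= 2.5 * sum(widths)) { ok <- TRUE; break }
      centers <- runif(2, 0.2 * len, 0.9 * len)
    }
    if (!ok) { nsten <- 1L; centers <- centers[1L]; widths <- widths[1L] }
  }
  sten <- data.frame(center = centers, width = widths,
                     severity = runif(nsten, 0.2, 0.7))
  cov_start <- runif(1, 1, 8)
  cov_end <- min(len - 1, cov_start + 54)
  vessel_spec(length = len, inlet_diameter = inlet, taper = taper,
              stenoses = sten, bifurcations = bifs,
              oct_coverage = c(cov_start, cov_end),
              angio_noise_sd = angio_noise_sd,
              oct_noise_sd = oct_noise_sd,
              contrast_velocity = runif(1, 150, 300),
              seed = seed)
}

# Truncated-normal draw by inverse CDF.
rtnorm1 <- function(mean, sd, lo, hi) {
  u <- runif(1, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Generate a synthetic validation cohort
#'
#' Per vessel, a positive/negative class is drawn with probability
#' `prevalence`, a target true distal value is drawn around the 0.80
#' cutoff (mixture matching an FFR distribution of roughly 0.81 +/-
#' 0.11), and the stenosis severity is solved by bisection against the
#' fine-grid oracle so the true value hits the target.  The wire
#' reference is the oracle value plus Gaussian measurement noise; the
#' computed columns are the full OCT-muFR and muQFR pipelines run on the
#' generated (noisy) case files.
#'
#' @param n Number of vessels (>= 10).
#' @param prevalence Probability a vessel is drawn reference-positive.
#' @param reference_noise_sd SD of wire-FFR measurement noise.
#' @param angio_noise_sd,oct_noise_sd Case measurement noise SDs.
#' @param seed Master seed; every per-case seed derives from it.
#' @param config A [mufr_config()].
#' @return Data frame: `id`, `ffr` (noisy reference), `oracle` (true
#'   distal value), `oct_mufr`, `muqfr`, `ds_percent`, `as_percent`.
#' @export
make_cohort <- function(n, prevalence = 0.45, reference_noise_sd = 0.03,
                        angio_noise_sd = 0.02, oct_noise_sd = 0.05,
                        seed = 1L, config = mufr_config()) {
  if (n < 10) stop("make_cohort: n must be >= 10", call. = FALSE)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  classes <- runif(n) < prevalence
  targets <- vapply(classes, function(pos) {
    if (pos) rtnorm1(0.72, 0.06, 0.45, 0.799)
    else rtnorm1(0.88, 0.05, 0.801, 0.985)
  }, numeric(1L))
  ref_noise <- rnorm(n, 0, reference_noise_sd)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec0 <- random_vessel_spec(case_seeds[i],
                                angio_noise_sd = angio_noise_sd,
                                oct_noise_sd = oct_noise_sd)
    base_sev <- spec0$stenoses$severity / max(spec0$stenoses$severity)
    with_scale <- function(t) {
      sp <- spec0
      sp$stenoses$severity <- pmin(base_sev * t, 0.93)
      sp
    }
    coarse <- function(t)
      oracle_pullback(with_scale(t), grid_step = 0.05,
                      config = config)$distal_value
    # bisection: oracle distal value is monotone decreasing in severity
    lo <- 0; hi <- 0.93
    if (coarse(lo) < targets[i]) {
      t_star <- 0
    } else if (coarse(hi) > targets[i]) {
      t_star <- hi
    } else {
      for (k in 1:30) {
        mid <- (lo + hi) / 2
        if (coarse(mid) > targets[i]) lo <- mid else hi <- mid
      }
      t_star <- (lo + hi) / 2
    }
    spec <- with_scale(t_star)
    cs <- make_case(spec, config = config)
    fit_f <- mufr(cs$case, mode = "fused", config = config)
    fit_a <- mufr(cs$case, mode = "angio_only", config = config)
    rows[[i]] <- data.frame(
      id = i,
      ffr = min(max(cs$truth$distal_value + ref_noise[i], 0.05), 1),
      oracle = cs$truth$distal_value,
      oct_mufr = fit_f$distal_value,
      muqfr = fit_a$distal_value,
      ds_percent = fit_f$stenosis$ds_percent,
      as_percent = fit_f$stenosis$as_percent)
  }
  do.call(rbind, rows)
}
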