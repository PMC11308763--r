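# One-dimensional pressure-loss model: Poiseuille viscous friction plus
# Borda-Carnot separation losses at stenosis exits.  Inputs are in mm /
# mm^2 / mm^3/s; the integration is carried out in SI and reported in mmHg.

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1L] + y[-n]) / 2 * diff(x)))
}

# Borda-Carnot pressure jump (Pa) for flow q (m^3/s) expanding from area
# a_min to a_rec (m^2).
borda_carnot <- function(q, a_min, a_rec, density, K) {
  0.5 * density * K * q^2 * (1 / a_min - 1 / a_rec)^2
}

# Minimum value of the parabola through three points; NA when they are
# not convex or the vertex falls outside [x0, x2].
parabola_min <- function(x0, y0, x1, y1, x2, y2) {
  f01 <- (y1 - y0) / (x1 - x0)
  f12 <- (y2 - y1) / (x2 - x1)
  a <- (f12 - f01) / (x2 - x0)
  if (a <= 1e-12) return(NA_real_)
  xv <- (x0 + x1) / 2 - f01 / (2 * a)
  if (xv < x0 || xv > x2) return(NA_real_)
  y0 + f01 * (xv - x0) + a * (xv - x0) * (xv - x1)
}

# General form with the local flow at the jet and at the recovery point
# (they differ when a lesion is interrupted by a bifurcation).
borda_carnot_local <- function(q_jet, a_min, q_rec, a_rec, density, K) {
  dv <- q_jet / a_min - q_rec / a_rec
  if (dv <= 0) return(0)
  0.5 * density * K * dv^2
}

#' Cumulative pressure-drop profile along a vessel
#'
#' Two loss terms, both cumulative from the ostium.  Viscous
#' (Poiseuille): `int_0^s 128 mu Q(u) / (pi D(u)^4) du`.  Separation
#' (Borda-Carnot): lesions are the maximal runs where lumen area falls
#' below `lesion_area_fraction` times the reference area; at the distal
#' shoulder of each run a jump `(rho K / 2) (Q/A_min - Q/A_rec)^2` is
#' added, where `A_min` is the run's minimal lumen area and `A_rec` the
#' lumen area at the first point distal to the run.  Runs are bounded by
#' bifurcations (each inter-bifurcation segment carries its own flow), and
#' the jet and recovery velocities use the local flow.  Abrupt expansions
#' from zero-blend fusion junctions are treated identically.
#'
#' @param geometry A `"fused_geometry"` (any sampling; resampled
#'   internally to `config$grid_step`).
#' @param ref A `"reference_function"`.
#' @param flow A `"flow_model"`.
#' @param config A [mufr_config()] (uses `blood_viscosity`,
#'   `blood_density`, `separation_K`, `grid_step`,
#'   `lesion_area_fraction`).
#' @return A list of class `"pressure_profile"`: `s_mm`, cumulative
#'   `dp_mmhg` (monotone non-decreasing), its `viscous_mmhg` and
#'   `separation_mmhg` parts, and a `lesions` table.
#' @export
pressure_drop_profile <- function(geometry, ref, flow,
                                  config = mufr_config()) {
  g <- resample_uniform(geometry, config$grid_step)
  s <- g$s_mm
  D <- g$d_mm
  if (any(!is.finite(D)) || any(D <= 0))
    stop("pressure_drop_profile: non-positive diameter on grid",
         call. = FALSE)
  A <- pi * D^2 / 4                       # mm^2, consistent with D
  q <- flow_at(flow, s)                   # mm^3/s

  mu <- config$blood_viscosity
  rho <- config$blood_density
  K <- config$separation_K

  q_m <- q * 1e-9
  # Poiseuille term, integrated exactly over each conical (linear-D)
  # cell of the *measured* profile (original nodes plus flow-segment
  # boundaries, so it does not depend on the reporting grid):
  # int ds / D^4 = (D1^-3 - D2^-3) / (3 b) with slope b
  sb_all <- flow$segments$s_start[-1L]
  sn <- sort(unique(c(geometry$s_mm, sb_all[sb_all > min(s) & sb_all < max(s)])))
  dn <- approx(geometry$s_mm, geometry$d_mm, sn, rule = 2)$y * 1e-3
  qn <- flow_at(flow, sn) * 1e-9
  sn_m <- sn * 1e-3
  nn <- length(sn_m)
  h_c <- diff(sn_m)
  b_c <- diff(dn) / h_c
  d1 <- dn[-nn]; d2 <- dn[-1L]
  cell <- ifelse(abs(b_c) < 1e-12,
                 h_c / d1^4,
                 (d1^-3 - d2^-3) / (3 * b_c))
  visc_n <- c(0, cumsum(128 * mu * qn[-nn] / pi * cell))   # Pa
  visc <- approx(sn, visc_n, s, rule = 2)$y

  a_ref <- pi * predict(ref, s)^2 / 4
  les <- A < config$lesion_area_fraction * a_ref
  sep <- numeric(length(s))
  lesions <- data.frame(s_start = numeric(), s_end = numeric(),
                        a_min_mm2 = numeric(), a_rec_mm2 = numeric(),
                        dp_sep_mmhg = numeric())
  # lesion runs never cross a bifurcation: each flow segment has its own
  # flow, so runs are bounded per segment
  segf <- findInterval(s, flow$segments$s_start[-1L]) + 1L
  r <- rle(paste0(as.integer(les), ".", segf))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(s)
  orig_s <- geometry$s_mm
  orig_a <- pi * geometry$d_mm^2 / 4
  for (k in which(les[starts])) {
    i1 <- starts[k]; i2 <- ends[k]
    imin <- i1 - 1L + which.min(A[i1:i2])
    a_min <- A[imin]
    # sub-sample refinement: parabola through the three measurement
    # samples around the minimum (a sampled profile cannot dip below its
    # nodes, which biases A_min high for deep narrow lesions)
    j0 <- which.min(abs(orig_s - s[imin]))
    seg_of <- function(sx) findInterval(sx, flow$segments$s_start[-1L]) + 1L
    if (j0 > 1L && j0 < length(orig_s) &&
        seg_of(orig_s[j0]) == segf[imin] &&
        orig_a[j0] < orig_a[j0 - 1L] && orig_a[j0] < orig_a[j0 + 1L]) {
      vert <- parabola_min(orig_s[j0 - 1L], orig_a[j0 - 1L],
                           orig_s[j0], orig_a[j0],
                           orig_s[j0 + 1L], orig_a[j0 + 1L])
      if (!is.na(vert) && vert > 0 && vert < a_min) a_min <- vert
    }
    # runs cut by a segment boundary: the minimum may sit at the exact
    # boundary, between grid points
    pwl_area <- function(sx)
      pi * approx(geometry$s_mm, geometry$d_mm, sx, rule = 2)$y^2 / 4
    if (i1 > 1L && segf[i1 - 1L] != segf[i1])
      a_min <- min(a_min, pwl_area(flow$segments$s_start[segf[i1]]))
    if (i2 < n && segf[i2 + 1L] != segf[i2])
      a_min <- min(a_min, pwl_area(flow$segments$s_end[segf[i2]]))
    irec <- min(i2 + 1L, n)
    # grid-independent recovery area: at the exact lesion-threshold
    # crossing, or at the exact segment boundary when the run is cut by
    # a bifurcation
    a_rec <- A[irec]
    if (irec > i2) {
      if (segf[irec] != segf[i2]) {
        sx <- flow$segments$s_end[segf[i2]]
      } else {
        g2 <- A[i2] - config$lesion_area_fraction * a_ref[i2]
        gr <- A[irec] - config$lesion_area_fraction * a_ref[irec]
        sx <- if (gr > g2)
          s[i2] + (s[irec] - s[i2]) * (-g2) / (gr - g2)
        else s[irec]
      }
      d_rec <- approx(geometry$s_mm, geometry$d_mm, sx, rule = 2)$y
      a_rec <- pi * d_rec^2 / 4
    }
    if (a_rec <= a_min) next
    dp <- borda_carnot_local(q_m[imin], a_min * 1e-6,
                             q_m[irec], a_rec * 1e-6, rho, K)
    if (dp <= 0) next
    sep[irec:n] <- sep[irec:n] + dp
    lesions[nrow(lesions) + 1L, ] <-
      list(s[i1], s[irec], a_min, a_rec, dp / MMHG_PA)
  }
  dp <- visc + sep
  structure(list(s_mm = s, dp_mmhg = dp / MMHG_PA,
                 viscous_mmhg = visc / MMHG_PA,
                 separation_mmhg = sep / MMHG_PA,
                 lesions = lesions),
            class = "pressure_profile")
}
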