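# Patient-specific hyperemic flow from the TIMI frame count, divided
# across bifurcations by Murray's law.

#' First frame of contrast arrival at a landmark
#'
#' Front detection on a per-frame contrast-intensity trace: the first
#' frame whose intensity reaches `threshold_fraction` of the trace
#' maximum.  Returns the ordinal frame number (first frame = 1), the
#' convention of TIMI frame counting.
#'
#' @param intensity Per-frame contrast intensity at the landmark.
#' @param threshold_fraction Fraction of the maximum, in (0, 1).
#' @return Ordinal frame number.
#' @examples
#' contrast_arrival_frame(c(0, 0, 1, 5, 9, 10), 0.5) # 4
#' @export
contrast_arrival_frame <- function(intensity, threshold_fraction = 0.5) {
  if (!length(intensity))
    stop("contrast_arrival_frame: empty intensity sequence", call. = FALSE)
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("contrast_arrival_frame: threshold_fraction must be in (0,1)",
         call. = FALSE)
  m <- max(intensity)
  if (m <= 0) stop("no contrast detected", call. = FALSE)
  which(intensity >= threshold_fraction * m)[1L]
}

#' TIMI frame-count contrast velocity
#'
#' Mean contrast-front velocity: `length / (n_frames / fps)`.
#'
#' @param length_mm Distance travelled by the contrast front, mm.
#' @param n_frames Cine frames elapsed; fractional counts allowed.
#' @param fps Cine frame rate, frames/s.
#' @return Velocity, mm/s.
#' @examples
#' timi_velocity(45, 9, 15) # 75 mm/s
#' @export
timi_velocity <- function(length_mm, n_frames, fps) {
  if (!is.numeric(length_mm) || length_mm <= 0)
    stop("timi_velocity: length must be > 0", call. = FALSE)
  if (!is.numeric(n_frames) || n_frames <= 0)
    stop("timi_velocity: n_frames must be > 0", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0)
    stop("timi_velocity: fps must be > 0", call. = FALSE)
  length_mm / (n_frames / fps)
}

#' Convert contrast velocity to hyperemic flow velocity
#'
#' A single configurable multiplier stands in for the empirical
#' contrast-to-hyperemic conversion, with a physiological cap.
#'
#' @param v_contrast Contrast velocity, mm/s.
#' @param multiplier Dimensionless conversion factor.
#' @param cap Maximum hyperemic velocity, mm/s.
#' @return Hyperemic velocity, mm/s.
#' @export
hyperemic_velocity <- function(v_contrast, multiplier = 1.33, cap = 500) {
  if (!is.numeric(v_contrast) || v_contrast <= 0)
    stop("hyperemic_velocity: v_contrast must be > 0", call. = FALSE)
  if (!is.numeric(multiplier) || multiplier <= 0)
    stop("hyperemic_velocity: multiplier must be > 0", call. = FALSE)
  min(multiplier * v_contrast, cap)
}

#' Murray-law flow split across daughter branches
#'
#' Fraction of the mother flow taken by each daughter:
#' `d_i^e / sum(d_j^e)`.
#'
#' @param daughter_diameters Daughter diameters, mm.
#' @param exponent Murray exponent.
#' @return Fractions summing to 1.
#' @examples
#' flow_division(c(2.5, 2)) # 0.6614, 0.3386
#' @export
flow_division <- function(daughter_diameters, exponent = 3) {
  if (!length(daughter_diameters))
    stop("flow_division: at least one daughter required", call. = FALSE)
  if (any(daughter_diameters <= 0))
    stop("flow_division: diameters must be > 0", call. = FALSE)
  p <- daughter_diameters^exponent
  p / sum(p)
}

#' Build the per-segment flow model for a vessel case
#'
#' Inlet flow is the hyperemic velocity times the reference
#' cross-sectional area at the ostium.  At every bifurcation the side
#' branch takes its Murray fraction, computed from the side-branch ostial
#' diameter against the distal-main *reference* diameter (so stenoses do
#' not distort the split); the remainder continues distally.
#'
#' @param case A `"vessel_case"`.
#' @param ref A `"reference_function"`.
#' @param config A [mufr_config()].
#' @return An object of class `"flow_model"` with the contrast and
#'   hyperemic velocities (mm/s), inlet flow (mm^3/s), a `segments` table
#'   (`s_start`, `s_end`, `q_mm3_s`) and a `branches` table.
#' @export
build_flow_model <- function(case, ref, config = mufr_config()) {
  fps <- case$constants$cine_fps
  v_c <- timi_velocity(case$distal_eval_s, case$timi_frame_count, fps)
  v_h <- hyperemic_velocity(v_c, config$hyperemic_multiplier,
                            config$velocity_cap)
  s0 <- ref$domain[1L]
  q0 <- v_h * pi * predict(ref, s0)^2 / 4
  bifs <- ref$step_positions
  sbd <- ref$sb_diameters
  e <- ref$murray_exponent
  q <- numeric(length(bifs) + 1L)
  q[1L] <- q0
  branches <- data.frame(s_mm = numeric(), sb_diameter_mm = numeric(),
                         fraction = numeric(), q_mm3_s = numeric())
  for (j in seq_along(bifs)) {
    d_dist <- predict(ref, bifs[j], side = "distal")
    fr <- flow_division(c(d_dist, sbd[j]), e)
    q[j + 1L] <- q[j] * fr[1L]
    branches[j, ] <- list(bifs[j], sbd[j], fr[2L], q[j] * fr[2L])
  }
  segs <- data.frame(s_start = c(s0, bifs),
                     s_end = c(bifs, ref$domain[2L]),
                     q_mm3_s = q)
  structure(list(contrast_velocity = v_c, hyperemic_velocity = v_h,
                 inlet_flow = q0, segments = segs, branches = branches,
                 multiplier = config$hyperemic_multiplier),
            class = "flow_model")
}

# Flow (mm^3/s) at arbitrary arc length; segments are half-open [start, end).
flow_at <- function(flow, s) {
  j <- findInterval(s, flow$segments$s_start[-1L]) + 1L
  flow$segments$q_mm3_s[j]
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("<flow_model> contrast %.1f mm/s -> hyperemic %.1f mm/s (x%g)\n",
              x$contrast_velocity, x$hyperemic_velocity, x$multiplier))
  cat(sprintf("  inlet flow %.1f mm^3/s over %d segment(s)\n",
              x$inlet_flow, nrow(x$segments)))
  invisible(x)
}
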