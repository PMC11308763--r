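# Landmark-based coregistration of the OCT pullback axis onto the
# angiographic centerline, and fusion of the two geometries.

#' Build the OCT-to-angiography coregistration mapping
#'
#' Monotone piecewise-linear warp through the matched landmark pairs, with
#' linear extrapolation beyond the outermost pairs.  Evaluating at a
#' landmark returns its partner exactly.
#'
#' @param landmarks Data frame with columns `oct_mm` (pullback axis) and
#'   `s_mm` (centerline arc length); >= 2 pairs, strictly increasing on
#'   both axes.
#' @return An object of class `"coreg_mapping"`; evaluate with
#'   [predict.coreg_mapping()].
#' @examples
#' m <- build_mapping(data.frame(oct_mm = c(10, 30), s_mm = c(32, 53)))
#' predict(m, 20) # 42.5
#' @export
build_mapping <- function(landmarks) {
  x <- as.numeric(landmarks$oct_mm)
  y <- as.numeric(landmarks$s_mm)
  if (length(x) < 2L)
    stop("build_mapping: at least 2 landmark pairs required", call. = FALSE)
  if (any(diff(x) <= 0) || any(diff(y) <= 0))
    stop("landmarks must be monotone (strictly increasing on both axes)",
         call. = FALSE)
  structure(list(oct_mm = x, s_mm = y), class = "coreg_mapping")
}

lin_interp_extrap <- function(xk, yk, x) {
  y <- approx(xk, yk, x, rule = 2)$y
  n <- length(xk)
  lo <- x < xk[1L]
  hi <- x > xk[n]
  if (any(lo))
    y[lo] <- yk[1L] + (yk[2L] - yk[1L]) / (xk[2L] - xk[1L]) * (x[lo] - xk[1L])
  if (any(hi))
    y[hi] <- yk[n] + (yk[n] - yk[n - 1L]) / (xk[n] - xk[n - 1L]) * (x[hi] - xk[n])
  y
}

#' Evaluate a coregistration mapping
#'
#' @param object A `"coreg_mapping"`.
#' @param x Positions to map, mm.
#' @param inverse If `TRUE`, map centerline arc length back to pullback
#'   distance.
#' @param ... Unused.
#' @return Mapped positions, mm.
#' @export
predict.coreg_mapping <- function(object, x, inverse = FALSE, ...) {
  if (inverse) lin_interp_extrap(object$s_mm, object$oct_mm, x)
  else lin_interp_extrap(object$oct_mm, object$s_mm, x)
}

#' @export
print.coreg_mapping <- function(x, ...) {
  cat(sprintf("<coreg_mapping> %d landmarks, pullback [%.1f, %.1f] mm -> centerline [%.1f, %.1f] mm\n",
              length(x$oct_mm), min(x$oct_mm), max(x$oct_mm),
              min(x$s_mm), max(x$s_mm)))
  invisible(x)
}

#' Fuse OCT-derived geometry into the angiographic profile
#'
#' Inside the mapped OCT interval the lumen is taken from the OCT areas
#' (circular-equivalent diameter); outside, from angiography.  Within
#' `blend_window` of each junction the two sources are linearly
#' cross-faded so the fused diameter is continuous; with
#' `blend_window = 0` a step discontinuity is allowed at the junctions and
#' downstream hemodynamics treats it as an abrupt area change.  Samples
#' farther than `blend_window` from the OCT interval are bit-identical to
#' the angiographic profile.  Media area is carried through where present.
#'
#' @param angio An [angio_profile()].
#' @param oct An [oct_pullback()].
#' @param mapping A [build_mapping()] result.
#' @param blend_window Half-width of the cross-fade at each junction, mm.
#' @return A data frame of class `"fused_geometry"` with columns `s_mm`,
#'   `d_mm`, `lumen_area_mm2`, `media_area_mm2`, `source`
#'   (`angio`/`oct`/`blend`).
#' @export
fuse_geometry <- function(angio, oct, mapping, blend_window = 1) {
  if (blend_window < 0)
    stop("fuse_geometry: blend_window must be >= 0", call. = FALSE)
  s_oct <- predict(mapping, oct$pullback_mm)
  if (any(diff(s_oct) <= 0))
    stop("fuse_geometry: mapped OCT positions are not increasing",
         call. = FALSE)
  dom <- range(angio$s_mm)
  keep <- s_oct >= dom[1L] - 1e-9 & s_oct <= dom[2L] + 1e-9
  if (!any(keep))
    stop("fuse_geometry: mapped OCT interval is disjoint from the angiographic domain",
         call. = FALSE)
  s_oct <- s_oct[keep]
  lum <- oct$lumen_area_mm2[keep]
  med <- oct$media_area_mm2[keep]
  d_oct <- effective_diameter(lum)
  s_start <- s_oct[1L]
  s_end <- s_oct[length(s_oct)]

  d_a <- function(s) approx(angio$s_mm, angio$d_mm, s, rule = 2)$y
  d_o <- function(s) approx(s_oct, d_oct, s, rule = 2)$y
  med_ok <- !is.na(med)
  m_o <- if (sum(med_ok) >= 2L)
    function(s) approx(s_oct[med_ok], med[med_ok], s, rule = 1)$y
  else function(s) rep(NA_real_, length(s))

  w <- blend_window
  wt <- function(s) {
    if (w == 0) return(as.numeric(s >= s_start & s <= s_end))
    pmax(0, pmin(1, (s - (s_start - w)) / (2 * w),
                 ((s_end + w) - s) / (2 * w)))
  }

  t_a <- wt(angio$s_mm)
  t_f <- wt(s_oct)

  # pure angiographic samples, untouched
  part_angio <- data.frame(s_mm = angio$s_mm[t_a == 0],
                           d_mm = angio$d_mm[t_a == 0],
                           lumen_area_mm2 = pi * angio$d_mm[t_a == 0]^2 / 4,
                           media_area_mm2 = NA_real_,
                           source = "angio")
  # pure OCT samples: original areas kept exactly
  part_oct <- data.frame(s_mm = s_oct[t_f == 1],
                         d_mm = d_oct[t_f == 1],
                         lumen_area_mm2 = lum[t_f == 1],
                         media_area_mm2 = med[t_f == 1],
                         source = "oct")
  # cross-fade zone: union of both sample sets
  sb <- sort(unique(c(angio$s_mm[t_a > 0 & t_a < 1],
                      s_oct[t_f > 0 & t_f < 1])))
  if (length(sb)) {
    tb <- wt(sb)
    db <- (1 - tb) * d_a(sb) + tb * d_o(sb)
    part_blend <- data.frame(s_mm = sb, d_mm = db,
                             lumen_area_mm2 = pi * db^2 / 4,
                             media_area_mm2 = m_o(sb),
                             source = "blend")
  } else part_blend <- NULL

  out <- rbind(part_angio, part_oct, part_blend)
  out <- out[order(out$s_mm), , drop = FALSE]
  out <- out[c(TRUE, diff(out$s_mm) > 1e-9), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "oct_interval") <- c(s_start, s_end)
  attr(out, "blend_window") <- w
  class(out) <- c("fused_geometry", "data.frame")
  out
}

#' Promote an angiographic profile to a fused-geometry container
#'
#' Used for angio-only computation: every sample keeps its angiographic
#' diameter, with the circular-equivalent area and no media.
#'
#' @param angio An [angio_profile()].
#' @return A `"fused_geometry"` data frame with `source = "angio"`.
#' @export
as_fused_geometry <- function(angio) {
  out <- data.frame(s_mm = angio$s_mm, d_mm = angio$d_mm,
                    lumen_area_mm2 = pi * angio$d_mm^2 / 4,
                    media_area_mm2 = NA_real_, source = "angio")
  class(out) <- c("fused_geometry", "data.frame")
  out
}
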