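# The central model function: compute the muQFR / OCT-muFR pullback for a
# vessel case, returning a classed result with the usual S3 methods.

#' Configuration of the muFR computation
#'
#' All tunable parameters in one document.  Defaults: Murray exponent 3;
#' hyperemic multiplier 1.33 with a 500 mm/s cap; aortic pressure 90 mmHg;
#' blood viscosity 0.0035 Pa s, density 1060 kg/m^3; separation
#' coefficient K = 1; integration grid 0.1 mm; fusion blend window 1 mm;
#' healthy-point window 10 mm at quantile 0.75 with plaque-burden
#' threshold 0.6; lesions bounded where lumen area < 0.98 x reference
#' area; positivity cutoffs 0.80 (pressure ratio), 50 (DS%), 70 (AS%).
#'
#' @param ... Named overrides of any default.
#' @return A list of class `"mufr_config"`.
#' @export
mufr_config <- function(...) {
  cfg <- list(
    murray_exponent = 3,
    hyperemic_multiplier = 1.33,
    velocity_cap = 500,
    aortic_pressure = 90,
    blood_viscosity = 0.0035,
    blood_density = 1060,
    separation_K = 1,
    grid_step = 0.1,
    blend_window = 1,
    healthy_window = 10,
    healthy_quantile = 0.75,
    healthy_tolerance = 0.02,
    plaque_burden_threshold = 0.6,
    lesion_area_fraction = 0.98,
    cutoff = 0.80,
    ds_cutoff = 50,
    as_cutoff = 70)
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1L]]) && is.null(names(ov)))
    ov <- ov[[1L]]
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad))
    stop("mufr_config: unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(ov)] <- ov
  stopifnot(cfg$murray_exponent > 0, cfg$hyperemic_multiplier > 0,
            cfg$aortic_pressure > 0, cfg$blood_viscosity > 0,
            cfg$blood_density > 0, cfg$grid_step > 0,
            cfg$blend_window >= 0,
            cfg$separation_K >= 0.5, cfg$separation_K <= 2,
            cfg$lesion_area_fraction > 0, cfg$lesion_area_fraction <= 1,
            cfg$cutoff > 0, cfg$cutoff <= 1)
  class(cfg) <- "mufr_config"
  cfg
}

#' Compute the muQFR / OCT-muFR pullback for a vessel case
#'
#' Runs the full pipeline: (for `mode = "fused"`) landmark coregistration
#' and OCT-angio fusion; healthy-point detection; Murray-law reference
#' reconstruction; TIMI-frame-count flow estimation; 1-D pressure-loss
#' integration.  The pullback value is `(Pa - dP(s)) / Pa` with `Pa` the
#' aortic pressure, 1 at the ostium and non-increasing distally.  The
#' value for each side branch is the main-vessel value at the bifurcation
#' minus the branch's own ostial separation drop (one Borda-Carnot
#' element, side-branch ostial lumen vs its Murray-implied reference).
#'
#' @param case A `"vessel_case"` (see [vessel_case()], [read_case()]).
#' @param mode `"fused"` (OCT-muFR; requires an OCT pullback and
#'   landmarks) or `"angio_only"` (muQFR).
#' @param config A [mufr_config()].
#' @return An object of class `"mufr"` with components `curve`
#'   (`s_mm`, `value`), `distal_value`, `branch_values`,
#'   `segment_deltas`, `stenosis` (DS%, AS%, MLA), `classification`,
#'   `reference`, `flow`, `geometry`, `pressure`, `mode`, `config`.
#' @examples
#' spec <- vessel_spec(length = 40, stenoses = data.frame(
#'   center = 20, width = 2, severity = 0.45))
#' cs <- make_case(spec)
#' fit <- mufr(cs$case, mode = "fused")
#' fit
#' @export
mufr <- function(case, mode = c("fused", "angio_only"),
                 config = mufr_config()) {
  mode <- match.arg(mode)
  validate_case(case)
  if (!inherits(config, "mufr_config")) config <- mufr_config(config)

  if (mode == "fused") {
    if (is.null(case$oct))
      stop("OCT pullback required for mode = \"fused\"", call. = FALSE)
    mapping <- build_mapping(case$landmarks)
    geometry <- fuse_geometry(case$angio, case$oct, mapping,
                              blend_window = config$blend_window)
  } else {
    mapping <- NULL
    geometry <- as_fused_geometry(case$angio)
  }

  healthy <- detect_healthy_points(
    geometry, window = config$healthy_window,
    quantile = config$healthy_quantile,
    tolerance = config$healthy_tolerance,
    plaque_burden_threshold = config$plaque_burden_threshold,
    bifurcations = case$bifurcations)
  ref <- fit_reference(geometry, healthy, case$bifurcations,
                       exponent = config$murray_exponent)
  flow <- build_flow_model(case, ref, config)
  pp <- pressure_drop_profile(geometry, ref, flow, config)

  pa <- case$constants$aortic_pressure
  value <- pmax((pa - pp$dp_mmhg) / pa, 1e-6)
  curve <- data.frame(s_mm = pp$s_mm, value = value)
  val_at <- function(s) approx(curve$s_mm, curve$value, s, rule = 2)$y
  distal_value <- val_at(case$distal_eval_s)

  # side-branch values
  bv <- data.frame(s_mm = numeric(), sb_diameter_mm = numeric(),
                   value = numeric())
  e <- ref$murray_exponent
  for (j in seq_len(nrow(flow$branches))) {
    br <- flow$branches[j, ]
    d_prox <- predict(ref, br$s_mm, side = "proximal")
    d_dist <- predict(ref, br$s_mm, side = "distal")
    d_sb_ref <- max((max(d_prox^e - d_dist^e, 0))^(1 / e), 1e-6)
    a_ost <- pi * br$sb_diameter_mm^2 / 4 * 1e-6      # m^2
    a_ref <- pi * d_sb_ref^2 / 4 * 1e-6
    drop <- if (a_ost < a_ref)
      borda_carnot(br$q_mm3_s * 1e-9, a_ost, a_ref,
                   config$blood_density, config$separation_K) / MMHG_PA
    else 0
    bv[j, ] <- list(br$s_mm, br$sb_diameter_mm,
                    max(val_at(br$s_mm) - drop / pa, 1e-6))
  }

  sd_tab <- pp$lesions
  sd_tab$delta <- if (nrow(sd_tab))
    val_at(sd_tab$s_start) - val_at(sd_tab$s_end) else numeric()

  sten <- percent_stenosis(geometry, ref)
  classification <- list(
    ffr_positive = distal_value <= config$cutoff,
    ds_positive = sten$ds_percent > config$ds_cutoff,
    as_positive = sten$as_percent > config$as_cutoff)

  structure(list(curve = curve, distal_value = distal_value,
                 branch_values = bv, segment_deltas = sd_tab,
                 stenosis = sten, classification = classification,
                 reference = ref, flow = flow, geometry = geometry,
                 healthy = healthy, pressure = pp, mapping = mapping,
                 mode = mode, config = config,
                 distal_eval_s = case$distal_eval_s,
                 aortic_pressure = pa),
            class = "mufr")
}

#' Compute a pullback result (spec-style interface)
#'
#' Alias of [mufr()].
#' @inheritParams mufr
#' @return See [mufr()].
#' @export
compute_pullback <- function(case, mode = c("fused", "angio_only"),
                             config = mufr_config()) {
  mufr(case, mode, config)
}

#' Pressure-ratio delta over a sub-segment
#'
#' `value(s1) - value(s2)`, the drop attributable to the segment
#' `[s1, s2]`; non-negative by monotonicity of the pullback curve.
#'
#' @param result A `"mufr"` object.
#' @param s1,s2 Segment bounds, mm, `0 <= s1 <= s2 <= s_max`.
#' @return The delta value.
#' @export
delta_over_segment <- function(result, s1, s2) {
  smax <- max(result$curve$s_mm)
  if (s1 < -1e-9 || s2 > smax + 1e-9 || s1 > s2)
    stop("delta_over_segment: require 0 <= s1 <= s2 <= s_max", call. = FALSE)
  v <- approx(result$curve$s_mm, result$curve$value, c(s1, s2), rule = 2)$y
  v[1L] - v[2L]
}

# ---- methods ---------------------------------------------------------------

#' @export
print.mufr <- function(x, ...) {
  lab <- if (x$mode == "fused") "OCT-muFR" else "muQFR"
  cat(sprintf("<%s pullback>\n", lab))
  cat(sprintf("  distal value @ %.1f mm : %.3f (%s at cutoff %.2f)\n",
              x$distal_eval_s, x$distal_value,
              if (x$classification$ffr_positive) "positive" else "negative",
              x$config$cutoff))
  cat(sprintf("  DS%% %.1f | AS%% %.1f | MLA %.2f mm^2 @ %.1f mm\n",
              x$stenosis$ds_percent, x$stenosis$as_percent,
              x$stenosis$mla_mm2, x$stenosis$s_mla))
  if (nrow(x$branch_values))
    cat(sprintf("  side branches: %s\n",
                paste(sprintf("%.3f @ %.1f mm", x$branch_values$value,
                              x$branch_values$s_mm), collapse = ", ")))
  invisible(x)
}

#' @export
summary.mufr <- function(object, ...) {
  structure(list(fit = object,
                 n_lesions = nrow(object$segment_deltas),
                 flow = object$flow),
            class = "summary.mufr")
}

#' @export
print.summary.mufr <- function(x, ...) {
  print(x$fit)
  print(x$flow)
  if (x$n_lesions) {
    cat("  lesions:\n")
    sd <- x$fit$segment_deltas
    for (i in seq_len(nrow(sd)))
      cat(sprintf("    [%5.1f, %5.1f] mm  A_min %.2f mm^2  delta %.3f\n",
                  sd$s_start[i], sd$s_end[i], sd$a_min_mm2[i], sd$delta[i]))
  } else cat("  no lesions below the reference envelope\n")
  invisible(x)
}

#' @export
coef.mufr <- function(object, ...) {
  c(distal_value = object$distal_value,
    ds_percent = object$stenosis$ds_percent,
    as_percent = object$stenosis$as_percent,
    mla_mm2 = object$stenosis$mla_mm2)
}

#' Evaluate the pullback curve at arbitrary positions
#'
#' @param object A `"mufr"` object.
#' @param s Arc-length positions, mm (default: the computation grid).
#' @param ... Unused.
#' @return Pressure-ratio values.
#' @export
predict.mufr <- function(object, s = NULL, ...) {
  if (is.null(s)) return(object$curve$value)
  approx(object$curve$s_mm, object$curve$value, s, rule = 2)$y
}

#' Plot a muFR result
#'
#' Two panels: lumen and reference diameter vs arc length (lesions
#' shaded), and the pressure-ratio pullback curve with the positivity
#' cutoff and the distal evaluation point.
#'
#' @param x A `"mufr"` object.
#' @param ... Passed to the curve panel's `plot`.
#' @return `x`, invisibly.
#' @export
plot.mufr <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1), mgp = c(2, 0.7, 0))
  on.exit(par(op))
  g <- x$geometry
  rt <- reference_table(x$reference, step = 0.2)
  plot(g$s_mm, g$d_mm, type = "l", xlab = "", ylab = "diameter (mm)",
       ylim = c(0, max(rt$d_ref_mm, g$d_mm) * 1.05),
       main = if (x$mode == "fused") "OCT-muFR" else "muQFR")
  lines(rt$s_mm, rt$d_ref_mm, lty = 2)
  if (nrow(x$segment_deltas))
    for (i in seq_len(nrow(x$segment_deltas)))
      polygon(c(x$segment_deltas$s_start[i], x$segment_deltas$s_end[i],
                x$segment_deltas$s_end[i], x$segment_deltas$s_start[i]),
              c(0, 0, 100, 100), col = "#00000018", border = NA)
  legend("bottomleft", legend = c("lumen", "reference"), lty = c(1, 2),
         bty = "n", cex = 0.8)
  plot(x$curve$s_mm, x$curve$value, type = "l",
       xlab = "arc length (mm)", ylab = "pressure ratio",
       ylim = c(min(x$curve$value, x$config$cutoff) * 0.95, 1), ...)
  abline(h = x$config$cutoff, lty = 3)
  points(x$distal_eval_s, x$distal_value, pch = 19)
  invisible(x)
}
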