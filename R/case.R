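# Domain types, validation and file I/O for vessel cases.
#
# Conventions: arc length s in mm, 0 at the ostium, increasing distally;
# OCT frame indices 0-based; intervals half-open [start, end); diameters mm,
# areas mm^2, velocities mm/s, pressures mmHg at the I/O boundary.

#' Acquisition constants for a vessel case
#'
#' Bundles the scanner/physiology constants every downstream computation
#' needs: cine frame rate, OCT frame spacing along the pullback, the maximum
#' pullback length the catheter supports, and the fluid parameters of the
#' pressure-loss model.
#'
#' @param cine_fps Cine angiography frame rate, frames/s.
#' @param oct_frame_spacing Pullback distance between consecutive OCT
#'   frames, mm/frame.
#' @param max_pullback_length Maximum motorised pullback length, mm.
#' @param aortic_pressure Assumed aortic (inlet) pressure, mmHg.
#' @param blood_viscosity Dynamic viscosity of blood, Pa s.
#' @param blood_density Blood density, kg/m^3.
#' @return An object of class `"acquisition_constants"`.
#' @examples
#' acquisition_constants(cine_fps = 15)
#' @export
acquisition_constants <- function(cine_fps = 15,
                                  oct_frame_spacing = 0.2,
                                  max_pullback_length = 54,
                                  aortic_pressure = 90,
                                  blood_viscosity = 0.0035,
                                  blood_density = 1060) {
  x <- list(cine_fps = cine_fps,
            oct_frame_spacing = oct_frame_spacing,
            max_pullback_length = max_pullback_length,
            aortic_pressure = aortic_pressure,
            blood_viscosity = blood_viscosity,
            blood_density = blood_density)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("constants: ", nm, " must be a single strictly positive number",
           call. = FALSE)
  }
  structure(x, class = "acquisition_constants")
}

#' Angiographic lumen-diameter profile
#'
#' @param s_mm Arc length from the ostium, mm; strictly increasing, first
#'   value 0.
#' @param d_mm Lumen diameter, mm; strictly positive.
#' @param quality Angiographic image quality flag.
#' @return A data frame of class `"angio_profile"` with columns `s_mm`,
#'   `d_mm` and a `quality` attribute.
#' @export
angio_profile <- function(s_mm, d_mm, quality = c("optimal", "suboptimal")) {
  quality <- match.arg(quality)
  if (length(s_mm) != length(d_mm))
    stop("angio_profile: s_mm and d_mm must have equal length", call. = FALSE)
  if (length(s_mm) < 2L)
    stop("angio_profile: at least 2 samples required", call. = FALSE)
  if (abs(s_mm[1L]) > 1e-9)
    stop("angio_profile: s_mm must start at 0", call. = FALSE)
  if (any(diff(s_mm) <= 0))
    stop("angio_profile: s_mm must be strictly increasing", call. = FALSE)
  if (any(!is.finite(d_mm)) || any(d_mm <= 0))
    stop("angio_profile: d_mm must be > 0", call. = FALSE)
  out <- data.frame(s_mm = as.numeric(s_mm), d_mm = as.numeric(d_mm))
  attr(out, "quality") <- quality
  class(out) <- c("angio_profile", "data.frame")
  out
}

#' OCT pullback frame table
#'
#' Frames are 0-based; pullback distance of frame `i` is
#' `i * frame_spacing`.  Media area, when present, must enclose the lumen.
#'
#' @param lumen_area_mm2 Lumen area per frame, mm^2.
#' @param media_area_mm2 Optional media (external elastic lamina) area per
#'   frame, mm^2; `NA` where not traceable.
#' @param sb_ostium Logical flag per frame: frame intersects a side-branch
#'   ostium.
#' @param frame_spacing Pullback distance between frames, mm.
#' @return A data frame of class `"oct_pullback"` with columns `index`,
#'   `pullback_mm`, `lumen_area_mm2`, `media_area_mm2`, `sb_ostium`.
#' @export
oct_pullback <- function(lumen_area_mm2, media_area_mm2 = NULL,
                         sb_ostium = NULL, frame_spacing = 0.2) {
  n <- length(lumen_area_mm2)
  if (n < 2L) stop("oct_pullback: at least 2 frames required", call. = FALSE)
  if (!is.numeric(frame_spacing) || frame_spacing <= 0)
    stop("oct_pullback: frame_spacing must be > 0", call. = FALSE)
  if (any(!is.finite(lumen_area_mm2)) || any(lumen_area_mm2 <= 0))
    stop("oct_pullback: lumen_area_mm2 must be > 0", call. = FALSE)
  if (is.null(media_area_mm2)) media_area_mm2 <- rep(NA_real_, n)
  if (length(media_area_mm2) != n)
    stop("oct_pullback: media_area_mm2 length mismatch", call. = FALSE)
  bad <- !is.na(media_area_mm2) & media_area_mm2 < lumen_area_mm2 - 1e-9
  if (any(bad))
    stop("oct_pullback: media_area_mm2 must be >= lumen_area_mm2 (frame ",
         which(bad)[1L] - 1L, ")", call. = FALSE)
  if (is.null(sb_ostium)) sb_ostium <- rep(FALSE, n)
  out <- data.frame(index = 0:(n - 1L),
                    pullback_mm = (0:(n - 1L)) * frame_spacing,
                    lumen_area_mm2 = as.numeric(lumen_area_mm2),
                    media_area_mm2 = as.numeric(media_area_mm2),
                    sb_ostium = as.logical(sb_ostium))
  attr(out, "frame_spacing") <- frame_spacing
  class(out) <- c("oct_pullback", "data.frame")
  out
}

#' Assemble a complete vessel case
#'
#' @param angio An [angio_profile()].
#' @param oct An [oct_pullback()] or `NULL` for angio-only cases.
#' @param bifurcations Data frame with columns `s_mm` (position on the
#'   centerline) and `sb_diameter_mm` (side-branch ostial diameter), or
#'   `NULL`.
#' @param landmarks Data frame with columns `oct_mm` (position on the
#'   pullback axis) and `s_mm` (position on the centerline), or `NULL`.
#'   Required (>= 2 pairs) when `oct` is present.
#' @param timi_frame_count Number of cine frames for the contrast front to
#'   travel from the ostium to `distal_eval_s`; fractional counts allowed.
#' @param constants An [acquisition_constants()] object.
#' @param distal_eval_s Arc length at which the distal value is read (the
#'   wire position it is compared against), mm.
#' @return A validated object of class `"vessel_case"`.
#' @seealso [read_case()], [write_case()], [mufr()]
#' @export
vessel_case <- function(angio, oct = NULL, bifurcations = NULL,
                        landmarks = NULL, timi_frame_count,
                        constants = acquisition_constants(),
                        distal_eval_s = max(angio$s_mm)) {
  if (is.null(bifurcations))
    bifurcations <- data.frame(s_mm = numeric(), sb_diameter_mm = numeric())
  if (is.null(landmarks))
    landmarks <- data.frame(oct_mm = numeric(), s_mm = numeric())
  case <- structure(list(angio = angio, oct = oct,
                         bifurcations = as.data.frame(bifurcations),
                         landmarks = as.data.frame(landmarks),
                         timi_frame_count = timi_frame_count,
                         constants = constants,
                         distal_eval_s = distal_eval_s),
                    class = "vessel_case")
  validate_case(case)
}

#' Validate a vessel case against the schema invariants
#'
#' Checks every type invariant and reports all violations at once, each
#' naming the offending field.
#'
#' @param case A `"vessel_case"` object.
#' @return The case, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_case <- function(case) {
  errs <- character()
  say <- function(...) errs[[length(errs) + 1L]] <<- paste0(...)

  a <- case$angio
  if (!is.data.frame(a) || !all(c("s_mm", "d_mm") %in% names(a))) {
    say("angio: must have columns s_mm, d_mm")
  } else {
    if (nrow(a) < 2L) say("angio: at least 2 samples required")
    if (nrow(a) >= 1L && abs(a$s_mm[1L]) > 1e-9) say("angio.s_mm: must start at 0")
    if (any(diff(a$s_mm) <= 0)) say("angio.s_mm: must be strictly increasing")
    bad <- which(!is.finite(a$d_mm) | a$d_mm <= 0)
    if (length(bad)) say("angio.d_mm: must be > 0 (row ", bad[1L], ")")
  }
  smax <- if (is.data.frame(a) && nrow(a)) max(a$s_mm) else NA_real_

  k <- case$constants
  if (!inherits(k, "acquisition_constants")) say("constants: wrong type")

  o <- case$oct
  if (!is.null(o)) {
    if (!all(c("index", "pullback_mm", "lumen_area_mm2") %in% names(o))) {
      say("oct: must have columns index, pullback_mm, lumen_area_mm2")
    } else {
      bad <- which(!is.finite(o$lumen_area_mm2) | o$lumen_area_mm2 <= 0)
      if (length(bad)) say("oct.lumen_area_mm2: must be > 0 (frame ",
                           o$index[bad[1L]], ")")
      if ("media_area_mm2" %in% names(o)) {
        bad <- which(!is.na(o$media_area_mm2) &
                       o$media_area_mm2 < o$lumen_area_mm2 - 1e-9)
        if (length(bad)) say("oct.media_area_mm2: must be >= lumen_area_mm2",
                             " (frame ", o$index[bad[1L]], ")")
      }
      sp <- attr(o, "frame_spacing")
      if (!is.null(sp) && inherits(k, "acquisition_constants")) {
        if (max(o$pullback_mm) > k$max_pullback_length + 1e-9)
          say("oct: pullback length exceeds max_pullback_length")
        if (any(abs(o$pullback_mm - o$index * sp) > 1e-9))
          say("oct.pullback_mm: must equal index * frame_spacing")
      }
    }
  }

  b <- case$bifurcations
  if (nrow(b)) {
    if (!all(c("s_mm", "sb_diameter_mm") %in% names(b))) {
      say("bifurcations: must have columns s_mm, sb_diameter_mm")
    } else {
      bad <- which(b$s_mm <= 0 | b$s_mm >= smax)
      if (length(bad)) say("bifurcations.s_mm: must lie strictly inside ",
                           "the vessel (row ", bad[1L], ")")
      bad <- which(!is.finite(b$sb_diameter_mm) | b$sb_diameter_mm <= 0)
      if (length(bad)) say("bifurcations.sb_diameter_mm: must be > 0 (row ",
                           bad[1L], ")")
      if (any(diff(sort(b$s_mm)) <= 0)) say("bifurcations.s_mm: duplicated")
    }
  }

  lm <- case$landmarks
  if (nrow(lm)) {
    if (!all(c("oct_mm", "s_mm") %in% names(lm))) {
      say("landmarks: must have columns oct_mm, s_mm")
    } else if (nrow(lm) >= 2L &&
               (any(diff(lm$oct_mm) <= 0) || any(diff(lm$s_mm) <= 0))) {
      say("landmarks: must be jointly strictly increasing on both axes")
    }
  }
  if (!is.null(o) && nrow(lm) < 2L)
    say("landmarks: at least 2 pairs required when an OCT pullback is present")

  tf <- case$timi_frame_count
  if (!is.numeric(tf) || length(tf) != 1L || !is.finite(tf) || tf <= 0)
    say("timi_frame_count: must be a single positive number")

  de <- case$distal_eval_s
  if (!is.numeric(de) || length(de) != 1L || !is.finite(de) ||
      de <= 0 || (is.finite(smax) && de > smax + 1e-9))
    say("distal_eval_s: must lie in (0, max(angio.s_mm)]")

  if (length(errs))
    stop("invalid vessel case:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(case)
}

#' @export
print.vessel_case <- function(x, ...) {
  cat("<vessel_case>\n")
  cat(sprintf("  angio profile : %d samples over %.1f mm (%s quality)\n",
              nrow(x$angio), max(x$angio$s_mm),
              attr(x$angio, "quality") %||% "optimal"))
  if (is.null(x$oct)) cat("  OCT pullback  : absent\n")
  else cat(sprintf("  OCT pullback  : %d frames, %.1f mm covered\n",
                   nrow(x$oct), max(x$oct$pullback_mm)))
  cat(sprintf("  bifurcations  : %d   landmarks: %d\n",
              nrow(x$bifurcations), nrow(x$landmarks)))
  cat(sprintf("  TIMI frames   : %.2f @ %g fps   distal eval: %.1f mm\n",
              x$timi_frame_count, x$constants$cine_fps, x$distal_eval_s))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- file I/O ---------------------------------------------------------------

# A case file is one YAML document; tabular sections may alternatively point
# to a delimiter-separated file (path relative to the case file) with the
# same column headers.

read_tabular_section <- function(x, dir) {
  if (is.character(x) && length(x) == 1L) {
    p <- file.path(dir, x)
    if (!file.exists(p)) stop("case file: referenced table not found: ", x,
                              call. = FALSE)
    return(read.delim(p, sep = "\t", check.names = FALSE))
  }
  x
}

#' Read a vessel case file
#'
#' The case schema is one YAML document with sections `constants`,
#' `angio_profile` (`s_mm`, `d_mm`), `oct_frames` (`index`,
#' `lumen_area_mm2`, optional `media_area_mm2`, `sb_ostium`),
#' `bifurcations`, `landmarks`, `timi_frame_count` and `distal_eval_s`.
#' Tabular sections may be inline column vectors or a path to a
#' tab-separated file with the same headers.  All schema invariants are
#' validated on read; violations are reported with field paths.
#'
#' @param path Path to a case file written by [write_case()] (or conforming
#'   to the schema).
#' @return A `"vessel_case"` object.
#' @export
read_case <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  dir <- dirname(path)

  need <- c("constants", "angio_profile", "timi_frame_count", "distal_eval_s")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("case file: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  kc <- doc$constants
  constants <- do.call(acquisition_constants,
                       kc[intersect(names(kc),
                                    names(formals(acquisition_constants)))])

  ap <- read_tabular_section(doc$angio_profile, dir)
  if (is.null(ap$s_mm) || is.null(ap$d_mm))
    stop("case file: angio_profile requires s_mm and d_mm", call. = FALSE)
  angio <- angio_profile(as.numeric(ap$s_mm), as.numeric(ap$d_mm),
                         quality = ap$quality %||% doc$quality %||% "optimal")

  oct <- NULL
  if (!is.null(doc$oct_frames)) {
    of <- read_tabular_section(doc$oct_frames, dir)
    sp <- of$frame_spacing_mm %||% constants$oct_frame_spacing
    med <- of$media_area_mm2
    if (!is.null(med)) med <- as.numeric(med)
    oct <- oct_pullback(as.numeric(of$lumen_area_mm2), med,
                        sb_ostium = as.logical(of$sb_ostium %||% FALSE),
                        frame_spacing = as.numeric(sp))
  }

  bif <- NULL
  if (!is.null(doc$bifurcations) && length(doc$bifurcations$s_mm)) {
    bf <- read_tabular_section(doc$bifurcations, dir)
    bif <- data.frame(s_mm = as.numeric(bf$s_mm),
                      sb_diameter_mm = as.numeric(bf$sb_diameter_mm))
  }
  lmk <- NULL
  if (!is.null(doc$landmarks) && length(doc$landmarks$oct_mm)) {
    lk <- read_tabular_section(doc$landmarks, dir)
    lmk <- data.frame(oct_mm = as.numeric(lk$oct_mm),
                      s_mm = as.numeric(lk$s_mm))
  }

  vessel_case(angio = angio, oct = oct, bifurcations = bif, landmarks = lmk,
              timi_frame_count = as.numeric(doc$timi_frame_count),
              constants = constants,
              distal_eval_s = as.numeric(doc$distal_eval_s))
}

#' Write a vessel case file
#'
#' Inverse of [read_case()]; the round trip is lossless to 1e-6 mm / mm^2.
#'
#' @param case A `"vessel_case"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  validate_case(case)
  doc <- list(
    constants = unclass(case$constants),
    angio_profile = list(s_mm = case$angio$s_mm, d_mm = case$angio$d_mm,
                         quality = attr(case$angio, "quality") %||% "optimal"),
    timi_frame_count = case$timi_frame_count,
    distal_eval_s = case$distal_eval_s)
  if (!is.null(case$oct)) {
    doc$oct_frames <- list(
      frame_spacing_mm = attr(case$oct, "frame_spacing"),
      lumen_area_mm2 = case$oct$lumen_area_mm2,
      media_area_mm2 = case$oct$media_area_mm2,
      sb_ostium = case$oct$sb_ostium)
  }
  if (nrow(case$bifurcations))
    doc$bifurcations <- list(s_mm = case$bifurcations$s_mm,
                             sb_diameter_mm = case$bifurcations$sb_diameter_mm)
  if (nrow(case$landmarks))
    doc$landmarks <- list(oct_mm = case$landmarks$oct_mm,
                          s_mm = case$landmarks$s_mm)
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

# ---- geometry helpers -------------------------------------------------------

#' Circular-equivalent diameter of a lumen area
#'
#' Links OCT cross-sectional areas to angiographic diameters:
#' `d = 2 * sqrt(area / pi)`.
#'
#' @param area Lumen area(s), mm^2; strictly positive.
#' @return Diameter(s), mm.
#' @examples
#' effective_diameter(pi) # 2 mm
#' @export
effective_diameter <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0))
    stop("effective_diameter: area must be > 0", call. = FALSE)
  2 * sqrt(area / pi)
}

#' Resample a profile onto a uniform arc-length grid
#'
#' Linear interpolation of every numeric column against `s_mm`; endpoints
#' are preserved exactly (the final point is appended when the vessel
#' length is not a multiple of `step`).  Character columns (e.g. the
#' `source` provenance flag of a fused geometry) take the value of the
#' nearest original sample.
#'
#' @param profile A data frame with an `s_mm` column ([angio_profile()] or
#'   [fuse_geometry()] output).
#' @param step Grid step, mm.
#' @return A data frame of the same class on the uniform grid.
#' @export
resample_uniform <- function(profile, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("resample_uniform: step must be > 0", call. = FALSE)
  s <- profile$s_mm
  if (length(s) < 2L)
    stop("resample_uniform: profile needs >= 2 samples", call. = FALSE)
  span <- s[length(s)] - s[1L]
  if (step >= span)
    stop("resample_uniform: step must be smaller than the vessel length",
         call. = FALSE)
  grid <- seq(s[1L], s[length(s)], by = step)
  if (s[length(s)] - grid[length(grid)] > 1e-9)
    grid <- c(grid, s[length(s)])
  out <- data.frame(s_mm = grid)
  for (nm in setdiff(names(profile), "s_mm")) {
    col <- profile[[nm]]
    if (is.numeric(col)) {
      ok <- !is.na(col)
      if (sum(ok) >= 2L) {
        y <- approx(s[ok], col[ok], grid, rule = 1)$y
      } else y <- rep(NA_real_, length(grid))
      out[[nm]] <- y
    } else {
      idx <- vapply(grid, function(g) which.min(abs(s - g)), integer(1L))
      out[[nm]] <- col[idx]
    }
  }
  for (at in setdiff(names(attributes(profile)),
                     c("names", "row.names", "class")))
    attr(out, at) <- attr(profile, at)
  class(out) <- class(profile)
  out
}
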