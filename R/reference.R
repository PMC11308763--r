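# Reconstruction of the reference ("non-diseased") diameter function with
# Murray-law step-downs across bifurcations.

#' Murray-law mother diameter from daughter diameters
#'
#' `(sum(d_i^e))^(1/e)` with the fractal exponent `e` (classically 3).
#'
#' @param daughters Daughter diameters, mm; all > 0.
#' @param exponent Fractal exponent, dimensionless.
#' @return Mother diameter, mm.
#' @examples
#' murray_mother_diameter(c(3, 2)) # 35^(1/3)
#' @export
murray_mother_diameter <- function(daughters, exponent = 3) {
  if (length(daughters) < 1L)
    stop("murray_mother_diameter: at least one daughter required",
         call. = FALSE)
  if (any(!is.finite(daughters)) || any(daughters <= 0))
    stop("murray_mother_diameter: daughters must be > 0", call. = FALSE)
  if (!is.numeric(exponent) || exponent <= 0)
    stop("murray_mother_diameter: exponent must be > 0", call. = FALSE)
  sum(daughters^exponent)^(1 / exponent)
}

#' Murray-law distal main-branch diameter (algebraic inverse)
#'
#' `(mother^e - sb^e)^(1/e)`: the diameter the main branch should step
#' down to distal to a bifurcation that gives off a side branch.
#'
#' @param mother Mother (proximal main) diameter, mm.
#' @param side_branch Side-branch ostial diameter, mm; must be smaller
#'   than `mother`.
#' @param exponent Fractal exponent.
#' @return Distal main-branch diameter, mm.
#' @export
murray_distal_diameter <- function(mother, side_branch, exponent = 3) {
  if (any(side_branch >= mother))
    stop("murray_distal_diameter: side branch must be smaller than mother",
         call. = FALSE)
  (mother^exponent - side_branch^exponent)^(1 / exponent)
}

#' Flag healthy (non-diseased) samples of a lumen profile
#'
#' A sample is healthy when its diameter reaches the local upper envelope:
#' `d >= (1 - tolerance) * quantile(d in a centered window, q)`.  The
#' caliber tolerance absorbs the natural taper across the window and
#' measurement noise, without which a tapering healthy vessel would keep
#' only the locally-largest quarter of its samples.  Windows are clipped
#' at bifurcation positions so the Murray step-down does not masquerade
#' as disease.  Where OCT media area is available the plaque-burden rule
#' takes precedence: healthy iff `lumen_area / media_area >= threshold`.
#'
#' @param profile A `"fused_geometry"` (or any data frame with `s_mm`,
#'   `d_mm`, optionally `lumen_area_mm2`, `media_area_mm2`).
#' @param window Window width, mm.
#' @param quantile Quantile defining the local envelope, in (0, 1).
#' @param tolerance Relative caliber tolerance on the envelope.
#' @param plaque_burden_threshold Minimum lumen/media area ratio for a
#'   sample to count as healthy under the media rule.
#' @param bifurcations Optional data frame with `s_mm` column; windows do
#'   not cross these positions.
#' @return Logical vector, one flag per sample.
#' @export
detect_healthy_points <- function(profile, window = 10, quantile = 0.75,
                                  tolerance = 0.02,
                                  plaque_burden_threshold = 0.6,
                                  bifurcations = NULL) {
  s <- profile$s_mm
  d <- profile$d_mm
  if (!length(s)) stop("detect_healthy_points: empty profile", call. = FALSE)
  if (window <= 0) stop("detect_healthy_points: window must be > 0",
                        call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("detect_healthy_points: quantile must be in (0,1)", call. = FALSE)
  breaks <- if (!is.null(bifurcations) && nrow(bifurcations))
    sort(bifurcations$s_mm) else numeric()
  seg <- findInterval(s, breaks)
  half <- window / 2
  healthy <- logical(length(s))
  for (i in seq_along(s)) {
    idx <- which(seg == seg[i] & abs(s - s[i]) <= half + 1e-12)
    q <- stats::quantile(d[idx], probs = quantile, names = FALSE)
    healthy[i] <- d[i] >= q * (1 - tolerance) - 1e-9
  }
  med <- profile$media_area_mm2
  lum <- profile$lumen_area_mm2
  if (!is.null(med) && !is.null(lum)) {
    has <- !is.na(med) & med > 0
    healthy[has] <- lum[has] / med[has] >= plaque_burden_threshold - 1e-12
  }
  healthy
}

# High-breakdown upper-envelope line fit.  Healthy-point detection can
# leave leverage contamination (a broad lesion filling a window flags its
# own interior as locally healthy), which plain L1 regression does not
# resist.  Deterministic elemental-pair search: candidate lines through
# pairs of well-separated points are scored by the number of samples
# inside a relative band minus twice the number above it (an envelope has
# nothing above it), and the winner is polished by LAD on its inliers.
envelope_fit <- function(x, y, band = 0.03) {
  n <- length(x)
  if (n < 8L || diff(range(x)) < 1e-9) return(lad_fit(x, y))
  idx <- unique(round(seq(1L, n, length.out = min(25L, n))))
  cand <- NULL
  best <- -Inf
  span <- diff(range(x))
  for (i in idx) for (j in idx) {
    if (x[j] - x[i] < 0.2 * span) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    f <- a + b * x
    r <- (y - f) / pmax(abs(f), 1e-9)
    score <- sum(abs(r) <= band) - 2 * sum(r > band)
    if (score > best) { best <- score; cand <- c(a, b) }
  }
  if (is.null(cand)) return(lad_fit(x, y))
  f <- cand[1L] + cand[2L] * x
  inl <- abs((y - f) / pmax(abs(f), 1e-9)) <= band
  if (sum(inl) >= 2L) lad_fit(x[inl], y[inl]) else cand
}

# Least-absolute-deviation straight-line fit via iteratively reweighted
# least squares.  Returns c(intercept, slope).
lad_fit <- function(x, y, iters = 60L, delta = 1e-8) {
  if (length(x) < 2L || diff(range(x)) < 1e-12)
    return(c(median(y), 0))
  X <- cbind(1, x)
  w <- rep(1, length(x))
  beta <- c(0, 0)
  for (k in seq_len(iters)) {
    fit <- lm.wfit(X, y, w)
    new <- fit$coefficients
    new[is.na(new)] <- 0
    if (max(abs(new - beta)) < 1e-12) { beta <- new; break }
    beta <- new
    r <- as.numeric(y - X %*% beta)
    w <- 1 / pmax(abs(r), delta)
  }
  as.numeric(beta)
}

#' Fit the reference (non-diseased) diameter function
#'
#' Produces a piecewise-linear reference diameter d_ref(s): one linear
#' taper trend per inter-bifurcation segment, with a Murray-law step-down
#' at every bifurcation.  Healthy diameters are normalised by the
#' cumulative Murray step factor of their segment, a single robust
#' (least-absolute-deviation) line is fitted to the normalised data, and
#' the per-segment lines are that line times the factors; the factors are
#' iterated to a fixed point so the step at each bifurcation satisfies
#' `d_prox^e = d_dist^e + d_sb^e` exactly.  Segments without healthy
#' samples inherit the reference propagated across the adjacent
#' bifurcations by the same relation.  The reference is clipped below at
#' half the observed maximum diameter to avoid degenerate fits.
#'
#' @param profile A `"fused_geometry"`.
#' @param healthy Logical mask from [detect_healthy_points()].
#' @param bifurcations Data frame with `s_mm`, `sb_diameter_mm`, or `NULL`.
#' @param exponent Murray exponent (default 3; some fractal-law variants
#'   use ~2.55).
#' @param floor_fraction Lower clip as a fraction of the observed maximum
#'   diameter.
#' @param trim One-sided envelope trim: samples falling more than this
#'   fraction below the current fit are excluded and the fit repeated, so
#'   diffuse disease wider than the healthy-detection window cannot drag
#'   the reference down.
#' @return An object of class `"reference_function"`; evaluate with
#'   [predict.reference_function()].
#' @export
fit_reference <- function(profile, healthy, bifurcations = NULL,
                          exponent = 3, floor_fraction = 0.5,
                          trim = 0.03) {
  s <- profile$s_mm
  d <- profile$d_mm
  if (sum(healthy) < 2L)
    stop("reference underdetermined: fewer than 2 healthy samples",
         call. = FALSE)
  if (is.null(bifurcations))
    bifurcations <- data.frame(s_mm = numeric(), sb_diameter_mm = numeric())
  bifurcations <- bifurcations[order(bifurcations$s_mm), , drop = FALSE]
  bifs <- bifurcations$s_mm
  sbd <- bifurcations$sb_diameter_mm
  nseg <- length(bifs) + 1L
  seg <- findInterval(s, bifs) + 1L

  # reference evidence: media-derived diameter where OCT media is
  # available (healthy wall encloses the non-diseased lumen), lumen
  # diameter elsewhere
  ev <- d
  med <- profile$media_area_mm2
  if (!is.null(med)) {
    has <- !is.na(med) & med > 0
    ev[has] <- 2 * sqrt(med[has] / pi)
  }

  hs <- s[healthy]
  hd <- ev[healthy]
  hseg <- seg[healthy]

  fac <- rep(1, nseg)
  keep <- rep(TRUE, length(hs))
  g <- c(max(hd), 0)
  for (iter in 1:60) {
    g <- envelope_fit(hs[keep], (hd / fac[hseg])[keep])
    newfac <- rep(1, nseg)
    for (j in seq_along(bifs)) {
      dpx <- newfac[j] * (g[1] + g[2] * bifs[j])
      dpx <- max(dpx, 1e-6)
      # guarded Murray inverse: distal main never below 20% of the mother
      ratio <- (max(dpx^exponent - sbd[j]^exponent,
                    (0.2 * dpx)^exponent))^(1 / exponent) / dpx
      newfac[j + 1L] <- newfac[j] * ratio
    }
    fitline <- g[1] + g[2] * hs
    newkeep <- hd / newfac[hseg] >= fitline * (1 - trim) - 1e-9
    if (sum(newkeep) < 2L) newkeep <- keep
    if (max(abs(newfac - fac)) < 1e-13 && identical(newkeep, keep)) {
      fac <- newfac
      break
    }
    fac <- newfac
    keep <- newkeep
  }

  segs <- data.frame(
    s_start = c(s[1L], bifs),
    s_end = c(bifs, s[length(s)]),
    a = fac * g[1],
    b = fac * g[2])
  structure(list(segments = segs, step_positions = bifs,
                 sb_diameters = sbd, murray_exponent = exponent,
                 trend = g, factors = fac,
                 floor = floor_fraction * max(d),
                 domain = range(s)),
            class = "reference_function")
}

#' Evaluate a reference diameter function
#'
#' Segments are half-open `[start, end)`: evaluating exactly at a
#' bifurcation returns the distal (stepped-down) piece.  Use
#' `side = "proximal"` for the limit from the left.
#'
#' @param object A `"reference_function"`.
#' @param s Arc-length positions, mm.
#' @param side Which piece to use at exact step positions.
#' @param ... Unused.
#' @return Reference diameters, mm.
#' @export
predict.reference_function <- function(object, s,
                                       side = c("distal", "proximal"), ...) {
  side <- match.arg(side)
  bp <- object$step_positions
  j <- if (side == "distal") findInterval(s, bp) + 1L
  else findInterval(s, bp, left.open = TRUE) + 1L
  val <- object$segments$a[j] + object$segments$b[j] * s
  pmax(val, object$floor)
}

#' @export
print.reference_function <- function(x, ...) {
  cat(sprintf("<reference_function> %d segment(s), Murray exponent %g\n",
              nrow(x$segments), x$murray_exponent))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  [%6.2f, %6.2f) mm : d_ref = %.4f %+.5f * s\n",
                x$segments$s_start[i], x$segments$s_end[i],
                x$segments$a[i], x$segments$b[i]))
  invisible(x)
}

#' Export a reference function as a table
#'
#' @param ref A `"reference_function"`.
#' @param step Grid step, mm.
#' @return Data frame with `s_mm`, `d_ref_mm`.
#' @export
reference_table <- function(ref, step = 0.1) {
  s <- seq(ref$domain[1L], ref$domain[2L], by = step)
  data.frame(s_mm = s, d_ref_mm = predict(ref, s))
}

#' Percent diameter / area stenosis against a reference
#'
#' `DS% = (1 - d/d_ref) * 100` at the arc length minimising `d/d_ref`;
#' `AS% = (1 - A_mla/A_ref) * 100` at the minimal-lumen-area position,
#' with `A_ref = pi d_ref^2 / 4`.  Both are floored at 0 for
#' super-reference lumina.
#'
#' @param profile A `"fused_geometry"`.
#' @param ref A `"reference_function"`.
#' @return List with `ds_percent`, `as_percent`, `s_mla`, `mla_mm2`,
#'   `s_ds`.
#' @export
percent_stenosis <- function(profile, ref) {
  s <- profile$s_mm
  d <- profile$d_mm
  A <- profile$lumen_area_mm2
  dref <- predict(ref, s)
  ratio <- d / dref
  i <- which.min(ratio)
  ia <- which.min(A)
  a_ref <- pi * dref[ia]^2 / 4
  list(ds_percent = max(0, (1 - ratio[i]) * 100),
       as_percent = max(0, (1 - A[ia] / a_ref) * 100),
       s_mla = s[ia], mla_mm2 = A[ia], s_ds = s[i])
}
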