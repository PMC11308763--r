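# Shared fixtures and independent oracles for the test suite.

# straight healthy tube: D = 3 mm, L = 50 mm; TIMI count chosen so the
# hyperemic velocity is exactly 300 mm/s under the default 1.33 multiplier
straight_case <- function(d = 3, len = 50, v_h = 300, spacing = 0.2) {
  s <- seq(0, len, by = spacing)
  ap <- angio_profile(s, rep(d, length(s)))
  vessel_case(ap, timi_frame_count = 15 * len / (v_h / 1.33),
              distal_eval_s = len)
}

# single-lesion synthetic spec with aligned OCT coverage
lesion_spec <- function(seed, severity = 0.5, width = 2, with_media = TRUE,
                        len = 50) {
  set.seed(seed + 5000)
  vessel_spec(length = len,
              inlet_diameter = runif(1, 2.8, 3.8),
              taper = runif(1, 0.005, 0.025),
              stenoses = data.frame(center = runif(1, 15, len - 12),
                                    width = width, severity = severity),
              oct_coverage = c(2, len - 2),
              with_media = with_media,
              contrast_velocity = runif(1, 150, 300),
              seed = seed)
}

# exhaustive pair-counting AUC oracle (ties count 1/2)
auc_pairs <- function(scores, labels, direction = "lower") {
  x <- if (direction == "lower") -scores else scores
  pos <- x[as.logical(labels)]
  neg <- x[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# grouped (per-class delete-one) jackknife variance of the AUC,
# recomputed by brute force
auc_jackknife_var <- function(scores, labels, direction = "lower") {
  labels <- as.logical(labels)
  ip <- which(labels); ineg <- which(!labels)
  jack <- function(idx_set) {
    th <- vapply(idx_set, function(i)
      auc_pairs(scores[-i], labels[-i], direction), numeric(1))
    m <- length(idx_set)
    (m - 1) / m * sum((th - mean(th))^2)
  }
  jack(ip) + jack(ineg)
}

# closed-form viscous pressure drop (Pa) over a conical segment
# D(s) = d0 + b s, s in [0, L] (SI inputs)
cone_viscous <- function(q, d0, d1, len, mu = 0.0035) {
  b <- (d1 - d0) / len
  if (abs(b) < 1e-15) return(128 * mu * q * len / (pi * d0^4))
  128 * mu * q / pi * (d0^-3 - d1^-3) / (3 * b)
}

MMHG <- 133.322
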