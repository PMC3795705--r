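# Independent oracles used across the suite.

# Analytic Fourier-series solution for a slab with both faces clamped to C0
# and zero initial condition.
slab_series <- function(h, D, C0, t, x, terms = 100) {
  s <- 0
  for (n in 0:(terms - 1)) {
    k <- 2 * n + 1
    s <- s + (4 / (k * pi)) * sin(k * pi * x / h) * exp(-D * (k * pi / h)^2 * t)
  }
  C0 * (1 - s)
}

# Brute-force per-pixel ROI classifier: for every pixel of the image, walk
# the two 2-segment border polylines explicitly, compute the normalized
# depth at the pixel center and classify with nested interval logic (ties
# toward the disc center). Deliberately scalar and structured differently
# from the vectorized production rasterizer.
brute_force_rois <- function(lms, shape) {
  nr <- shape[1]; nc <- shape[2]
  eval_border <- function(pts, xc) {
    if (xc <= pts[2, 2]) {
      p1 <- pts[1, ]; p2 <- pts[2, ]
    } else {
      p1 <- pts[2, ]; p2 <- pts[3, ]
    }
    p1[1] + (p2[1] - p1[1]) * (xc - p1[2]) / (p2[2] - p1[2])
  }
  labels <- c("EPZ_upper", "Peripheral_upper", "Central",
              "Peripheral_lower", "EPZ_lower", "SCB_upper", "SCB_lower")
  masks <- lapply(labels, function(l) matrix(FALSE, nr, nc))
  names(masks) <- labels
  c_lo <- max(lms$upper[1, 2], lms$lower[1, 2])
  c_hi <- min(lms$upper[3, 2], lms$lower[3, 2])
  for (col in 0:(nc - 1)) {
    if (col < ceiling(c_lo) || col > floor(c_hi)) next
    yu <- eval_border(lms$upper, col)
    yl <- eval_border(lms$lower, col)
    for (row in 0:(nr - 1)) {
      u <- (row - yu) / (yl - yu)
      if (u >= 0 && u <= 1) {
        band <- if (u < 0.5) {
          if (u < 0.2) "EPZ_upper"
          else if (u < 0.4) "Peripheral_upper"
          else "Central"
        } else {
          ud <- 1 - u
          if (ud < 0.2) "EPZ_lower"
          else if (ud < 0.4) "Peripheral_lower"
          else "Central"
        }
        masks[[band]][row + 1, col + 1] <- TRUE
      }
      if (yu - row > 1 && yu - row <= 7)
        masks[["SCB_upper"]][row + 1, col + 1] <- TRUE
      if (row - yl > 1 && row - yl <= 7)
        masks[["SCB_lower"]][row + 1, col + 1] <- TRUE
    }
  }
  masks
}

# Random valid quadrilateral disc landmark set inside a given image shape.
random_quad_landmarks <- function(shape, spacing = 0.83, id = "DX") {
  nr <- shape[1]; nc <- shape[2]
  c0 <- runif(1, 10, 20)
  c1 <- c0 + runif(1, 25, nc - 25 - c0)
  cB <- (c0 + c1) / 2
  yu0 <- runif(1, 25, nr - 45)
  tilt <- runif(1, -0.15, 0.15)
  h_px <- runif(1, 6, 20)
  upper <- rbind(c(yu0 + tilt * (c0 - cB), c0),
                 c(yu0 - runif(1, 0, 2), cB),
                 c(yu0 + tilt * (c1 - cB), c1))
  lower <- rbind(c(upper[1, 1] + h_px + runif(1, -1, 1), c0),
                 c(yu0 + h_px + runif(1, 0, 2), cB),
                 c(upper[3, 1] + h_px + runif(1, -1, 1), c1))
  landmark_set(id, upper, lower, spacing)
}

# Small, fast phantom configuration for tests that just need images.
small_config <- function(n_levels = 2, ...) {
  phantom_config(n_levels = n_levels, vb_px = 16, margin_px = 6, ...)
}

# Planted-effect cohort configuration: heights uniform on [5, 14] mm,
# independent of grade; Modic changes with probability 0.25 at every grade;
# no endplate defects or irregular endplates.
uniform_cohort_config <- function(mc_prob = rep(0.25, 5), ...) {
  phantom_config(height_model = "uniform", mc_prob = mc_prob,
                 defect_prob = 0, irregular_prob = 0, spondy_prob = 0, ...)
}
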