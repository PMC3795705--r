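## Synthetic sagittal spine phantom: stacked vertebral bodies and discs with
## ground-truth geometry, contrast kinetics and additive Gaussian noise.

#' Specification of one synthetic disc
#'
#' @param height disc height (mm), > 0.
#' @param pfirrmann degeneration surrogate grade, integer 1-5.
#' @param hydration nucleus hydration in [0, 1]; drives T2 brightness.
#' @param mc_upper,mc_lower Modic change type per endplate, one of
#'   `"0"`, `"I"`, `"II"`, `"I/II"`.
#' @param defect_upper,defect_lower logical endplate defect (Schmorl's node)
#'   flags.
#' @param irregular logical "irregular endplate" flag.
#' @param spondylolisthesis logical severe spondylolisthesis flag.
#' @return object of class `disc_spec`.
#' @export
disc_spec <- function(height, pfirrmann = 1L, hydration = 0.9,
                      mc_upper = "0", mc_lower = "0",
                      defect_upper = FALSE, defect_lower = FALSE,
                      irregular = FALSE, spondylolisthesis = FALSE) {
  if (height <= 0) stop("disc height must be > 0")
  if (hydration < 0 || hydration > 1) stop("hydration must be in [0, 1]")
  if (!pfirrmann %in% 1:5) stop("pfirrmann grade must be in 1..5")
  mc_levels <- c("0", "I", "II", "I/II")
  if (!mc_upper %in% mc_levels || !mc_lower %in% mc_levels)
    stop("MC type must be one of '0', 'I', 'II', 'I/II'")
  structure(list(height = height, pfirrmann = as.integer(pfirrmann),
                 hydration = hydration, mc_upper = mc_upper,
                 mc_lower = mc_lower, defect_upper = defect_upper,
                 defect_lower = defect_lower, irregular = irregular,
                 spondylolisthesis = spondylolisthesis),
            class = "disc_spec")
}

#' Phantom configuration
#'
#' Geometry, signal model, acquisition schedule and cohort distributions for
#' the synthetic spine phantom. Defaults reproduce the acquisition geometry
#' of a sagittal lumbar protocol (0.83 mm pixels; PRE plus post-contrast
#' scans at 5 min, 10 min, 2 h, 4 h, 6 h) and a noise level at which the
#' ROI-mean enhancement of a central disc ROI of roughly 100-200 pixels has
#' a standard deviation of order 8 signal units on a PRE baseline of 99.
#'
#' Cohort distributions: with `height_model = "grade"` disc height and
#' hydration decrease monotonically with the Pfirrmann surrogate grade and
#' endplate permeability increases mildly with grade; with
#' `height_model = "uniform"` heights are uniform on `height_range`,
#' independent of grade, and kinetics are identical for all avascular discs
#' (the cleanest design for planted-effect recovery studies). Discs with
#' Modic changes (probability `mc_prob[grade]`) or an irregular endplate
#' receive a nonzero perfusion rate (`v_mc`, `v_irregular`).
#'
#' @param grid_cols image width in pixels.
#' @param pixel_spacing mm per pixel.
#' @param time_points acquisition times in minutes; strictly increasing,
#'   first element 0 (the PRE scan).
#' @param noise_sd additive Gaussian noise standard deviation per pixel
#'   (signal units).
#' @param baseline PRE T1 intensity of disc and vertebral tissue.
#' @param kinetics base [kinetics_params()] for avascular discs.
#' @param v_mc,v_irregular perfusion exchange rates (1/min) for discs with
#'   Modic changes / irregular endplates.
#' @param n_levels discs per synthetic subject slice.
#' @param vb_px vertebral body height in pixels.
#' @param margin_px image margin in pixels.
#' @param disc_cols anterior/posterior disc extent, 0-based columns.
#' @param csf_cols CSF band extent, 0-based columns.
#' @param csf_t1,bg_t1 T1 intensities of CSF and background.
#' @param t2_disc_base,t2_disc_gain disc T2 intensity is
#'   `t2_disc_base + t2_disc_gain * hydration`.
#' @param t2_vb,t2_csf,t2_bg T2 intensities of vertebra, CSF, background.
#' @param height_model `"grade"` (height coupled to grade) or `"uniform"`.
#' @param height_range height support (mm) for the uniform model.
#' @param grade_probs sampling probabilities for grades 1-5.
#' @param grade_counts optional exact per-grade counts (overrides
#'   `grade_probs`; must sum to the cohort size).
#' @param mc_prob probability of Modic changes per grade (length 5).
#' @param defect_prob per-endplate Schmorl's node probability.
#' @param irregular_prob probability of an irregular endplate given grade
#'   >= 4 and Modic changes present.
#' @param spondy_prob probability of the severe spondylolisthesis flag.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_cols = 96, pixel_spacing = 0.83,
                           time_points = c(0, 5, 10, 120, 240, 360),
                           noise_sd = 80, baseline = 99,
                           kinetics = kinetics_params(),
                           v_mc = 0.08, v_irregular = 0.12,
                           n_levels = 5, vb_px = 28, margin_px = 8,
                           disc_cols = c(16, 64), csf_cols = c(72, 80),
                           csf_t1 = 30, bg_t1 = 60,
                           t2_disc_base = 150, t2_disc_gain = 450,
                           t2_vb = 120, t2_csf = 600, t2_bg = 80,
                           height_model = c("grade", "uniform"),
                           height_range = c(5, 14),
                           grade_probs = c(50, 43, 58, 48, 15) / 214,
                           grade_counts = NULL,
                           mc_prob = c(0.05, 0.10, 0.20, 0.45, 0.60),
                           defect_prob = 0.28,
                           irregular_prob = 0.25,
                           spondy_prob = 0.01) {
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(time_points) < 2 || time_points[1] != 0 ||
      any(diff(time_points) <= 0))
    stop("time_points must be strictly increasing and start at 0 (PRE)")
  structure(list(grid_cols = grid_cols, pixel_spacing = pixel_spacing,
                 time_points = time_points, noise_sd = noise_sd,
                 baseline = baseline, kinetics = kinetics,
                 v_mc = v_mc, v_irregular = v_irregular,
                 n_levels = n_levels, vb_px = vb_px, margin_px = margin_px,
                 disc_cols = disc_cols, csf_cols = csf_cols,
                 csf_t1 = csf_t1, bg_t1 = bg_t1,
                 t2_disc_base = t2_disc_base, t2_disc_gain = t2_disc_gain,
                 t2_vb = t2_vb, t2_csf = t2_csf, t2_bg = t2_bg,
                 height_model = match.arg(height_model),
                 height_range = height_range,
                 grade_probs = grade_probs, grade_counts = grade_counts,
                 mc_prob = mc_prob, defect_prob = defect_prob,
                 irregular_prob = irregular_prob, spondy_prob = spondy_prob),
            class = "phantom_config")
}

#' Label for an acquisition time in minutes
#' @param minutes numeric vector of times.
#' @return character labels (`PRE`, `POST_5MIN`, `POST_2H`, ...).
#' @export
time_label <- function(minutes) {
  vapply(minutes, function(t) {
    if (t == 0) "PRE"
    else if (t < 60 || t %% 60 != 0) sprintf("POST_%gMIN", t)
    else sprintf("POST_%gH", t / 60)
  }, character(1))
}

## Per-disc kinetics derived from the base kinetics and the disc spec.
.disc_kinetics <- function(spec, config) {
  k <- config$kinetics
  vascular <- spec$irregular || spec$mc_upper != "0" || spec$mc_lower != "0"
  v <- if (spec$irregular) config$v_irregular
       else if (vascular) config$v_mc else 0
  P <- k$P
  if (config$height_model == "grade")
    P <- P * (1 + 0.1 * (spec$pfirrmann - 1))
  kinetics_params(A = k$A, tau_a = k$tau_a, tau_e = k$tau_e, D = k$D,
                  P = P, v = v, tau_v = k$tau_v, alpha = k$alpha)
}

## Vertical layout + landmark geometry for one subject stack. Uses the
## current RNG state for tilt and endplate bulge.
.subject_geometry <- function(specs, config) {
  sp <- config$pixel_spacing
  c0 <- config$disc_cols[1]; c1 <- config$disc_cols[2]
  cB <- (c0 + c1) / 2
  y <- config$margin_px
  discs <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    h_px <- specs[[i]]$height / sp
    yu0 <- y + config$vb_px + 0.5       # half-integer: borders between pixels
    tilt <- stats::runif(1, -0.04, 0.04)
    bu <- stats::runif(1, 0.2, 1.0)
    bl <- stats::runif(1, 0.2, 1.0)
    upper <- rbind(c(yu0 + tilt * (c0 - cB), c0),
                   c(yu0 - bu, cB),
                   c(yu0 + tilt * (c1 - cB), c1))
    lower <- rbind(c(upper[1, 1] + h_px, c0),
                   c(yu0 + h_px + bl, cB),
                   c(upper[3, 1] + h_px, c1))
    discs[[i]] <- list(upper = upper, lower = lower,
                       center_row = yu0 + h_px / 2)
    y <- yu0 + h_px + 0.5
  }
  rows <- ceiling(y + config$vb_px + config$margin_px)
  list(discs = discs, rows = rows)
}

#' Render one synthetic subject slice series
#'
#' Draws a stack of `length(specs)` discs separated by vertebral bodies,
#' with a bright CSF band posterior to the spine, and renders the T1 series
#' (PRE plus each post-contrast time point) and the T2 image. T1 intensity
#' is `baseline + alpha * concentration + noise`; vertebral pixels track the
#' blood curve, disc pixels the solved diffusion-perfusion field. T2
#' intensity encodes hydration inside the disc and a fixed bright value in
#' the CSF band.
#'
#' @param specs list of [disc_spec()] objects (one per level).
#' @param config a [phantom_config()].
#' @param subject_id identifier used to build disc ids.
#' @param noise logical; add Gaussian noise (`noise_sd`) to every pixel.
#' @return list with `series` (named list of image matrices, `PRE`,
#'   `POST_*`, `T2`; plus `times`, `spacing`), `landmarks` (list of
#'   [landmark_set()]), `csf_rects` (per disc, 0-based top-left of the 3x5
#'   CSF reference rectangle), and `truth` (per-disc solved concentration
#'   fields and the disc specs).
#' @export
render_subject <- function(specs, config, subject_id = "S01", noise = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  geom <- .subject_geometry(specs, config)
  nr <- geom$rows; nc <- config$grid_cols
  times <- config$time_points
  labels <- time_label(times)
  sp <- config$pixel_spacing
  k <- config$kinetics
  Cb <- simulate_blood_curve(k, times)

  sols <- lapply(seq_along(specs), function(i)
    solve_disc_diffusion(specs[[i]]$height, .disc_kinetics(specs[[i]], config),
                         times = times))

  ## tissue maps: conc index per pixel per time is assembled from per-pixel
  ## class: 0 background, 1 vertebra, 2 csf, 3 disc (with depth u, disc idx)
  rows_all <- 0:(nr - 1)
  disc_cols <- config$disc_cols[1]:config$disc_cols[2]
  u_map <- matrix(NA_real_, nr, nc)
  disc_map <- matrix(NA_integer_, nr, nc)
  vb_map <- matrix(FALSE, nr, nc)
  borders <- lapply(geom$discs, function(d)
    list(yu = .border_interp(d$upper, disc_cols),
         yl = .border_interp(d$lower, disc_cols)))
  for (j in seq_along(disc_cols)) {
    cj <- disc_cols[j] + 1L
    prev_yl <- config$margin_px - 1
    for (i in seq_along(specs)) {
      yu <- borders[[i]]$yu[j]; yl <- borders[[i]]$yl[j]
      u <- (rows_all - yu) / (yl - yu)
      inside <- u >= 0 & u <= 1
      u_map[rows_all[inside] + 1L, cj] <- u[inside]
      disc_map[rows_all[inside] + 1L, cj] <- i
      vb <- rows_all > prev_yl & rows_all < yu
      vb_map[rows_all[vb] + 1L, cj] <- TRUE
      prev_yl <- yl
    }
    last <- rows_all > prev_yl & rows_all <= prev_yl + config$vb_px
    vb_map[rows_all[last] + 1L, cj] <- TRUE
  }
  csf_map <- matrix(FALSE, nr, nc)
  csf_map[, (config$csf_cols[1]:config$csf_cols[2]) + 1L] <- TRUE

  images <- vector("list", length(times) + 1L)
  names(images) <- c(labels, "T2")
  disc_idx <- which(!is.na(disc_map))
  for (tix in seq_along(times)) {
    img <- matrix(config$bg_t1, nr, nc)
    img[vb_map] <- config$baseline + k$alpha * Cb[tix]
    img[csf_map] <- config$csf_t1
    cvals <- numeric(length(disc_idx))
    for (i in seq_along(specs)) {
      sel <- disc_map[disc_idx] == i
      if (any(sel))
        cvals[sel] <- interp_conc(sols[[i]],
                                  u_map[disc_idx[sel]] * specs[[i]]$height,
                                  tix)
    }
    img[disc_idx] <- config$baseline + k$alpha * cvals
    if (noise && config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
    images[[tix]] <- img
  }
  t2 <- matrix(config$t2_bg, nr, nc)
  t2[vb_map] <- config$t2_vb
  t2[csf_map] <- config$t2_csf
  for (i in seq_along(specs)) {
    sel <- disc_idx[disc_map[disc_idx] == i]
    t2[sel] <- config$t2_disc_base + config$t2_disc_gain * specs[[i]]$hydration
  }
  if (noise && config$noise_sd > 0)
    t2 <- t2 + matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  images[["T2"]] <- t2

  lms <- lapply(seq_along(specs), function(i)
    landmark_set(sprintf("%s_D%d", subject_id, i),
                 geom$discs[[i]]$upper, geom$discs[[i]]$lower, sp))
  csf_mid <- round(mean(config$csf_cols))
  csf_rects <- lapply(geom$discs, function(d)
    c(round(d$center_row) - 2, csf_mid - 1))   # 5 rows x 3 cols, top-left

  list(series = list(images = images, times = times, spacing = sp),
       landmarks = lms, csf_rects = csf_rects,
       truth = list(conc = sols, specs = specs, blood = Cb))
}

## Draw one disc spec from the configured cohort distributions.
.draw_disc_spec <- function(grade, config) {
  if (config$height_model == "uniform") {
    h <- stats::runif(1, config$height_range[1], config$height_range[2])
    w <- stats::runif(1, 0.2, 1)
  } else {
    h <- 13 - 1.1 * (grade - 1) + stats::runif(1, -0.75, 0.75)
    w <- min(1, max(0, 1 - 0.16 * (grade - 1) + stats::runif(1, -0.05, 0.05)))
  }
  mc_u <- mc_l <- "0"
  if (stats::runif(1) < config$mc_prob[grade]) {
    pattern <- sample(c("upper", "lower", "both"), 1,
                      prob = c(0.25, 0.25, 0.5))
    draw_type <- function() sample(c("I", "II", "I/II"), 1,
                                   prob = c(0.30, 0.55, 0.15))
    if (pattern != "lower") mc_u <- draw_type()
    if (pattern != "upper") mc_l <- draw_type()
  }
  irregular <- grade >= 4 && (mc_u != "0" || mc_l != "0") &&
    stats::runif(1) < config$irregular_prob
  disc_spec(height = h, pfirrmann = grade, hydration = w,
            mc_upper = mc_u, mc_lower = mc_l,
            defect_upper = stats::runif(1) < config$defect_prob,
            defect_lower = stats::runif(1) < config$defect_prob,
            irregular = irregular,
            spondylolisthesis = stats::runif(1) < config$spondy_prob)
}

#' Generate a synthetic cohort
#'
#' Draws `n_discs` discs (grouped into subject slices of
#' `config$n_levels` discs), renders the full image series for each subject,
#' and returns the images together with the true landmarks, the metadata
#' table used by the statistical stage, and the generating ground truth.
#' Fully reproducible for a given seed.
#'
#' @param config a [phantom_config()].
#' @param n_discs number of discs (>= 1).
#' @param seed integer RNG seed.
#' @param noise logical; render with additive noise.
#' @return object of class `disc_cohort`: list with `subjects` (each the
#'   result of [render_subject()] plus a `subject_id`), `metadata` (one row
#'   per disc: grades, Modic types, flags, age, true height and kinetics),
#'   and `config`.
#' @export
generate_cohort <- function(config = phantom_config(), n_discs, seed = 1,
                            noise = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_discs < 1) stop("n_discs must be >= 1")
  set.seed(seed)
  if (!is.null(config$grade_counts)) {
    if (sum(config$grade_counts) != n_discs)
      stop("grade_counts must sum to n_discs")
    grades <- sample(rep(1:5, times = config$grade_counts))
  } else {
    grades <- sample(1:5, n_discs, replace = TRUE, prob = config$grade_probs)
  }
  n_sub <- ceiling(n_discs / config$n_levels)
  subjects <- vector("list", n_sub)
  meta <- vector("list", n_discs)
  d <- 0
  for (s in seq_len(n_sub)) {
    n_here <- min(config$n_levels, n_discs - d)
    age <- round(stats::runif(1, 18, 60))
    specs <- lapply(grades[d + seq_len(n_here)],
                    function(g) .draw_disc_spec(g, config))
    subject_id <- sprintf("S%02d", s)
    sub <- render_subject(specs, config, subject_id = subject_id,
                          noise = noise)
    sub$subject_id <- subject_id
    subjects[[s]] <- sub
    for (i in seq_len(n_here)) {
      spc <- specs[[i]]
      kin <- .disc_kinetics(spc, config)
      meta[[d + i]] <- data.frame(
        disc_id = sprintf("%s_D%d", subject_id, i), subject = subject_id,
        level = i, age = age, pfirrmann = spc$pfirrmann,
        height_true_mm = spc$height, hydration = spc$hydration,
        mc_upper = spc$mc_upper, mc_lower = spc$mc_lower,
        defect_upper = spc$defect_upper, defect_lower = spc$defect_lower,
        irregular = spc$irregular,
        spondylolisthesis = spc$spondylolisthesis,
        v_true = kin$v, P_true = kin$P, D_true = kin$D,
        stringsAsFactors = FALSE)
    }
    d <- d + n_here
  }
  structure(list(subjects = subjects,
                 metadata = do.call(rbind, meta),
                 config = config),
            class = "disc_cohort")
}
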