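## Landmark-based layered ROI construction.
##
## Coordinate convention (documented in the landmark JSON too): 0-based
## (row, col) pixel coordinates, row increasing downward, pixel centers at
## integer coordinates. Landmarks may be sub-pixel.

#' ROI labels in cranio-caudal order
#' @export
ROI_LABELS <- c("SCB_upper", "EPZ_upper", "Peripheral_upper", "Central",
                "Peripheral_lower", "EPZ_lower", "SCB_lower")

#' Disc-layer labels (the five bands between the endplate borders)
#' @export
DISC_LAYERS <- c("EPZ_upper", "Peripheral_upper", "Central",
                 "Peripheral_lower", "EPZ_lower")

#' Construct a landmark set for one disc
#'
#' Three operator-placed points per endplate border (A anterior, B middle,
#' C posterior; A and C at the disc margins) in 0-based (row, col) pixel
#' coordinates, sub-pixel allowed.
#'
#' @param disc_id disc identifier.
#' @param upper,lower 3 x 2 matrices, rows = points A, B, C, columns =
#'   (row, col).
#' @param pixel_spacing pixel size in mm/pixel.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(disc_id, upper, lower, pixel_spacing) {
  upper <- as.matrix(upper); lower <- as.matrix(lower)
  if (!all(dim(upper) == c(3, 2)) || !all(dim(lower) == c(3, 2)))
    stop("upper and lower must be 3 x 2 matrices of (row, col) points")
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  for (m in list(upper, lower))
    if (!(m[1, 2] < m[2, 2] && m[2, 2] < m[3, 2]))
      stop("points A, B, C must be ordered anterior to posterior (by column)")
  if (!(upper[1, 1] < lower[1, 1] && upper[3, 1] < lower[3, 1]))
    stop("upper border must lie strictly above the lower border at A and C")
  structure(list(disc_id = disc_id, upper = upper, lower = lower,
                 pixel_spacing = pixel_spacing),
            class = "landmark_set")
}

#' Disc height from landmarks
#'
#' The height estimate is the mean of the Euclidean point-pair distances
#' |A1 A2| and |C1 C2| (in pixels), converted to mm with the pixel spacing.
#'
#' @param lms a [landmark_set()].
#' @return height in mm.
#' @export
estimate_disc_height <- function(lms) {
  stopifnot(inherits(lms, "landmark_set"))
  dA <- sqrt(sum((lms$upper[1, ] - lms$lower[1, ])^2))
  dC <- sqrt(sum((lms$upper[3, ] - lms$lower[3, ])^2))
  if (dA < 1e-9 || dC < 1e-9)
    stop("degenerate landmark pair: coincident points")
  lms$pixel_spacing * mean(c(dA, dC))
}

## Piecewise-linear border ordinate through (A, B, C) evaluated at columns x.
.border_interp <- function(pts, x) {
  y <- numeric(length(x))
  left <- x <= pts[2, 2]
  y[left] <- pts[1, 1] + (pts[2, 1] - pts[1, 1]) *
    (x[left] - pts[1, 2]) / (pts[2, 2] - pts[1, 2])
  y[!left] <- pts[2, 1] + (pts[3, 1] - pts[2, 1]) *
    (x[!left] - pts[2, 2]) / (pts[3, 2] - pts[2, 2])
  y
}

## Band index 1..5 for normalized depth u in [0, 1]; ties on band edges go
## to the band closer to the disc center (u = 0.5).
.band_of_u <- function(u) {
  b <- integer(length(u))
  lo <- u < 0.5
  b[lo] <- pmin(floor(u[lo] / 0.2), 2) + 1
  b[!lo] <- 5 - pmin(floor((1 - u[!lo]) / 0.2), 2)
  b
}

#' Build the seven layered ROI masks for one disc
#'
#' The endplate borders are piecewise-linear polylines through the (A, B, C)
#' landmarks. For every image column between the anterior and posterior
#' landmark columns, a normalized depth u runs from the upper border (u = 0)
#' to the lower border (u = 1); the five disc layers are fifths of u
#' (endplate zone, peripheral, central, peripheral, endplate zone). A pixel
#' belongs to the band containing its center; a center exactly on a band
#' edge goes to the band nearer the disc center. The subchondral bone (SCB)
#' masks extend 6 pixels beyond each border along the image column
#' direction, separated from the disc by a 1-pixel gap.
#'
#' @param lms a [landmark_set()].
#' @param image_shape integer c(rows, cols) of the target image.
#' @return object of class `disc_rois`: list with `disc_id`, `masks` (named
#'   list of logical matrices, names [ROI_LABELS]), and `geometry` (list
#'   with `height_mm`, `cols`, `upper`, `lower` border ordinates).
#' @export
build_disc_rois <- function(lms, image_shape) {
  stopifnot(inherits(lms, "landmark_set"))
  nr <- image_shape[1]; nc <- image_shape[2]
  all_pts <- rbind(lms$upper, lms$lower)
  if (any(all_pts[, 1] < 0) || any(all_pts[, 1] > nr - 1) ||
      any(all_pts[, 2] < 0) || any(all_pts[, 2] > nc - 1))
    stop("landmarks outside image bounds")

  c_lo <- max(lms$upper[1, 2], lms$lower[1, 2])
  c_hi <- min(lms$upper[3, 2], lms$lower[3, 2])
  cols <- seq(ceiling(c_lo), floor(c_hi))        # 0-based pixel columns
  yu <- .border_interp(lms$upper, cols)
  yl <- .border_interp(lms$lower, cols)
  if (any(yl <= yu))
    stop("endplate borders cross: lower border not below upper border")

  rows_all <- 0:(nr - 1)
  masks <- lapply(ROI_LABELS, function(l) matrix(FALSE, nr, nc))
  names(masks) <- ROI_LABELS
  clipped <- FALSE
  for (j in seq_along(cols)) {
    cj <- cols[j] + 1L                           # 1-based matrix column
    u <- (rows_all - yu[j]) / (yl[j] - yu[j])
    inside <- u >= 0 & u <= 1
    if (any(inside)) {
      band <- .band_of_u(u[inside])
      rr <- rows_all[inside] + 1L
      for (b in 1:5) {
        sel <- rr[band == b]
        if (length(sel)) masks[[DISC_LAYERS[b]]][sel, cj] <- TRUE
      }
    }
    du <- yu[j] - rows_all                       # distance above upper border
    dl <- rows_all - yl[j]                       # distance below lower border
    scb_u <- du > 1 & du <= 7
    scb_l <- dl > 1 & dl <= 7
    if (sum(scb_u) < 6 || sum(scb_l) < 6) clipped <- TRUE
    masks[["SCB_upper"]][rows_all[scb_u] + 1L, cj] <- TRUE
    masks[["SCB_lower"]][rows_all[scb_l] + 1L, cj] <- TRUE
  }
  if (clipped)
    warning("SCB mask clipped at image boundary for disc ", lms$disc_id)

  structure(list(disc_id = lms$disc_id, masks = masks,
                 geometry = list(height_mm = estimate_disc_height(lms),
                                 cols = cols, upper = yu, lower = yl)),
            class = "disc_rois")
}

#' Apply the cohort exclusion rules
#'
#' Discs with height <= 3 mm (inclusive), a spondylolisthesis flag, or a
#' missing height are removed from the metadata; the exclusion log records
#' each removed disc and the reason.
#'
#' @param meta data frame with at least `disc_id` and `spondylolisthesis`.
#' @param heights data frame with `disc_id` and `height_mm` (NA allowed).
#' @return list with `retained` (filtered metadata) and `log` (data frame
#'   `disc_id`, `reason`).
#' @export
apply_exclusions <- function(meta, heights) {
  stopifnot(is.data.frame(meta), "disc_id" %in% names(meta))
  h <- heights$height_mm[match(meta$disc_id, heights$disc_id)]
  reason <- rep(NA_character_, nrow(meta))
  reason[is.na(h)] <- "unsegmentable"
  reason[!is.na(h) & h <= 3] <- "height <= 3 mm"
  sp <- as.logical(meta$spondylolisthesis)
  reason[is.na(reason) & sp] <- "severe spondylolisthesis"
  keep <- is.na(reason)
  list(retained = meta[keep, , drop = FALSE],
       log = data.frame(disc_id = meta$disc_id[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE))
}

#' Select the defect-free subset used for time-curve analysis
#'
#' Keeps discs with no endplate defect at either endplate, no "irregular
#' endplate" flag, and Modic change type 0 at both endplates.
#'
#' @param meta metadata data frame with columns `defect_upper`,
#'   `defect_lower`, `irregular`, `mc_upper`, `mc_lower`.
#' @return character vector of retained `disc_id`s.
#' @export
select_timecurve_subset <- function(meta) {
  keep <- !as.logical(meta$defect_upper) & !as.logical(meta$defect_lower) &
    !as.logical(meta$irregular) &
    meta$mc_upper == "0" & meta$mc_lower == "0"
  meta$disc_id[keep]
}
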