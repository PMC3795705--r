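## Enhancement and CSF-adjusted T2 quantification.

#' Mean signal under a mask
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same shape.
#' @return arithmetic mean of the pixel intensities under the mask.
#' @export
roi_mean <- function(image, mask) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask dimensions differ")
  if (!any(mask)) stop("empty mask")
  mean(image[mask])
}

#' Per-ROI enhancement table for one disc
#'
#' For each ROI and post-contrast time point the enhancement is the
#' difference of ROI means, `roi_mean(post) - roi_mean(pre)`, with no
#' normalization by the PRE signal.
#'
#' @param series image series as produced by [render_subject()] (`$series`):
#'   list with `images` (named matrices incl. `PRE` and `POST_*`) and
#'   `times`.
#' @param rois a [build_disc_rois()] result.
#' @return data frame with one row per ROI x post time point: `disc_id`,
#'   `roi`, `time` (label), `minutes`, `pre_mean`, `post_mean`,
#'   `enhancement`, `pixel_count`.
#' @export
compute_enhancement <- function(series, rois) {
  stopifnot(inherits(rois, "disc_rois"))
  labels <- time_label(series$times)
  if (!"PRE" %in% names(series$images)) stop("series lacks a PRE image")
  post <- labels[labels != "PRE"]
  missing <- setdiff(post, names(series$images))
  if (length(missing)) {
    warning("missing time points dropped: ", paste(missing, collapse = ", "))
    post <- setdiff(post, missing)
  }
  pre_img <- series$images[["PRE"]]
  out <- list()
  for (roi in names(rois$masks)) {
    m <- rois$masks[[roi]]
    if (!any(m)) next
    pre <- roi_mean(pre_img, m)
    for (lab in post) {
      pm <- roi_mean(series$images[[lab]], m)
      out[[length(out) + 1L]] <- data.frame(
        disc_id = rois$disc_id, roi = roi, time = lab,
        minutes = series$times[match(lab, labels)],
        pre_mean = pre, post_mean = pm, enhancement = pm - pre,
        pixel_count = sum(m), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' CSF-adjusted T2-weighted signal intensity for one disc
#'
#' The mean T2 signal over the disc (central plus both peripheral ROIs)
#' divided by the mean over a 3-column x 5-row rectangular reference region
#' placed in the cerebrospinal fluid. The ratio is invariant to global
#' intensity scaling.
#'
#' @param t2_image T2-weighted image matrix.
#' @param rois a [build_disc_rois()] result.
#' @param csf_rect numeric c(row, col): 0-based top-left corner of the 5x3
#'   CSF rectangle.
#' @return data frame with `disc_id`, `disc_mean`, `csf_mean`, `csf_adj_t2`.
#' @export
compute_csf_adj_t2 <- function(t2_image, rois, csf_rect) {
  stopifnot(inherits(rois, "disc_rois"))
  r0 <- csf_rect[1]; c0 <- csf_rect[2]
  if (r0 < 0 || c0 < 0 || r0 + 4 > nrow(t2_image) - 1 ||
      c0 + 2 > ncol(t2_image) - 1)
    stop("CSF rectangle (5 rows x 3 cols) not fully inside the image")
  csf_mask <- matrix(FALSE, nrow(t2_image), ncol(t2_image))
  csf_mask[(r0:(r0 + 4)) + 1L, (c0:(c0 + 2)) + 1L] <- TRUE
  disc_mask <- rois$masks$Central | rois$masks$Peripheral_upper |
    rois$masks$Peripheral_lower
  csf <- roi_mean(t2_image, csf_mask)
  if (csf <= 0) stop("non-positive CSF reference mean")
  dm <- roi_mean(t2_image, disc_mask)
  data.frame(disc_id = rois$disc_id, disc_mean = dm, csf_mean = csf,
             csf_adj_t2 = dm / csf, stringsAsFactors = FALSE)
}

#' Quantify a whole synthetic cohort
#'
#' Runs landmark-based segmentation on every disc (using the cohort's
#' landmarks) and computes the enhancement table and the CSF-adjusted T2
#' index for each disc.
#'
#' @param cohort a [generate_cohort()] result.
#' @return list with `enhancement` (row per disc x ROI x post time),
#'   `quant` (row per disc: CSF-adjusted T2), and `heights` (row per disc:
#'   landmark-based height estimate).
#' @export
quantify_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "disc_cohort"))
  enh <- list(); quant <- list(); hts <- list()
  for (sub in cohort$subjects) {
    shape <- dim(sub$series$images[["PRE"]])
    for (i in seq_along(sub$landmarks)) {
      rois <- build_disc_rois(sub$landmarks[[i]], shape)
      enh[[length(enh) + 1L]] <- compute_enhancement(sub$series, rois)
      quant[[length(quant) + 1L]] <-
        compute_csf_adj_t2(sub$series$images[["T2"]], rois,
                           sub$csf_rects[[i]])
      hts[[length(hts) + 1L]] <- data.frame(
        disc_id = rois$disc_id, height_mm = rois$geometry$height_mm,
        stringsAsFactors = FALSE)
    }
  }
  list(enhancement = do.call(rbind, enh), quant = do.call(rbind, quant),
       heights = do.call(rbind, hts))
}

#' Median and quartile time curves per ROI
#'
#' Summarizes the enhancement table over a subset of discs: per ROI and per
#' post-contrast time point the median and the 25%/75% percentiles
#' (quantile type 7, linear interpolation).
#'
#' @param table enhancement table as from [compute_enhancement()] rows.
#' @param subset character vector of disc ids to include.
#' @return data frame with `roi`, `time`, `minutes`, `n`, `q25`, `median`,
#'   `q75`.
#' @export
assemble_timecurves <- function(table, subset) {
  if (!length(subset)) stop("empty disc subset")
  tab <- table[table$disc_id %in% subset, , drop = FALSE]
  keys <- unique(tab[, c("roi", "time", "minutes")])
  keys <- keys[order(keys$minutes, keys$roi), ]
  out <- lapply(seq_len(nrow(keys)), function(i) {
    v <- tab$enhancement[tab$roi == keys$roi[i] & tab$time == keys$time[i]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(roi = keys$roi[i], time = keys$time[i],
               minutes = keys$minutes[i], n = length(v),
               q25 = q[1], median = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
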