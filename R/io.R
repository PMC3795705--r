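## Standard-format I/O: single-slice NIfTI images (pixel spacing in the
## header), landmark JSON, tidy CSV tables.
##
## Landmark JSON schema: one object per disc id, each with `upper` and
## `lower` (3 x 2 arrays of 0-based [row, col] pixel coordinates, row
## increasing downward, sub-pixel allowed; points ordered A, B, C anterior
## to posterior) and optionally `csf` ([row, col] top-left of the 5 x 3
## CSF reference rectangle).

#' Write a 2-D image slice as NIfTI
#'
#' @param mat numeric matrix (rows x cols).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing pixel spacing in mm/pixel, written to the header.
#' @return the path, invisibly.
#' @export
write_slice_nifti <- function(mat, path, spacing) {
  im <- RNifti::asNifti(mat)
  RNifti::pixdim(im) <- c(spacing, spacing)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a 2-D NIfTI slice
#'
#' @param path NIfTI file path.
#' @return numeric matrix with attribute `spacing` (mm/pixel).
#' @export
read_slice_nifti <- function(path) {
  im <- RNifti::readNifti(path)
  out <- matrix(as.numeric(im), dim(im)[1], dim(im)[2])
  attr(out, "spacing") <- RNifti::pixdim(im)[1]
  out
}

#' Write per-disc landmarks (and CSF reference rectangles) as JSON
#'
#' @param landmarks list of [landmark_set()] objects.
#' @param path output path.
#' @param csf_rects optional list (parallel to `landmarks`) of c(row, col)
#'   top-left corners of the CSF rectangles.
#' @return the path, invisibly.
#' @export
write_landmarks_json <- function(landmarks, path, csf_rects = NULL) {
  obj <- list()
  for (i in seq_along(landmarks)) {
    lm <- landmarks[[i]]
    entry <- list(upper = unname(lm$upper), lower = unname(lm$lower))
    if (!is.null(csf_rects)) entry$csf <- unname(csf_rects[[i]])
    obj[[lm$disc_id]] <- entry
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a landmark JSON file
#'
#' @param path JSON path.
#' @param pixel_spacing mm/pixel for the [landmark_set()] objects.
#' @return list with `landmarks` (list of [landmark_set()]) and `csf_rects`
#'   (list of c(row, col) or NULL entries).
#' @export
read_landmarks_json <- function(path, pixel_spacing) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  landmarks <- list(); csf <- list()
  for (id in names(obj)) {
    landmarks[[id]] <- landmark_set(id, obj[[id]]$upper, obj[[id]]$lower,
                                    pixel_spacing)
    csf[[id]] <- if (!is.null(obj[[id]]$csf)) as.numeric(obj[[id]]$csf)
                 else NULL
  }
  list(landmarks = landmarks, csf_rects = csf)
}
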