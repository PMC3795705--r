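## Directory-per-run pipeline: simulate -> segment -> quantify -> analyze,
## with a manifest recording seed, stage list and output checksums.

.roi_codes <- function() stats::setNames(seq_along(ROI_LABELS), ROI_LABELS)

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.stage_simulate <- function(out_dir, config, n_discs, seed, noise) {
  cohort <- generate_cohort(config, n_discs, seed = seed, noise = noise)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  lms <- list(); csf <- list()
  for (sub in cohort$subjects) {
    for (lab in names(sub$series$images))
      write_slice_nifti(sub$series$images[[lab]],
                        file.path(img_dir,
                                  sprintf("%s_%s.nii.gz", sub$subject_id, lab)),
                        config$pixel_spacing)
    lms <- c(lms, sub$landmarks)
    csf <- c(csf, sub$csf_rects)
  }
  write_landmarks_json(lms, file.path(out_dir, "landmarks.json"), csf)
  .write_csv(cohort$metadata, file.path(out_dir, "metadata.csv"))
  .write_csv(data.frame(minutes = config$time_points,
                        label = time_label(config$time_points)),
             file.path(out_dir, "time_points.csv"))
  invisible(cohort)
}

.subject_of <- function(disc_id) sub("_D[0-9]+$", "", disc_id)
.level_of <- function(disc_id) as.integer(sub("^.*_D", "", disc_id))

.build_all_rois <- function(out_dir, config) {
  lj <- read_landmarks_json(file.path(out_dir, "landmarks.json"),
                            config$pixel_spacing)
  ids <- names(lj$landmarks)
  rois <- list()
  for (id in ids) {
    pre <- read_slice_nifti(file.path(out_dir, "images",
                                      sprintf("%s_PRE.nii.gz",
                                              .subject_of(id))))
    rois[[id]] <- build_disc_rois(lj$landmarks[[id]], dim(pre))
  }
  list(rois = rois, csf_rects = lj$csf_rects)
}

.stage_segment <- function(out_dir, config) {
  br <- .build_all_rois(out_dir, config)
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(br$rois)
  by_sub <- split(ids, .subject_of(ids))
  for (s in names(by_sub)) {
    pre <- read_slice_nifti(file.path(out_dir, "images",
                                      sprintf("%s_PRE.nii.gz", s)))
    lab <- matrix(0L, nrow(pre), ncol(pre))
    for (id in by_sub[[s]]) {
      lv <- .level_of(id)
      for (roi in ROI_LABELS)
        lab[br$rois[[id]]$masks[[roi]]] <- lv * 10L + .roi_codes()[[roi]]
    }
    write_slice_nifti(lab, file.path(mask_dir,
                                     sprintf("%s_masks.nii.gz", s)),
                      config$pixel_spacing)
  }
  .write_csv(data.frame(code = unname(.roi_codes()), roi = ROI_LABELS),
             file.path(mask_dir, "legend.csv"))
  meta <- utils::read.csv(file.path(out_dir, "metadata.csv"),
                          colClasses = c(mc_upper = "character",
                                         mc_lower = "character"))
  heights <- data.frame(disc_id = ids,
                        height_mm = vapply(br$rois, function(r)
                          r$geometry$height_mm, numeric(1)))
  excl <- apply_exclusions(meta, heights)
  geom <- data.frame(disc_id = ids, height_mm = heights$height_mm)
  geom$excluded <- !(geom$disc_id %in% excl$retained$disc_id)
  geom$reason <- excl$log$reason[match(geom$disc_id, excl$log$disc_id)]
  .write_csv(geom, file.path(out_dir, "geometry.csv"))
  invisible(geom)
}

.stage_quantify <- function(out_dir, config) {
  ## masks are reconstructed deterministically from the landmarks, so the
  ## stage does not depend on the segment stage's mask files being present
  br <- .build_all_rois(out_dir, config)
  ids <- names(br$rois)
  tp <- utils::read.csv(file.path(out_dir, "time_points.csv"))
  enh <- list(); quant <- list()
  for (s in unique(.subject_of(ids))) {
    images <- lapply(stats::setNames(tp$label, tp$label), function(lab)
      read_slice_nifti(file.path(out_dir, "images",
                                 sprintf("%s_%s.nii.gz", s, lab))))
    t2 <- read_slice_nifti(file.path(out_dir, "images",
                                     sprintf("%s_T2.nii.gz", s)))
    series <- list(images = images, times = tp$minutes,
                   spacing = config$pixel_spacing)
    for (id in ids[.subject_of(ids) == s]) {
      enh[[id]] <- compute_enhancement(series, br$rois[[id]])
      quant[[id]] <- compute_csf_adj_t2(t2, br$rois[[id]],
                                        br$csf_rects[[id]])
    }
  }
  .write_csv(do.call(rbind, c(enh, list(make.row.names = FALSE))),
             file.path(out_dir, "enhancement.csv"))
  .write_csv(do.call(rbind, c(quant, list(make.row.names = FALSE))),
             file.path(out_dir, "quant.csv"))
}

.stage_analyze <- function(out_dir, alpha = 0.05) {
  enh <- utils::read.csv(file.path(out_dir, "enhancement.csv"))
  quant <- utils::read.csv(file.path(out_dir, "quant.csv"))
  meta <- utils::read.csv(file.path(out_dir, "metadata.csv"),
                          colClasses = c(mc_upper = "character",
                                         mc_lower = "character"))
  geom <- utils::read.csv(file.path(out_dir, "geometry.csv"))
  meta <- meta[meta$disc_id %in% geom$disc_id[!geom$excluded], ]
  res <- run_paper_analyses(enh, quant, meta,
                            geom[, c("disc_id", "height_mm")], alpha = alpha)
  .write_csv(res$results, file.path(out_dir, "stats_results.csv"))
  if (!is.null(res$pairwise))
    .write_csv(res$pairwise, file.path(out_dir, "stats_pairwise.csv"))
  if (!is.null(res$timecurves))
    .write_csv(res$timecurves, file.path(out_dir, "timecurves.csv"))
  writeLines(res$report, file.path(out_dir, "report.txt"))
  invisible(res)
}

#' Run the full pipeline into a run directory
#'
#' Executes the requested stages (simulate, segment, quantify, analyze) in
#' order, writing standard-format artifacts (NIfTI images and label maps,
#' landmark JSON, tidy CSV tables, a text report) plus a `manifest.json`
#' recording the seed, configuration summary, stages run and MD5 checksums
#' of every output file. A rerun with the same configuration and seed
#' produces byte-identical CSV outputs.
#'
#' @param out_dir run directory (created if needed).
#' @param n_discs cohort size for the simulate stage.
#' @param seed RNG seed for the simulate stage.
#' @param config a [phantom_config()].
#' @param stages character subset of
#'   `c("simulate", "segment", "quantify", "analyze")`.
#' @param noise render with noise (default TRUE).
#' @param alpha significance level for the analyze stage.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, n_discs = 25, seed = 1,
                         config = phantom_config(),
                         stages = c("simulate", "segment", "quantify",
                                    "analyze"),
                         noise = TRUE, alpha = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in stages) {
    ok <- tryCatch({
      switch(st,
             simulate = .stage_simulate(out_dir, config, n_discs, seed, noise),
             segment = .stage_segment(out_dir, config),
             quantify = .stage_quantify(out_dir, config),
             analyze = .stage_analyze(out_dir, alpha))
      TRUE
    }, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", st,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(seed = seed, n_discs = n_discs, stages = stages,
                   package_version = as.character(
                     utils::packageVersion("discdiff")),
                   pixel_spacing = config$pixel_spacing,
                   time_points = config$time_points,
                   noise_sd = config$noise_sd,
                   coordinate_convention =
                     "0-based (row, col), row increasing downward",
                   checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate the small test fixture cohort
#'
#' A six-disc phantom (one disc per degeneration grade 1-5 plus one
#' vascularized disc with a Modic type II endplate) rendered as a single
#' subject stack; small enough for routine test runs.
#'
#' @param seed RNG seed.
#' @param noise render with noise.
#' @param config a [phantom_config()]; `n_levels` is forced to 6.
#' @return a `disc_cohort` object with one subject and six discs.
#' @export
make_fixtures <- function(seed = 42, noise = TRUE, config = phantom_config()) {
  config$n_levels <- 6L
  set.seed(seed)
  specs <- c(lapply(1:5, function(g)
    disc_spec(height = 13 - 1.1 * (g - 1), pfirrmann = g,
              hydration = max(0, 1 - 0.16 * (g - 1)))),
    list(disc_spec(height = 10, pfirrmann = 3, hydration = 0.6,
                   mc_upper = "II")))
  sub <- render_subject(specs, config, subject_id = "S01", noise = noise)
  sub$subject_id <- "S01"
  meta <- do.call(rbind, lapply(seq_along(specs), function(i) {
    spc <- specs[[i]]
    kin <- .disc_kinetics(spc, config)
    data.frame(disc_id = sprintf("S01_D%d", i), subject = "S01", level = i,
               age = 45, pfirrmann = spc$pfirrmann,
               height_true_mm = spc$height, hydration = spc$hydration,
               mc_upper = spc$mc_upper, mc_lower = spc$mc_lower,
               defect_upper = spc$defect_upper,
               defect_lower = spc$defect_lower,
               irregular = spc$irregular,
               spondylolisthesis = spc$spondylolisthesis,
               v_true = kin$v, P_true = kin$P, D_true = kin$D,
               stringsAsFactors = FALSE)
  }))
  structure(list(subjects = list(sub), metadata = meta, config = config),
            class = "disc_cohort")
}

#' @rdname render_subject
#' @export
render_series <- render_subject
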