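test_that("disc height is the mean of the two landmark pair distances", {
  # parallel horizontal borders, 10 px apart, spacing 0.83
  lm <- landmark_set("d", rbind(c(10, 5), c(10, 22), c(10, 40)),
                     rbind(c(20, 5), c(20, 22), c(20, 40)), 0.83)
  expect_equal(estimate_disc_height(lm), 0.83 * 10)
  # arithmetic mean of unequal pair distances at unit spacing
  lm2 <- landmark_set("d", rbind(c(10, 5), c(10, 22), c(10, 40)),
                      rbind(c(20, 5), c(21, 22), c(24, 40)), 1.0)
  expect_equal(estimate_disc_height(lm2), mean(c(10, 14)))
  # tilted pair: Euclidean distance, hand value sqrt(45)
  lm3 <- landmark_set("d", rbind(c(10, 5), c(11, 22), c(12, 40)),
                      rbind(c(16, 8), c(18, 22), c(19, 43)), 1.0)
  dA <- sqrt((16 - 10)^2 + (8 - 5)^2)
  dC <- sqrt((19 - 12)^2 + (43 - 40)^2)
  expect_equal(dA, sqrt(45))
  expect_equal(estimate_disc_height(lm3), mean(c(dA, dC)))
  # degenerate coincident pair is rejected
  expect_error(estimate_disc_height(
    landmark_set("d", rbind(c(10, 5), c(9, 22), c(10, 40)),
                 rbind(c(10.000000000000001, 5), c(20, 22), c(20, 40)), 1)),
    "degenerate|strictly above")
})

test_that("landmark ordering and border validity are enforced", {
  expect_error(landmark_set("d", rbind(c(10, 40), c(10, 22), c(10, 5)),
                            rbind(c(20, 5), c(20, 22), c(20, 40)), 1),
               "ordered")
  expect_error(landmark_set("d", rbind(c(20, 5), c(20, 22), c(20, 40)),
                            rbind(c(10, 5), c(10, 22), c(10, 40)), 1),
               "strictly above")
  expect_error(landmark_set("d", rbind(c(10, 5), c(10, 22), c(10, 40)),
                            rbind(c(20, 5), c(20, 22), c(20, 40)), 0),
               "pixel_spacing")
})

test_that("a rectangular disc splits into exact fifths with 6-px SCB bands", {
  # borders on half-integers: 20 pixel rows between them, 40 columns wide
  lm <- landmark_set("d", rbind(c(29.5, 20), c(29.5, 39.5), c(29.5, 59)),
                     rbind(c(49.5, 20), c(49.5, 39.5), c(49.5, 59)), 0.83)
  rois <- build_disc_rois(lm, c(96, 96))
  for (layer in DISC_LAYERS)
    expect_equal(sum(rois$masks[[layer]]), 4 * 40)
  # SCB: 6 pixel rows per column with a 1-pixel gap to the disc
  expect_equal(sum(rois$masks$SCB_upper), 6 * 40)
  expect_equal(sum(rois$masks$SCB_lower), 6 * 40)
  scb_rows <- which(apply(rois$masks$SCB_upper, 1, any)) - 1  # 0-based
  expect_equal(max(scb_rows), 28)   # gap row 29 just above border 29.5
  expect_equal(length(scb_rows), 6)
  # physical SCB thickness at the default spacing
  expect_equal(6 * 0.83, 4.98)
  # height estimate: 20 px at 0.83 mm/px
  expect_equal(rois$geometry$height_mm, 20 * 0.83)
})

test_that("masks match the brute-force per-pixel classifier exactly", {
  set.seed(42)
  shape <- c(110, 110)
  for (rep in 1:25) {
    lm <- random_quad_landmarks(shape, id = sprintf("q%d", rep))
    rois <- build_disc_rois(lm, shape)
    oracle <- brute_force_rois(lm, shape)
    for (roi in ROI_LABELS)
      expect_identical(rois$masks[[roi]], oracle[[roi]])
    # partition: the five layers tile the inter-border raster disjointly
    layer_sum <- Reduce(`+`, lapply(DISC_LAYERS,
                                    function(l) rois$masks[[l]] * 1L))
    expect_lte(max(layer_sum), 1L)
    inter <- Reduce(`|`, oracle[c("EPZ_upper", "Peripheral_upper", "Central",
                                  "Peripheral_lower", "EPZ_lower")])
    expect_equal(sum(layer_sum), sum(inter))
  }
})

test_that("height in mm is invariant to a joint rescaling of pixels", {
  lm <- landmark_set("d", rbind(c(10, 5), c(9.5, 22), c(11, 40)),
                     rbind(c(21, 6), c(22, 22), c(23, 41)), 0.83)
  k <- 2.5
  lm_scaled <- landmark_set("d", lm$upper * k, lm$lower * k,
                            lm$pixel_spacing / k)
  expect_equal(estimate_disc_height(lm_scaled), estimate_disc_height(lm))
})

test_that("crossing borders and out-of-bounds landmarks are rejected", {
  lm <- landmark_set("d", rbind(c(10, 5), c(18, 22), c(10, 40)),
                     rbind(c(12, 5), c(12, 22), c(12, 40)), 1)
  expect_error(build_disc_rois(lm, c(64, 64)), "cross")
  lm2 <- landmark_set("d", rbind(c(10, 5), c(10, 22), c(10, 40)),
                      rbind(c(20, 5), c(20, 22), c(20, 40)), 1)
  expect_error(build_disc_rois(lm2, c(64, 30)), "outside image bounds")
  # masks clipped at the image edge only warn
  lm3 <- landmark_set("d", rbind(c(3, 5), c(3, 22), c(3, 40)),
                      rbind(c(13, 5), c(13, 22), c(13, 40)), 1)
  expect_warning(build_disc_rois(lm3, c(64, 64)), "clipped")
})

test_that("exclusion rules reproduce the cohort bookkeeping", {
  # 222 graded levels: 2 severe spondylolisthesis, 6 too thin (3 mm is
  # inclusive) leave 214
  n <- 222
  meta <- data.frame(disc_id = sprintf("L%03d", 1:n),
                     spondylolisthesis = c(rep(TRUE, 2), rep(FALSE, n - 2)))
  heights <- data.frame(disc_id = meta$disc_id,
                        height_mm = c(rep(8, 2),          # spondylolisthesis
                                      rep(2.5, 5), 3.0,   # thin, one boundary
                                      rep(9, n - 8)))
  ex <- apply_exclusions(meta, heights)
  expect_equal(nrow(ex$retained), 214)
  expect_equal(sum(ex$log$reason == "severe spondylolisthesis"), 2)
  expect_equal(sum(ex$log$reason == "height <= 3 mm"), 6)
  # nothing to exclude
  ok <- apply_exclusions(data.frame(disc_id = "a", spondylolisthesis = FALSE),
                         data.frame(disc_id = "a", height_mm = 8))
  expect_equal(nrow(ok$retained), 1)
  expect_equal(nrow(ok$log), 0)
  # missing height is logged as unsegmentable
  na <- apply_exclusions(data.frame(disc_id = "a", spondylolisthesis = FALSE),
                         data.frame(disc_id = "b", height_mm = 8))
  expect_equal(na$log$reason, "unsegmentable")
})

test_that("time-curve subset equals the brute-force set comprehension", {
  set.seed(77)
  n <- 60
  meta <- data.frame(disc_id = sprintf("d%02d", 1:n),
                     defect_upper = runif(n) < 0.3,
                     defect_lower = runif(n) < 0.3,
                     irregular = runif(n) < 0.1,
                     mc_upper = sample(c("0", "I", "II", "I/II"), n, TRUE,
                                       prob = c(0.7, 0.1, 0.15, 0.05)),
                     mc_lower = sample(c("0", "I", "II", "I/II"), n, TRUE,
                                       prob = c(0.7, 0.1, 0.15, 0.05)),
                     stringsAsFactors = FALSE)
  oracle <- character()
  for (i in 1:n)
    if (!meta$defect_upper[i] && !meta$defect_lower[i] &&
        !meta$irregular[i] && meta$mc_upper[i] == "0" &&
        meta$mc_lower[i] == "0")
      oracle <- c(oracle, meta$disc_id[i])
  expect_identical(select_timecurve_subset(meta), oracle)
  # single-rule spot checks: any Modic change or defect excludes the disc
  one <- meta[1, ]; one$defect_upper <- FALSE; one$defect_lower <- FALSE
  one$irregular <- FALSE; one$mc_upper <- "0"; one$mc_lower <- "II"
  expect_length(select_timecurve_subset(one), 0)
  one$mc_lower <- "0"; one$defect_upper <- TRUE
  expect_length(select_timecurve_subset(one), 0)
})
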