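test_that("segment_primary matches the flood-fill component oracle", {
  # two clean disks well inside the frame
  img <- matrix(10, 64, 64)
  d <- raster_disk(6, 4) # 21x21
  img[8 + seq_len(21), 8 + seq_len(21)][d] <- 1000
  img[36 + seq_len(21), 36 + seq_len(21)][d] <- 1000
  mask <- segment_primary(img, 0.5)
  expect_equal(max(mask$labels), 2)
  expect_equal(max(mask$labels), flood_fill_count(img > 500))
  # determinism
  expect_identical(mask$labels, segment_primary(img, 0.5)$labels)
})

test_that("segmentation handles degenerate and invalid input", {
  expect_equal(max(segment_primary(matrix(0, 32, 32))$labels), 0)
  expect_error(segment_primary(array(1, c(4, 4, 2))), "2-D")
  # border-touching object removed
  img <- matrix(0, 32, 32)
  img[1:6, 10:15] <- 100
  img[15:20, 15:20] <- 100
  expect_equal(max(segment_primary(img, strategy = "fixed",
                                   threshold = 50)$labels), 1)
})

test_that("fixed and quantile threshold strategies are available", {
  img <- matrix(10, 48, 48)
  img[20:28, 20:28] <- 100
  expect_equal(max(segment_primary(img, strategy = "fixed",
                                   threshold = 50)$labels), 1)
  expect_equal(max(segment_primary(img, strategy = "quantile",
                                   prob = 0.9)$labels), 1)
  expect_error(segment_primary(img, strategy = "fixed"), "threshold")
})

test_that("measure_shape agrees with analytic disk and ellipse values", {
  mk_mask <- function(m, px = 0.5) {
    lab <- matrix(0L, nrow(m) + 8, ncol(m) + 8)
    lab[4 + seq_len(nrow(m)), 4 + seq_len(ncol(m))][m] <- 1L
    structure(list(labels = lab, pixel_size = px), class = "labeled_mask")
  }
  disk <- measure_shape(mk_mask(raster_disk(20)))
  expect_lt(disk$eccentricity, 0.02) # a circle has eccentricity 0
  # disk radius 10 px at 0.5 um/px -> equivalent diameter ~10 um
  d10 <- measure_shape(mk_mask(raster_disk(10)))
  expect_equal(d10$equivalent_diameter, 10, tolerance = 0.05)
  # axis-aligned ellipse a = 2b: eccentricity sqrt(1 - 1/4) = 0.866
  ell <- measure_shape(mk_mask(raster_ellipse(40, 20)))
  expect_equal(ell$eccentricity, sqrt(3) / 2, tolerance = 0.02)
  expect_true(all(ell$eccentricity >= 0 & ell$eccentricity <= 1))
  # empty mask -> empty frame
  empty <- structure(list(labels = matrix(0L, 8, 8), pixel_size = 0.5),
                     class = "labeled_mask")
  expect_equal(nrow(measure_shape(empty)), 0)
})

test_that("eccentricity is monotone under stretching along the major axis", {
  eccs <- vapply(c(20, 26, 34, 44), function(a) {
    m <- raster_ellipse(a, 20)
    lab <- matrix(0L, nrow(m) + 8, ncol(m) + 8)
    lab[4 + seq_len(nrow(m)), 4 + seq_len(ncol(m))][m] <- 1L
    measure_shape(structure(list(labels = lab, pixel_size = 0.5),
                            class = "labeled_mask"))$eccentricity
  }, numeric(1))
  expect_true(all(diff(eccs) > 0))
})

test_that("filter_primary applies the inclusive 9-36 um window", {
  obj <- data.frame(object_id = 1:4, x = 0, y = 0, area_px = 0,
                    equivalent_diameter = c(8.9, 9.0, 36.0, 36.1),
                    eccentricity = 0)
  kept <- filter_primary(obj, gate_config())
  expect_identical(kept$object_id, c(2L, 3L))
  expect_identical(nrow(filter_primary(obj[0, ], gate_config())), 0L)
  # all-compliant input passes through unchanged, order preserved
  ok <- obj[2:3, ]
  expect_identical(filter_primary(ok, gate_config()), ok)
  # eccentric objects are excluded
  obj$eccentricity <- 0.95
  expect_identical(nrow(filter_primary(obj, gate_config())), 0L)
})

test_that("expand_secondary grows objects and matches nearest-object search", {
  lab <- matrix(0L, 48, 48)
  d <- raster_disk(10, 0) # 21x21
  lab[13 + seq_len(21), 13 + seq_len(21)][d] <- 1L
  mask <- structure(list(labels = lab, pixel_size = 0.5),
                    class = "labeled_mask")
  # radius 0 is the identity
  expect_identical(expand_secondary(mask, 0)$labels, lab)
  expect_error(expand_secondary(mask, -1), ">= 0")
  # area grows to that of a disk of radius 13
  sec <- expand_secondary(mask, 3)
  expect_equal(sum(sec$labels == 1), sum(raster_disk(13)), tolerance = 0.02)
  # two nearby objects: labels never merge, pixels go to the nearest object
  lab2 <- matrix(0L, 40, 40)
  lab2[10:14, 10:14] <- 1L
  lab2[10:14, 20:24] <- 2L
  m2 <- structure(list(labels = lab2, pixel_size = 0.5),
                  class = "labeled_mask")
  sec2 <- expand_secondary(m2, 4)$labels
  expect_setequal(unique(sec2[sec2 > 0]), c(1L, 2L))
  pix1 <- which(lab2 == 1, arr.ind = TRUE)
  pix2 <- which(lab2 == 2, arr.ind = TRUE)
  grown <- which(sec2 > 0 & lab2 == 0, arr.ind = TRUE)
  for (k in seq_len(nrow(grown))) {
    p <- grown[k, ]
    d1 <- min(sqrt((pix1[, 1] - p[1])^2 + (pix1[, 2] - p[2])^2))
    d2 <- min(sqrt((pix2[, 1] - p[1])^2 + (pix2[, 2] - p[2])^2))
    expect_identical(sec2[p[1], p[2]], if (d1 <= d2) 1L else 2L)
    expect_lte(min(d1, d2), 4)
  }
})

test_that("measure_intensity is the per-object arithmetic mean and local", {
  lab <- matrix(0L, 8, 8)
  lab[2, 2:5] <- 1L
  lab[6, 6:7] <- 2L
  mask <- structure(list(labels = lab, pixel_size = 1),
                    class = "labeled_mask")
  ch <- matrix(0, 8, 8)
  ch[2, 2:5] <- c(10, 20, 30, 40)
  ch[6, 6:7] <- c(5, 7)
  m <- measure_intensity(mask, ch)
  expect_equal(unname(m["1"]), 25)
  expect_equal(unname(m["2"]), 6)
  # uniform channel -> every object mean is the constant
  expect_equal(unname(measure_intensity(mask, matrix(7, 8, 8))), c(7, 7))
  # locality: editing pixels of object 1 leaves object 2 unchanged
  ch[2, 2] <- 1000
  expect_equal(unname(measure_intensity(mask, ch)["2"]), 6)
  expect_error(measure_intensity(mask, matrix(0, 4, 4)), "dimensions")
})

test_that("calibrate_gates implements mean + k*SD negative-control gating", {
  iso <- data.frame(mean_ck_epcam = rep(10, 5), mean_cd45 = rep(10, 5))
  pos <- data.frame(mean_ck_epcam = rep(100, 20), mean_cd45 = rep(5, 20))
  g <- calibrate_gates(pos, iso, k = 3)
  expect_equal(g$ck_epcam_positive_threshold, 10) # SD 0
  iso2 <- data.frame(mean_ck_epcam = c(8, 10, 12), mean_cd45 = c(8, 10, 12))
  g2 <- calibrate_gates(pos, iso2, k = 3)
  expect_equal(g2$ck_epcam_positive_threshold, 10 + 3 * sd(c(8, 10, 12)))
  # monotone nondecreasing in k
  ks <- c(0, 1, 2, 3, 5)
  thr <- vapply(ks, function(k)
    calibrate_gates(pos, iso2, k)$ck_epcam_positive_threshold, numeric(1))
  expect_true(all(diff(thr) >= 0))
  expect_error(calibrate_gates(pos, iso2[0, ], 3), "empty")
  # dim positive control triggers the calibration warning
  dim_pos <- data.frame(mean_ck_epcam = rep(9, 20), mean_cd45 = rep(5, 20))
  expect_warning(calibrate_gates(dim_pos, iso2, 3), "calibration warning")
})

test_that("classification is an exhaustive partition over the gates", {
  g <- default_gates()
  meas <- data.frame(mean_ck_epcam = c(1000, 1000, 10, 10, 500),
                     mean_cd45 = c(10, 1000, 1000, 10, 500))
  rec <- classify_cells(meas, g)
  expect_identical(rec$assigned_class,
                   c("CTC", "DUAL_POSITIVE", "WBC", "NEGATIVE", "NEGATIVE"))
  # exactly one class each (partition)
  expect_true(all(rec$assigned_class %in%
                    c("CTC", "WBC", "DUAL_POSITIVE", "NEGATIVE")))
  expect_error(classify_cells(meas, gate_config()), "not calibrated")
})

test_that("enumerate_cells reports counts, purity and the undefined flag", {
  rec <- data.frame(assigned_class = c(rep("CTC", 10), rep("WBC", 990)))
  res <- enumerate_cells(rec)
  expect_equal(res$ctc_purity, 0.01)
  expect_equal(res$total_cells, 1000)
  expect_equal(sum(res$counts), res$total_cells)
  empty <- enumerate_cells(data.frame(assigned_class = character(0)))
  expect_false(empty$purity_defined)
  expect_true(is.na(empty$ctc_purity))
  expect_identical(sum(empty$counts), 0L)
})

test_that("end-to-end pipeline recovers ground truth on separable fixtures", {
  for (s in 1:5) {
    fx <- separable_fixture(s)
    r <- count_ctcs(fx$dna, fx$ck_epcam, fx$cd45, fx$pixel_size,
                    default_gates())
    expect_identical(unname(r$result$counts),
                     unname(ground_truth_counts(fx)))
  }
})

test_that("lobed leukocyte nuclei are excluded by the eccentricity filter", {
  fx <- generate_fixture(fixture_config(
    c(192L, 192L), cells = fixture_cells(2, 6, wbc_n_lobes = 3L),
    noise_sd = 0, seed = 21))
  r <- count_ctcs(fx$dna, fx$ck_epcam, fx$cd45, fx$pixel_size,
                  default_gates())
  expect_identical(unname(r$result$counts[c("CTC", "WBC")]), c(2L, 0L))
  # the lobed nuclei were segmented, then dropped by shape filtering
  expect_equal(nrow(r$objects), 8)
  expect_equal(nrow(r$records), 2)
})

test_that("export_gallery writes one montage per non-empty class", {
  fx <- separable_fixture(13, 3, 2, 0, 0)
  r <- count_ctcs(fx$dna, fx$ck_epcam, fx$cd45, fx$pixel_size,
                  default_gates())
  dir <- withr::local_tempdir()
  files <- export_gallery(list(dna = fx$dna, ck_epcam = fx$ck_epcam,
                               cd45 = fx$cd45), r$records, dir)
  expect_true(file.exists(files[["CTC"]]))
  expect_true(file.exists(files[["WBC"]]))
  expect_false("DUAL_POSITIVE" %in% names(files))
  # CTC montage is a grid of 41 px tiles holding 3 crops
  img <- png::readPNG(files[["CTC"]])
  expect_equal(dim(img)[1] * dim(img)[2] / 41^2 >= 3, TRUE)
})
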