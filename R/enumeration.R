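#' Gating and filtering configuration for CTC enumeration
#'
#' Holds the intensity gates and morphology filters applied between nucleus
#' segmentation and cell classification. The 9-36 micrometer nuclear
#' diameter window is the published filter; both bounds are inclusive. The
#' eccentricity cutoff excludes lobed/irregular leukocyte nuclei; no
#' published value exists, so it defaults to 0.80 and is always reported in
#' output metadata.
#'
#' @param ck_epcam_positive_threshold,cd45_positive_threshold intensity gate
#'   per marker channel (same arbitrary units as the images); usually set by
#'   [calibrate_gates()].
#' @param diameter_min,diameter_max nuclear equivalent-diameter window in
#'   micrometers (inclusive).
#' @param eccentricity_max maximum fitted-ellipse eccentricity retained
#'   (0 = circle).
#' @param secondary_expand_radius radius in pixels by which primary objects
#'   are grown into secondary measurement objects.
#' @param calibration_k SD multiplier used by [calibrate_gates()].
#' @return a `gate_config` list.
#' @export
gate_config <- function(ck_epcam_positive_threshold = NA_real_,
                        cd45_positive_threshold = NA_real_,
                        diameter_min = 9, diameter_max = 36,
                        eccentricity_max = 0.80,
                        secondary_expand_radius = 3L,
                        calibration_k = 3) {
  stopifnot(diameter_min < diameter_max, eccentricity_max > 0,
            eccentricity_max <= 1, secondary_expand_radius >= 0)
  if (!is.na(ck_epcam_positive_threshold))
    stopifnot(ck_epcam_positive_threshold >= 0)
  if (!is.na(cd45_positive_threshold))
    stopifnot(cd45_positive_threshold >= 0)
  structure(list(ck_epcam_positive_threshold = ck_epcam_positive_threshold,
                 cd45_positive_threshold = cd45_positive_threshold,
                 diameter_min = diameter_min, diameter_max = diameter_max,
                 eccentricity_max = eccentricity_max,
                 secondary_expand_radius = as.integer(secondary_expand_radius),
                 calibration_k = calibration_k),
            class = "gate_config")
}

threshold_strategies <- function() c("otsu", "fixed", "quantile")

#' Segment nucleated cells on the DNA channel
#'
#' Computes a single global threshold over the whole image (robust for
#' fluorescent images with a uniform background), splits the foreground into
#' 4-connected components, fills holes, and removes objects touching the
#' image border (cells cut by the field of view are unmeasurable).
#'
#' @param dna_channel 2-D nonnegative intensity matrix.
#' @param pixel_size micrometers per pixel.
#' @param strategy `"otsu"` (default), `"fixed"` (uses `threshold`) or
#'   `"quantile"` (uses `prob`).
#' @param threshold fixed global threshold, for `strategy = "fixed"`.
#' @param prob quantile for `strategy = "quantile"`.
#' @return a `labeled_mask`: list with `labels` (integer matrix, 0 =
#'   background, k = object k, labels contiguous) and `pixel_size`.
#' @export
segment_primary <- function(dna_channel, pixel_size = 0.5,
                            strategy = c("otsu", "fixed", "quantile"),
                            threshold = NULL, prob = 0.99) {
  strategy <- match.arg(strategy)
  if (!is.matrix(dna_channel) || !is.numeric(dna_channel))
    stop("dna_channel must be a 2-D numeric matrix")
  if (any(dna_channel < 0) || any(!is.finite(dna_channel)))
    stop("dna_channel must be nonnegative and finite")
  mx <- max(dna_channel)
  thr <- switch(strategy,
    otsu = if (mx == min(dna_channel)) mx else
      EBImage::otsu(EBImage::Image(dna_channel / mx), range = c(0, 1)) * mx,
    fixed = {
      if (is.null(threshold)) stop("strategy 'fixed' needs `threshold`")
      threshold
    },
    quantile = stats::quantile(dna_channel, prob, names = FALSE))
  fg <- dna_channel > thr
  lab <- EBImage::bwlabel(fg) # 4-connected components
  lab <- EBImage::fillHull(lab)
  lab <- drop_border_objects(as.matrix(lab))
  structure(list(labels = lab, pixel_size = pixel_size),
            class = "labeled_mask")
}

drop_border_objects <- function(lab) {
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) lab[lab %in% border] <- 0L
  relabel(lab)
}

relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- match(lab, c(0L, ids)) - 1L
  matrix(as.integer(out), nrow(lab), ncol(lab))
}

#' Restrict a labeled mask to a set of objects
#'
#' @param mask a `labeled_mask`.
#' @param object_ids labels to keep; everything else becomes background.
#'   Surviving objects keep their original ids.
#' @return a `labeled_mask`.
#' @export
keep_objects <- function(mask, object_ids) {
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$labels
  lab[!(lab %in% object_ids)] <- 0L
  mask$labels <- lab
  mask
}

#' Measure size and shape of segmented nuclei
#'
#' Equivalent diameter is derived from pixel area
#' (`2 * sqrt(area / pi) * pixel_size`); eccentricity comes from the
#' best-fit ellipse via second central moments — the ratio of the distance
#' between the ellipse foci to its major axis length, 0 for a circle, and
#' guaranteed in `[0, 1]`.
#'
#' @param mask a `labeled_mask`.
#' @return `data.frame` with `object_id`, `x`, `y` (centroid, px),
#'   `area_px`, `equivalent_diameter` (micrometers), `eccentricity`.
#' @export
measure_shape <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$labels
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids))
    return(data.frame(object_id = integer(0), x = numeric(0), y = numeric(0),
                      area_px = numeric(0), equivalent_diameter = numeric(0),
                      eccentricity = numeric(0)))
  # relabel contiguously for computeFeatures; row k then maps to ids[k]
  lab2 <- relabel(lab)
  mom <- EBImage::computeFeatures.moment(lab2)
  shp <- EBImage::computeFeatures.shape(lab2)
  area <- shp[, "s.area"]
  data.frame(object_id = ids,
             x = mom[, "m.cx"], y = mom[, "m.cy"],
             area_px = area,
             equivalent_diameter = 2 * sqrt(area / pi) * mask$pixel_size,
             eccentricity = pmin(pmax(mom[, "m.eccentricity"], 0), 1),
             row.names = NULL)
}

#' Filter nuclei on diameter and eccentricity
#'
#' Retains objects whose equivalent diameter lies in the inclusive
#' `[diameter_min, diameter_max]` window and whose eccentricity does not
#' exceed `eccentricity_max`, excluding lobed or irregular leukocyte nuclei.
#' Input order is preserved.
#'
#' @param objects output of [measure_shape()].
#' @param gates a [gate_config()].
#' @return subset of `objects`.
#' @export
filter_primary <- function(objects, gates) {
  stopifnot(inherits(gates, "gate_config"))
  keep <- objects$equivalent_diameter >= gates$diameter_min &
    objects$equivalent_diameter <= gates$diameter_max &
    objects$eccentricity <= gates$eccentricity_max
  objects[keep, , drop = FALSE]
}

#' Grow primary objects into secondary measurement objects
#'
#' Each object is expanded by up to `radius` pixels (Euclidean distance);
#' contested pixels are assigned to the nearest primary object, ties to the
#' lower label. Expansions never merge: the number of secondary objects
#' equals the number of primary objects.
#'
#' @param mask a `labeled_mask`.
#' @param radius expansion radius in pixels (>= 0).
#' @return a `labeled_mask` of secondary objects with identical labels.
#' @export
expand_secondary <- function(mask, radius = 3) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (radius < 0) stop("radius must be >= 0")
  lab <- mask$labels
  if (radius == 0) return(mask)
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(mask)
  best_d <- matrix(Inf, nrow(lab), ncol(lab))
  best_l <- matrix(0L, nrow(lab), ncol(lab))
  for (id in ids) {
    # distance of every pixel to the nearest pixel of object `id`
    d <- as.matrix(EBImage::distmap(matrix(as.numeric(lab != id),
                                           nrow(lab), ncol(lab))))
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_l[upd] <- id
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  within <- best_d <= radius
  out[within] <- best_l[within]
  mask$labels <- out
  mask
}

#' Mean marker intensity per object
#'
#' Arithmetic mean of the channel pixels under each label of the (usually
#' secondary) object mask.
#'
#' @param mask a `labeled_mask`.
#' @param channel intensity matrix, same dimensions as the mask.
#' @return named numeric vector, one mean per object id (ascending ids).
#' @export
measure_intensity <- function(mask, channel) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (!identical(dim(mask$labels), dim(channel)))
    stop("mask and channel dimensions differ")
  lab <- mask$labels
  sel <- lab > 0
  if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(channel[sel], lab[sel], mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Calibrate intensity gates from staining controls
#'
#' Sets each channel's positive threshold to `mean + k * SD` of the
#' isotype (negative) control intensities — the flow-cytometry-style
#' negative-control gate. If fewer than 90% of the positive-control cells
#' exceed the CK/EpCAM threshold, a calibration warning is raised.
#'
#' @param positive_control,isotype_control data frames with columns
#'   `mean_ck_epcam` and `mean_cd45`; `positive_control` may be `NULL` to
#'   skip the positivity check.
#' @param k SD multiplier (default 3).
#' @param gates template [gate_config()] whose morphology settings are kept.
#' @return a calibrated `gate_config`.
#' @export
calibrate_gates <- function(positive_control, isotype_control, k = 3,
                            gates = gate_config()) {
  if (is.null(isotype_control) || nrow(isotype_control) == 0)
    stop("isotype control is empty")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  ck_thr <- mean(isotype_control$mean_ck_epcam) +
    k * sd0(isotype_control$mean_ck_epcam)
  cd_thr <- mean(isotype_control$mean_cd45) +
    k * sd0(isotype_control$mean_cd45)
  if (!is.null(positive_control) && nrow(positive_control) > 0) {
    frac <- mean(positive_control$mean_ck_epcam > ck_thr)
    if (frac < 0.9)
      warning(sprintf(paste0("calibration warning: only %.0f%% of positive-",
                             "control cells exceed the CK/EpCAM gate"),
                      100 * frac))
  }
  gates$ck_epcam_positive_threshold <- ck_thr
  gates$cd45_positive_threshold <- cd_thr
  gates$calibration_k <- k
  gates
}

#' Classify cells from marker gates
#'
#' CTC: CK/EpCAM above gate and CD45 at or below gate (DAPI+CK/EpCAM+CD45-).
#' DUAL_POSITIVE: both above. WBC: only CD45 above. NEGATIVE: neither.
#' Every cell receives exactly one class.
#'
#' @param measurements data frame with `mean_ck_epcam`, `mean_cd45` (plus
#'   any shape columns, carried through).
#' @param gates calibrated [gate_config()].
#' @return `measurements` with an `assigned_class` column.
#' @export
classify_cells <- function(measurements, gates) {
  stopifnot(inherits(gates, "gate_config"))
  if (is.na(gates$ck_epcam_positive_threshold) ||
      is.na(gates$cd45_positive_threshold))
    stop("gates are not calibrated: intensity thresholds are NA")
  ck_pos <- measurements$mean_ck_epcam > gates$ck_epcam_positive_threshold
  cd_pos <- measurements$mean_cd45 > gates$cd45_positive_threshold
  cls <- ifelse(ck_pos & !cd_pos, "CTC",
         ifelse(ck_pos & cd_pos, "DUAL_POSITIVE",
         ifelse(cd_pos, "WBC", "NEGATIVE")))
  measurements$assigned_class <- cls
  measurements
}

#' Count cells per class and estimate CTC purity
#'
#' CTC purity is the CTC count divided by the total cell count in the
#' enrichment output; it feeds the somatic caller's variant-frequency
#' threshold. With zero cells the purity is flagged undefined rather than
#' reported as 0.
#'
#' @param records classified cell table (from [classify_cells()]).
#' @return an `enumeration_result`: list with `counts` (named, all four
#'   classes), `total_cells`, `ctc_purity`, `purity_defined`.
#' @export
enumerate_cells <- function(records) {
  cls <- factor(records$assigned_class, levels = cell_classes())
  counts <- c(table(cls))
  total <- sum(counts)
  structure(list(counts = counts, total_cells = total,
                 ctc_purity = if (total > 0) unname(counts["CTC"]) / total
                              else NA_real_,
                 purity_defined = total > 0),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat("CTC enumeration result\n")
  for (k in names(x$counts)) cat(sprintf("  %-14s %d\n", k, x$counts[[k]]))
  cat(sprintf("  total          %d\n", x$total_cells))
  cat(sprintf("  CTC purity     %s\n",
              if (x$purity_defined) sprintf("%.4f", x$ctc_purity)
              else "undefined (no cells)"))
  invisible(x)
}

#' Run the full enumeration pipeline on three channels
#'
#' Segmentation of the DNA channel, nuclear size/shape measurement,
#' diameter and eccentricity filtering, secondary-object expansion, mean
#' CK/EpCAM and CD45 intensity measurement, gating, and enumeration.
#'
#' @param dna,ck_epcam,cd45 channel matrices of equal dimension.
#' @param pixel_size micrometers per pixel.
#' @param gates calibrated [gate_config()].
#' @param strategy global threshold strategy for [segment_primary()].
#' @param ... passed to [segment_primary()].
#' @return list with `primary` (mask), `secondary` (mask), `objects`
#'   (all measured nuclei), `records` (filtered, classified cells), and
#'   `result` (an `enumeration_result`), plus the `gates` used.
#' @export
count_ctcs <- function(dna, ck_epcam, cd45, pixel_size = 0.5, gates,
                       strategy = "otsu", ...) {
  stopifnot(identical(dim(dna), dim(ck_epcam)),
            identical(dim(dna), dim(cd45)))
  primary <- segment_primary(dna, pixel_size, strategy, ...)
  objects <- measure_shape(primary)
  kept <- filter_primary(objects, gates)
  primary_kept <- keep_objects(primary, kept$object_id)
  secondary <- expand_secondary(primary_kept, gates$secondary_expand_radius)
  ck_mean <- measure_intensity(secondary, ck_epcam)
  cd_mean <- measure_intensity(secondary, cd45)
  meas <- kept
  meas$mean_ck_epcam <- unname(ck_mean[as.character(kept$object_id)])
  meas$mean_cd45 <- unname(cd_mean[as.character(kept$object_id)])
  records <- classify_cells(meas, gates)
  list(primary = primary, secondary = secondary, objects = objects,
       records = records, result = enumerate_cells(records), gates = gates)
}

#' Export per-class image galleries
#'
#' Writes one PNG montage per non-empty class, each tile a fixed-size crop
#' centered on the cell centroid with the standard color overlay: DNA/DAPI
#' blue, CK/EpCAM green, CD45 red.
#'
#' @param channels list with `dna`, `ck_epcam`, `cd45` matrices.
#' @param records classified cell table carrying `x`, `y`,
#'   `assigned_class`.
#' @param dir output directory.
#' @param tile crop side length in pixels (odd; default 41).
#' @return invisibly, named character vector of files written (per class).
#' @export
export_gallery <- function(channels, records, dir, tile = 41L) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create gallery directory: ", dir)
  tile <- as.integer(tile)
  if (tile %% 2 == 0) tile <- tile + 1L
  half <- (tile - 1L) %/% 2L
  hi <- vapply(channels, max, numeric(1))
  hi[hi == 0] <- 1
  crop <- function(ch, cx, cy, scale) {
    out <- matrix(0, tile, tile)
    xs <- (cx - half):(cx + half)
    ys <- (cy - half):(cy + half)
    okx <- xs >= 1 & xs <= nrow(ch)
    oky <- ys >= 1 & ys <= ncol(ch)
    out[okx, oky] <- ch[xs[okx], ys[oky]] / scale
    out
  }
  files <- character(0)
  for (cls in cell_classes()) {
    rows <- records[records$assigned_class == cls, , drop = FALSE]
    if (nrow(rows) == 0) next
    n <- nrow(rows)
    ncolm <- ceiling(sqrt(n))
    nrowm <- ceiling(n / ncolm)
    rgb <- array(0, dim = c(nrowm * tile, ncolm * tile, 3))
    for (i in seq_len(n)) {
      cx <- as.integer(round(rows$x[i]))
      cy <- as.integer(round(rows$y[i]))
      r <- (i - 1) %/% ncolm
      cc <- (i - 1) %% ncolm
      ix <- r * tile + seq_len(tile)
      iy <- cc * tile + seq_len(tile)
      rgb[ix, iy, 1] <- crop(channels$cd45, cx, cy, hi["cd45"])
      rgb[ix, iy, 2] <- crop(channels$ck_epcam, cx, cy, hi["ck_epcam"])
      rgb[ix, iy, 3] <- crop(channels$dna, cx, cy, hi["dna"])
    }
    path <- file.path(dir, paste0("gallery_", cls, ".png"))
    png::writePNG(aperm(pmin(rgb, 1), c(2, 1, 3)), path)
    files[cls] <- path
  }
  invisible(files)
}

#' Write the per-object measurement table as CSV
#'
#' @param records classified cell table.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
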