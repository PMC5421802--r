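#' Describe one synthetic cell
#'
#' Builds a one-row cell table for the synthetic fixture generator. Cells are
#' rendered as rasterized nuclei on the DNA (DAPI) channel; the CK/EpCAM and
#' CD45 channels carry the cell's marker intensity over the same footprint.
#'
#' @param x,y nucleus center in pixel coordinates; `NA` asks
#'   [generate_fixture()] to place the cell by rejection sampling.
#' @param diameter_um nucleus diameter in micrometers (per lobe).
#' @param n_lobes number of nuclear lobes; 1 renders a round (disk) nucleus,
#'   `k >= 2` a union of `k` overlapping offset disks, mimicking the lobed,
#'   irregular nuclei of granulocytic white blood cells.
#' @param ck_epcam,cd45 mean signal level of the cell on each marker channel
#'   (arbitrary units, `>= 0`).
#' @param true_class one of `"CTC"`, `"WBC"`, `"DUAL_POSITIVE"`, `"NEGATIVE"`.
#' @return a one-row `data.frame` with columns
#'   `x, y, diameter_um, n_lobes, ck_epcam, cd45, true_class`.
#' @export
#' @examples
#' cell_spec(diameter_um = 14, ck_epcam = 1500, cd45 = 50, true_class = "CTC")
cell_spec <- function(x = NA_real_, y = NA_real_, diameter_um = 12,
                      n_lobes = 1L, ck_epcam = 0, cd45 = 0,
                      true_class = c("CTC", "WBC", "DUAL_POSITIVE", "NEGATIVE")) {
  true_class <- match.arg(true_class)
  stopifnot(diameter_um > 0, n_lobes >= 1, ck_epcam >= 0, cd45 >= 0)
  data.frame(x = x, y = y, diameter_um = diameter_um,
             n_lobes = as.integer(n_lobes), ck_epcam = ck_epcam,
             cd45 = cd45, true_class = true_class,
             stringsAsFactors = FALSE)
}

cell_classes <- function() c("CTC", "WBC", "DUAL_POSITIVE", "NEGATIVE")

validate_cells <- function(cells) {
  need <- c("x", "y", "diameter_um", "n_lobes", "ck_epcam", "cd45", "true_class")
  if (!all(need %in% names(cells)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  if (nrow(cells) > 0) {
    stopifnot(all(cells$diameter_um > 0), all(cells$n_lobes >= 1),
              all(cells$ck_epcam >= 0), all(cells$cd45 >= 0),
              all(cells$true_class %in% cell_classes()))
  }
  cells
}

#' Default marker intensities and nuclear morphology per cell class
#'
#' Convenience constructor of a cell table emulating a microfluidic CTC
#' enrichment output: a few large, round, CK/EpCAM-positive CD45-negative
#' tumor cells in a background of smaller CD45-positive leukocytes whose
#' nuclei may be lobed. Positions are left `NA` for rejection-sampled
#' placement by [generate_fixture()].
#'
#' @param n_ctc,n_wbc,n_dual,n_negative number of cells per class.
#' @param ctc_diameter_um,wbc_diameter_um nucleus diameters (micrometers).
#' @param wbc_n_lobes lobe count for WBC nuclei; the default 3 gives a
#'   clearly elongated footprint excluded by the eccentricity filter, 1 gives
#'   round WBC nuclei that pass the shape filter and are classified by gating.
#' @param positive,negative marker signal levels for positive and negative
#'   staining (arbitrary units).
#' @return a cell `data.frame` as produced by [cell_spec()].
#' @export
fixture_cells <- function(n_ctc = 5, n_wbc = 20, n_dual = 0, n_negative = 0,
                          ctc_diameter_um = 16, wbc_diameter_um = 10,
                          wbc_n_lobes = 3L, positive = 1500, negative = 50) {
  one <- function(n, d, lobes, ck, cd, cls) {
    if (n == 0) return(NULL)
    do.call(rbind, replicate(n, cell_spec(
      diameter_um = d, n_lobes = lobes, ck_epcam = ck, cd45 = cd,
      true_class = cls), simplify = FALSE))
  }
  cells <- rbind(
    one(n_ctc, ctc_diameter_um, 1L, positive, negative, "CTC"),
    one(n_wbc, wbc_diameter_um, wbc_n_lobes, negative, positive, "WBC"),
    one(n_dual, ctc_diameter_um, 1L, positive, positive, "DUAL_POSITIVE"),
    one(n_negative, wbc_diameter_um, 1L, negative, negative, "NEGATIVE"))
  if (is.null(cells)) cells <- cell_spec()[0, ]
  rownames(cells) <- NULL
  cells
}

#' Configuration for the synthetic image generator
#'
#' @param image_size `c(width, height)` in pixels.
#' @param pixel_size micrometers per pixel (default 0.5).
#' @param background_level baseline signal of every channel (arbitrary units).
#' @param noise_sd standard deviation of additive Gaussian noise applied to
#'   all three channels; 0 gives noise-free images.
#' @param dna_intensity nuclear signal on the DNA channel.
#' @param cells cell table (see [cell_spec()], [fixture_cells()]).
#' @param seed integer seed; the same configuration and seed reproduce
#'   bit-identical channels.
#' @param max_retries rejection-sampling retries per cell before failing.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(image_size = c(512L, 512L), pixel_size = 0.5,
                           background_level = 100, noise_sd = 10,
                           dna_intensity = 2000,
                           cells = fixture_cells(), seed = 1L,
                           max_retries = 1000L) {
  stopifnot(length(image_size) == 2, all(image_size >= 8), pixel_size > 0,
            background_level >= 0, noise_sd >= 0, dna_intensity > 0)
  cells <- validate_cells(cells)
  max_d <- if (nrow(cells)) max(nucleus_extent_px(cells, pixel_size)) else 0
  if (max_d > min(image_size))
    stop("image too small to contain the largest nucleus (", round(max_d),
         " px footprint)")
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 background_level = background_level, noise_sd = noise_sd,
                 dna_intensity = dna_intensity, cells = cells,
                 seed = as.integer(seed), max_retries = as.integer(max_retries)),
            class = "fixture_config")
}

# full pixel extent of a nucleus along its lobe axis
nucleus_extent_px <- function(cells, pixel_size) {
  d <- cells$diameter_um / pixel_size
  d * (1 + 0.6 * (cells$n_lobes - 1))
}

#' Rasterize one nucleus footprint
#'
#' A round nucleus (`n_lobes = 1`) is a filled disk of the requested
#' diameter. A lobed nucleus is the union of `n_lobes` overlapping disks with
#' centers spaced 0.6 diameters apart along the x axis, giving an elongated
#' footprint whose fitted-ellipse eccentricity exceeds that of a disk.
#'
#' @param center `c(x, y)` in pixels.
#' @param diameter_um nucleus (lobe) diameter in micrometers.
#' @param n_lobes number of lobes (>= 1).
#' @param pixel_size micrometers per pixel.
#' @param dim image size `c(width, height)`; the mask is returned at this size.
#' @return logical matrix (`width x height`), `TRUE` inside the nucleus.
#' @export
#' @examples
#' m <- render_nucleus(c(32, 32), 15, 1, 0.5, c(64, 64))
#' sum(m) # ~ area of a 30 px disk
render_nucleus <- function(center, diameter_um, n_lobes = 1L, pixel_size = 0.5,
                           dim = c(64L, 64L)) {
  stopifnot(diameter_um > 0, n_lobes >= 1, pixel_size > 0)
  d_px <- diameter_um / pixel_size
  r <- d_px / 2
  extent <- d_px * (1 + 0.6 * (n_lobes - 1))
  if (extent > min(dim))
    stop("nucleus (", round(extent), " px) larger than image")
  # lobe centers along x, centered on `center`
  offs <- (seq_len(n_lobes) - (n_lobes + 1) / 2) * 0.6 * d_px
  xs <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1], dim[2])
  ys <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
  mask <- matrix(FALSE, dim[1], dim[2])
  for (o in offs)
    mask <- mask | ((xs - (center[1] + o))^2 + (ys - center[2])^2 <= r^2)
  mask
}

place_cells <- function(cells, image_size, pixel_size, max_retries) {
  n <- nrow(cells)
  if (n == 0) return(cells)
  ext <- nucleus_extent_px(cells, pixel_size)
  half <- ext / 2 + 1
  placed_x <- cells$x
  placed_y <- cells$y
  # overlap test between nuclear footprints approximated by their bounding
  # circles along the lobe axis (conservative: never accepts a true overlap);
  # the margin keeps rasterized footprints and their secondary expansions
  # from touching
  margin <- 8
  overlaps <- function(i, x, y) {
    j <- which(!is.na(placed_x))
    j <- j[j != i]
    if (!length(j)) return(FALSE)
    any(sqrt((placed_x[j] - x)^2 + (placed_y[j] - y)^2) <
          (ext[j] + ext[i]) / 2 + margin)
  }
  for (i in seq_len(n)) {
    if (!is.na(placed_x[i]) && !is.na(placed_y[i])) {
      if (overlaps(i, placed_x[i], placed_y[i]))
        stop("cell ", i, " overlaps a previously placed cell")
      next
    }
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      x <- stats::runif(1, half[i], image_size[1] - half[i])
      y <- stats::runif(1, half[i], image_size[2] - half[i])
      if (!overlaps(i, x, y)) {
        placed_x[i] <- x; placed_y[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place cell ", i, " after ", max_retries,
                  " retries; reduce cell number or enlarge the image")
  }
  cells$x <- placed_x
  cells$y <- placed_y
  cells
}

#' Generate a three-channel fluorescence image fixture with ground truth
#'
#' Renders every nucleus on the DNA channel at `dna_intensity` and each
#' cell's specified CK/EpCAM and CD45 signal over its nuclear footprint, on a
#' constant background with additive Gaussian noise (clipped at zero). Cells
#' with `NA` positions are placed by rejection sampling so that nuclear
#' footprints never overlap.
#'
#' @param config a [fixture_config()].
#' @return a `ctc_fixture` list with elements `dna`, `ck_epcam`, `cd45`
#'   (numeric matrices of equal dimension), `ground_truth` (cell table with
#'   a `cell_id` column and resolved positions), and `pixel_size`.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_config(cells = fixture_cells(2, 5), seed = 7))
#' dim(fx$dna); nrow(fx$ground_truth)
generate_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, {
    cells <- place_cells(config$cells, config$image_size, config$pixel_size,
                         config$max_retries)
    dim <- config$image_size
    dna <- matrix(config$background_level, dim[1], dim[2])
    ck <- matrix(config$background_level, dim[1], dim[2])
    cd <- matrix(config$background_level, dim[1], dim[2])
    for (i in seq_len(nrow(cells))) {
      m <- render_nucleus(c(cells$x[i], cells$y[i]), cells$diameter_um[i],
                          cells$n_lobes[i], config$pixel_size, dim)
      dna[m] <- config$dna_intensity
      ck[m] <- cells$ck_epcam[i]
      cd[m] <- cells$cd45[i]
    }
    if (config$noise_sd > 0) {
      dna <- dna + stats::rnorm(length(dna), 0, config$noise_sd)
      ck <- ck + stats::rnorm(length(ck), 0, config$noise_sd)
      cd <- cd + stats::rnorm(length(cd), 0, config$noise_sd)
    }
    dna <- pmax(dna, 0); ck <- pmax(ck, 0); cd <- pmax(cd, 0)
    gt <- cells
    if (nrow(gt)) gt <- cbind(cell_id = seq_len(nrow(gt)), gt)
    else gt <- cbind(cell_id = integer(0), gt)
    structure(list(dna = dna, ck_epcam = ck, cd45 = cd, ground_truth = gt,
                   pixel_size = config$pixel_size),
              class = "ctc_fixture")
  })
}

#' Ground-truth class counts of a fixture
#'
#' @param fixture a `ctc_fixture`.
#' @return named integer vector over all four classes; sums to the number of
#'   rendered cells.
#' @export
ground_truth_counts <- function(fixture) {
  stopifnot(inherits(fixture, "ctc_fixture"))
  cls <- factor(fixture$ground_truth$true_class, levels = cell_classes())
  table(cls) |> c()
}

#' Write fixture channels and ground truth to disk
#'
#' Channels go out as single-plane 16-bit grayscale TIFF (or 8-bit PNG);
#' intensities are scaled by the maximum over the three channels. Ground
#' truth is written as a CSV with header
#' `cell_id,x,y,diameter_um,n_lobes,ck_epcam,cd45,true_class`.
#'
#' @param fixture a `ctc_fixture`.
#' @param dir output directory (created if missing).
#' @param format `"tiff"` or `"png"`.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(fixture, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(fixture, "ctc_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hi <- max(fixture$dna, fixture$ck_epcam, fixture$cd45, 1)
  ext <- if (format == "tiff") "tif" else "png"
  paths <- file.path(dir, paste0(c("dna", "ck_epcam", "cd45"), ".", ext))
  chans <- list(fixture$dna, fixture$ck_epcam, fixture$cd45)
  for (i in 1:3) {
    img <- t(chans[[i]] / hi) # writers expect row-major (y, x)
    if (format == "tiff") tiff::writeTIFF(img, paths[i], bits.per.sample = 16L)
    else png::writePNG(img, paths[i])
  }
  gt_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(fixture$ground_truth, gt_path, row.names = FALSE)
  invisible(c(paths, gt_path))
}

#' Read one fluorescence channel from TIFF or PNG
#'
#' @param path file path; format chosen by extension.
#' @return numeric matrix in `(x, y)` orientation matching the generator.
#' @export
read_channel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  t(img)
}
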