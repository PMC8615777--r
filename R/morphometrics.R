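#' Shape descriptors for mycelial objects
#'
#' The three reported descriptors are the projected area A (silhouette
#' area, um^2), the elongation E (ratio of maximum to minimum Feret
#' diameter, >= 1) and the morphology number
#' `Mo = 2 * sqrt(pi * A) / (P * E) = sqrt(C) / E`, where
#' `C = 4 * pi * A / P^2` is the circularity and P the boundary length.
#' Mo is 1 for a smooth disk and approaches 0 for elongated hyphae.
#'
#' The perimeter uses a 4-direction Crofton estimate (intercept counts
#' along horizontal, vertical and both diagonal line families); naive
#' pixel-edge counting would overestimate P by up to ~27% on disks and
#' push compact pellets out of their Mo band.  Feret diameters come from
#' rotating calipers on the convex hull of the boundary pixel centres,
#' with a one-pixel extent correction.
#'
#' @name morphometrics
NULL

# Crofton perimeter of a logical mask, in pixels.
# P ~ (pi/8) * (N0 + N90 + (N45 + N135)/sqrt(2)) with N* the number of
# foreground/background transitions along each line family.
crofton_perimeter <- function(bw) {
  H <- nrow(bw) + 2L; W <- ncol(bw) + 2L
  p <- matrix(FALSE, H, W)
  p[2:(H - 1), 2:(W - 1)] <- bw
  n0 <- sum(p[, -1] != p[, -W])
  n90 <- sum(p[-1, ] != p[-H, ])
  n45 <- sum(p[-H, -1] != p[-1, -W])
  n135 <- sum(p[-H, -W] != p[-1, -1])
  (pi / 8) * (n0 + n90 + (n45 + n135) / sqrt(2))
}

# boundary pixel coordinates (x = col, y = row) of a logical mask:
# foreground pixels with at least one 4-neighbour outside the object
boundary_coords <- function(bw) {
  H <- nrow(bw); W <- ncol(bw)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- bw
  core <- pad[2:(H + 1), 2:(W + 1)]
  inner <- core &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  idx <- which(core & !inner, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

# Feret diameters by rotating calipers on the convex hull.
# Returns c(d_max, d_min) in pixels, including a +1 px extent correction
# so a rasterised disk of diameter d reports d, not d - 1.
feret_diameters <- function(coords) {
  if (nrow(coords) < 2) return(c(d_max = 1, d_min = 1))
  hull <- coords[grDevices::chull(coords[, 1], coords[, 2]), , drop = FALSE]
  h <- nrow(hull)
  if (h == 1) return(c(d_max = 1, d_min = 1))
  dmax <- 0
  for (i in seq_len(h - 1)) {
    d2 <- (hull[(i + 1):h, 1] - hull[i, 1])^2 + (hull[(i + 1):h, 2] - hull[i, 2])^2
    dmax <- max(dmax, d2)
  }
  dmax <- sqrt(dmax)
  if (h == 2) return(c(d_max = dmax + 1, d_min = 1))
  dmin <- Inf
  for (i in seq_len(h)) {
    j <- if (i == h) 1L else i + 1L
    ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    w <- max(abs((hull[, 1] - hull[i, 1]) * ey - (hull[, 2] - hull[i, 2]) * ex) / len)
    dmin <- min(dmin, w)
  }
  c(d_max = dmax + 1, d_min = dmin + 1)
}

#' Elongation from Feret diameters
#'
#' `E = d_max / d_min`, 1 for a disk, large for filaments.
#'
#' @param d_max,d_min maximum and minimum Feret diameters (um), with
#'   `d_max >= d_min > 0`.
#' @return The dimensionless elongation (>= 1).
#' @export
elongation <- function(d_max, d_min) {
  if (any(d_min <= 0)) abort("degenerate object: d_min must be > 0.",
                             class = "mycomorph_degenerate_object")
  if (any(d_max < d_min)) abort("d_max must be >= d_min.",
                                class = "mycomorph_parameter_error")
  d_max / d_min
}

#' Morphology number
#'
#' `Mo = 2 * sqrt(pi * A) / (P * E)`, i.e. the square root of the
#' circularity divided by the elongation; decreasing in both P and E,
#' exactly 1 for a smooth disk.
#'
#' @param area projected area A (um^2, > 0).
#' @param perimeter boundary length P (um, > 0).
#' @param elongation elongation E (>= 1).
#' @return The dimensionless morphology number.
#' @export
morphology_number <- function(area, perimeter, elongation) {
  if (any(area <= 0) || any(perimeter <= 0))
    abort("`area` and `perimeter` must be > 0.", class = "mycomorph_parameter_error")
  if (any(elongation < 1)) abort("`elongation` must be >= 1.",
                                 class = "mycomorph_parameter_error")
  2 * sqrt(pi * area) / (perimeter * elongation)
}

#' Measure one labelled object
#'
#' Computes the full descriptor vector of a single object: projected area
#' (pixel count x scale^2), Crofton perimeter, Feret diameters, centroid,
#' circularity, elongation and morphology number.
#'
#' @param mask a `labeled_mask` from [segment_image()] (or any integer
#'   label matrix).
#' @param label positive integer label present in the mask.
#' @param scale_um micrometres per pixel; defaults to the mask's own
#'   calibration attribute.
#' @return One-row tibble with columns `label, area_um2, perimeter_um,
#'   feret_max_um, feret_min_um, circularity, elongation,
#'   morphology_number, centroid_x_um, centroid_y_um, border_touching`.
#' @export
measure_object <- function(mask, label, scale_um = attr(mask, "scale_um")) {
  if (is.null(scale_um)) abort("`scale_um` is required.", class = "mycomorph_parameter_error")
  bw <- mask == label
  npx <- sum(bw)
  if (npx == 0) abort(sprintf("label %d not present in mask.", label),
                      class = "mycomorph_parameter_error")
  if (npx < 4) abort(sprintf("label %d is a degenerate (<4 px) object.", label),
                     class = "mycomorph_degenerate_object")
  area <- npx * scale_um^2
  per <- crofton_perimeter(bw) * scale_um
  fer <- feret_diameters(boundary_coords(bw)) * scale_um
  E <- elongation(fer["d_max"], fer["d_min"])
  Mo <- morphology_number(area, per, E)
  idx <- which(bw, arr.ind = TRUE)
  H <- nrow(mask); W <- ncol(mask)
  tibble(
    label = as.integer(label),
    area_um2 = area, perimeter_um = per,
    feret_max_um = unname(fer["d_max"]), feret_min_um = unname(fer["d_min"]),
    circularity = 4 * pi * area / per^2,
    elongation = unname(E), morphology_number = unname(Mo),
    centroid_x_um = mean(idx[, 2]) * scale_um,
    centroid_y_um = mean(idx[, 1]) * scale_um,
    border_touching = any(idx[, 1] == 1L | idx[, 1] == H |
                          idx[, 2] == 1L | idx[, 2] == W)
  )
}

#' Measure every object of a mask
#'
#' One row per label in label order, carrying the image metadata.
#' Degenerate objects (fewer than 4 pixels) are skipped with a warning
#' rather than failing the whole table.
#'
#' @param mask a `labeled_mask`.
#' @param image optional [calibrated_image] supplying metadata (scale,
#'   experiment, culture, time); defaults to the mask's attributes.
#' @return Tibble with metadata columns `experiment, culture, time_h`
#'   followed by the [measure_object()] descriptor columns.
#' @export
measure_objects <- function(mask, image = NULL) {
  scale_um <- if (!is.null(image)) image$scale_um else attr(mask, "scale_um")
  meta <- list(
    experiment = if (!is.null(image)) image$experiment else attr(mask, "experiment"),
    culture = if (!is.null(image)) image$culture else attr(mask, "culture"),
    time_h = if (!is.null(image)) image$time_h else attr(mask, "time_h")
  )
  labels <- sort(unique(as.vector(mask[mask != 0])))
  rows <- list()
  for (lb in labels) {
    row <- tryCatch(measure_object(mask, lb, scale_um),
                    mycomorph_degenerate_object = function(e) {
                      warn(sprintf("skipping label %d: %s", lb, conditionMessage(e)))
                      NULL
                    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows) == 0) measure_object_prototype() else list_rbind(rows)
  bind_cols(tibble(experiment = rep(meta$experiment %||% NA_character_, nrow(out)),
                   culture = rep(meta$culture %||% NA_character_, nrow(out)),
                   time_h = rep(meta$time_h %||% NA_real_, nrow(out))),
            out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

measure_object_prototype <- function() {
  tibble(label = integer(), area_um2 = double(), perimeter_um = double(),
         feret_max_um = double(), feret_min_um = double(), circularity = double(),
         elongation = double(), morphology_number = double(),
         centroid_x_um = double(), centroid_y_um = double(),
         border_touching = logical())
}
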