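#' Calibrated grayscale image
#'
#' Lightweight container pairing a pixel matrix (grayscale in `[0, 1]`,
#' row = y, column = x) with its physical calibration and culture metadata.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param scale_um micrometres per pixel (> 0).
#' @param experiment experiment identifier string.
#' @param culture one of `"monoA"`, `"monoB"`, `"coculture"`.
#' @param time_h sampling time in hours (>= 0).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, scale_um,
                             experiment = NA_character_,
                             culture = NA_character_,
                             time_h = NA_real_) {
  if (!is.matrix(pixels)) abort("`pixels` must be a 2-D matrix.",
                                class = "mycomorph_parameter_error")
  if (!is.numeric(scale_um) || scale_um <= 0)
    abort("`scale_um` must be a positive number.", class = "mycomorph_parameter_error")
  if (!is.na(culture) && !culture %in% .cultures)
    abort("`culture` must be monoA, monoB or coculture.",
          class = "mycomorph_parameter_error")
  structure(
    list(pixels = pixels, scale_um = scale_um, experiment = experiment,
         culture = culture, time_h = time_h),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image %d x %d px, %.3g um/px, %s / %s / %s h>\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_um,
              x$experiment, x$culture, format(x$time_h)))
  invisible(x)
}

# ---- rasterisers -----------------------------------------------------------
# All rasterisers return list(rows, cols, mask) where mask is a logical
# matrix over the bounding box [rows] x [cols] in pixel indices.

# pellet / clump core: polar test rho <= R + amp * sin(k theta + phase),
# after anisotropic scaling that turns the disk into an area-preserving
# ellipse with Feret axis ratio `axis_ratio`.
raster_fringed_ellipse <- function(cx, cy, r_px, amp_px, lobes, phase,
                                   axis_ratio, orientation, dim_hw) {
  half <- ceiling((r_px + amp_px) * sqrt(axis_ratio)) + 2L
  rows <- max(1L, floor(cy) - half):min(dim_hw[1], ceiling(cy) + half)
  cols <- max(1L, floor(cx) - half):min(dim_hw[2], ceiling(cx) + half)
  dx <- matrix(rep(cols - cx, each = length(rows)), nrow = length(rows))
  dy <- matrix(rep(rows - cy, times = length(cols)), nrow = length(rows))
  u <- (dx * cos(orientation) + dy * sin(orientation)) / sqrt(axis_ratio)
  v <- (-dx * sin(orientation) + dy * cos(orientation)) * sqrt(axis_ratio)
  rho <- sqrt(u^2 + v^2)
  rb <- r_px + if (amp_px > 0) amp_px * sin(lobes * atan2(v, u) + phase) else 0
  list(rows = rows, cols = cols, mask = rho <= rb)
}

raster_pellet <- function(obj, scale_um, dim_hw) {
  r_px <- obj$core_radius_um / scale_um
  amp_px <- obj$fringe_depth_um / (2 * scale_um)
  lobes <- if (obj$fringe_density > 0) max(2L, round(obj$fringe_density * 64)) else 0L
  raster_fringed_ellipse(obj$center_x_um / scale_um, obj$center_y_um / scale_um,
                         r_px, if (lobes > 0) amp_px else 0, lobes,
                         obj$fringe_phase, obj$axis_ratio, obj$orientation, dim_hw)
}

# clump: union of 3-8 jittered fringed ellipses spread along the major axis
raster_clump <- function(obj, scale_um, dim_hw) {
  cx <- obj$center_x_um / scale_um; cy <- obj$center_y_um / scale_um
  r_px <- obj$core_radius_um / scale_um
  ar <- obj$axis_ratio
  with_seed(obj$shape_seed, {
    m <- sample(3:8, 1)
    # chained sub-ellipses: evenly spaced along the major axis with jitter
    # small enough that neighbours always overlap (connected blob)
    off_u <- (seq(-0.55, 0.55, length.out = m) + runif(m, -0.05, 0.05)) *
      r_px * sqrt(ar)
    off_v <- runif(m, -0.25, 0.25) * r_px / sqrt(ar)
    sub_r <- runif(m, 0.45, 0.60) * r_px
    sub_ar <- runif(m, 1.2, 2.0)
    sub_or <- obj$orientation + rnorm(m, 0, 0.4)
    sub_ph <- runif(m, 0, 2 * pi)
  })
  half <- ceiling(r_px * sqrt(ar) * 1.4 + max(sub_r) * 1.6) + 2L
  rows <- max(1L, floor(cy) - half):min(dim_hw[1], ceiling(cy) + half)
  cols <- max(1L, floor(cx) - half):min(dim_hw[2], ceiling(cx) + half)
  acc <- matrix(FALSE, length(rows), length(cols))
  lobes <- max(2L, round(obj$fringe_density * 48))
  amp_frac <- obj$fringe_depth_um / obj$core_radius_um / 2  # relative raggedness
  for (i in seq_len(m)) {
    scx <- cx + off_u[i] * cos(obj$orientation) - off_v[i] * sin(obj$orientation)
    scy <- cy + off_u[i] * sin(obj$orientation) + off_v[i] * cos(obj$orientation)
    sub <- raster_fringed_ellipse(scx, scy, sub_r[i], amp_frac * sub_r[i], lobes,
                                  sub_ph[i], sub_ar[i], sub_or[i], dim_hw)
    ri <- match(sub$rows, rows); ci <- match(sub$cols, cols)
    keep_r <- !is.na(ri); keep_c <- !is.na(ci)
    acc[ri[keep_r], ci[keep_c]] <-
      acc[ri[keep_r], ci[keep_c]] | sub$mask[keep_r, keep_c, drop = FALSE]
  }
  list(rows = rows, cols = cols, mask = acc)
}

# hypha: tube of constant thickness along a smooth curve whose heading
# swings by +/- tortuosity radians (two-harmonic perturbation)
hypha_path <- function(obj, scale_um) {
  L <- obj$length_um / scale_um
  step <- 0.5
  s <- seq(0, L, by = step)
  with_seed(obj$shape_seed, {
    n1 <- sample(1:2, 1); n2 <- sample(2:4, 1)
    ph <- runif(2, 0, 2 * pi)
  })
  theta <- obj$orientation +
    obj$tortuosity * (sin(2 * pi * n1 * s / L + ph[1]) +
                      0.5 * sin(2 * pi * n2 * s / L + ph[2])) / 1.5
  x <- cumsum(c(0, diff(s) * cos(theta[-1])))
  y <- cumsum(c(0, diff(s) * sin(theta[-1])))
  cbind(x - mean(range(x)), y - mean(range(y)))
}

raster_hypha <- function(obj, scale_um, dim_hw) {
  cx <- obj$center_x_um / scale_um; cy <- obj$center_y_um / scale_um
  path <- hypha_path(obj, scale_um)
  rad <- obj$thickness_um / (2 * scale_um)
  # trim the skeleton so that end caps stay inside the nominal length
  L_px <- obj$length_um / scale_um
  s_vals <- (seq_len(nrow(path)) - 1) * 0.5
  keep <- which(s_vals >= rad & s_vals <= L_px - rad)
  if (length(keep) == 0) keep <- round(nrow(path) / 2)
  px <- path[keep, 1] + cx; py <- path[keep, 2] + cy
  half_x <- diff(range(path[, 1])) / 2 + rad + 2
  half_y <- diff(range(path[, 2])) / 2 + rad + 2
  rows <- max(1L, floor(cy - half_y)):min(dim_hw[1], ceiling(cy + half_y))
  cols <- max(1L, floor(cx - half_x)):min(dim_hw[2], ceiling(cx + half_x))
  acc <- matrix(FALSE, length(rows), length(cols))
  # stamp a disk at each sample around its *fractional* centre, so the
  # average tube width converges to the nominal thickness
  rr <- ceiling(rad) + 1L
  off <- as.matrix(expand.grid(dr = -rr:rr, dc = -rr:rr))
  for (k in seq_along(px)) {
    r0 <- round(py[k]); c0 <- round(px[k])
    ri <- r0 + off[, 1]; ci <- c0 + off[, 2]
    hit <- (ri - py[k])^2 + (ci - px[k])^2 <= rad^2
    ri <- ri - rows[1] + 1L; ci <- ci - cols[1] + 1L
    ok <- hit & ri >= 1L & ri <= nrow(acc) & ci >= 1L & ci <= ncol(acc)
    acc[cbind(ri[ok], ci[ok])] <- TRUE
  }
  list(rows = rows, cols = cols, mask = acc)
}

object_bounding_radius_um <- function(objects, scale_um) {
  vapply(seq_len(nrow(objects)), function(i) {
    o <- objects[i, ]
    switch(o$kind,
      pellet = (o$core_radius_um + o$fringe_depth_um) * sqrt(o$axis_ratio),
      clump = o$core_radius_um * (0.62 * sqrt(o$axis_ratio) + 0.95),
      hypha = {
        p <- hypha_path(o, scale_um) * scale_um
        max(sqrt(p[, 1]^2 + p[, 2]^2)) + o$thickness_um / 2
      })
  }, numeric(1))
}

#' Assemble a renderable scene from sampled objects
#'
#' Places objects (largest first) uniformly at random inside the frame so
#' that bounding circles do not overlap and stay clear of the border,
#' unless centres were already assigned in the object table.
#'
#' @param objects object tibble from [sample_population()].
#' @param image_size frame size in pixels, `c(height, width)`.
#' @param scale_um micrometres per pixel.
#' @param background,foreground background and object grayscale levels in
#'   `[0, 1]` (dark objects on a bright background).
#' @param noise_sd additive Gaussian noise SD (grayscale units).
#' @param halo phase-contrast bright-rim strength added just outside each
#'   object boundary; 0 disables the halo.
#' @param margin_um minimal clearance between bounding circles and to the
#'   frame border.
#' @param allow_border if `TRUE` objects may touch the border (placement
#'   then only keeps centres in-frame).
#' @param seed integer seed for placement and rendering noise.
#' @param experiment,culture,time_h metadata forwarded to the rendered
#'   [calibrated_image()].
#' @return A `scene_spec` list understood by [render_scene()].
#' @export
build_scene <- function(objects, image_size = c(1024L, 1024L), scale_um = 2,
                        background = 0.80, foreground = 0.25,
                        noise_sd = 0.04, halo = 0.10, margin_um = 20,
                        allow_border = FALSE, seed = 1L,
                        experiment = "synthetic", culture = "coculture",
                        time_h = 0) {
  seed <- as.integer(seed)
  frame_um <- rev(image_size) * scale_um  # (x extent, y extent)
  rad <- object_bounding_radius_um(objects, scale_um)
  ord <- order(rad, decreasing = TRUE)
  objects <- objects[ord, ]
  rad <- rad[ord]
  need <- which(is.na(objects$center_x_um))
  with_seed(seed + 1L, {
    placed_x <- objects$center_x_um
    placed_y <- objects$center_y_um
    for (i in need) {
      lo <- if (allow_border) 0 else rad[i] + margin_um
      if (frame_um[1] - lo <= lo || frame_um[2] - lo <= lo)
        abort("object too large for the frame.", class = "mycomorph_placement_error")
      ok <- FALSE
      for (try in 1:4000) {
        x <- runif(1, lo, frame_um[1] - lo)
        y <- runif(1, lo, frame_um[2] - lo)
        others <- !is.na(placed_x)
        if (!any(others) ||
            all(sqrt((placed_x[others] - x)^2 + (placed_y[others] - y)^2) >
                rad[others] + rad[i] + margin_um)) {
          ok <- TRUE; break
        }
      }
      if (!ok) abort("could not place all objects without overlap; reduce count or size.",
                     class = "mycomorph_placement_error")
      placed_x[i] <- x; placed_y[i] <- y
    }
  })
  objects$center_x_um <- placed_x
  objects$center_y_um <- placed_y
  structure(
    list(objects = objects, image_size = as.integer(image_size),
         scale_um = scale_um, background = background, foreground = foreground,
         noise_sd = noise_sd, halo = halo, seed = seed,
         experiment = experiment, culture = culture, time_h = time_h),
    class = "scene_spec"
  )
}

#' Render a synthetic phase-contrast scene with ground truth
#'
#' Rasterises every object of the scene into a shared frame, producing the
#' grayscale image (dark bodies, optional bright halo rim, additive
#' Gaussian noise), an integer label map of the ground truth (background 0,
#' objects labelled in placement order) and a per-object truth table.
#' Rendering is bit-identical for identical scene specs.
#'
#' @param scene a `scene_spec` from [build_scene()].
#' @return A list of class `morph_scene` with elements `image`
#'   ([calibrated_image]), `mask` (integer label matrix) and `truth`
#'   (tibble: one row per object with its generative parameters, rasterised
#'   `true_area_um2_raster`, `border_touching` and `overlaps` flags).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  H <- scene$image_size[1]; W <- scene$image_size[2]
  lab <- matrix(0L, H, W)
  objs <- scene$objects
  n <- nrow(objs)
  raster_area <- numeric(n); overlaps <- logical(n); border <- logical(n)
  for (i in seq_len(n)) {
    o <- objs[i, ]
    r <- switch(o$kind,
      pellet = raster_pellet(o, scene$scale_um, c(H, W)),
      clump = raster_clump(o, scene$scale_um, c(H, W)),
      hypha = raster_hypha(o, scene$scale_um, c(H, W)))
    sub <- lab[r$rows, r$cols, drop = FALSE]
    hit <- r$mask & sub != 0L
    if (any(hit)) {
      overlaps[i] <- TRUE
      overlaps[unique(sub[hit])] <- TRUE
    }
    sub[r$mask] <- i
    lab[r$rows, r$cols] <- sub
    raster_area[i] <- sum(r$mask) * scene$scale_um^2
    border[i] <- any(r$mask[1, ]) && r$rows[1] == 1L ||
      any(r$mask[nrow(r$mask), ]) && r$rows[length(r$rows)] == H ||
      any(r$mask[, 1]) && r$cols[1] == 1L ||
      any(r$mask[, ncol(r$mask)]) && r$cols[length(r$cols)] == W
  }
  img <- matrix(scene$background, H, W)
  fg <- lab != 0L
  img[fg] <- scene$foreground
  if (scene$halo > 0) {
    rim <- dilate3x3(fg) & !fg
    img[rim] <- pmin(1, scene$background + scene$halo)
  }
  with_seed(scene$seed, {
    img <- img + matrix(rnorm(H * W, 0, scene$noise_sd), H, W)
  })
  img <- pmin(pmax(img, 0), 1)
  truth <- objs |>
    mutate(label = dplyr::row_number(), .before = 1) |>
    mutate(true_area_um2_raster = raster_area,
           overlaps = overlaps, border_touching = border)
  structure(
    list(image = calibrated_image(img, scene$scale_um, scene$experiment,
                                  scene$culture, scene$time_h),
         mask = lab, truth = truth, spec = scene),
    class = "morph_scene"
  )
}

# binary dilation with a 3x3 structuring element via shifts
dilate3x3 <- function(bw) {
  H <- nrow(bw); W <- ncol(bw)
  out <- bw
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    if (dr == 0 && dc == 0) next
    r_src <- max(1, 1 - dr):min(H, H - dr)
    c_src <- max(1, 1 - dc):min(W, W - dc)
    out[r_src + dr, c_src + dc] <- out[r_src + dr, c_src + dc] | bw[r_src, c_src]
  }
  out
}

#' Write / read a rendered scene as plain image files
#'
#' The image and label mask go to single-page 16-bit grayscale TIFF
#' (`<name>.tif`, `<name>_mask.tif`; labels are stored as value/65535 and
#' recovered on read), the truth table to `<name>_truth.csv`.
#'
#' @param scene a rendered `morph_scene`.
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  stopifnot(inherits(scene, "morph_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(name, ".tif"))
  mask_path <- file.path(dir, paste0(name, "_mask.tif"))
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  tiff::writeTIFF(scene$image$pixels, img_path, bits.per.sample = 16L)
  tiff::writeTIFF(scene$mask / 65535, mask_path, bits.per.sample = 16L)
  readr::write_csv(scene$truth, truth_path)
  invisible(c(img_path, mask_path, truth_path))
}

#' @param path TIFF or PNG file.
#' @param scale_um,experiment,culture,time_h calibration and metadata for
#'   the image being read.
#' @rdname write_scene
#' @export
read_calibrated_image <- function(path, scale_um, experiment = NA_character_,
                                  culture = NA_character_, time_h = NA_real_) {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
        else tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  calibrated_image(px, scale_um, experiment, culture, time_h)
}

#' @rdname write_scene
#' @export
read_label_mask <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  matrix(as.integer(round(px * 65535)), nrow(px), ncol(px))
}
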