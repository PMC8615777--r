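#' Segmentation parameters
#'
#' Tunable knobs of the semiautomatic segmentation front end.  The
#' binarisation rule is Otsu's threshold on the median-filtered intensity
#' by default (objects are darker than the background); the Sobel gradient
#' magnitude is available as an alternative threshold channel and for
#' boundary QC.
#'
#' @param median_radius median-filter radius in pixels (0 = no smoothing).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold grayscale cut in `[0, 1]` used when
#'   `threshold_method = "fixed"`.
#' @param channel threshold channel: `"intensity"` (dark objects) or
#'   `"gradient"` (bright edges).
#' @param min_object_area_um2 components smaller than this physical area
#'   are discarded (resolution-invariant: converted to pixels via the
#'   image scale).
#' @param fill_holes fill interior holes of each component.
#' @param exclude_border drop components touching the frame border (their
#'   area is censored); set `FALSE` to keep them.
#' @param otsu_guard_sd contrast guard for automatic thresholding: the
#'   foreground and background class means must differ by at least this
#'   many background-class standard deviations, otherwise the image is
#'   treated as empty (Otsu always splits even pure noise).  Ignored for
#'   fixed thresholds.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(median_radius = 2L,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.5,
                                channel = c("intensity", "gradient"),
                                min_object_area_um2 = 500,
                                fill_holes = TRUE,
                                exclude_border = TRUE,
                                otsu_guard_sd = 4) {
  threshold_method <- match.arg(threshold_method)
  channel <- match.arg(channel)
  if (median_radius < 0) abort("`median_radius` must be >= 0.",
                               class = "mycomorph_parameter_error")
  if (min_object_area_um2 < 0) abort("`min_object_area_um2` must be >= 0.",
                                     class = "mycomorph_parameter_error")
  structure(list(median_radius = as.integer(median_radius),
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold, channel = channel,
                 min_object_area_um2 = min_object_area_um2,
                 fill_holes = fill_holes, exclude_border = exclude_border,
                 otsu_guard_sd = otsu_guard_sd),
            class = "segmentation_params")
}

#' Median-filter smoothing
#'
#' Smooths object edges with a square median filter of the given radius;
#' radius 0 returns the input unchanged.  Metadata is preserved.
#'
#' @param image a [calibrated_image].
#' @param median_radius filter radius in pixels.
#' @return A [calibrated_image] with filtered pixels.
#' @export
preprocess <- function(image, median_radius = 2L) {
  stopifnot(inherits(image, "calibrated_image"))
  if (median_radius < 0) abort("`median_radius` must be >= 0.",
                               class = "mycomorph_parameter_error")
  if (median_radius == 0) return(image)
  image$pixels <- as.matrix(EBImage::medianFilter(image$pixels, as.integer(median_radius)))
  image
}

#' Sobel gradient magnitude
#'
#' Gradient magnitude from the two orthogonal 3x3 Sobel kernels; used for
#' edge detection and as an optional segmentation channel.
#'
#' @param image a [calibrated_image] (ideally already median-filtered).
#' @return A non-negative numeric matrix of the same shape.
#' @export
detect_edges <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3x3(px, kx)
  gy <- conv3x3(px, t(kx))
  sqrt(gx^2 + gy^2)
}

# 3x3 convolution with edge replication, via shifts (no FFT wrap-around)
conv3x3 <- function(px, k) {
  H <- nrow(px); W <- ncol(px)
  pad <- rbind(px[1, , drop = FALSE], px, px[H, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, W, drop = FALSE])
  out <- matrix(0, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    if (w != 0) out <- out + w * pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  out
}

# 8-connected components labelled in raster order.  EBImage::bwlabel is
# 4-connected, so diagonal-adjacent labels are merged with a union-find
# pass before relabelling by first-pixel position (column-major scan).
label_components8 <- function(bw) {
  lab <- as.matrix(EBImage::bwlabel(bw))
  k <- max(lab)
  if (k > 1) {
    H <- nrow(lab); W <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1]))
    )
    pairs <- pairs[pairs[, 1] != 0 & pairs[, 2] != 0 & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0) {
      parent <- seq_len(k)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (p in seq_len(nrow(pairs))) {
        a <- find(pairs[p, 1]); b <- find(pairs[p, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(k), find, integer(1))
      lab[lab != 0] <- root[lab[lab != 0]]
    }
  }
  relabel_raster_order(lab)
}

relabel_raster_order <- function(lab) {
  ids <- lab[lab != 0]
  if (length(ids) == 0) return(lab)
  first <- tapply(seq_along(lab)[lab != 0], ids, min)
  new_of <- integer(max(as.integer(names(first))))
  new_of[as.integer(names(first))[order(first)]] <- seq_along(first)
  lab[lab != 0] <- new_of[lab[lab != 0]]
  lab
}

#' Segment a calibrated image into labelled objects
#'
#' Median smoothing, binarisation (Otsu on the intensity by default, Sobel
#' gradient as an alternative channel, or a fixed cut), optional hole
#' filling, removal of components below the physical minimum area and of
#' border-touching components, and 8-connected labelling in raster order.
#'
#' @param image a [calibrated_image].
#' @param params a [segmentation_params] object.
#' @return An integer label matrix (class `labeled_mask`) with background
#'   0 and objects 1..K; the image scale and metadata travel along as
#'   attributes.
#' @export
segment_image <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "calibrated_image"))
  stopifnot(inherits(params, "segmentation_params"))
  sm <- preprocess(image, params$median_radius)
  if (params$channel == "gradient") {
    ch <- detect_edges(sm)
    rng <- range(ch)
    if (diff(rng) < 1e-8) {
      warn("uniform gradient channel: no objects found.")
      return(empty_mask(image))
    }
    chn <- (ch - rng[1]) / diff(rng)
    thr <- if (params$threshold_method == "otsu") EBImage::otsu(chn) else params$fixed_threshold
    bw <- chn > thr
    if (params$threshold_method == "otsu" &&
        contrast_too_low(chn[bw], chn[!bw], params$otsu_guard_sd)) {
      warn("no contrast between edge and background classes: zero objects found.")
      return(empty_mask(image))
    }
    # (gradient channel: foreground is the bright edge class)
  } else {
    px <- sm$pixels
    if (diff(range(px)) < 1e-8) {
      warn("uniform intensity image: no objects found.")
      return(empty_mask(image))
    }
    thr <- if (params$threshold_method == "otsu") EBImage::otsu(px) else params$fixed_threshold
    bw <- px < thr  # objects are darker than the background
    if (params$threshold_method == "otsu" &&
        contrast_too_low(px[bw], px[!bw], params$otsu_guard_sd)) {
      warn("no contrast between foreground and background classes: zero objects found.")
      return(empty_mask(image))
    }
  }
  if (params$fill_holes) bw <- as.matrix(EBImage::fillHull(bw * 1L)) > 0
  lab <- label_components8(bw)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab != 0], nbins = max(lab))
    drop <- which(sizes * image$scale_um^2 < params$min_object_area_um2)
    if (params$exclude_border) {
      edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      drop <- union(drop, edge[edge != 0])
    }
    if (length(drop) > 0) lab[lab %in% drop] <- 0L
    lab <- relabel_raster_order(lab)
  }
  if (max(lab) == 0) warn("segmentation produced zero objects.")
  as_labeled_mask(lab, image)
}

# TRUE when the thresholded classes are not genuinely separated: the class
# means must differ by at least `guard` background-class SDs
contrast_too_low <- function(fg_vals, bg_vals, guard) {
  if (length(fg_vals) == 0 || length(bg_vals) == 0) return(TRUE)
  bg_sd <- if (length(bg_vals) > 1) sd(bg_vals) else 0
  abs(mean(fg_vals) - mean(bg_vals)) < guard * bg_sd
}

empty_mask <- function(image) {
  as_labeled_mask(matrix(0L, nrow(image$pixels), ncol(image$pixels)), image)
}

as_labeled_mask <- function(lab, image) {
  structure(lab, class = c("labeled_mask", class(matrix())),
            scale_um = image$scale_um, experiment = image$experiment,
            culture = image$culture, time_h = image$time_h)
}

#' Apply declarative operator overrides to a label mask
#'
#' The "operator" of the semiautomatic workflow is replayed from a
#' declarative edit table, making manual corrections reproducible.  Edits
#' are applied in row order.  Supported actions: `delete` (remove a
#' label), `merge` (fuse a label set, `arg = "l1;l2;..."`, lowest label
#' wins), `split` (partition a label among seed points,
#' `arg = "x1,y1;x2,y2;..."` in pixel coordinates; the first seed keeps
#' the old label, the rest get fresh labels), `species` (tag a label with
#' a species call, `arg = "A"` or `"B"`, consumed by the classification
#' stage).  Labels are not renumbered so later edits can refer to them.
#'
#' @param mask a `labeled_mask`.
#' @param edits tibble/data frame with columns `label`, `action`, `arg`.
#' @return The edited mask; the audit log is attached as attribute
#'   `"audit"` and species tags as attribute `"species_tags"`.
#' @export
apply_overrides <- function(mask, edits) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (is.null(edits) || nrow(edits) == 0) return(mask)
  audit <- character(0)
  tags <- tibble(label = integer(), species = character())
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    lb <- as.integer(e$label)
    if (!lb %in% mask)
      abort(sprintf("override row %d refers to nonexistent label %d.", i, lb),
            class = "mycomorph_edit_error")
    if (e$action == "delete") {
      mask[mask == lb] <- 0L
      audit <- c(audit, sprintf("delete %d", lb))
    } else if (e$action == "merge") {
      group <- sort(unique(c(lb, as.integer(strsplit(as.character(e$arg), ";")[[1]]))))
      missing <- setdiff(group, unique(as.vector(mask)))
      if (length(missing) > 0)
        abort(sprintf("override row %d merges nonexistent label(s) %s.",
                      i, paste(missing, collapse = ",")),
              class = "mycomorph_edit_error")
      mask[mask %in% group] <- group[1]
      audit <- c(audit, sprintf("merge {%s} -> %d", paste(group, collapse = ","), group[1]))
    } else if (e$action == "split") {
      seeds <- do.call(rbind, lapply(strsplit(strsplit(as.character(e$arg), ";")[[1]], ","),
                                     as.numeric))
      pix <- which(mask == lb, arr.ind = TRUE)  # (row=y, col=x)
      d <- vapply(seq_len(nrow(seeds)), function(s)
        (pix[, 2] - seeds[s, 1])^2 + (pix[, 1] - seeds[s, 2])^2, numeric(nrow(pix)))
      assign_to <- max.col(-d)
      new_labels <- c(lb, max(mask) + seq_len(nrow(seeds) - 1L))
      mask[pix] <- new_labels[assign_to]
      audit <- c(audit, sprintf("split %d -> {%s}", lb, paste(new_labels, collapse = ",")))
    } else if (e$action == "species") {
      tags <- bind_rows(tags, tibble(label = lb, species = as.character(e$arg)))
      audit <- c(audit, sprintf("species %d -> %s", lb, e$arg))
    } else {
      abort(sprintf("override row %d has unknown action '%s'.", i, e$action),
            class = "mycomorph_edit_error")
    }
  }
  attr(mask, "audit") <- audit
  attr(mask, "species_tags") <- tags
  mask
}
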