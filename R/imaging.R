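#' Grayscale drop-snapshot image
#'
#' @param pixels numeric matrix of intensities in 0..255 (rows = image
#'   rows).
#' @param mm_per_pixel spatial calibration (> 0).
#' @param roi optional region-of-interest polygon, a matrix with columns
#'   `x`, `y` in pixel-center coordinates; pixels outside it are ignored by
#'   segmentation (used to mask out the probe or window reflections).
#' @return An object of class `srf_gray_image`.
#' @export
gray_image <- function(pixels, mm_per_pixel = 1, roi = NULL) {
  abort_if(!is.matrix(pixels) || nrow(pixels) == 0 || ncol(pixels) == 0,
           "pixels must be a non-empty matrix")
  abort_if(any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255),
           "pixel intensities must lie in 0..255")
  abort_if(!is_scalar_num(mm_per_pixel) || mm_per_pixel <= 0,
           "mm_per_pixel must be > 0")
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    abort_if(ncol(roi) != 2 || nrow(roi) < 3,
             "roi must be a polygon matrix with >= 3 (x, y) rows")
  }
  structure(list(pixels = pixels, mm_per_pixel = mm_per_pixel, roi = roi),
            class = "srf_gray_image")
}

#' @export
print.srf_gray_image <- function(x, ...) {
  cat("<srf_gray_image> ", nrow(x$pixels), " x ", ncol(x$pixels),
      " px, ", x$mm_per_pixel, " mm/px",
      if (!is.null(x$roi)) ", with ROI", "\n", sep = "")
  invisible(x)
}

#' Read / write an 8-bit grayscale PNG
#'
#' @param path PNG file; color images are converted by channel averaging.
#' @param mm_per_pixel calibration to attach.
#' @return An `srf_gray_image`.
#' @export
read_gray_png <- function(path, mm_per_pixel = 1) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3])],
                                          c(1, 2), mean)
  gray_image(round(arr * 255), mm_per_pixel = mm_per_pixel)
}

#' @rdname read_gray_png
#' @param img an `srf_gray_image`.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

# 8-connected component labelling by iterative minimum-label propagation.
# Deterministic and exact; iteration count is bounded by the longest
# geodesic path inside a component, which is small for blob-like aggregates.
label_components_8 <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0, h, w)
  lab[fg] <- which(fg)
  if (!any(fg)) return(lab)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    cur <- lab
    cur[!fg] <- Inf
    best <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      best <- pmin(best, shift(cur, dr, dc))
    }
    best[!fg] <- 0
    if (identical(best, lab)) break
    lab <- best
  }
  # renumber 1..k
  ids <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], ids)
  lab
}

#' Segment dark aggregates in a grayscale snapshot
#'
#' Pixels darker than the threshold are foreground. The threshold comes
#' from Otsu's method on the image histogram (`"otsu"`, via
#' \pkg{EBImage}) or is supplied directly (`"fixed"`). Foreground is
#' labelled with 8-connectivity and components smaller than
#' `min_component_px` are discarded as speckle. When an ROI polygon is
#' attached to the image, pixels outside it never enter the mask (nor the
#' Otsu histogram).
#'
#' A uniform image has no meaningful Otsu threshold: the result is flagged
#' `degenerate` and the mask is empty.
#'
#' @param img an `srf_gray_image`.
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param threshold intensity in 0..255 for `"fixed"` mode.
#' @param min_component_px minimum component size kept, px.
#' @return list of class `srf_segmentation`: logical `mask`, `labels`
#'   matrix, `n_components`, `area_px2`, `area_mm2`, `threshold` used,
#'   `degenerate`, and the parameters (logged for audit).
#' @export
segment_aggregate <- function(img, threshold_mode = c("otsu", "fixed"),
                              threshold = NULL, min_component_px = 25) {
  abort_if(!inherits(img, "srf_gray_image"), "img must be an srf_gray_image")
  threshold_mode <- match.arg(threshold_mode)
  abort_if(!is_count(min_component_px, 0L),
           "min_component_px must be a non-negative count")
  px <- img$pixels
  in_roi <- matrix(TRUE, nrow(px), ncol(px))
  if (!is.null(img$roi)) {
    xs <- rep(seq_len(ncol(px)) - 0.5, each = nrow(px))
    ys <- rep(seq_len(nrow(px)) - 0.5, times = ncol(px))
    in_roi <- matrix(mgcv::in.out(rbind(img$roi, img$roi[1, ]),
                                  cbind(xs, ys)),
                     nrow(px), ncol(px))
  }
  vals <- px[in_roi]
  degenerate <- FALSE
  if (threshold_mode == "otsu") {
    if (diff(range(vals)) == 0) {
      degenerate <- TRUE
      thr <- NA_real_
    } else {
      thr <- 255 * EBImage::otsu(EBImage::Image(matrix(vals / 255)),
                                 range = c(0, 1), levels = 256)
    }
  } else {
    abort_if(is.null(threshold) || !is_scalar_num(threshold),
             "fixed threshold_mode needs a numeric threshold (0..255)")
    thr <- threshold
  }
  if (degenerate) {
    mask <- matrix(FALSE, nrow(px), ncol(px))
    labels <- matrix(0, nrow(px), ncol(px))
  } else {
    fg <- px < thr & in_roi
    labels <- label_components_8(fg)
    if (min_component_px > 0 && max(labels) > 0) {
      sizes <- tabulate(labels[labels > 0])
      drop <- which(sizes < min_component_px)
      labels[labels %in% drop] <- 0
      ids <- sort(unique(labels[labels > 0]))
      labels[labels > 0] <- match(labels[labels > 0], ids)
    }
    mask <- labels > 0
  }
  structure(list(
    mask = mask, labels = labels,
    n_components = max(labels),
    area_px2 = sum(mask),
    area_mm2 = sum(mask) * img$mm_per_pixel^2,
    threshold = thr, degenerate = degenerate,
    params = list(threshold_mode = threshold_mode,
                  min_component_px = min_component_px,
                  mm_per_pixel = img$mm_per_pixel,
                  roi = !is.null(img$roi))
  ), class = "srf_segmentation")
}

#' @export
print.srf_segmentation <- function(x, ...) {
  cat(sprintf(
    "<srf_segmentation> %d component(s), %d px^2 (%.4f mm^2), threshold %s\n",
    x$n_components, x$area_px2, x$area_mm2,
    if (x$degenerate) "degenerate" else sprintf("%.1f", x$threshold)))
  invisible(x)
}

#' Aggregate area over an image series
#'
#' Segments each snapshot (same parameters throughout) and reports the
#' total aggregate area in px^2 and, through the shared calibration, mm^2.
#'
#' @param images list of `srf_gray_image` with identical `mm_per_pixel`.
#' @param times time labels (e.g. minutes), one per image.
#' @param ... passed on to [segment_aggregate()].
#' @return tibble of class `srf_area_series`: `time`, `area_px2`,
#'   `area_mm2`, `n_components`, `threshold`.
#' @export
aggregate_area_series <- function(images, times = seq_along(images), ...) {
  abort_if(length(images) == 0, "need at least one image")
  abort_if(length(times) != length(images),
           "times must match the number of images")
  calib <- vapply(images, function(i) i$mm_per_pixel, numeric(1))
  abort_if(length(unique(calib)) != 1,
           "calibration mismatch across images: ",
           paste(unique(calib), collapse = ", "))
  segs <- lapply(images, segment_aggregate, ...)
  out <- tibble::tibble(
    time = times,
    area_px2 = vapply(segs, `[[`, numeric(1), "area_px2"),
    area_mm2 = vapply(segs, `[[`, numeric(1), "area_mm2"),
    n_components = vapply(segs, `[[`, numeric(1), "n_components"),
    threshold = vapply(segs, `[[`, numeric(1), "threshold"))
  class(out) <- c("srf_area_series", class(out))
  out
}
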