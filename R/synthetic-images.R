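#' Specification for a synthetic aggregate-snapshot image series
#'
#' Emulates grayscale drop snapshots in which dark ligand aggregates sit on
#' a light background and shrink over time as they dissolve: each aggregate
#' is a disk whose radius decreases linearly frame by frame (clamped at 0).
#' The analytic disk areas are recorded as ground truth.
#'
#' @param width,height image size in pixels.
#' @param mm_per_pixel spatial calibration (> 0).
#' @param disks matrix or data frame with columns `cx`, `cy`, `radius_t0`
#'   (pixels); disks must lie inside the image at t0.
#' @param shrink_rate radius decrease per frame, px.
#' @param n_frames number of snapshots.
#' @param background_gray,foreground_gray intensities in 0..255 (background
#'   must be lighter).
#' @param noise_sigma Gaussian intensity noise (0..255 scale).
#' @param seed integer seed.
#' @return An `srf_image_spec`.
#' @export
aggregate_image_spec <- function(width = 200, height = 200,
                                 mm_per_pixel = 0.02,
                                 disks = cbind(cx = 100, cy = 100,
                                               radius_t0 = 50),
                                 shrink_rate = 5, n_frames = 5,
                                 background_gray = 210, foreground_gray = 40,
                                 noise_sigma = 0, seed = 1L) {
  abort_if(!is_count(width, 1L) || !is_count(height, 1L),
           "image dimensions must be positive")
  abort_if(!is_scalar_num(mm_per_pixel) || mm_per_pixel <= 0,
           "mm_per_pixel must be > 0")
  disks <- as.data.frame(disks)
  abort_if(!all(c("cx", "cy", "radius_t0") %in% names(disks)),
           "disks need columns cx, cy, radius_t0")
  abort_if(any(disks$radius_t0 < 0), "disk radii must be non-negative")
  inside <- disks$cx - disks$radius_t0 >= 0 &
    disks$cx + disks$radius_t0 <= width &
    disks$cy - disks$radius_t0 >= 0 &
    disks$cy + disks$radius_t0 <= height
  abort_if(!all(inside), "disks must lie inside the image bounds at t0")
  abort_if(shrink_rate < 0, "shrink_rate must be >= 0")
  abort_if(!is_count(n_frames, 1L), "n_frames must be a positive count")
  abort_if(background_gray <= foreground_gray,
           "background must be lighter than foreground (dark aggregates)")
  abort_if(noise_sigma < 0, "noise_sigma must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 mm_per_pixel = mm_per_pixel, disks = disks,
                 shrink_rate = shrink_rate, n_frames = as.integer(n_frames),
                 background_gray = background_gray,
                 foreground_gray = foreground_gray,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "srf_image_spec")
}

#' Generate a synthetic aggregate image series
#'
#' @param spec an [aggregate_image_spec()].
#' @return list of class `srf_image_sim`: `images` (list of
#'   [gray_image()]), `truth` (per-frame disk radii and analytic total area
#'   `pi * sum(r^2)` in px^2).
#' @export
gen_aggregate_image_series <- function(spec) {
  abort_if(!inherits(spec, "srf_image_spec"),
           "spec must come from aggregate_image_spec()")
  withr::with_seed(spec$seed, {
    # pixel centers: column x in [0.5, width - 0.5], row y likewise
    xs <- matrix(rep(seq_len(spec$width) - 0.5, each = spec$height),
                 nrow = spec$height)
    ys <- matrix(rep(seq_len(spec$height) - 0.5, times = spec$width),
                 nrow = spec$height)
    images <- vector("list", spec$n_frames)
    radii <- matrix(NA_real_, spec$n_frames, nrow(spec$disks))
    for (f in seq_len(spec$n_frames)) {
      img <- matrix(spec$background_gray, spec$height, spec$width)
      for (d in seq_len(nrow(spec$disks))) {
        r <- max(0, spec$disks$radius_t0[d] - spec$shrink_rate * (f - 1))
        radii[f, d] <- r
        if (r > 0) {
          inside <- (xs - spec$disks$cx[d])^2 + (ys - spec$disks$cy[d])^2 <=
            r^2
          img[inside] <- spec$foreground_gray
        }
      }
      if (spec$noise_sigma > 0) {
        img <- img + rnorm(length(img), 0, spec$noise_sigma)
      }
      img[] <- pmin(255, pmax(0, round(img)))
      images[[f]] <- gray_image(img, mm_per_pixel = spec$mm_per_pixel)
    }
    structure(list(
      images = images,
      truth = list(radii_px = radii,
                   area_px2 = pi * rowSums(radii^2),
                   mm_per_pixel = spec$mm_per_pixel, seed = spec$seed)
    ), class = "srf_image_sim")
  })
}
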