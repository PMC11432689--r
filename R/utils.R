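# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# squared Euclidean distances from one point to each row of a matrix;
# plain differences (no crossprod tricks) so results are bit-reproducible
# against naive per-pair evaluation
sq_dist_to <- function(pts, p) {
  dx <- pts[, 1] - p[1]
  dy <- pts[, 2] - p[2]
  dz <- pts[, 3] - p[3]
  dx * dx + dy * dy + dz * dz
}

# minimum distance between two coordinate sets (rows are points)
min_pair_dist <- function(a, b) {
  m2 <- Inf
  for (i in seq_len(nrow(a))) {
    m2 <- min(m2, min(sq_dist_to(b, a[i, ])))
  }
  sqrt(m2)
}

# angle between two direction vectors folded to [0, 90] degrees (sign-free)
folded_angle_deg <- function(u, v) {
  cu <- sqrt(sum(u^2))
  cv <- sqrt(sum(v^2))
  abort_if(cu == 0 || cv == 0, "zero-length direction vector")
  ca <- abs(sum(u * v)) / (cu * cv)
  ca <- min(1, max(-1, ca))
  acos(ca) * 180 / pi
}
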