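# Shared fixtures and independent oracles, built in code at test time.

# digitized ellipse mask: long axis along y rotated by theta_deg, transverse
# width w mm, elongation e, pixel size dx, optional subpixel center offset
ellipse_mask <- function(theta_deg, w = 13, e = 1.6, dx = 0.5, n = 72,
                         off = c(0, 0)) {
  a <- w / 2; b <- e * a
  x <- ((1:n) - 0.5) * dx - n * dx / 2 - off[1]
  y <- ((1:n) - 0.5) * dx - n * dx / 2 - off[2]
  XX <- matrix(x, n, n); YY <- matrix(y, n, n, byrow = TRUE)
  th <- theta_deg * pi / 180
  u <- XX * cos(th) + YY * sin(th)
  v <- -XX * sin(th) + YY * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# exhaustive 0.1-degree sweep oracle for the bounding-rectangle orientation:
# minimizes the pixel-center extent area (the same objective the rectangle
# fit optimizes) over a dense angle grid, with none of the convex-hull /
# rotating-calipers machinery
bf_rect_sweep <- function(mask, spacing = c(1, 1), step_deg = 0.1) {
  idx <- which(mask > 0, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 0.5) * spacing[1], (idx[, 2] - 0.5) * spacing[2])
  best <- NULL
  for (deg in seq(0, 90 - step_deg, by = step_deg)) {
    th <- deg * pi / 180
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    eu <- diff(range(pts %*% u)); ev <- diff(range(pts %*% v))
    area <- eu * ev
    if (is.null(best) || area < best$area)
      best <- list(area = area, angle = deg, extents = c(eu, ev))
  }
  best
}

# pixel-center extents of a mask along the axes of a given orientation
center_extents <- function(mask, spacing, angle_deg) {
  idx <- which(mask > 0, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 0.5) * spacing[1], (idx[, 2] - 0.5) * spacing[2])
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  c(diff(range(pts %*% u)), diff(range(pts %*% v)))
}

# random two-blob ventricle slice with a guaranteed empty column gap;
# returns the mask plus the ground-truth left/right column ranges
random_two_blob <- function(n = 48) {
  w1 <- sample(4:10, 1); w2 <- sample(4:10, 1)
  gap <- sample(1:6, 1)
  start1 <- sample(2:6, 1)
  start2 <- start1 + w1 + gap
  stopifnot(start2 + w2 < n)
  mask <- matrix(FALSE, n, n)
  rows1 <- sample(5:(n - 15), 1) + 0:sample(4:10, 1)
  rows2 <- sample(5:(n - 15), 1) + 0:sample(4:10, 1)
  mask[start1:(start1 + w1 - 1), rows1] <- TRUE
  mask[start2:(start2 + w2 - 1), rows2] <- TRUE
  list(mask = mask, left_cols = c(start1, start1 + w1 - 1),
       right_cols = c(start2, start2 + w2 - 1))
}

# small simplified label volume with hand-placed structures
tiny_label_volume <- function(dgm_slices = list(), vent_slices = list(),
                              dims = c(12, 12, 10), spacing = c(0.5, 0.5, 0.5)) {
  arr <- array(0L, dim = dims)
  for (k in names(vent_slices))
    arr[, , as.integer(k)][vent_slices[[k]]] <- 1L
  for (k in names(dgm_slices))
    arr[, , as.integer(k)][dgm_slices[[k]]] <- 2L
  new_label_volume_from_array(arr, spacing, label_set = 0:2)
}
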