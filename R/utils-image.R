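## Internal pixel-level primitives shared by the simulator, the filters, the
## segmenter and the scoring layer. Conventions (package-wide): images are
## numeric matrices indexed [row, col]; x = column - 1, y = row - 1 (0-based
## pixel coordinates); linear indices are column-major as in base R.

# Reflect-pad a matrix by `r` pixels on every side (edge mirror without
# repeating the border pixel would be "reflect_101"; here the border pixel is
# repeated once, i.e. symmetric padding, matching the documented contract).
pad_reflect <- function(m, r) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- c(rev(seq_len(min(r, nr))), seq_len(nr), nr + 1 - seq_len(min(r, nr)))
  if (r > nr) stop("padding radius exceeds image size", call. = FALSE)
  ci <- c(rev(seq_len(min(r, nc))), seq_len(nc), nc + 1 - seq_len(min(r, nc)))
  if (r > nc) stop("padding radius exceeds image size", call. = FALSE)
  m[ri, ci, drop = FALSE]
}

# 8-connected component labeling of a binary matrix. Deterministic: component
# ids are assigned in column-major order of each component's first pixel.
label_components <- function(bw) {
  nr <- nrow(bw)
  nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  fg <- which(bw > 0)
  if (length(fg) == 0L) return(lab)
  dr <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dc <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      co <- ((frontier - 1L) %/% nr) + 1L
      rr <- rep(r, times = 8L) + rep(dr, each = length(r))
      cc <- rep(co, times = 8L) + rep(dc, each = length(co))
      keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- (cc[keep] - 1L) * nr + rr[keep]
      idx <- unique(idx[bw[idx] > 0 & lab[idx] == 0L])
      if (length(idx)) lab[idx] <- cur
      frontier <- idx
    }
  }
  lab
}

# Binary dilation of a pixel set by a Euclidean disc of radius `r`.
# `idx`: linear indices of the set; returns linear indices of the dilation,
# clipped to the image. Work is done on a cropped bounding box.
dilate_indices <- function(idx, dim, r) {
  if (length(idx) == 0L || r <= 0) return(sort(unique(idx)))
  nr <- dim[1]
  nc <- dim[2]
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  ri <- as.integer(floor(r))
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  rr <- rep(row, times = nrow(off)) + rep(off$dr, each = length(row))
  cc <- rep(col, times = nrow(off)) + rep(off$dc, each = length(col))
  keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  sort(unique((cc[keep] - 1L) * nr + rr[keep]))
}

# Paint Gaussian-profile discs onto an image. `cells` is a data.frame with
# columns x, y (0-based), radius, and optionally intensity. The profile is
# peak * exp(-d^2 / (2 sigma^2)) with sigma = radius / sqrt(2 * log(5)), so
# the 20%-of-peak contour sits exactly at `radius` pixels from the center.
render_cells <- function(cells, dim, peak = 1) {
  img <- matrix(0, dim[1], dim[2])
  if (nrow(cells) == 0L) return(img)
  if (is.null(cells[["intensity"]])) cells$intensity <- peak
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]
    cy <- cells$y[i]
    rad <- cells$radius[i]
    sg <- rad / sqrt(2 * log(5))
    ext <- ceiling(rad * 2)
    r0 <- max(1L, floor(cy + 1 - ext))
    r1 <- min(dim[1], ceiling(cy + 1 + ext))
    c0 <- max(1L, floor(cx + 1 - ext))
    c1 <- min(dim[2], ceiling(cx + 1 + ext))
    if (r0 > r1 || c0 > c1) next
    yy <- (r0:r1) - 1
    xx <- (c0:c1) - 1
    d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
      cells$intensity[i] * exp(-d2 / (2 * sg^2))
  }
  img
}

# Ratio of the mask contour radius (10% of peak) to the nominal radius
# (20% of peak): sqrt(log 10 / log 5) ~ 1.196.
mask_radius_factor <- sqrt(log(10) / log(5))

# Binary mask of the same discs, thresholded at 10% of each cell's own peak
# (distance <= radius * sqrt(log 10 / log 5) ~ 1.196 radius). This is the
# same contour the reference segmenter extracts at its default threshold of
# 0.1 on normalized intensities, so simulated ground truth and segmentation
# agree at the operating point. Returns a logical matrix.
render_cell_mask <- function(cells, dim) {
  bw <- matrix(FALSE, dim[1], dim[2])
  if (nrow(cells) == 0L) return(bw)
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]
    cy <- cells$y[i]
    rad <- cells$radius[i] * mask_radius_factor
    r0 <- max(1L, floor(cy + 1 - rad))
    r1 <- min(dim[1], ceiling(cy + 1 + rad))
    c0 <- max(1L, floor(cx + 1 - rad))
    c1 <- min(dim[2], ceiling(cx + 1 + rad))
    if (r0 > r1 || c0 > c1) next
    yy <- (r0:r1) - 1
    xx <- (c0:c1) - 1
    d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
    bw[r0:r1, c0:c1] <- bw[r0:r1, c0:c1] | (d2 <= rad^2)
  }
  bw
}
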