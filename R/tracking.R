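#' Tracking configuration
#'
#' Parameters of the sparse Kanade--Lucas--Tomasi style tracker. The ROI is
#' tiled into `n_rows` x `n_cols` subregions; up to `max_features_per_cell`
#' minimum-eigenvalue corners are detected in each at frame 0 and followed
#' frame-to-frame with an iterative sub-pixel Lucas--Kanade refinement on an
#' image pyramid.
#'
#' @param n_rows,n_cols Subregion grid used for feature detection.
#' @param max_features_per_cell Feature cap per subregion.
#' @param min_features Minimum total features required at frame 0.
#' @param window Odd side length (px) of the integration window.
#' @param pyramid_levels Number of pyramid levels (1 = no pyramid).
#' @param max_iter Maximum refinement iterations per level.
#' @param eps Convergence threshold on the update step, px.
#' @param fb_max_px Forward-backward error above which a feature is dropped
#'   for all subsequent frames.
#' @param min_alive_fraction Below this surviving-feature fraction tracking
#'   aborts with a tracking-collapse error.
#' @param min_eigen_quality Corner acceptance threshold as a fraction of the
#'   strongest corner response in the ROI.
#' @param min_spacing Minimum distance between detected corners, px.
#' @return A list of class `tracking_config`.
#' @export
tracking_config <- function(n_rows = 2, n_cols = 2,
                            max_features_per_cell = 10,
                            min_features = 5,
                            window = 15,
                            pyramid_levels = 3,
                            max_iter = 30,
                            eps = 0.01,
                            fb_max_px = 1.0,
                            min_alive_fraction = 0.5,
                            min_eigen_quality = 0.01,
                            min_spacing = 5) {
  stopifnot(window %% 2 == 1, window >= 3, pyramid_levels >= 1,
            min_alive_fraction > 0, min_alive_fraction <= 1)
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         max_features_per_cell = max_features_per_cell,
         min_features = min_features, window = window,
         pyramid_levels = pyramid_levels, max_iter = max_iter, eps = eps,
         fb_max_px = fb_max_px, min_alive_fraction = min_alive_fraction,
         min_eigen_quality = min_eigen_quality, min_spacing = min_spacing),
    class = "tracking_config"
  )
}

#' Tile an ROI into subregions
#'
#' Splits an ROI into an `n_rows` x `n_cols` grid of disjoint sub-ROIs whose
#' union is the original ROI; remainder pixels from the integer division go
#' to the last row / column.
#'
#' @param r A [roi()].
#' @param n_rows,n_cols Grid shape (each >= 1).
#' @return List of [roi()] in row-major order.
#' @export
subdivide_roi <- function(r, n_rows, n_cols) {
  stopifnot(inherits(r, "roi"), n_rows >= 1, n_cols >= 1)
  w <- roi_width(r) %/% n_cols
  h <- roi_height(r) %/% n_rows
  if (w < 4 || h < 4) stop("subregions would be smaller than 4x4 px")
  out <- vector("list", n_rows * n_cols)
  k <- 1
  for (i in seq_len(n_rows)) {
    y0 <- r$y0 + (i - 1) * h
    y1 <- if (i == n_rows) r$y1 else y0 + h
    for (j in seq_len(n_cols)) {
      x0 <- r$x0 + (j - 1) * w
      x1 <- if (j == n_cols) r$x1 else x0 + w
      out[[k]] <- roi(x0, y0, x1, y1)
      k <- k + 1
    }
  }
  out
}

# --- low-level image helpers (0-based x = column, y = row coordinates) ----

# Bilinearly interpolated square patch of side 2*half+1 centred at (cx, cy).
# Indices are clamped at the border, so patches near the edge flatten rather
# than error; callers keep features away from borders via the margin check.
bilinear_patch <- function(img, cx, cy, half) {
  n <- 2L * half + 1L
  hh <- nrow(img); ww <- ncol(img)
  xs <- cx + seq.int(-half, half)
  ys <- cy + seq.int(-half, half)
  x0 <- pmin(pmax(floor(xs), 0), ww - 2L)
  y0 <- pmin(pmax(floor(ys), 0), hh - 2L)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  rr <- rep(y0 + 1L, times = n)
  cc <- rep(x0 + 1L, each = n)
  wfy <- rep(fy, times = n)
  wfx <- rep(fx, each = n)
  v <- (1 - wfy) * (1 - wfx) * img[cbind(rr, cc)] +
       (1 - wfy) * wfx       * img[cbind(rr, cc + 1L)] +
       wfy       * (1 - wfx) * img[cbind(rr + 1L, cc)] +
       wfy       * wfx       * img[cbind(rr + 1L, cc + 1L)]
  matrix(v, n, n)
}

# Box-filter sum over a (2*half+1)^2 window via summed-area table.
box_sum <- function(m, half) {
  hh <- nrow(m); ww <- ncol(m)
  p <- matrix(0, hh + 1, ww + 1)
  p[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r0 <- pmax(seq_len(hh) - half - 1, 0) + 1
  r1 <- pmin(seq_len(hh) + half, hh) + 1
  c0 <- pmax(seq_len(ww) - half - 1, 0) + 1
  c1 <- pmin(seq_len(ww) + half, ww) + 1
  p[r1, c1] - p[r0, c1] - p[r1, c0] + p[r0, c0]
}

image_gradients <- function(img) {
  hh <- nrow(img); ww <- ncol(img)
  gx <- matrix(0, hh, ww)
  gy <- matrix(0, hh, ww)
  gx[, 2:(ww - 1)] <- (img[, 3:ww] - img[, 1:(ww - 2)]) / 2
  gy[2:(hh - 1), ] <- (img[3:hh, ] - img[1:(hh - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# 2x decimation after separable [1 4 6 4 1]/16 smoothing.
pyr_down <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  pad <- function(m) {
    m <- rbind(m[1, ], m[1, ], m, m[nrow(m), ], m[nrow(m), ])
    cbind(m[, 1], m[, 1], m, m[, ncol(m)], m[, ncol(m)])
  }
  p <- pad(img)
  hh <- nrow(img); ww <- ncol(img)
  sm <- matrix(0, hh, ww + 4)
  for (i in 1:5) sm <- sm + k[i] * p[i:(i + hh - 1), ]
  out <- matrix(0, hh, ww)
  for (i in 1:5) out <- out + k[i] * sm[, i:(i + ww - 1)]
  out[seq(1, hh, by = 2), seq(1, ww, by = 2), drop = FALSE]
}

build_pyramid <- function(img, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- img
  for (l in seq_len(levels - 1)) {
    prev <- pyr[[l]]
    if (min(dim(prev)) < 16) {
      pyr <- pyr[seq_len(l)]
      break
    }
    pyr[[l + 1]] <- pyr_down(prev)
  }
  pyr
}

# Single-level Lucas-Kanade refinement of the translation of a template
# window around `p` in image A towards image B, starting from offset `d0`.
lk_refine <- function(imgA, imgB, p, d0, half, max_iter, eps) {
  big <- bilinear_patch(imgA, p[1], p[2], half + 1L)
  n <- 2L * half + 1L
  core <- 2:(n + 1)
  tmpl <- big[core, core]
  tx <- (big[core, core + 1] - big[core, core - 1]) / 2
  ty <- (big[core + 1, core] - big[core - 1, core]) / 2
  gxx <- sum(tx * tx); gxy <- sum(tx * ty); gyy <- sum(ty * ty)
  det <- gxx * gyy - gxy * gxy
  if (!is.finite(det) || det < 1e-8) {
    return(list(d = d0, ok = FALSE))
  }
  d <- d0
  for (it in seq_len(max_iter)) {
    cur <- bilinear_patch(imgB, p[1] + d[1], p[2] + d[2], half)
    e <- tmpl - cur
    bx <- sum(e * tx); by <- sum(e * ty)
    step <- c(gyy * bx - gxy * by, gxx * by - gxy * bx) / det
    d <- d + step
    if (sqrt(sum(step^2)) < eps) break
  }
  list(d = d, ok = TRUE)
}

# Pyramidal LK: track point p (0-based x,y in full resolution) from A to B.
lk_track_point <- function(pyrA, pyrB, p, cfg) {
  half <- (cfg$window - 1L) / 2L
  levels <- length(pyrA)
  d <- c(0, 0)
  for (l in rev(seq_len(levels))) {
    s <- 2^(l - 1)
    res <- lk_refine(pyrA[[l]], pyrB[[l]], p / s, d / s, half,
                     cfg$max_iter, cfg$eps)
    if (!res$ok) return(list(pos = p + d, ok = FALSE))
    d <- res$d * s
  }
  list(pos = p + d, ok = TRUE)
}

#' Detect minimum-eigenvalue corner features inside an ROI
#'
#' Shi--Tomasi style detection: the smaller eigenvalue of the box-smoothed
#' structure tensor scores each pixel; corners must exceed
#' `min_eigen_quality` times the strongest response in the ROI and respect a
#' minimum spacing, with at most `max_features_per_cell` corners kept per
#' subregion (strongest first).
#'
#' @param img Numeric matrix (one frame).
#' @param r A [roi()].
#' @param cfg A [tracking_config()].
#' @return Matrix with columns `x`, `y` (0-based sub-ROI ordered positions).
#' @export
detect_features <- function(img, r, cfg = tracking_config()) {
  check_roi_in_frame(r, dim(img))
  g <- image_gradients(img)
  half <- (cfg$window - 1L) / 2L
  sxx <- box_sum(g$gx * g$gx, half)
  sxy <- box_sum(g$gx * g$gy, half)
  syy <- box_sum(g$gy * g$gy, half)
  tr <- sxx + syy
  lam <- (tr - sqrt((sxx - syy)^2 + 4 * sxy^2)) / 2
  margin <- half + 2L
  subs <- subdivide_roi(r, cfg$n_rows, cfg$n_cols)
  # ROI-wide quality floor
  rows_all <- (r$y0 + 1):r$y1
  cols_all <- (r$x0 + 1):r$x1
  best <- max(lam[rows_all, cols_all])
  if (best <= 0) {
    # structureless (e.g. constant) ROI: nothing trackable
    out <- matrix(numeric(0), 0, 2)
    colnames(out) <- c("x", "y")
    return(out)
  }
  floor_val <- cfg$min_eigen_quality * best
  pts <- list()
  for (s in subs) {
    rows <- (s$y0 + 1):s$y1
    cols <- (s$x0 + 1):s$x1
    sub <- lam[rows, cols, drop = FALSE]
    ord <- order(sub, decreasing = TRUE)
    ord <- ord[sub[ord] >= floor_val]
    taken <- matrix(numeric(0), 0, 2)
    for (idx in ord) {
      if (nrow(taken) >= cfg$max_features_per_cell) break
      iy <- ((idx - 1) %% nrow(sub)) + s$y0      # 0-based y
      ix <- ((idx - 1) %/% nrow(sub)) + s$x0     # 0-based x
      if (ix < margin || iy < margin ||
          ix >= ncol(img) - margin || iy >= nrow(img) - margin) next
      if (nrow(taken) > 0 &&
          min((taken[, 1] - ix)^2 + (taken[, 2] - iy)^2) <
            cfg$min_spacing^2) next
      taken <- rbind(taken, c(ix, iy))
    }
    pts[[length(pts) + 1]] <- taken
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y")
  out
}

#' Track ROI displacement through a video
#'
#' Reconstructs the mean-displacement trace of a region of interest:
#' corner features are detected inside the ROI subregions at frame 0 (the
#' resting position, which defines the zero point) and followed
#' frame-to-frame with pyramidal sub-pixel Lucas--Kanade refinement. Each
#' surviving feature contributes its Euclidean distance from its frame-0
#' position; the trace value is the mean over surviving features. Features
#' failing the forward-backward consistency check are dropped for all
#' subsequent frames.
#'
#' @param stack A [frame_stack()].
#' @param r A [roi()] inside the frames.
#' @param cfg A [tracking_config()].
#' @return A [displacement_trace()] in pixels (frame 0 at time 0).
#' @export
track_displacement <- function(stack, r, cfg = tracking_config()) {
  stopifnot(inherits(stack, "frame_stack"), inherits(r, "roi"))
  check_roi_in_frame(r, dim(stack$frames[[1]]))
  pts0 <- detect_features(stack$frames[[1]], r, cfg)
  n0 <- nrow(pts0)
  if (is.null(n0) || n0 < cfg$min_features) {
    stop(sprintf("insufficient features: %d found, %d required",
                 if (is.null(n0)) 0L else n0, cfg$min_features))
  }
  nf <- n_frames(stack)
  pos <- pts0                    # current position per feature
  alive <- rep(TRUE, n0)
  disp <- numeric(nf)
  n_alive <- integer(nf)
  n_alive[1] <- n0
  pyr_prev <- build_pyramid(stack$frames[[1]], cfg$pyramid_levels)
  for (f in 2:nf) {
    pyr_cur <- build_pyramid(stack$frames[[f]], cfg$pyramid_levels)
    for (i in which(alive)) {
      fw <- lk_track_point(pyr_prev, pyr_cur, pos[i, ], cfg)
      if (!fw$ok) { alive[i] <- FALSE; next }
      bw <- lk_track_point(pyr_cur, pyr_prev, fw$pos, cfg)
      fb_err <- sqrt(sum((bw$pos - pos[i, ])^2))
      if (!bw$ok || fb_err > cfg$fb_max_px) { alive[i] <- FALSE; next }
      pos[i, ] <- fw$pos
    }
    if (sum(alive) < cfg$min_alive_fraction * n0) {
      stop(sprintf("tracking collapse at frame %d: %d of %d features alive",
                   f, sum(alive), n0))
    }
    d <- sqrt((pos[alive, 1] - pts0[alive, 1])^2 +
              (pos[alive, 2] - pts0[alive, 2])^2)
    disp[f] <- mean(d)
    n_alive[f] <- sum(alive)
    pyr_prev <- pyr_cur
  }
  disp[1] <- 0
  displacement_trace(times = (seq_len(nf) - 1) * stack$frame_interval,
                     displacement = disp, n_points_alive = n_alive,
                     units = "px")
}

#' Rigid shift between two frames by phase correlation
#'
#' Independent registration oracle for the feature tracker: returns the
#' translation `(dx, dy)` maximizing the normalized cross-power spectrum of
#' the two frames, refined to sub-pixel precision by a parabolic fit around
#' the correlation peak. `(dx, dy)` is the motion of image content from
#' `frame_a` to `frame_b` (positive x = rightwards columns, positive
#' y = downwards rows).
#'
#' Both frames are mean-subtracted and Hann-windowed (the shift is not
#' circular on real images), and the cross-power normalization is
#' regularized so that spectral whitening does not amplify noise-dominated
#' high frequencies of smooth textures.
#'
#' @param frame_a,frame_b Numeric matrices of identical shape.
#' @param regularization Fraction of the peak cross-power magnitude added
#'   to the normalizer.
#' @return Numeric vector `c(dx, dy)` in pixels.
#' @export
phase_correlation_shift <- function(frame_a, frame_b,
                                    regularization = 1e-2) {
  stopifnot(identical(dim(frame_a), dim(frame_b)))
  if (stats::sd(frame_a) == 0 || stats::sd(frame_b) == 0) {
    stop("phase correlation is degenerate on a constant image")
  }
  hh0 <- nrow(frame_a); ww0 <- ncol(frame_a)
  win <- outer(0.5 - 0.5 * cos(2 * pi * (0:(hh0 - 1)) / (hh0 - 1)),
               0.5 - 0.5 * cos(2 * pi * (0:(ww0 - 1)) / (ww0 - 1)))
  fa <- stats::fft((frame_a - mean(frame_a)) * win)
  fb <- stats::fft((frame_b - mean(frame_b)) * win)
  cross <- fb * Conj(fa)
  mag <- Mod(cross)
  r <- Re(stats::fft(cross / (mag + regularization * max(mag)),
                     inverse = TRUE))
  hh <- nrow(r); ww <- ncol(r)
  pk <- arrayInd(which.max(r), dim(r))
  iy <- pk[1]; ix <- pk[2]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  # parabolic sub-pixel refinement along each axis with wrapped neighbours
  refine <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    if (abs(den) < 1e-12) return(0)
    delta <- 0.5 * (ym - yp) / den
    max(min(delta, 0.5), -0.5)
  }
  dx <- wrap(ix, ww) + refine(r[iy, ((ix - 2) %% ww) + 1], r[iy, ix],
                              r[iy, (ix %% ww) + 1])
  dy <- wrap(iy, hh) + refine(r[((iy - 2) %% hh) + 1, ix], r[iy, ix],
                              r[(iy %% hh) + 1, ix])
  c(dx = dx, dy = dy)
}
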