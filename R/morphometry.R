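#' Fusion index
#'
#' Differentiation metric of a myotube culture: the percentage of nuclei
#' lying inside myotubes, where a labelled mask counts as a myotube only if
#' it contains at least two nuclei. Membership is by nucleus centroid:
#' a nucleus belongs to the mask label at its (rounded) centroid pixel.
#'
#' @param nuclei Data frame of nucleus centroids with columns `x_px`,
#'   `y_px` (0-based pixel coordinates, x = column).
#' @param masks Integer label matrix (0 = background, k = myotube k).
#' @return Fusion index in percent, in `[0, 100]`.
#' @export
fusion_index <- function(nuclei, masks) {
  stopifnot(is.data.frame(nuclei), nrow(nuclei) >= 1,
            all(c("x_px", "y_px") %in% names(nuclei)))
  rr <- round(nuclei$y_px) + 1L
  cc <- round(nuclei$x_px) + 1L
  stopifnot(all(rr >= 1), all(rr <= nrow(masks)),
            all(cc >= 1), all(cc <= ncol(masks)))
  lab <- masks[cbind(rr, cc)]
  lab <- lab[lab > 0]
  if (length(lab) == 0) return(0)
  per_mask <- table(lab)
  inside <- sum(per_mask[per_mask >= 2])
  100 * inside / nrow(nuclei)
}

#' Orientation statistics relative to a reference direction
#'
#' Treats orientations as axial data (defined modulo 180 degrees): the
#' deviation of each object from the reference is
#' `min(d, 180 - d)` with `d = |angle - reference| mod 180`, which lies in
#' `[0, 90]`. Returns the mean and SD of the deviations. With
#' `axial = FALSE` the raw linear differences `angle - reference` are
#' summarized instead (for comparability with degree-histogram analyses).
#'
#' @param angles Orientations in degrees.
#' @param reference Reference direction in degrees (e.g. the pattern
#'   direction).
#' @param axial Fold angles modulo 180 degrees (default `TRUE`).
#' @return Named numeric vector `c(mean, sd)` in degrees.
#' @export
orientation_stats <- function(angles, reference = 0, axial = TRUE) {
  stopifnot(length(angles) >= 1)
  if (axial) {
    d <- abs(angles - reference) %% 180
    dev <- pmin(d, 180 - d)
  } else {
    dev <- angles - reference
  }
  s <- stats::sd(dev)
  c(mean = mean(dev), sd = if (is.na(s)) 0 else s)
}

#' Percentage of dead cells
#'
#' @param dead Number of propidium-iodide-positive (dead) nuclei.
#' @param total Total nuclei count (Hoechst).
#' @return Dead fraction in percent.
#' @export
dead_fraction <- function(dead, total) {
  stopifnot(total > 0, dead >= 0)
  if (dead > total) stop("dead count exceeds total count")
  100 * dead / total
}

#' Blob-detection parameters for nucleus counting
#'
#' @param bg_radius Radius (px) of the rolling-median background filter;
#'   0 disables background subtraction.
#' @param threshold_factor Multiplier applied to the Otsu threshold.
#' @param min_area,max_area Connected-component area filter, px.
#' @param min_snr A component counts as a nucleus only if its peak
#'   intensity exceeds the image median by this many robust SDs (MAD);
#'   guards against Otsu splitting a noise-only image.
#' @return A list of class `blob_params`.
#' @export
blob_params <- function(bg_radius = 15, threshold_factor = 1,
                        min_area = 5, max_area = Inf, min_snr = 6) {
  stopifnot(bg_radius >= 0, threshold_factor > 0, min_area >= 1,
            min_snr >= 0)
  structure(list(bg_radius = bg_radius, threshold_factor = threshold_factor,
                 min_area = min_area, max_area = max_area,
                 min_snr = min_snr),
            class = "blob_params")
}

#' Count nuclei in a fluorescence image
#'
#' Deterministic blob counter standing in for interactive spot-tracking
#' tools: rolling-median background subtraction, Otsu thresholding (scaled
#' by `threshold_factor`), connected-component labelling, an area filter,
#' and one centroid per surviving component. Touching nuclei closer than
#' the optical resolution merge into one component and are counted once; a
#' documented limitation.
#'
#' @param image Single-channel numeric matrix (rows = y, columns = x).
#' @param params A [blob_params()].
#' @return Data frame of centroids `x_px`, `y_px` (0-based) with one row
#'   per detected nucleus, plus an `area_px` column.
#' @export
count_nuclei <- function(image, params = blob_params()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- range(image)
  if (rng[2] <= rng[1]) stop("image is empty or saturated (constant)")
  v <- (image - rng[1]) / (rng[2] - rng[1])
  v_raw <- v
  if (params$bg_radius > 0) {
    bg <- EBImage::medianFilter(EBImage::Image(v), params$bg_radius)
    v <- pmax(v - as.matrix(EBImage::imageData(bg)), 0)
  }
  th <- EBImage::otsu(EBImage::Image(v), range = c(0, 1)) *
    params$threshold_factor
  bin <- EBImage::Image(v > th)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(bin)))
  if (max(lab) == 0) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[idx]
  area <- tabulate(labs)
  # SNR guard on the pre-subtraction intensities: background statistics of
  # the subtracted image are censored at zero and useless for a cut
  peak <- tapply(v_raw[idx], labs, max)
  peak <- as.numeric(peak[as.character(seq_along(area))])
  snr_cut <- stats::median(v_raw) + params$min_snr * stats::mad(v_raw)
  keep <- which(area >= params$min_area & area <= params$max_area &
                  peak >= snr_cut)
  if (length(keep) == 0) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0)))
  }
  cy <- tapply(idx[, 1], labs, mean)[as.character(keep)] - 1
  cx <- tapply(idx[, 2], labs, mean)[as.character(keep)] - 1
  out <- data.frame(x_px = as.numeric(cx), y_px = as.numeric(cy),
                    area_px = area[keep])
  out[order(out$x_px, out$y_px), , drop = FALSE]
}
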