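#' Detect anchors in a brightfield image
#'
#' Ring template matching: the brightfield plane is correlated (FFT-based,
#' replicate-padded) with a zero-mean annulus kernel of the anchor radius;
#' peaks are kept by greedy non-maximum suppression and refined to sub-pixel
#' precision by quadratic interpolation. With a layout prior the detections
#' are matched to lattice sites, a rigid similarity transform (translation +
#' rotation + scale) is fitted by iterated closest point / Procrustes, and the
#' returned centres are the lattice snapped through that transform.
#'
#' @param frame a [chip_frame()] with a `bf` channel, or a bare numeric matrix
#'   (then `pixel_size` and `anchor_radius_um` are required).
#' @param layout optional `chip_layout` prior.
#' @param pixel_size_um,anchor_radius_um calibration when `frame` is a matrix;
#'   taken from `layout`/`frame` otherwise.
#' @param min_separation_px minimum peak separation; default 0.6 x pitch (with
#'   prior) or 2.5 x anchor radius.
#' @param z_threshold peak significance: a peak must exceed
#'   `z_threshold` standard deviations of the correlation field. A blank or
#'   structureless image therefore yields no peaks.
#' @return data frame of centres: `x_px`, `y_px` (0-based sub-pixel), `x_um`,
#'   `y_um`, `score`; with a prior also `anchor_id` and `detected` (whether a
#'   raw peak supported that site). Errors if fewer than 50% of the expected
#'   anchors are found.
#' @export
detect_anchors <- function(frame, layout = NULL,
                           pixel_size_um = NULL, anchor_radius_um = NULL,
                           min_separation_px = NULL, z_threshold = 8) {
  if (inherits(frame, "chip_frame")) {
    img <- frame$channels$bf
    if (is.null(img)) stop("frame has no brightfield ('bf') channel")
    ps <- frame$pixel_size
  } else {
    img <- frame
    ps <- pixel_size_um
    if (is.null(ps)) stop("pixel_size_um required for a bare matrix")
  }
  r_um <- if (!is.null(layout)) layout$anchor_radius else anchor_radius_um
  if (is.null(r_um)) stop("anchor_radius_um required without a layout prior")
  r_px <- r_um / ps
  if (is.null(min_separation_px)) {
    min_separation_px <- if (!is.null(layout)) 0.6 * layout$pitch / ps
    else 2.5 * r_px
  }

  score <- ring_match_score(img, r_px)
  peaks <- find_peaks(score, min_separation_px, z_threshold)

  n_expected <- if (!is.null(layout)) layout$n_anchors else NA_integer_
  if (!is.null(layout) && nrow(peaks) < 0.5 * n_expected) {
    stop(sprintf(
      "anchor detection failure: found %d of %d expected anchors",
      nrow(peaks), n_expected))
  }
  if (is.null(layout)) {
    if (nrow(peaks) == 0L) {
      stop("anchor detection failure: no significant ring features found")
    }
    peaks$x_um <- px_to_um(peaks$x_px, ps)
    peaks$y_um <- px_to_um(peaks$y_px, ps)
    # row-major ordering for reproducibility
    ord <- order(round(peaks$y_px / (2 * r_px)), peaks$x_px)
    rownames(peaks) <- NULL
    return(peaks[ord, c("x_px", "y_px", "x_um", "y_um", "score")])
  }

  # rigid lattice fit: iterated closest point with similarity Procrustes
  lattice <- cbind(um_to_px(layout$anchors$x_um, ps),
                   um_to_px(layout$anchors$y_um, ps))
  det_xy <- cbind(peaks$x_px, peaks$y_px)
  fit <- list(R = diag(2), s = 1,
              t = colMeans(det_xy) - colMeans(lattice))
  for (iter in 1:3) {
    mapped <- sweep(lattice %*% t(fit$R) * fit$s, 2, fit$t, `+`)
    nn <- nearest_rows(mapped, det_xy)
    ok <- nn$dist < 0.5 * layout$pitch / ps
    if (sum(ok) >= 2L) {
      fit <- similarity_fit(lattice[ok, , drop = FALSE],
                            det_xy[nn$index[ok], , drop = FALSE])
    }
  }
  snapped <- sweep(lattice %*% t(fit$R) * fit$s, 2, fit$t, `+`)
  nn <- nearest_rows(snapped, det_xy)
  out <- data.frame(
    anchor_id = layout$anchors$anchor_id,
    x_px = snapped[, 1], y_px = snapped[, 2],
    x_um = px_to_um(snapped[, 1], ps), y_um = px_to_um(snapped[, 2], ps),
    score = peaks$score[nn$index],
    detected = nn$dist < 0.5 * layout$pitch / ps
  )
  if (sum(out$detected) < 0.5 * n_expected) {
    stop(sprintf(
      "anchor detection failure: only %d of %d lattice sites supported by peaks",
      sum(out$detected), n_expected))
  }
  out
}

# Zero-mean ring-kernel correlation score via FFT, replicate padding.
ring_match_score <- function(img, r_px, ring_width_px = 3) {
  half <- ceiling(r_px + ring_width_px)
  w <- 2L * half + 1L
  d <- sqrt(outer((-half:half)^2, (-half:half)^2, `+`))
  kern <- matrix(0, w, w)
  kern[abs(d - r_px) <= ring_width_px / 2] <- 1
  kern <- kern - mean(kern)

  s <- stats::sd(img)
  z <- if (s > 0) (img - mean(img)) / s else img * 0
  # replicate-pad so border anchors correlate cleanly
  zp <- pad_replicate(z, half)
  sc <- xcorr2_fft(zp, kern)
  sc[(half + 1L):(half + nrow(z)), (half + 1L):(half + ncol(z)), drop = FALSE]
}

pad_replicate <- function(m, p) {
  m2 <- m[c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p)), , drop = FALSE]
  m2[, c(rep(1L, p), seq_len(ncol(m2)), rep(ncol(m2), p)), drop = FALSE]
}

# 2-D cross-correlation, 'same' size, kernel centred (odd dimensions).
xcorr2_fft <- function(img, kern) {
  nr <- nrow(img) + nrow(kern) - 1L
  nc <- ncol(img) + ncol(kern) - 1L
  nr2 <- stats::nextn(nr, c(2, 3, 5))
  nc2 <- stats::nextn(nc, c(2, 3, 5))
  A <- matrix(0, nr2, nc2)
  B <- matrix(0, nr2, nc2)
  A[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  B[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  full <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) /
    (nr2 * nc2)
  # correlation with conj flips the kernel offset: result at (i, j) is
  # sum img[i + u, j + v] * kern[1 + u, 1 + v]; centre the kernel
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  idx_r <- ((seq_len(nrow(img)) - 1L - kr) %% nr2) + 1L
  idx_c <- ((seq_len(ncol(img)) - 1L - kc) %% nc2) + 1L
  full[idx_r, idx_c, drop = FALSE]
}

# Greedy non-maximum suppression peak finding with sub-pixel refinement.
find_peaks <- function(score, min_sep_px, z_threshold) {
  mu <- stats::median(score)
  s <- stats::mad(score)
  if (s == 0) s <- stats::sd(score)
  if (is.na(s) || s == 0) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      score = numeric(0)))
  }
  cand <- which(score > mu + z_threshold * s)
  if (length(cand) == 0L) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      score = numeric(0)))
  }
  cand <- cand[order(score[cand], decreasing = TRUE)]
  nr <- nrow(score)
  rr <- ((cand - 1L) %% nr) + 1L
  cc <- ((cand - 1L) %/% nr) + 1L
  keep_r <- numeric(0)
  keep_c <- numeric(0)
  keep_s <- numeric(0)
  for (i in seq_along(cand)) {
    if (length(keep_r) > 0L &&
        any((rr[i] - keep_r)^2 + (cc[i] - keep_c)^2 < min_sep_px^2)) next
    keep_r <- c(keep_r, rr[i])
    keep_c <- c(keep_c, cc[i])
    keep_s <- c(keep_s, score[cand[i]])
  }
  # sub-pixel: 1-D quadratic fit per axis
  sub <- function(r, c) {
    dr <- 0
    dc <- 0
    if (r > 1 && r < nrow(score)) {
      a <- score[r - 1, c]; b <- score[r, c]; d <- score[r + 1, c]
      den <- a - 2 * b + d
      if (den < 0) dr <- 0.5 * (a - d) / den
    }
    if (c > 1 && c < ncol(score)) {
      a <- score[r, c - 1]; b <- score[r, c]; d <- score[r, c + 1]
      den <- a - 2 * b + d
      if (den < 0) dc <- 0.5 * (a - d) / den
    }
    c(dr, dc)
  }
  adj <- t(mapply(sub, keep_r, keep_c))
  data.frame(x_px = keep_c - 1 + adj[, 2], y_px = keep_r - 1 + adj[, 1],
             score = keep_s)
}

# For each row of `a`, index and distance of the nearest row of `b`.
nearest_rows <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  idx <- max.col(-d2)
  list(index = idx, dist = sqrt(pmax(d2[cbind(seq_len(nrow(a)), idx)], 0)))
}

# Least-squares similarity transform src -> dst (Umeyama/Procrustes).
similarity_fit <- function(src, dst) {
  mu_s <- colMeans(src)
  mu_d <- colMeans(dst)
  S <- sweep(src, 2, mu_s)
  D <- sweep(dst, 2, mu_d)
  H <- t(S) %*% D / nrow(src)
  sv <- svd(H)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  C <- diag(c(1, sgn))
  R <- sv$v %*% C %*% t(sv$u)
  var_s <- mean(rowSums(S^2))
  s <- if (var_s > 0) sum(diag(C %*% diag(sv$d))) / var_s else 1
  t_vec <- mu_d - s * as.vector(R %*% mu_s)
  list(R = R, s = s, t = t_vec)
}

#' Segmentation parameter set
#'
#' Morphological selection bounds for [segment_spheroid()]. Bounds are set
#' from the synthetic spheroid size range (the production values are
#' unpublished) and exposed here for configuration.
#'
#' @param min_area_um2,max_area_um2 accepted spheroid area range.
#' @param min_circularity minimum `4*pi*A/P^2` (taxicab perimeter with the
#'   Cauchy pi/4 correction, clipped to 1).
#' @param min_contrast reject a threshold split whose between-class mean
#'   separation is below `min_contrast` pooled within-class standard
#'   deviations (guards empty droplets: thresholding pure Gaussian noise
#'   separates the classes by only ~2.7 pooled sigmas).
#' @param crop_factor crop half-width as a fraction of the anchor radius
#'   (< 1 keeps the bright anchor ring out of the crop).
#' @param guard_band_px mask dilation radius excluded from background sampling.
#' @return a list of parameters.
#' @export
segmentation_params <- function(min_area_um2 = 1000, max_area_um2 = 2e5,
                                min_circularity = 0.6, min_contrast = 8,
                                crop_factor = 0.8, guard_band_px = 5) {
  list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
       min_circularity = min_circularity, min_contrast = min_contrast,
       crop_factor = crop_factor, guard_band_px = guard_band_px)
}

#' Segment one spheroid in an anchor crop
#'
#' Automatic two-class (Otsu) intensity threshold on the brightfield crop
#' (spheroids image dark), hole filling, largest connected component, then
#' morphological selection: area within bounds and circularity at least
#' `min_circularity`. Returns `NULL` when no object passes - an empty droplet
#' is a valid result, guarded by requiring the threshold to split the crop
#' into classes separated by at least `min_contrast` robust sigma.
#'
#' @param crop numeric matrix (brightfield crop centred on the anchor). When
#'   brightfield contrast is insufficient, pass the negated sum of the
#'   fluorescence channels instead.
#' @param pixel_size_um micrometres per pixel.
#' @param params a [segmentation_params()].
#' @param anchor_id carried into the result.
#' @param roi optional logical matrix (same size as `crop`): region of
#'   interest for thresholding and object search, e.g. the inscribed disc of
#'   the anchor interior so the bright anchor ring in the crop corners cannot
#'   capture the threshold.
#' @return an object of class `spheroid_mask` (list with `anchor_id`, `mask`
#'   logical matrix, `area_px`, `centroid_px` 0-based crop coordinates,
#'   `circularity`, `equivalent_diameter_um`) or `NULL`.
#' @export
segment_spheroid <- function(crop, pixel_size_um, params = segmentation_params(),
                             anchor_id = NA_integer_, roi = NULL) {
  stopifnot(is.matrix(crop), pixel_size_um > 0)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(crop), ncol(crop))
  stopifnot(all(dim(roi) == dim(crop)))
  vals <- crop[roi]
  thr <- otsu_threshold(as.numeric(vals))
  obj <- crop < thr & roi
  if (!any(obj) || all(obj == roi)) return(NULL)
  # contrast guard: Otsu always splits, even pure noise. A genuine object
  # separates the classes by many within-class sigmas; splitting a Gaussian
  # noise crop gives a separation of only ~1.6 sigma (~2.7 pooled sigmas).
  lo <- crop[obj]
  hi <- crop[roi & !obj]
  s_w <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                max(1L, length(lo) + length(hi) - 2L))
  if (mean(hi) - mean(lo) < params$min_contrast * max(s_w, .Machine$double.eps)) {
    return(NULL)
  }
  obj <- fill_holes(obj)
  labels <- label_components(obj)
  if (max(labels) == 0L) return(NULL)
  sizes <- tabulate(labels[labels > 0L])
  best <- which.max(sizes)
  mask <- labels == best
  area_px <- sizes[best]
  area_um2 <- area_px * pixel_size_um^2
  if (area_um2 < params$min_area_um2 || area_um2 > params$max_area_um2) {
    return(NULL)
  }
  circ <- mask_circularity(mask)
  if (circ < params$min_circularity) return(NULL)
  idx <- which(mask, arr.ind = TRUE)
  structure(list(
    anchor_id = anchor_id,
    mask = mask,
    area_px = area_px,
    centroid_px = c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1),
    circularity = circ,
    equivalent_diameter_um = measure_diameter(area_px, pixel_size_um)
  ), class = "spheroid_mask")
}

# Logical disc ROI inside a crop: pixels within radius_um of the anchor.
crop_roi_disc <- function(dims, origin_px, x_um, y_um, radius_um, pixel_size) {
  cx <- um_to_px(x_um, pixel_size) - origin_px[["x"]] + 1
  cy <- um_to_px(y_um, pixel_size) - origin_px[["y"]] + 1
  r_px <- radius_um / pixel_size
  outer((seq_len(dims[1]) - cy)^2, (seq_len(dims[2]) - cx)^2, `+`) <= r_px^2
}

# Re-embed a mask cropped at one origin into a window at another origin.
embed_mask <- function(mask, origin_small, origin_big, dim_big) {
  out <- matrix(FALSE, dim_big[1], dim_big[2])
  dr <- origin_small[["y"]] - origin_big[["y"]]
  dc <- origin_small[["x"]] - origin_big[["x"]]
  rr <- seq_len(nrow(mask)) + dr
  cc <- seq_len(ncol(mask)) + dc
  ok_r <- rr >= 1L & rr <= dim_big[1]
  ok_c <- cc >= 1L & cc <= dim_big[2]
  out[rr[ok_r], cc[ok_c]] <- mask[ok_r, ok_c]
  out
}

# 4*pi*A/P^2 with P = taxicab boundary length * pi/4 (exact for discs on
# average over orientations, by Cauchy's projection formula); clipped to 1.
mask_circularity <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  edges <- sum(pad[-1, ] != pad[-nrow(pad), ]) +
    sum(pad[, -1] != pad[, -ncol(pad)])
  p <- edges * pi / 4
  min(1, 4 * pi * sum(mask) / p^2)
}

#' Local-background PI threshold
#'
#' `median(background) + k * MAD(background)` where the background pixels are
#' those of the crop outside the spheroid mask dilated by a guard band (halo
#' exclusion). MAD uses the usual 1.4826 consistency constant, so at k = 3 the
#' threshold sits ~3 robust sigma above the local background.
#'
#' @param pi_crop numeric matrix (PI channel crop, same size as the mask).
#' @param mask a `spheroid_mask` or a logical matrix.
#' @param k MAD multiplier (default 3, the standard robust outlier cut).
#' @param guard_band_px dilation radius before background sampling.
#' @param min_background minimum number of background pixels required.
#' @return the intensity threshold (scalar).
#' @export
local_background_threshold <- function(pi_crop, mask, k = 3,
                                       guard_band_px = 5,
                                       min_background = 100) {
  m <- if (inherits(mask, "spheroid_mask")) mask$mask else mask
  stopifnot(is.matrix(pi_crop), all(dim(pi_crop) == dim(m)))
  bg <- !dilate_disc(m, guard_band_px)
  if (sum(bg) < min_background) {
    stop(sprintf("insufficient background pixels: %d < %d",
                 sum(bg), min_background))
  }
  vals <- pi_crop[bg]
  stats::median(vals) + k * stats::mad(vals)
}

#' Score spheroid death from the PI channel
#'
#' `dead_pixel_count` is the number of mask pixels whose PI intensity exceeds
#' the threshold; `dead_fraction = dead_pixel_count / area_px` and
#' `viability = 1 - dead_fraction`. `mean_dead_intensity` is the mean PI
#' intensity over the whole mask. Pixels in `exclude` (e.g. CFSE-positive
#' lymphocyte regions on immune arms) are removed from the mask before
#' counting.
#'
#' @param pi_crop numeric matrix (PI channel crop).
#' @param mask a `spheroid_mask` or logical matrix.
#' @param threshold intensity threshold, e.g. [local_background_threshold()].
#' @param exclude optional logical matrix of pixels to drop from the mask.
#' @param pixel_size_um micrometres per pixel (for the diameter field).
#' @param timepoint_h carried into the result.
#' @param anchor_id carried into the result.
#' @return an object of class `spheroid_measurement`: list with `anchor_id`,
#'   `timepoint_h`, `area_px`, `diameter_um`, `dead_pixel_count`,
#'   `dead_fraction`, `viability`, `mean_dead_intensity`,
#'   `local_threshold_used`.
#' @export
score_viability <- function(pi_crop, mask, threshold, exclude = NULL,
                            pixel_size_um = 1, timepoint_h = NA_real_,
                            anchor_id = NA_integer_) {
  m <- if (inherits(mask, "spheroid_mask")) mask$mask else mask
  if (inherits(mask, "spheroid_mask") && is.na(anchor_id)) {
    anchor_id <- mask$anchor_id
  }
  stopifnot(is.matrix(pi_crop), all(dim(pi_crop) == dim(m)))
  if (!is.null(exclude)) m <- m & !exclude
  area <- sum(m)
  if (area == 0L) stop("empty mask after exclusion: nothing to score")
  dead <- sum(pi_crop[m] > threshold)
  structure(list(
    anchor_id = anchor_id,
    timepoint_h = timepoint_h,
    area_px = area,
    diameter_um = measure_diameter(area, pixel_size_um),
    dead_pixel_count = dead,
    dead_fraction = dead / area,
    viability = 1 - dead / area,
    mean_dead_intensity = mean(pi_crop[m]),
    local_threshold_used = threshold
  ), class = "spheroid_measurement")
}

#' Equivalent circular diameter of a mask
#'
#' `2 * sqrt(area / pi) * pixel_size`: the diameter of the circle with the
#' mask's area.
#'
#' @param mask a `spheroid_mask`, a logical matrix, or a pixel area (scalar).
#' @param pixel_size_um micrometres per pixel.
#' @return diameter in micrometres.
#' @export
measure_diameter <- function(mask, pixel_size_um) {
  area_px <- if (inherits(mask, "spheroid_mask")) mask$area_px
  else if (is.matrix(mask)) sum(mask)
  else mask
  stopifnot(area_px >= 0, pixel_size_um > 0)
  2 * sqrt(area_px / pi) * pixel_size_um
}

#' Segment and score every anchor of a frame
#'
#' For each anchor: crop brightfield and PI (crop half-width `crop_factor x
#' anchor_radius`, inside the bright ring), [segment_spheroid()], then
#' [local_background_threshold()] and [score_viability()]. On immune arms
#' (`immune_arm = TRUE`) CFSE-positive pixels - the `cfse_channel` crop above
#' its own local-background threshold - are excluded from the dead counts so
#' labelled lymphocytes are not scored as dead tumour cells.
#'
#' @param frame a [chip_frame()].
#' @param layout a `chip_layout`.
#' @param params a [segmentation_params()].
#' @param k MAD multiplier for the PI threshold.
#' @param immune_arm logical: apply the CFSE exclusion rule.
#' @param cfse_channel channel name holding the CFSE signal.
#' @return data frame, one row per anchor: measurement fields plus `qc_flags`
#'   (`""` or `"no_spheroid"`); unsegmented anchors carry `NA` measurements.
#' @export
score_chip <- function(frame, layout, params = segmentation_params(), k = 3,
                       immune_arm = FALSE, cfse_channel = "green") {
  stopifnot(inherits(frame, "chip_frame"), inherits(layout, "chip_layout"))
  ps <- frame$pixel_size
  half_px <- as.integer(round(params$crop_factor * layout$anchor_radius / ps))
  # PI/CFSE statistics use a wider window than segmentation: the brightfield
  # crop must stay inside the bright anchor ring, but the local background
  # needs room around the dilated mask (the ring is dark in fluorescence)
  half_big <- as.integer(round(1.4 * layout$anchor_radius / ps))
  rows <- lapply(seq_len(layout$n_anchors), function(i) {
    a <- layout$anchors[i, ]
    cr <- crop_anchor(frame, a$x_um, a$y_um, half_px, channels = "bf")
    roi <- crop_roi_disc(dim(cr$channels$bf), cr$origin_px, a$x_um, a$y_um,
                         half_px * ps, ps)
    sph <- segment_spheroid(cr$channels$bf, ps, params, a$anchor_id,
                            roi = roi)
    if (is.null(sph)) {
      return(data.frame(anchor_id = a$anchor_id, timepoint_h = frame$timepoint,
                        area_px = NA, diameter_um = NA, dead_pixel_count = NA,
                        dead_fraction = NA, viability = NA,
                        mean_dead_intensity = NA, local_threshold_used = NA,
                        circularity = NA, qc_flags = "no_spheroid"))
    }
    big <- crop_anchor(frame, a$x_um, a$y_um, half_big,
                       channels = intersect(c("pi", cfse_channel),
                                            names(frame$channels)))
    mask_big <- embed_mask(sph$mask, cr$origin_px, big$origin_px,
                           dim(big$channels$pi))
    thr <- local_background_threshold(big$channels$pi, mask_big, k = k,
                                      guard_band_px = params$guard_band_px)
    exclude <- NULL
    if (immune_arm && cfse_channel %in% names(big$channels)) {
      cf <- big$channels[[cfse_channel]]
      cf_thr <- local_background_threshold(cf, mask_big, k = k,
                                           guard_band_px = params$guard_band_px)
      exclude <- cf > cf_thr
    }
    meas <- score_viability(big$channels$pi, mask_big, thr, exclude = exclude,
                            pixel_size_um = ps,
                            timepoint_h = frame$timepoint,
                            anchor_id = a$anchor_id)
    data.frame(anchor_id = meas$anchor_id, timepoint_h = meas$timepoint_h,
               area_px = meas$area_px, diameter_um = meas$diameter_um,
               dead_pixel_count = meas$dead_pixel_count,
               dead_fraction = meas$dead_fraction, viability = meas$viability,
               mean_dead_intensity = meas$mean_dead_intensity,
               local_threshold_used = meas$local_threshold_used,
               circularity = sph$circularity, qc_flags = "")
  })
  do.call(rbind, rows)
}
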