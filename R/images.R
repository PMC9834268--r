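#' Multichannel chip image frame
#'
#' In-memory container for one imaging timepoint: a named list of numeric
#' matrices (rows = y, columns = x), one per channel, plus calibration. The
#' standard channel set is `bf` (brightfield), `blue` (CF350, 450 nm display),
#' `green` (CF488A / CFSE, 488 nm), `pi` (propidium iodide, 555 nm) and `red`
#' (CF647, 647 nm).
#'
#' @param channels named list of equally sized numeric matrices.
#' @param pixel_size_um micrometres per pixel.
#' @param timepoint_h acquisition time, hours.
#' @param bit_depth intensity quantisation, bits.
#' @return an object of class `chip_frame`.
#' @export
chip_frame <- function(channels, pixel_size_um, timepoint_h = 0,
                       bit_depth = 16L) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channels must have identical dimensions")
  }
  structure(list(channels = channels, pixel_size = pixel_size_um,
                 timepoint = timepoint_h, bit_depth = as.integer(bit_depth)),
            class = "chip_frame")
}

#' @export
print.chip_frame <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("chip_frame: t = %g h, %d x %d px, %g um/px, channels: %s\n",
              x$timepoint, d[2], d[1], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# micrometre <-> 0-based pixel-centre coordinate conversion
um_to_px <- function(um, pixel_size) um / pixel_size - 0.5
px_to_um <- function(px, pixel_size) (px + 0.5) * pixel_size

# 1-based matrix indices of pixels whose centre lies within `radius_um` of
# (x_um, y_um); returns list(rows, cols, idx) restricted to the image.
disc_pixels <- function(nrow_img, ncol_img, x_um, y_um, radius_um, pixel_size) {
  cx <- um_to_px(x_um, pixel_size) + 1  # 1-based fractional col
  cy <- um_to_px(y_um, pixel_size) + 1
  r_px <- radius_um / pixel_size
  cols <- max(1L, floor(cx - r_px)):min(ncol_img, ceiling(cx + r_px))
  rows <- max(1L, floor(cy - r_px)):min(nrow_img, ceiling(cy + r_px))
  if (length(cols) == 0L || length(rows) == 0L) {
    return(list(idx = integer(0)))
  }
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - cy)^2 + (g$col - cx)^2 <= r_px^2
  g <- g[keep, , drop = FALSE]
  list(rows = g$row, cols = g$col,
       idx = g$row + (g$col - 1L) * nrow_img)
}

# Separable Gaussian blur with edge replication; sigma in pixels, 0 = identity.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    # pad rows by replication, filter each column
    top <- m[rep(1L, r), , drop = FALSE]
    bot <- m[rep(nrow(m), r), , drop = FALSE]
    padded <- rbind(top, m, bot)
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(r + 1L):(r + nrow(m)), ], nrow = nrow(m))
  }
  t(blur_1d(t(blur_1d(mat))))
}

# Otsu's two-class threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(
    n_bins, 1L + floor((values - rng[1]) / diff(rng) * n_bins)), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # upper edge of the argmax bin, so the whole lower class sits below the
  # threshold (the bin centre can slice through a narrow intensity mode)
  rng[1] + which.max(sigma_b) / n_bins * diff(rng)
}

# Connected components of a logical matrix (4-connectivity).
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0)
      for (delta in c(-1L, 1L, -nr, nr)) {
        nb <- cur + delta
        ok <- nb >= 1L & nb <= nr * nc
        # forbid vertical wrap between column ends
        if (delta == -1L) ok <- ok & (cur - 1L) %% nr != 0L
        if (delta ==  1L) ok <- ok & cur %% nr != 0L
        nb <- nb[ok]
        nb <- nb[mask[nb] & labels[nb] == 0L]
        if (length(nb) > 0L) {
          labels[nb] <- lab
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

# Fill holes: background components not touching the border become foreground.
fill_holes <- function(mask) {
  comp <- label_components(!mask)
  border_labels <- unique(c(comp[1, ], comp[nrow(comp), ],
                            comp[, 1], comp[, ncol(comp)]))
  border_labels <- setdiff(border_labels, 0L)
  mask | (comp != 0L & !(comp %in% border_labels))
}

# Binary dilation by a disc of radius r pixels (small masks only).
dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2 & !(offs$dy == 0 & offs$dx == 0), ]
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  for (i in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs$dy[i]
    cc <- idx[, 2] + offs$dx[i]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

# Crop a square window (half-width in px) around an anchor centre.
# Returns list of cropped channel matrices plus the crop origin (0-based px).
crop_anchor <- function(frame, x_um, y_um, half_px,
                        channels = names(frame$channels)) {
  ps <- frame$pixel_size
  nr <- nrow(frame$channels[[1]])
  nc <- ncol(frame$channels[[1]])
  cx <- round(um_to_px(x_um, ps)) + 1L  # 1-based
  cy <- round(um_to_px(y_um, ps)) + 1L
  rows <- max(1L, cy - half_px):min(nr, cy + half_px)
  cols <- max(1L, cx - half_px):min(nc, cx + half_px)
  crops <- lapply(frame$channels[channels], function(m) {
    m[rows, cols, drop = FALSE]
  })
  list(channels = crops, origin_px = c(x = cols[1] - 1L, y = rows[1] - 1L))
}

#' Write / read a chip frame as 16-bit PGM planes
#'
#' Each channel goes to `<prefix>_<channel>.pgm` (binary NetPBM P5, maxval
#' 65535, big-endian) and the calibration to `<prefix>_meta.yaml`. PGM is used
#' because the stack must survive as plain standard files and 16 bits are
#' needed to span the barcode dynamic range.
#'
#' @param frame a [chip_frame()].
#' @param prefix file path prefix.
#' @return `write_frame_pgm`: the prefix, invisibly; `read_frame_pgm`: a
#'   `chip_frame`.
#' @export
write_frame_pgm <- function(frame, prefix) {
  stopifnot(inherits(frame, "chip_frame"))
  maxval <- 2^frame$bit_depth - 1
  for (ch in names(frame$channels)) {
    m <- frame$channels[[ch]]
    con <- file(sprintf("%s_%s.pgm", prefix, ch), "wb")
    writeLines(c("P5", sprintf("%d %d", ncol(m), nrow(m)),
                 sprintf("%d", maxval)), con)
    # PGM is row-major; R matrices are column-major
    vals <- as.integer(round(pmin(pmax(t(m), 0), maxval)))
    writeBin(vals, con, size = 2L, endian = "big")
    close(con)
  }
  yaml::write_yaml(list(pixel_size = frame$pixel_size,
                        timepoint = frame$timepoint,
                        bit_depth = frame$bit_depth,
                        channels = names(frame$channels)),
                   sprintf("%s_meta.yaml", prefix))
  invisible(prefix)
}

#' @rdname write_frame_pgm
#' @export
read_frame_pgm <- function(prefix) {
  meta <- yaml::read_yaml(sprintf("%s_meta.yaml", prefix))
  channels <- lapply(meta$channels, function(ch) {
    con <- file(sprintf("%s_%s.pgm", prefix, ch), "rb")
    on.exit(close(con))
    magic <- readLines(con, 1L)
    if (!identical(magic, "P5")) stop("not a binary PGM: ", ch)
    dims <- scan(text = readLines(con, 1L), quiet = TRUE)
    readLines(con, 1L)  # maxval
    vals <- readBin(con, "integer", n = dims[1] * dims[2], size = 2L,
                    signed = FALSE, endian = "big")
    t(matrix(vals, nrow = dims[1], ncol = dims[2]))
  })
  names(channels) <- meta$channels
  chip_frame(channels, meta$pixel_size, meta$timepoint, meta$bit_depth)
}
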