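#' Geometric model of the anchor-array chip
#'
#' A `chip_layout` describes the trapping chamber and the positions of the
#' droplet anchors: a triangular ("hexagonal packing") lattice filled row-major
#' from the chamber origin. The canonical chip holds 154 anchors in a 2 cm^2
#' chamber; an abstract-style 150-anchor chip is obtained by passing
#' `n_anchors = 150`.
#'
#' Coordinates: origin at the chamber top-left corner, x rightward, y downward,
#' units are micrometres. Pixel coordinates used elsewhere are 0-based with the
#' convention `px = um / pixel_size - 0.5` (pixel centres).
#'
#' @param n_anchors number of anchors to place (>= 1).
#' @param chamber_area_mm2 chamber area in mm^2 (2 cm^2 = 200 mm^2).
#' @param pitch_um centre-to-centre nearest-neighbour distance, micrometres.
#' @param anchor_radius_um radius of the circular trapping zone, micrometres.
#'   Default `pitch_um / 4`.
#' @param pixel_size_um image calibration, micrometres per pixel.
#' @param aspect chamber width / height ratio (the chamber is modelled as a
#'   rectangle of the stated area).
#' @param anchor_height_um anchor wall height, micrometres. Carried as metadata
#'   only; the 2-D pipeline never uses it.
#'
#' @return An object of class `chip_layout`: a list with fields `n_anchors`,
#'   `pitch`, `anchor_radius`, `chamber_width`, `chamber_height`, `pixel_size`,
#'   `anchor_height` and `anchors`, a data frame with columns `anchor_id`,
#'   `x_um`, `y_um` and `dual_zone` (every anchor carries both a primary
#'   circular and a secondary triangular droplet slot; the slots are metadata,
#'   not physics).
#' @examples
#' layout <- build_hexagonal_layout(154)
#' layout$n_anchors
#' @export
build_hexagonal_layout <- function(n_anchors = 154L,
                                   chamber_area_mm2 = 200,
                                   pitch_um = 1000,
                                   anchor_radius_um = pitch_um / 4,
                                   pixel_size_um = 10,
                                   aspect = 2,
                                   anchor_height_um = 165) {
  stopifnot(n_anchors >= 1, pitch_um > 0, chamber_area_mm2 > 0,
            anchor_radius_um > 0, pixel_size_um > 0, aspect > 0)
  area_um2 <- chamber_area_mm2 * 1e6
  width  <- sqrt(area_um2 * aspect)
  height <- width / aspect

  margin <- anchor_radius_um
  row_step <- pitch_um * sqrt(3) / 2
  if (height - margin < margin || width - margin < margin) {
    stop("chamber too small: no lattice row fits at the given pitch and margin")
  }
  ys <- seq(margin, height - margin, by = row_step)
  xs_list <- lapply(seq_along(ys), function(i) {
    offset <- if (i %% 2L == 0L) pitch_um / 2 else 0
    x <- seq(margin + offset, width - margin, by = pitch_um)
    x
  })
  capacity <- sum(lengths(xs_list))
  if (n_anchors > capacity) {
    stop(sprintf(
      "capacity error: %d anchors requested but only %d lattice sites fit in the chamber",
      n_anchors, capacity))
  }
  centers <- do.call(rbind, lapply(seq_along(ys), function(i) {
    cbind(x = xs_list[[i]], y = ys[i])
  }))
  centers <- centers[seq_len(n_anchors), , drop = FALSE]

  layout <- structure(list(
    n_anchors = as.integer(n_anchors),
    pitch = pitch_um,
    anchor_radius = anchor_radius_um,
    chamber_width = width,
    chamber_height = height,
    pixel_size = pixel_size_um,
    anchor_height = anchor_height_um,
    anchors = data.frame(
      anchor_id = seq_len(n_anchors),
      x_um = centers[, "x"],
      y_um = centers[, "y"],
      dual_zone = TRUE
    )
  ), class = "chip_layout")
  validate_chip_layout(layout)
  layout
}

#' Validate a chip layout
#'
#' Checks the structural invariants: anchor count matches the centre table, all
#' centres lie inside the chamber with at least one anchor radius of margin,
#' and (for >= 2 anchors) the nearest-neighbour distance equals the pitch.
#'
#' @param layout a `chip_layout`.
#' @param tol relative tolerance on the nearest-neighbour check.
#' @return the layout, invisibly. Errors on violation.
#' @export
validate_chip_layout <- function(layout, tol = 1e-6) {
  stopifnot(inherits(layout, "chip_layout"))
  a <- layout$anchors
  if (nrow(a) != layout$n_anchors) {
    stop("n_anchors does not match the number of anchor centres")
  }
  r <- layout$anchor_radius
  inside <- a$x_um >= r - 1e-9 & a$x_um <= layout$chamber_width - r + 1e-9 &
    a$y_um >= r - 1e-9 & a$y_um <= layout$chamber_height - r + 1e-9
  if (!all(inside)) {
    stop("anchor centres violate the chamber margin")
  }
  if (layout$n_anchors >= 2L) {
    nn <- nearest_neighbour_distances(a$x_um, a$y_um)
    if (any(abs(nn - layout$pitch) > tol * layout$pitch)) {
      stop("nearest-neighbour distances do not equal the pitch: not a hexagonal packing")
    }
  }
  invisible(layout)
}

# All-pairs nearest-neighbour distances (n is a few hundred at most).
nearest_neighbour_distances <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf(
    "chip_layout: %d anchors, pitch %.0f um, chamber %.1f x %.1f mm, %g um/px\n",
    x$n_anchors, x$pitch, x$chamber_width / 1000, x$chamber_height / 1000,
    x$pixel_size))
  invisible(x)
}

#' Droplet volume and loading specification
#'
#' Volumes of the primary (cell) and secondary (drug/barcode library) droplets,
#' the cell suspension concentration, and the PI concentration in the library.
#' Defaults are the production values: 50 nL primary, 14 nL secondary,
#' 1e6 cells/mL, 0.3 umol/L PI.
#'
#' @param v_first_nl primary (cell) droplet volume, nL.
#' @param v_second_nl secondary (library) droplet volume, nL.
#' @param cell_concentration_per_ml cell suspension concentration, cells/mL.
#' @param pi_umol propidium iodide concentration in the library, umol/L.
#' @return an object of class `droplet_spec`.
#' @export
droplet_spec <- function(v_first_nl = 50, v_second_nl = 14,
                         cell_concentration_per_ml = 1e6, pi_umol = 0.3) {
  stopifnot(v_first_nl >= 0, v_second_nl > 0,
            cell_concentration_per_ml >= 0, pi_umol >= 0)
  structure(list(v_first = v_first_nl, v_second = v_second_nl,
                 cell_concentration = cell_concentration_per_ml,
                 pi_umol = pi_umol),
            class = "droplet_spec")
}

#' Expected number of cells encapsulated per droplet
#'
#' The Poisson expectation `cell_concentration x v_first`, with the
#' cells/mL x nL unit conversion. At the default 1e6 cells/mL and 50 nL this
#' is 50 cells per droplet.
#'
#' @param spec a [droplet_spec()].
#' @return expected cell count (real-valued).
#' @export
expected_cells_per_droplet <- function(spec) {
  stopifnot(inherits(spec, "droplet_spec"))
  spec$cell_concentration * spec$v_first * 1e-6  # nL -> mL
}

#' Expected number of cells loaded on a whole chip
#'
#' `n_anchors x expected_cells_per_droplet(spec)`; 7,700 for the canonical
#' 154-anchor chip at 50 cells/droplet.
#'
#' @param layout a `chip_layout`.
#' @param spec a [droplet_spec()].
#' @return expected cell count for the chip.
#' @export
expected_cells_per_chip <- function(layout, spec) {
  stopifnot(inherits(layout, "chip_layout"))
  layout$n_anchors * expected_cells_per_droplet(spec)
}

#' Dilution of library contents on droplet-pair merging
#'
#' When the secondary droplet (volume v2, solute concentration `c_library`)
#' merges into the primary droplet (volume v1), the solute is diluted to
#' `c_post = c_library * v2 / (v1 + v2)`. Two dilution-factor conventions are
#' returned so downstream code can state which it uses: the exact factor
#' `(v1 + v2) / v2` and the v1/v2 approximation commonly quoted for this chip
#' (50/14 ~ 3.5).
#'
#' @param spec a [droplet_spec()].
#' @param c_library solute concentration in the library droplet (any unit).
#' @return list with `c_post`, `paper_factor` (v1/v2) and `exact_factor`
#'   ((v1+v2)/v2). Solute amount is conserved: `c_post * (v1+v2) ==
#'   c_library * v2`.
#' @examples
#' merge_dilution(droplet_spec(), c_library = 20)$c_post  # 20 * 14/64
#' @export
merge_dilution <- function(spec, c_library = 1) {
  stopifnot(inherits(spec, "droplet_spec"), c_library >= 0)
  v1 <- spec$v_first
  v2 <- spec$v_second
  list(
    c_post = c_library * v2 / (v1 + v2),
    paper_factor = v1 / v2,
    exact_factor = (v1 + v2) / v2
  )
}

#' Write / read a chip layout as CSV (+ YAML config)
#'
#' The anchor table is written as plain CSV (`anchor_id,x_um,y_um,dual_zone`)
#' and the scalar geometry as a YAML sidecar so a layout round-trips through
#' text files.
#'
#' @param layout a `chip_layout`.
#' @param path CSV file path; the sidecar is `<path>.yaml`.
#' @return `write_layout_csv`: the path, invisibly. `read_layout_csv`: a
#'   `chip_layout`.
#' @export
write_layout_csv <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  utils::write.csv(layout$anchors, path, row.names = FALSE)
  meta <- layout[c("n_anchors", "pitch", "anchor_radius", "chamber_width",
                   "chamber_height", "pixel_size", "anchor_height")]
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  anchors <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  layout <- structure(c(meta, list(anchors = anchors)), class = "chip_layout")
  layout$n_anchors <- as.integer(layout$n_anchors)
  validate_chip_layout(layout)
  layout
}
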