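#' Read droplet-centre channel intensities
#'
#' The robust centre statistic used for barcode decoding: the per-channel
#' median over a circular window of `window_radius` pixels centred on the
#' anchor (droplet) centre.
#'
#' @param frame a [chip_frame()].
#' @param layout a `chip_layout`.
#' @param anchor_id anchor to read.
#' @param window_radius window radius in pixels (1 = the single centre pixel).
#' @param channels channels to read; defaults to all non-brightfield channels.
#' @return an object of class `droplet_observation`: list with `anchor_id`,
#'   `timepoint`, `channel_intensities` (named numeric) and `window_radius`.
#' @export
read_droplet <- function(frame, layout, anchor_id, window_radius = 5,
                         channels = setdiff(names(frame$channels), "bf")) {
  stopifnot(inherits(frame, "chip_frame"), inherits(layout, "chip_layout"))
  missing_ch <- setdiff(channels, names(frame$channels))
  if (length(missing_ch) > 0) {
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  }
  a <- layout$anchors[layout$anchors$anchor_id == anchor_id, , drop = FALSE]
  if (nrow(a) != 1L) stop("unknown anchor_id: ", anchor_id)
  nr <- nrow(frame$channels[[1]])
  nc <- ncol(frame$channels[[1]])
  ps <- frame$pixel_size
  # window: pixels within (window_radius - 0.5) px of the centre pixel, so
  # window_radius = 1 is exactly the single centre pixel
  cx <- round(um_to_px(a$x_um, ps)) + 1L  # 1-based centre pixel
  cy <- round(um_to_px(a$y_um, ps)) + 1L
  r <- window_radius - 0.5
  if (cx - r < 1 || cx + r > nc || cy - r < 1 || cy + r > nr) {
    stop("read window extends outside the image for anchor ", anchor_id)
  }
  span <- -floor(r):floor(r)
  g <- expand.grid(dy = span, dx = span)
  g <- g[g$dy^2 + g$dx^2 <= r^2, ]
  idx <- (cy + g$dy) + (cx + g$dx - 1L) * nr
  intens <- vapply(channels, function(ch) {
    stats::median(frame$channels[[ch]][idx])
  }, numeric(1))
  structure(list(anchor_id = anchor_id, timepoint = frame$timepoint,
                 channel_intensities = intens,
                 window_radius = window_radius),
            class = "droplet_observation")
}

# Per-dye log-ladder geometry: log levels, the pseudo-log of the "absent"
# class (one mean spacing below the lowest level) and the mean spacing.
ladder_log_geometry <- function(ladder) {
  ll <- log(sort(ladder, decreasing = TRUE))
  spacing <- if (length(ll) > 1L) mean(abs(diff(ll))) else log(8)
  list(log_levels = ll, absent_log = min(ll) - spacing, spacing = spacing)
}

#' Decode a droplet observation to a treatment condition
#'
#' Background-subtracted intensities are converted to concentrations with the
#' calibration gains, multiplied by the codebook's merge dilution factor to sit
#' on the library ladder scale, and classified per dye to the nearest ladder
#' level in log-concentration (an "absent" class sits one ladder spacing below
#' the lowest level, i.e. the decision boundary is the geometric midpoint
#' below it). The level vector must match a codebook code exactly; the
#' assignment also carries `log_margin`, the log-space distance gap between
#' the best and second-best codes, and is `UNASSIGNED` when no code matches or
#' the margin falls below `margin_threshold` (default 10% of the smallest
#' inter-level log spacing).
#'
#' @param obs a [read_droplet()] observation.
#' @param codebook a `barcode_codebook`.
#' @param calibration list with named numeric `gain` (counts per umol/L,
#'   post-merge scale) and `background` (counts), per dye channel; e.g.
#'   [calibration_from_optics()].
#' @param margin_threshold minimum `log_margin`; `NULL` = 10% of the smallest
#'   ladder spacing.
#' @return an object of class `condition_assignment`: list with `anchor_id`,
#'   `condition_label` (or `NA` = UNASSIGNED), `unassigned_reason`,
#'   `log_margin` and `levels` (named inferred per-dye level indices).
#' @export
decode_droplet <- function(obs, codebook, calibration,
                           margin_threshold = NULL) {
  stopifnot(inherits(obs, "droplet_observation"),
            inherits(codebook, "barcode_codebook"))
  dyes <- names(codebook$dyes)
  if (!all(dyes %in% names(obs$channel_intensities))) {
    stop("observation lacks codebook dye channel(s)")
  }
  gain <- calibration$gain
  bg <- calibration$background
  stopifnot(all(gain[dyes] > 0))

  geom <- lapply(codebook$levels, ladder_log_geometry)
  if (is.null(margin_threshold)) {
    margin_threshold <- 0.1 * min(vapply(geom, `[[`, numeric(1), "spacing"))
  }

  # measured log-concentration on the library scale, one per dye
  log_meas <- vapply(dyes, function(dye) {
    conc_post <- (obs$channel_intensities[[dye]] - bg[[dye]]) / gain[[dye]]
    conc_lib <- conc_post * codebook$dilution_factor
    if (conc_lib <= exp(geom[[dye]]$absent_log)) geom[[dye]]$absent_log
    else log(conc_lib)
  }, numeric(1))

  # nearest-level classification per dye (0 = absent)
  levels <- vapply(dyes, function(dye) {
    cand_logs <- c(geom[[dye]]$absent_log, geom[[dye]]$log_levels)
    which.min(abs(log_meas[[dye]] - cand_logs)) - 1L
  }, integer(1))

  # distance to every code in log space
  code_dist <- vapply(seq_len(nrow(codebook$codes)), function(i) {
    d2 <- 0
    for (dye in dyes) {
      lv <- codebook$codes[[paste0(dye, "_level")]][i]
      target <- if (lv == 0) geom[[dye]]$absent_log else
        geom[[dye]]$log_levels[lv]
      d2 <- d2 + (log_meas[[dye]] - target)^2
    }
    sqrt(d2)
  }, numeric(1))
  ord <- order(code_dist)
  log_margin <- if (length(code_dist) > 1L) {
    code_dist[ord[2]] - code_dist[ord[1]]
  } else {
    min(vapply(geom, `[[`, numeric(1), "spacing"))
  }

  lv_cols <- paste0(dyes, "_level")
  match_row <- which(apply(codebook$codes[lv_cols], 1L, function(r) {
    all(r == levels)
  }))

  reason <- NA_character_
  label <- NA_character_
  if (length(match_row) != 1L) {
    reason <- if (all(levels == 0L)) "no_dye_detected" else "no_code_match"
  } else if (log_margin < margin_threshold) {
    reason <- "low_margin"
  } else {
    label <- codebook$codes$condition_label[match_row]
  }
  structure(list(anchor_id = obs$anchor_id, condition_label = label,
                 unassigned_reason = reason,
                 log_margin = log_margin, levels = levels),
            class = "condition_assignment")
}

#' Calibration taken from a rendering optics model
#'
#' The decoding calibration (per-channel gain and background) matching an
#' [optics_model()]; in a real experiment these numbers come from config or
#' from control anchors.
#'
#' @param optics an [optics_model()].
#' @return list with `gain` and `background` usable by [decode_droplet()].
#' @export
calibration_from_optics <- function(optics) {
  stopifnot(inherits(optics, "optics_model"))
  bg <- rep(optics$background_level, length(optics$gain))
  names(bg) <- names(optics$gain)
  list(gain = optics$gain, background = bg)
}

#' Decode every anchor of a chip frame
#'
#' @param frame a [chip_frame()] (typically the first post-merge timepoint).
#' @param layout a `chip_layout`.
#' @param codebook a `barcode_codebook`.
#' @param calibration see [decode_droplet()].
#' @param window_radius read window radius, pixels.
#' @param margin_threshold see [decode_droplet()].
#' @return data frame with one row per anchor: `anchor_id`, `condition_label`
#'   (`NA` = UNASSIGNED), `unassigned_reason`, `log_margin` and one
#'   `<dye>_level` column per dye.
#' @export
decode_chip <- function(frame, layout, codebook, calibration,
                        window_radius = 5, margin_threshold = NULL) {
  rows <- lapply(layout$anchors$anchor_id, function(id) {
    obs <- read_droplet(frame, layout, id, window_radius)
    asg <- decode_droplet(obs, codebook, calibration, margin_threshold)
    cbind(data.frame(anchor_id = id,
                     condition_label = asg$condition_label,
                     unassigned_reason = asg$unassigned_reason,
                     log_margin = asg$log_margin),
          as.data.frame(as.list(asg$levels)))
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:4)] <- paste0(names(codebook$dyes), "_level")
  out
}
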