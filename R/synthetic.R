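#' Microscope response model for synthetic rendering
#'
#' Linear per-channel response: `intensity = gain * concentration + background
#' + N(0, noise_sd)`, quantised to `bit_depth` bits. Defaults are chosen so the
#' 8-fold barcode ladders span well-separated log-intensity bands inside the
#' 16-bit range, with signal-to-noise ~ 20 at the weakest red/green level
#' (separability, not microscope realism, is the goal): the top post-merge red
#' level (20 umol/L / 4.571 = 4.375 umol/L) maps near 60,000 counts and the
#' weakest (0.00875 umol/L) to ~120 counts over background at noise_sd 6.
#'
#' @param gain named per-dye-channel gain, counts per umol/L (post-merge).
#' @param background_level fluorescence background, counts.
#' @param noise_sd additive Gaussian read-noise sd, counts.
#' @param psf_sigma Gaussian point-spread sigma, pixels. Default 0: the
#'   pixel-level PI scoring rule (median + k*MAD local threshold) is not
#'   robust to PSF bleed from scattered single-pixel dead signal, so the
#'   default optics renders pixel-resolved images; set > 0 to study blur.
#' @param pi_positive_level PI signal added on dead pixels, counts.
#' @param bf_background,bf_ring_level,bf_spheroid_level brightfield grey
#'   levels for chamber background, anchor ring and spheroid body.
#' @param ring_width_um brightfield anchor-ring thickness, micrometres.
#' @param bit_depth quantisation depth, bits.
#' @return an object of class `optics_model`.
#' @export
optics_model <- function(gain = c(red = 13700, green = 13700, blue = 914),
                         background_level = 100,
                         noise_sd = 6,
                         psf_sigma = 0,
                         pi_positive_level = 3000,
                         bf_background = 30000,
                         bf_ring_level = 48000,
                         bf_spheroid_level = 12000,
                         ring_width_um = 30,
                         bit_depth = 16L) {
  stopifnot(all(gain > 0), noise_sd >= 0, psf_sigma >= 0,
            pi_positive_level >= 0, bit_depth %in% c(8L, 16L))
  structure(list(gain = gain, background_level = background_level,
                 noise_sd = noise_sd, psf_sigma = psf_sigma,
                 pi_positive_level = pi_positive_level,
                 bf_background = bf_background,
                 bf_ring_level = bf_ring_level,
                 bf_spheroid_level = bf_spheroid_level,
                 ring_width_um = ring_width_um,
                 bit_depth = as.integer(bit_depth)),
            class = "optics_model")
}

#' Hill-type dose-death model
#'
#' Terminal dead fraction after long exposure at a delivered (post-merge) dose:
#' `baseline + (max_dead - baseline) * d^h / (ec50^h + d^h)`. Per-drug
#' parameter sets; unknown drugs (and vehicle) sit at baseline. The default
#' parameters reproduce the qualitative screen phenotype: tamoxifen kills only
#' at the top of its dose ladder (post-merge EC50 25 umol/L, steep slope) and
#' alpelisib, a growth inhibitor, induces no cell death.
#'
#' @param drugs named list; each entry a list with `max_dead`, `ec50_umol`
#'   (post-merge scale), `hill`.
#' @param baseline_dead_fraction spontaneous dead fraction.
#' @return an object of class `dose_response_model`.
#' @export
dose_response_model <- function(
    drugs = list(
      tamoxifen = list(max_dead = 0.65, ec50_umol = 25, hill = 4),
      alpelisib = list(max_dead = 0, ec50_umol = 1, hill = 1)
    ),
    baseline_dead_fraction = 0.05) {
  stopifnot(baseline_dead_fraction >= 0, baseline_dead_fraction <= 1)
  for (d in drugs) {
    stopifnot(d$max_dead >= 0, d$max_dead <= 1, d$ec50_umol > 0, d$hill > 0)
  }
  structure(list(drugs = drugs, baseline = baseline_dead_fraction),
            class = "dose_response_model")
}

#' Terminal dead fraction under a drug dose
#'
#' @param model a [dose_response_model()].
#' @param drug drug name (character); unknown names give the baseline.
#' @param dose_umol delivered (post-merge) dose, umol/L.
#' @return dead fraction in `[0, 1]`, non-decreasing in dose.
#' @export
hill_dead_fraction <- function(model, drug, dose_umol) {
  stopifnot(inherits(model, "dose_response_model"), all(dose_umol >= 0))
  p <- model$drugs[[drug]]
  if (is.null(p) || p$max_dead <= model$baseline) {
    return(rep(model$baseline, length(dose_umol)))
  }
  frac <- dose_umol^p$hill / (p$ec50_umol^p$hill + dose_umol^p$hill)
  model$baseline + (p$max_dead - model$baseline) * frac
}

#' Logistic spheroid growth specification
#'
#' `d(t) = dmax / (1 + ((dmax - d0)/d0) exp(-rate * t))` with lognormal
#' anchor-level size noise. Defaults emulate a fast-growing tumour line seeded
#' from ~50 cells: 80 um at t = 0 saturating near 250 um within ~3 days.
#'
#' @param d0_um initial spheroid diameter, micrometres.
#' @param dmax_um plateau diameter, micrometres.
#' @param rate_per_h logistic growth rate, 1/h.
#' @param sdlog lognormal sd of the per-anchor size multiplier.
#' @return an object of class `growth_spec`.
#' @export
growth_spec <- function(d0_um = 80, dmax_um = 250, rate_per_h = 0.05,
                        sdlog = 0.08) {
  stopifnot(d0_um > 0, dmax_um >= d0_um, rate_per_h >= 0, sdlog >= 0)
  structure(list(d0 = d0_um, dmax = dmax_um, rate = rate_per_h, sdlog = sdlog),
            class = "growth_spec")
}

logistic_diameter <- function(growth, t_h) {
  a <- (growth$dmax - growth$d0) / growth$d0
  growth$dmax / (1 + a * exp(-growth$rate * t_h))
}

# Beta noise around a mean fraction; phi = Inf gives the mean itself.
beta_noise <- function(mean_frac, phi) {
  if (!is.finite(phi)) return(mean_frac)
  m <- pmin(pmax(mean_frac, 1e-6), 1 - 1e-6)
  stats::rbeta(length(m), m * phi, (1 - m) * phi)
}

#' Simulate a full barcoded drug screen
#'
#' Assigns each anchor a condition uniformly at random (emulating random
#' droplet mixing), draws per-anchor logistic growth trajectories with
#' lognormal size noise, draws dead fractions from the Hill dose-death model
#' ramping in with first-order kinetics (time constant `effect_tau_h`) plus
#' Beta-distributed anchor noise, and renders one multichannel frame per
#' timepoint. Everything is reproducible from `seed`. Spheroid diameters are
#' capped at 90% of the droplet diameter (`1.8 * anchor_radius`): a spheroid
#' cannot outgrow the droplet that contains it.
#'
#' @param layout a `chip_layout`.
#' @param codebook a `barcode_codebook`; condition doses and dye levels come
#'   from it (doses delivered at the post-merge concentration).
#' @param dose_model a [dose_response_model()].
#' @param timepoints_h imaging times, hours.
#' @param growth a [growth_spec()].
#' @param optics an [optics_model()]; `NULL` skips rendering (truth only).
#' @param seed integer seed (mandatory).
#' @param effect_tau_h first-order time constant of drug-effect onset, hours.
#' @param noise_phi Beta concentration parameter of the anchor-level dead
#'   fraction noise (`Inf` = noise-free).
#' @param p_empty probability that an anchor trapped no cell droplet.
#' @return list with `truth` (data frame: `anchor_id`, `condition_label`,
#'   `drug`, `dose_umol` post-merge, `timepoint_h`, `true_diameter_um`,
#'   `true_dead_fraction`, `red_umol`/`green_umol`/`blue_umol` post-merge dye
#'   levels, `n_immune_cells`, `empty`) and `frames` (list of [chip_frame()],
#'   one per timepoint; `NULL` if `optics` is `NULL`).
#' @export
simulate_screen <- function(layout, codebook, dose_model = dose_response_model(),
                            timepoints_h = c(0, 72, 144),
                            growth = growth_spec(),
                            optics = optics_model(),
                            seed,
                            effect_tau_h = 24,
                            noise_phi = 80,
                            p_empty = 0) {
  stopifnot(inherits(layout, "chip_layout"),
            inherits(codebook, "barcode_codebook"))
  if (missing(seed)) stop("a seed is mandatory for simulation")
  n_codes <- nrow(codebook$codes)
  if (n_codes < 1L) stop("codebook is empty")
  if (n_codes > layout$n_anchors) {
    stop("layout/codebook mismatch: more conditions than anchors")
  }
  set.seed(seed)
  n <- layout$n_anchors
  cond_idx <- sample.int(n_codes, n, replace = TRUE)
  codes <- codebook$codes[cond_idx, , drop = FALSE]
  conc <- code_concentrations(codebook)[cond_idx, , drop = FALSE]
  empty <- stats::runif(n) < p_empty
  size_mult <- stats::rlnorm(n, 0, growth$sdlog)
  dose_post <- codes$dose_umol / codebook$dilution_factor
  d_inf <- hill_dead_fraction_by_row(dose_model, codes$drug, dose_post)

  truth <- do.call(rbind, lapply(timepoints_h, function(t_h) {
    mean_dead <- dose_model$baseline +
      (d_inf - dose_model$baseline) * (1 - exp(-t_h / effect_tau_h))
    data.frame(
      anchor_id = layout$anchors$anchor_id,
      condition_label = codes$condition_label,
      drug = codes$drug,
      dose_umol = dose_post,
      timepoint_h = t_h,
      true_diameter_um = ifelse(empty, 0,
                                pmin(logistic_diameter(growth, t_h) * size_mult,
                                     1.8 * layout$anchor_radius)),
      true_dead_fraction = ifelse(empty, 0, beta_noise(mean_dead, noise_phi)),
      red_umol = conc$red_umol / codebook$dilution_factor,
      green_umol = conc$green_umol / codebook$dilution_factor,
      blue_umol = conc$blue_umol / codebook$dilution_factor,
      n_immune_cells = 0L,
      empty = empty,
      row.names = NULL
    )
  }))

  frames <- NULL
  if (!is.null(optics)) {
    frames <- lapply(timepoints_h, function(t_h) {
      render_chip_image(layout, truth[truth$timepoint_h == t_h, ],
                        optics, seed = seed + round(t_h) + 1L)
    })
    names(frames) <- paste0("t", timepoints_h)
  }
  list(truth = truth, frames = frames)
}

# vectorised per-row Hill lookup across different drugs
hill_dead_fraction_by_row <- function(model, drug, dose) {
  out <- numeric(length(drug))
  for (d in unique(drug)) {
    sel <- drug == d
    out[sel] <- hill_dead_fraction(model, d, dose[sel])
  }
  out
}

#' Render one multichannel chip image from ground truth
#'
#' Brightfield shows the anchor rings and one disc per spheroid at its true
#' diameter; each barcode dye channel shows a uniform droplet fill at
#' `gain * concentration + background`; the PI channel marks a seeded random
#' subset of spheroid pixels, `round(true_dead_fraction * area)` of them, with
#' `pi_positive_level` counts over background. Gaussian read noise, optional
#' PSF blur, then clipping/quantisation to the bit depth.
#'
#' @param layout a `chip_layout`.
#' @param truth single-timepoint ground-truth table (see [simulate_screen()]);
#'   every `anchor_id` must exist in the layout. An empty table renders
#'   background only.
#' @param optics an [optics_model()].
#' @param seed integer seed for noise and dead-pixel placement.
#' @return a [chip_frame()] with channels `bf`, `blue`, `green`, `pi`, `red`.
#' @export
render_chip_image <- function(layout, truth, optics, seed) {
  stopifnot(inherits(layout, "chip_layout"), inherits(optics, "optics_model"))
  if (missing(seed)) stop("a seed is mandatory for rendering")
  if (nrow(truth) > 0) {
    if (length(unique(truth$timepoint_h)) > 1L) {
      stop("render_chip_image expects a single-timepoint truth table")
    }
    if (!all(truth$anchor_id %in% layout$anchors$anchor_id)) {
      stop("truth refers to anchors absent from the layout")
    }
  }
  ps <- layout$pixel_size
  nc_img <- as.integer(ceiling(layout$chamber_width / ps))
  nr_img <- as.integer(ceiling(layout$chamber_height / ps))
  set.seed(seed)

  bf <- matrix(optics$bf_background, nr_img, nc_img)
  dye <- list(
    blue = matrix(optics$background_level, nr_img, nc_img),
    green = matrix(optics$background_level, nr_img, nc_img),
    red = matrix(optics$background_level, nr_img, nc_img)
  )
  pi_ch <- matrix(optics$background_level, nr_img, nc_img)

  anchors <- layout$anchors
  for (i in seq_len(nrow(anchors))) {
    x <- anchors$x_um[i]
    y <- anchors$y_um[i]
    ring_outer <- disc_pixels(nr_img, nc_img, x, y,
                              layout$anchor_radius + optics$ring_width_um / 2, ps)
    ring_inner <- disc_pixels(nr_img, nc_img, x, y,
                              layout$anchor_radius - optics$ring_width_um / 2, ps)
    ring_idx <- setdiff(ring_outer$idx, ring_inner$idx)
    bf[ring_idx] <- optics$bf_ring_level

    row <- truth[truth$anchor_id == anchors$anchor_id[i], , drop = FALSE]
    if (nrow(row) == 0L) next
    droplet <- disc_pixels(nr_img, nc_img, x, y, layout$anchor_radius, ps)
    for (ch in names(dye)) {
      conc <- row[[paste0(ch, "_umol")]]
      if (conc > 0) {
        dye[[ch]][droplet$idx] <- optics$background_level +
          optics$gain[[ch]] * conc
      }
    }
    if (row$true_diameter_um > 0) {
      sph <- disc_pixels(nr_img, nc_img, x, y, row$true_diameter_um / 2, ps)
      bf[sph$idx] <- optics$bf_spheroid_level
      n_dead <- round(row$true_dead_fraction * length(sph$idx))
      if (n_dead > 0) {
        dead_idx <- if (n_dead >= length(sph$idx)) sph$idx else
          sample(sph$idx, n_dead)
        pi_ch[dead_idx] <- pi_ch[dead_idx] + optics$pi_positive_level
      }
    }
  }

  channels <- list(bf = bf, blue = dye$blue, green = dye$green,
                   pi = pi_ch, red = dye$red)
  maxval <- 2^optics$bit_depth - 1
  channels <- lapply(channels, function(m) {
    if (optics$psf_sigma > 0) m <- gaussian_blur(m, optics$psf_sigma)
    if (optics$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, optics$noise_sd),
                      nrow(m), ncol(m))
    }
    matrix(round(pmin(pmax(m, 0), maxval)), nrow(m), ncol(m))
  })
  tp <- if (nrow(truth) > 0) truth$timepoint_h[1] else 0
  chip_frame(channels, ps, tp, optics$bit_depth)
}

#' Simulate a CD8+ T-cell co-culture cytotoxicity experiment
#'
#' Dead fraction follows saturating first-order killing,
#' `d(t) = baseline + (max_dead - baseline) * (1 - exp(-k_eff * t))` with
#' `k_eff = killing_rate * immune_ratio / 10` (normalised to the 10:1
#' effector:target ratio used on chip), so killing is front-loaded: the 0-24 h
#' increment always exceeds the 24-48 h increment. A ratio of 0 is the control
#' arm and stays at baseline. Per-anchor Beta noise as in [simulate_screen()].
#'
#' @param n_tumor tumour cells per droplet (also sets `n_immune_cells`).
#' @param immune_ratio CD8+ T cells per tumour cell (10 on chip; 0 = control).
#' @param killing_rate first-order killing rate at ratio 10, 1/h.
#' @param timepoints_h observation times, hours (chip schedule: 1, 24, 48).
#' @param seed integer seed.
#' @param n_anchors number of simulated anchors per arm.
#' @param max_dead_fraction killing plateau.
#' @param baseline_dead_fraction spontaneous dead fraction.
#' @param noise_phi Beta concentration of anchor noise (`Inf` = noise-free).
#' @param diameter_um spheroid diameter (co-cultures are not grown long enough
#'   to change size materially).
#' @return ground-truth data frame in the [simulate_screen()] layout, with
#'   `condition_label` `"cd8_<ratio>x"` or `"control"` and the CF647 2 umol/L
#'   co-culture barcode (post-merge) on the immune arm.
#' @export
simulate_coculture <- function(n_tumor = 50, immune_ratio = 10,
                               killing_rate = 0.06,
                               timepoints_h = c(1, 24, 48),
                               seed,
                               n_anchors = 154,
                               max_dead_fraction = 0.5,
                               baseline_dead_fraction = 0.05,
                               noise_phi = 80,
                               diameter_um = 120) {
  stopifnot(immune_ratio >= 0, killing_rate >= 0, n_tumor > 0)
  if (missing(seed)) stop("a seed is mandatory for simulation")
  set.seed(seed)
  k_eff <- killing_rate * immune_ratio / 10
  label <- if (immune_ratio > 0) sprintf("cd8_%gx", immune_ratio) else "control"
  barcode_red <- if (immune_ratio > 0) {
    2.0 / merge_dilution(droplet_spec())$exact_factor
  } else 0
  do.call(rbind, lapply(timepoints_h, function(t_h) {
    mean_dead <- baseline_dead_fraction +
      (max_dead_fraction - baseline_dead_fraction) * (1 - exp(-k_eff * t_h))
    data.frame(
      anchor_id = seq_len(n_anchors),
      condition_label = label,
      drug = "cd8",
      dose_umol = 0,
      timepoint_h = t_h,
      true_diameter_um = diameter_um,
      true_dead_fraction = beta_noise(rep(mean_dead, n_anchors), noise_phi),
      red_umol = barcode_red,
      green_umol = 0,
      blue_umol = 0,
      n_immune_cells = as.integer(round(n_tumor * immune_ratio)),
      empty = FALSE,
      row.names = NULL
    )
  }))
}
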