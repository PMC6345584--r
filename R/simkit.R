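# Synthetic-data generators with recorded ground truth.  Every input
# type the pipeline consumes can be produced here with known parameters,
# so the whole analysis chain is testable without external data.  Seeds
# are mandatory arguments, never global state; identical truth + seed
# gives bit-identical output.

#' Ground truth for a two-channel vesicle scene
#'
#' Describes a field of diffraction-limited vesicles rendered as
#' isotropic Gaussians on a uniform cytoplasmic background with additive
#' Gaussian noise.  A controlled fraction of channel-A vesicles is
#' duplicated at identical centers in channel B, so colocalization ground
#' truth is exact.
#'
#' When `vesicle_centers` is `NULL`, centers are drawn uniformly at
#' random inside a 3-sigma margin with a minimum pairwise separation
#' (rejection sampling), reproducibly from `seed`.
#'
#' @param n_vesicles number of channel-A vesicles.
#' @param shape image dimensions `c(rows, cols)` (used to place random
#'   centers).
#' @param vesicle_centers optional n x 2 matrix of 0-based (row, col)
#'   centers; overrides random placement.
#' @param vesicle_sigma Gaussian point-spread sigma in pixels (> 0).
#' @param vesicle_amplitudes peak amplitudes (recycled to n).
#' @param coloc_fraction fraction in [0, 1] of A vesicles duplicated into
#'   channel B.
#' @param background_level uniform background intensity.
#' @param noise_sigma additive Gaussian noise sigma (0 for noise-free).
#' @param min_separation minimum center-to-center distance in pixels for
#'   random placement.
#' @param coloc_jitter sigma in pixels of Gaussian jitter applied to the
#'   duplicated centers in channel B (0 = identical centers).
#' @param seed integer seed (mandatory).
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(n_vesicles, shape, vesicle_centers = NULL,
                        vesicle_sigma = 1.5, vesicle_amplitudes = 100,
                        coloc_fraction = 0, background_level = 10,
                        noise_sigma = 0, min_separation = 8,
                        coloc_jitter = 0, seed = 1L) {
  if (vesicle_sigma <= 0) stop("`vesicle_sigma` must be > 0", call. = FALSE)
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    stop("`coloc_fraction` must be in [0, 1]", call. = FALSE)
  }
  shape <- as.integer(shape)
  if (is.null(vesicle_centers)) {
    margin <- 3 * vesicle_sigma
    if (any(shape <= 2 * margin) && n_vesicles > 0) {
      stop("image too small to place vesicles with a 3-sigma margin",
           call. = FALSE)
    }
    vesicle_centers <- with_seed(substream_seed(seed, "centers"), {
      pts <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(pts) < n_vesicles && tries < 20000L) {
        cand <- c(stats::runif(1, margin, shape[1] - 1 - margin),
                  stats::runif(1, margin, shape[2] - 1 - margin))
        if (nrow(pts) == 0 ||
            min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_separation) {
          pts <- rbind(pts, cand)
        }
        tries <- tries + 1L
      }
      if (nrow(pts) < n_vesicles) {
        stop("could not place vesicles at the requested density", call. = FALSE)
      }
      pts
    })
  } else {
    vesicle_centers <- matrix(as.numeric(vesicle_centers), ncol = 2)
    if (nrow(vesicle_centers) != n_vesicles) {
      stop("`vesicle_centers` must have `n_vesicles` rows", call. = FALSE)
    }
  }
  structure(list(vesicle_centers = vesicle_centers,
                 vesicle_sigma = vesicle_sigma,
                 vesicle_amplitudes = rep_len(vesicle_amplitudes,
                                              max(1L, n_vesicles)),
                 coloc_fraction = coloc_fraction,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 coloc_jitter = coloc_jitter,
                 shape = shape, seed = as.integer(seed)),
            class = "scene_truth")
}

# Render Gaussian spots onto a background matrix.
render_spots <- function(shape, centers, sigma, amplitudes, background) {
  img <- matrix(background, shape[1], shape[2])
  if (nrow(centers) == 0) return(img)
  r <- seq_len(shape[1]) - 1
  cc <- seq_len(shape[2]) - 1
  for (i in seq_len(nrow(centers))) {
    gr <- exp(-(r - centers[i, 1])^2 / (2 * sigma^2))
    gc <- exp(-(cc - centers[i, 2])^2 / (2 * sigma^2))
    img <- img + amplitudes[i] * outer(gr, gc)
  }
  img
}

#' Generate a two-channel synthetic vesicle scene
#'
#' Channel A contains all vesicles in `truth`; channel B contains exactly
#' `round(coloc_fraction * n)` of them (the first ones in truth order),
#' duplicated at identical centers (optionally jittered).  Gaussian noise
#' of `noise_sigma` is added independently per channel.
#'
#' @param truth a [scene_truth()] object.
#' @param shape image dimensions `c(rows, cols)`; must contain every
#'   center with a 3-sigma margin.
#' @return list with `channel_a`, `channel_b` ([pixel_image()]s) and
#'   `truth` (the input, with `coloc_centers_b` recording the duplicated
#'   centers).
#' @export
make_vesicle_scene <- function(truth, shape = truth$shape) {
  stopifnot(inherits(truth, "scene_truth"))
  shape <- as.integer(shape)
  ctr <- truth$vesicle_centers
  n <- nrow(ctr)
  margin <- 3 * truth$vesicle_sigma
  if (n > 0) {
    bad <- which(ctr[, 1] < margin | ctr[, 1] > shape[1] - 1 - margin |
                 ctr[, 2] < margin | ctr[, 2] > shape[2] - 1 - margin)
    if (length(bad)) {
      stop(sprintf("vesicle %d at (%.1f, %.1f) lies outside the 3-sigma margin",
                   bad[1], ctr[bad[1], 1], ctr[bad[1], 2]), call. = FALSE)
    }
  }
  n_dup <- round(truth$coloc_fraction * n)
  dup_idx <- seq_len(n_dup)
  ctr_b <- ctr[dup_idx, , drop = FALSE]
  if (truth$coloc_jitter > 0 && n_dup > 0) {
    ctr_b <- ctr_b + with_seed(substream_seed(truth$seed, "jitter"),
                               matrix(stats::rnorm(2 * n_dup,
                                                   sd = truth$coloc_jitter),
                                      n_dup, 2))
  }
  a <- render_spots(shape, ctr, truth$vesicle_sigma,
                    truth$vesicle_amplitudes, truth$background_level)
  b <- render_spots(shape, ctr_b, truth$vesicle_sigma,
                    truth$vesicle_amplitudes[dup_idx],
                    truth$background_level)
  if (truth$noise_sigma > 0) {
    a <- a + with_seed(substream_seed(truth$seed, "noise_a"),
                       matrix(stats::rnorm(length(a), sd = truth$noise_sigma),
                              shape[1], shape[2]))
    b <- b + with_seed(substream_seed(truth$seed, "noise_b"),
                       matrix(stats::rnorm(length(b), sd = truth$noise_sigma),
                              shape[1], shape[2]))
  }
  truth$coloc_centers_b <- ctr_b
  list(channel_a = pixel_image(pmax(a, 0), channel_name = "A"),
       channel_b = pixel_image(pmax(b, 0), channel_name = "B"),
       truth = truth)
}

#' Ground truth for a FRAP recovery series
#'
#' @param rate_k recovery rate, per second (> 0).
#' @param mobile_fraction fraction in [0, 1] of fluorophores exchanging
#'   with the unbleached pool.
#' @param postbleach_floor normalized ROI intensity immediately after the
#'   bleach, in [0, 1).
#' @param fading_rate whole-image acquisition-bleaching rate, per second.
#' @param frame_interval seconds between frames (default 5 s).
#' @param n_prebleach prebleach frame count (default 3).
#' @param noise_sigma additive Gaussian noise on normalized intensities.
#' @param seed integer seed.
#' @return An object of class `frap_truth`.
#' @export
frap_truth <- function(rate_k, mobile_fraction, postbleach_floor = 0.2,
                       fading_rate = 0, frame_interval = 5, n_prebleach = 3L,
                       noise_sigma = 0, seed = 1L) {
  if (rate_k <= 0) stop("`rate_k` must be > 0", call. = FALSE)
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    stop("`mobile_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (postbleach_floor < 0 || postbleach_floor >= 1) {
    stop("`postbleach_floor` must be in [0, 1)", call. = FALSE)
  }
  if (n_prebleach < 1L) stop("`n_prebleach` must be >= 1", call. = FALSE)
  structure(list(rate_k = rate_k, mobile_fraction = mobile_fraction,
                 postbleach_floor = postbleach_floor,
                 fading_rate = fading_rate,
                 frame_interval = frame_interval,
                 n_prebleach = as.integer(n_prebleach),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "frap_truth")
}

#' Generate a synthetic FRAP trace
#'
#' The bleach-ROI signal is 1.0 during the prebleach frames, then follows
#' the mono-exponential recovery
#' `F(t) = floor + mobile_fraction * (1 - floor) * (1 - exp(-k t))`
#' with t measured from the bleach event (placed at the last prebleach
#' frame).  Both the ROI and the whole-image traces are multiplied by the
#' acquisition-fading factor `exp(-fading_rate * t_abs)` in absolute
#' time, so the ratio-based fading correction of [normalize_trace()]
#' removes the fading exactly.  Noise is added after composition.
#'
#' @param truth a [frap_truth()] object.
#' @param n_post number of post-bleach frames (>= 3).
#' @return A [frap_trace()] object.
#' @export
make_frap_series <- function(truth, n_post) {
  stopifnot(inherits(truth, "frap_truth"))
  if (n_post < 3L) {
    stop("`n_post` must be >= 3 (fewer points leave the fit under-determined)",
         call. = FALSE)
  }
  dt <- truth$frame_interval
  n_pre <- truth$n_prebleach
  t_abs <- (seq_len(n_pre + n_post) - 1) * dt
  t_bleach <- (n_pre - 1) * dt
  t_post <- t_abs[(n_pre + 1):(n_pre + n_post)] - t_bleach
  plateau <- truth$postbleach_floor +
    truth$mobile_fraction * (1 - truth$postbleach_floor)
  model <- c(rep(1, n_pre),
             plateau - (plateau - truth$postbleach_floor) *
               exp(-truth$rate_k * t_post))
  fading <- exp(-truth$fading_rate * t_abs)
  roi <- model * fading
  whole <- fading
  if (truth$noise_sigma > 0) {
    eps <- with_seed(substream_seed(truth$seed, "frap"),
                     stats::rnorm(2 * length(roi), sd = truth$noise_sigma))
    roi <- roi + eps[seq_along(roi)]
    whole <- whole + eps[length(roi) + seq_along(whole)]
  }
  frap_trace(times = t_abs, roi_intensity = roi,
             whole_image_intensity = whole, n_prebleach = n_pre)
}

#' Ground truth for persistent-random-walk migration tracks
#'
#' @param mean_speed mean cell speed in micrometres per minute (>= 0).
#' @param persistence step-direction correlation in [0, 1] (0 = pure
#'   random walk, 1 = straight line).
#' @param frame_interval minutes between frames (default 10 min).
#' @param n_frames frames per track (default 97, i.e. 16 h at 10 min).
#' @param pixel_size micrometres per pixel of the exported coordinates.
#' @param speed_cv coefficient of variation of per-step lengths (gamma
#'   distributed); 0 gives constant step lengths.
#' @param seed integer seed.
#' @return An object of class `track_truth`.
#' @export
track_truth <- function(mean_speed, persistence = 0.7, frame_interval = 10,
                        n_frames = 97L, pixel_size = 1, speed_cv = 0.3,
                        seed = 1L) {
  if (mean_speed < 0) stop("`mean_speed` must be >= 0", call. = FALSE)
  if (persistence < 0 || persistence > 1) {
    stop("`persistence` must be in [0, 1]", call. = FALSE)
  }
  if (n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  structure(list(mean_speed = mean_speed, persistence = persistence,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), pixel_size = pixel_size,
                 speed_cv = speed_cv, seed = as.integer(seed)),
            class = "track_truth")
}

#' Generate persistent-random-walk cell tracks
#'
#' Each track takes `n_frames - 1` steps.  Step lengths are gamma
#' distributed with mean `mean_speed * frame_interval` and coefficient of
#' variation `speed_cv` (constant when `speed_cv = 0`).  Headings evolve
#' as a wrapped-normal increment process whose angular standard deviation
#' is chosen so that the expected step-direction correlation
#' `E[cos(delta)]` equals `persistence`; persistence 0 draws directions
#' uniformly and persistence 1 keeps them fixed.
#'
#' @param truth a [track_truth()] object.
#' @param n_cells number of tracks (>= 1).
#' @return list of [track()] objects, cell ids `"cell_1"`, ...
#' @export
make_tracks <- function(truth, n_cells) {
  stopifnot(inherits(truth, "track_truth"))
  if (n_cells < 1L) stop("`n_cells` must be >= 1", call. = FALSE)
  step_mean <- truth$mean_speed * truth$frame_interval   # um per step
  n_steps <- truth$n_frames - 1L
  ang_sd <- if (truth$persistence >= 1) 0 else
    if (truth$persistence <= 0) Inf else sqrt(-2 * log(truth$persistence))
  with_seed(substream_seed(truth$seed, "tracks"), {
    lapply(seq_len(n_cells), function(i) {
      len <- if (truth$speed_cv > 0 && step_mean > 0) {
        shape <- 1 / truth$speed_cv^2
        stats::rgamma(n_steps, shape = shape, rate = shape / step_mean)
      } else {
        rep(step_mean, n_steps)
      }
      theta0 <- stats::runif(1, 0, 2 * pi)
      dtheta <- if (is.infinite(ang_sd)) {
        stats::runif(n_steps, 0, 2 * pi)
      } else if (ang_sd == 0) {
        rep(0, n_steps)
      } else {
        stats::rnorm(n_steps, sd = ang_sd)
      }
      theta <- if (is.infinite(ang_sd)) dtheta else theta0 + cumsum(dtheta)
      dx <- len * cos(theta)
      dy <- len * sin(theta)
      pos_um <- cbind(x = cumsum(c(0, dx)), y = cumsum(c(0, dy)))
      track(cell_id = paste0("cell_", i),
            frames = seq_len(truth$n_frames) - 1L,
            positions = pos_um / truth$pixel_size,
            frame_interval = truth$frame_interval,
            pixel_size = truth$pixel_size)
    })
  })
}

#' Ground truth for a saturation-binding titration
#'
#' @param kd dissociation constant, mol/L (> 0).
#' @param target_conc concentration of the labeled species held constant
#'   across the titration, mol/L (default 50e-9, i.e. 50 nM).
#' @param response_unbound,response_bound signal plateaus of the free and
#'   fully bound labeled species.
#' @param noise_sigma Gaussian noise sigma in signal units.
#' @param seed integer seed.
#' @return An object of class `binding_truth`.
#' @export
binding_truth <- function(kd, target_conc = 50e-9, response_unbound = 800,
                          response_bound = 860, noise_sigma = 0, seed = 1L) {
  if (kd <= 0) stop("`kd` must be > 0", call. = FALSE)
  if (target_conc <= 0) stop("`target_conc` must be > 0", call. = FALSE)
  structure(list(kd = kd, target_conc = target_conc,
                 response_unbound = response_unbound,
                 response_bound = response_bound,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "binding_truth")
}

#' Generate a synthetic thermophoresis titration
#'
#' Responses follow the quadratic single-site mass-action model with
#' ligand depletion (see [fraction_bound()]) plus Gaussian noise.
#'
#' @param truth a [binding_truth()] object.
#' @param ligand_concs strictly positive ligand concentrations, mol/L,
#'   at least 6 points.
#' @return A [titration_series()] object.
#' @export
make_titration <- function(truth, ligand_concs) {
  stopifnot(inherits(truth, "binding_truth"))
  if (length(ligand_concs) < 6L) {
    stop("at least 6 titration points are required (fit unstable below that)",
         call. = FALSE)
  }
  if (any(ligand_concs <= 0)) {
    stop("ligand concentrations must be strictly positive", call. = FALSE)
  }
  f <- fraction_bound(ligand_concs, truth$kd, truth$target_conc)
  resp <- truth$response_unbound +
    (truth$response_bound - truth$response_unbound) * f
  if (truth$noise_sigma > 0) {
    resp <- resp + with_seed(substream_seed(truth$seed, "titration"),
                             stats::rnorm(length(resp),
                                          sd = truth$noise_sigma))
  }
  titration_series(ligand_conc = ligand_concs, response = resp,
                   target_conc = truth$target_conc)
}

#' Ground truth for a time-domain fluorescence decay
#'
#' @param lifetime_tau fluorescence lifetime in nanoseconds (> 0).
#' @param total_counts total photon count (> 0).
#' @param bin_width histogram bin width in nanoseconds.
#' @param n_bins number of bins; the window `n_bins * bin_width` must be
#'   at least 5 lifetimes to avoid truncation bias.
#' @param seed integer seed.
#' @return An object of class `decay_truth`.
#' @export
decay_truth <- function(lifetime_tau, total_counts = 1e5, bin_width = 0.05,
                        n_bins = 256L, seed = 1L) {
  if (lifetime_tau <= 0) stop("`lifetime_tau` must be > 0", call. = FALSE)
  if (total_counts <= 0) stop("`total_counts` must be > 0", call. = FALSE)
  if (n_bins * bin_width < 5 * lifetime_tau) {
    stop("measurement window must be at least 5 lifetimes (truncation bias)",
         call. = FALSE)
  }
  structure(list(lifetime_tau = lifetime_tau,
                 total_counts = as.integer(total_counts),
                 bin_width = bin_width, n_bins = as.integer(n_bins),
                 seed = as.integer(seed)),
            class = "decay_truth")
}

#' Generate a synthetic photon-decay histogram
#'
#' Photon counts are multinomial over the bins with probabilities
#' proportional to `exp(-t / tau)` at bin centers; the histogram sums to
#' `total_counts` exactly.
#'
#' @param truth a [decay_truth()] object.
#' @return A [decay_histogram()] object.
#' @export
make_decay <- function(truth) {
  stopifnot(inherits(truth, "decay_truth"))
  centers <- (seq_len(truth$n_bins) - 0.5) * truth$bin_width
  p <- exp(-centers / truth$lifetime_tau)
  p <- p / sum(p)
  counts <- with_seed(substream_seed(truth$seed, "decay"),
                      as.integer(stats::rmultinom(1, truth$total_counts, p)))
  decay_histogram(bin_centers = centers, counts = counts)
}
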