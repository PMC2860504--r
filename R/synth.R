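# Synthetic masked 4D series with planted hub/module structure.
#
# The generator emulates the data regime the method targets — masked,
# band-limited BOLD-like series at TR 2.3 s, a few hundred seconds long —
# at desk scale: a 12 x 12 x 8 grid with a 10 x 10 x 5 block mask (500
# voxels), T = 180 volumes. Each module has one latent band-limited Gaussian
# signal; module voxels carry their module's latent plus white noise, hub
# voxels carry the mean of all module latents plus noise, so hubs correlate
# moderately with every module while module voxels correlate strongly only
# within their own. Ground-truth labels accompany every dataset.

#' Synthetic-data configuration
#'
#' @param grid_shape 3D grid dimensions.
#' @param mask_shape Dimensions of the centered block mask (all in-mask
#'   voxels); defaults to 500 voxels on the default grid.
#' @param n_modules Number of spatially contiguous modules (>= 1).
#' @param hub_fraction Fraction of in-mask voxels re-assigned as hubs,
#'   loaded on all modules.
#' @param signal_amplitude Latent signal amplitude (SNR =
#'   `signal_amplitude / noise_sd` since latents are unit-variance).
#' @param noise_sd White-noise standard deviation.
#' @param signal_band_hz Two-sided frequency band `(low, high)` of the
#'   latents, below Nyquist.
#' @param module_bands_hz Optional list of per-module `(low, high)` bands
#'   overriding `signal_band_hz` (used to plant modules in disjoint spectral
#'   bands).
#' @param t_len Number of volumes `T`.
#' @param tr_seconds Repetition time in seconds.
#' @param voxel_size Voxel edge lengths in mm.
#' @param seed RNG seed used by [synth_generate()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(12L, 12L, 8L),
                         mask_shape = c(10L, 10L, 5L),
                         n_modules = 4L, hub_fraction = 0.05,
                         signal_amplitude = 1, noise_sd = 1,
                         signal_band_hz = c(0.01, 0.1),
                         module_bands_hz = NULL,
                         t_len = 180L, tr_seconds = 2.3,
                         voxel_size = c(3, 3, 3), seed = 1L) {
  stopifnot(length(grid_shape) == 3L, length(mask_shape) == 3L,
            all(mask_shape <= grid_shape), n_modules >= 1L,
            hub_fraction > 0, hub_fraction < 1,
            signal_amplitude > 0, noise_sd > 0, t_len >= 8L, tr_seconds > 0)
  nyquist <- 1 / (2 * tr_seconds)
  bands <- if (is.null(module_bands_hz)) list(signal_band_hz) else module_bands_hz
  for (b in bands) {
    if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1]) stop("malformed frequency band")
    if (b[2] > nyquist + 1e-12) {
      stop(sprintf("band upper edge %.4g Hz above Nyquist %.4g Hz", b[2], nyquist))
    }
  }
  if (!is.null(module_bands_hz) && length(module_bands_hz) != n_modules) {
    stop("module_bands_hz must have one band per module")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 mask_shape = as.integer(mask_shape),
                 n_modules = as.integer(n_modules),
                 hub_fraction = hub_fraction,
                 signal_amplitude = signal_amplitude, noise_sd = noise_sd,
                 signal_band_hz = signal_band_hz,
                 module_bands_hz = module_bands_hz,
                 t_len = as.integer(t_len), tr_seconds = tr_seconds,
                 voxel_size = as.double(voxel_size), seed = as.integer(seed)),
            class = "synth_config")
}

# centered block mask on the grid
synth_geometry <- function(cfg) {
  inside <- array(FALSE, cfg$grid_shape)
  lo <- pmax(1L, (cfg$grid_shape - cfg$mask_shape) %/% 2L + 1L)
  hi <- lo + cfg$mask_shape - 1L
  inside[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  mask_geometry(inside, voxel_size = cfg$voxel_size)
}

# contiguous module slabs: in-mask voxels ordered by (x, y, z) grid
# coordinate and cut into n_modules equal-count runs
module_partition <- function(geometry, n_modules) {
  coords <- mask_coordinates(geometry)
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  labels <- integer(geometry$n)
  labels[ord] <- as.integer(cut(seq_len(geometry$n), breaks = n_modules,
                                labels = FALSE))
  labels
}

# unit-variance band-limited latent: white noise filtered by a boxcar
# frequency mask (both frequency tails), inverse-transformed
band_limited_latent <- function(t_len, tr_seconds, band_hz) {
  freqs <- (0:(t_len - 1)) / (t_len * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)      # fold to physical frequency
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  if (!any(keep)) stop("frequency band contains no DFT bin at this T and TR")
  spec <- stats::fft(stats::rnorm(t_len))
  spec[!keep] <- 0
  s <- Re(stats::fft(spec, inverse = TRUE)) / t_len
  s / stats::sd(s)
}

synth_generate_impl <- function(cfg, amplitude_scale = NULL) {
  geom <- synth_geometry(cfg)
  n <- geom$n
  labels <- module_partition(geom, cfg$n_modules)
  n_hubs <- max(1L, round(cfg$hub_fraction * n))
  hub_idx <- sample.int(n, n_hubs)
  labels[hub_idx] <- 0L                              # 0 marks hubs

  bands <- if (is.null(cfg$module_bands_hz)) {
    rep(list(cfg$signal_band_hz), cfg$n_modules)
  } else cfg$module_bands_hz
  latents <- do.call(rbind, lapply(seq_len(cfg$n_modules), function(m) {
    band_limited_latent(cfg$t_len, cfg$tr_seconds, bands[[m]])
  }))

  amp <- rep(cfg$signal_amplitude, n)
  if (!is.null(amplitude_scale)) amp <- amp * amplitude_scale
  signal <- matrix(0, n, cfg$t_len)
  hub_signal <- colMeans(latents)
  for (v in seq_len(n)) {
    signal[v, ] <- amp[v] * (if (labels[v] == 0L) hub_signal else latents[labels[v], ])
  }
  noise <- matrix(stats::rnorm(n * cfg$t_len, sd = cfg$noise_sd), n, cfg$t_len)
  series <- masked_series(signal + noise, geom, cfg$tr_seconds)
  list(series = series, labels = labels)
}

#' Generate a synthetic masked series with planted structure
#'
#' @param cfg A [synth_config()].
#' @return List with `series` (a [masked_series()]) and `labels` (integer
#'   per-voxel ground truth: module id `1..n_modules`, or `0` for hub
#'   voxels).
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  synth_generate_impl(cfg)
}

#' Generate a paired two-condition cohort
#'
#' Per subject, one scan in condition A and one in condition B. In condition
#' B the coupling (signal amplitude) of `effect_region` voxels to their
#' module latents is multiplied by `1 + effect_size`; `effect_size = 0`
#' makes the two conditions identically distributed. Subjects are i.i.d.
#' given the seed.
#'
#' @param cfg A [synth_config()] (its own `seed` field is ignored here).
#' @param n_subjects Number of matched subjects.
#' @param effect_region Integer in-mask voxel indices receiving the effect.
#' @param effect_size Relative coupling increase in condition B (>= 0).
#' @param seed RNG seed for the whole cohort.
#' @return List with `condition_a`, `condition_b` (lists of
#'   [masked_series()]), `labels` (from the first subject; the partition and
#'   hub draw are re-sampled per scan), and `effect_region`.
#' @export
two_condition_cohort <- function(cfg, n_subjects, effect_region,
                                 effect_size = 0, seed = 1L) {
  stopifnot(inherits(cfg, "synth_config"), n_subjects >= 2L)
  if (length(effect_region) == 0L) stop("effect region is empty")
  geom <- synth_geometry(cfg)
  if (any(effect_region < 1L) || any(effect_region > geom$n)) {
    stop("effect region outside the mask (n = ", geom$n, ")")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  scale_b <- rep(1, geom$n)
  scale_b[effect_region] <- 1 + effect_size
  set.seed(seed)
  condition_a <- vector("list", n_subjects)
  condition_b <- vector("list", n_subjects)
  labels <- NULL
  for (i in seq_len(n_subjects)) {
    ga <- synth_generate_impl(cfg)
    gb <- synth_generate_impl(cfg, amplitude_scale = scale_b)
    condition_a[[i]] <- ga$series
    condition_b[[i]] <- gb$series
    if (i == 1L) labels <- ga$labels
  }
  list(condition_a = condition_a, condition_b = condition_b,
       labels = labels, effect_region = effect_region)
}
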