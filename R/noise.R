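#' Noise-addition simulation for MS/MS spectra
#'
#' Reference-library spectra are cleaner than spectra from a biological
#' LC-MS/MS run. This simulator degrades a spectrum towards run quality:
#' retained peak intensities are jittered multiplicatively (log-normal), a
#' fraction of peaks is removed (never the base peak), and noise peaks are
#' added. Noise-peak masses are drawn from a pool of masses observed in
#' other measured spectra — uniform random masses would be trivially
#' recognizable as artificial — and noise intensities are sampled below a
#' low quantile of the spectrum's own intensities.
#'
#' @param s a [spectrum()].
#' @param peak_pool numeric vector of candidate noise-peak m/z values
#'   (masses pooled from other measured spectra); must be non-empty when
#'   `n_noise_peaks > 0`.
#' @param drop_fraction fraction of peaks removed, in \[0, 1).
#' @param intensity_jitter_sd standard deviation of the log-normal
#'   multiplicative intensity jitter (0 disables).
#' @param n_noise_peaks number of noise peaks to add; `NULL` means 20% of
#'   the original peak count (rounded).
#' @param noise_intensity_quantile noise intensities are drawn uniformly
#'   between 0 and this quantile of the retained intensities.
#' @param seed integer seed; all randomness flows through it.
#' @return a degraded `spectrum`, peaks re-sorted by m/z.
#' @export
simulate_noise <- function(s, peak_pool = numeric(), drop_fraction = 0.2,
                           intensity_jitter_sd = 0.3, n_noise_peaks = NULL,
                           noise_intensity_quantile = 0.25, seed) {
  stopifnot(inherits(s, "fpkit_spectrum"))
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  if (missing(seed)) stop("seed is required for reproducibility")
  np <- length(s$mz)
  if (is.null(n_noise_peaks)) n_noise_peaks <- round(0.2 * np)
  if (n_noise_peaks > 0 && !length(peak_pool))
    stop("peak_pool must be non-empty when n_noise_peaks > 0")
  withr::with_seed(seed, {
    mz <- s$mz; intensity <- s$intensity
    base <- which.max(intensity)
    n_drop <- floor(drop_fraction * np)
    if (n_drop > 0) {
      droppable <- setdiff(seq_len(np), base)
      drop <- sample(droppable, min(n_drop, length(droppable)))
      mz <- mz[-drop]; intensity <- intensity[-drop]
    }
    if (intensity_jitter_sd > 0)
      intensity <- intensity *
        exp(stats::rnorm(length(intensity), 0, intensity_jitter_sd))
    if (n_noise_peaks > 0) {
      qi <- stats::quantile(intensity, noise_intensity_quantile, names = FALSE)
      nmz <- sample(peak_pool, n_noise_peaks, replace = TRUE)
      nint <- stats::runif(n_noise_peaks, 0, max(qi, .Machine$double.eps))
      mz <- c(mz, nmz); intensity <- c(intensity, nint)
    }
    spectrum(mz, intensity, precursor_mz = s$precursor_mz,
             structure_key = s$structure_key, compound_id = s$compound_id,
             adduct = s$adduct, collision_energy = s$collision_energy,
             instrument = s$instrument, tolerance = Inf)
  })
}
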