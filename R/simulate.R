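# Synthetic profile-mode spectra with known ground truth. The generator
# realizes exactly the measurement model the annotation method assumes:
# raw signal points normally distributed in m/z around each true fragment
# ion, with an optional calibration bias, plus uniform noise points.

#' Specification of a synthetic MS2 spectrum
#'
#' @param fragments Character vector of true fragment ion formulas (with
#'   charge sign), e.g. `c("C6NH6+", "C10SO3N3H12+")`.
#' @param abundance Peak abundances (arbitrary counts), recycled; default
#'   100 for every fragment.
#' @param sigma_ppm Standard deviation of the m/z scatter around each true
#'   ion m/z, in ppm.
#' @param points_per_peak Profile points drawn per fragment.
#' @param calibration_bias_ppm Systematic shift of all true m/z values, in
#'   ppm (models an uncalibrated instrument).
#' @param noise_points Number of noise points, uniform in m/z over
#'   `mz_range`.
#' @param noise_intensity Intensity range (min, max) for noise points.
#' @param mz_range m/z range for noise points; default spans 50 Da to 10%
#'   above the heaviest fragment.
#' @param intensity_profile `"gaussian"`: point intensity falls off with the
#'   standardized distance from the peak center, the approximate shape of an
#'   Orbitrap profile peak; `"flat"`: all points at the fragment abundance
#'   (worst case for centroid weighting).
#' @param seed Integer seed; a fixed seed makes [simulate_spectrum()]
#'   reproducible without touching the caller's RNG state.
#' @return A `simulation_spec` list.
#' @examples
#' simulation_spec(c("C6NH6+", "C6NH7+"), sigma_ppm = 3, seed = 1)
#' @export
simulation_spec <- function(fragments, abundance = 100, sigma_ppm = 3,
                            points_per_peak = 8, calibration_bias_ppm = 0,
                            noise_points = 0, noise_intensity = c(0, 1),
                            mz_range = NULL,
                            intensity_profile = c("gaussian", "flat"),
                            seed = NULL) {
  stopifnot(is.character(fragments), length(fragments) >= 1L,
            sigma_ppm >= 0, points_per_peak >= 1,
            noise_points >= 0, length(noise_intensity) == 2L)
  true_mz <- ion_mz(fragments)
  structure(
    list(
      fragments = format_formula(fragments),
      true_mz = true_mz,
      abundance = rep_len(abundance, length(fragments)),
      sigma_ppm = sigma_ppm,
      points_per_peak = as.integer(points_per_peak),
      calibration_bias_ppm = calibration_bias_ppm,
      noise_points = as.integer(noise_points),
      noise_intensity = noise_intensity,
      mz_range = mz_range %||% c(50, 1.1 * max(true_mz)),
      intensity_profile = match.arg(intensity_profile),
      seed = seed
    ),
    class = c("simulation_spec", "list")
  )
}

.simulate_spectrum_impl <- function(spec) {
  frags <- purrr::map_dfr(seq_along(spec$fragments), function(i) {
    center <- spec$true_mz[i] * (1 + spec$calibration_bias_ppm * 1e-6)
    sd_da <- spec$true_mz[i] * spec$sigma_ppm * 1e-6
    mz <- rnorm(spec$points_per_peak, center, sd_da)
    intensity <- if (spec$intensity_profile == "gaussian" && sd_da > 0) {
      spec$abundance[i] * exp(-0.5 * ((mz - center) / sd_da)^2)
    } else {
      rep(spec$abundance[i], spec$points_per_peak)
    }
    tibble::tibble(
      mz = mz, intensity = intensity,
      true_formula = spec$fragments[i], true_mz = spec$true_mz[i],
      is_noise = FALSE
    )
  })
  noise <- tibble::tibble(
    mz = runif(spec$noise_points, spec$mz_range[1], spec$mz_range[2]),
    intensity = runif(spec$noise_points, spec$noise_intensity[1],
                      spec$noise_intensity[2]),
    true_formula = NA_character_, true_mz = NA_real_, is_noise = TRUE
  )
  dplyr::bind_rows(frags, noise) |> dplyr::arrange(.data$mz)
}

#' Simulate a profile-mode MS2 spectrum with ground truth
#'
#' For each true fragment, `points_per_peak` m/z values are drawn from
#' `Normal(ion_mz * (1 + bias), ion_mz * sigma_ppm * 1e-6)` with intensities
#' shaped by the chosen profile; noise points are uniform in m/z and tagged,
#' so every downstream step (noise filtering, clustering, CI coverage,
#' end-to-end formula recovery) can be asserted against the truth columns.
#'
#' @param spec A [simulation_spec()].
#' @return Tibble of profile points sorted by m/z: `mz`, `intensity`,
#'   `true_formula` (NA for noise), `true_mz`, `is_noise`.
#' @examples
#' simulate_spectrum(simulation_spec("C6NH6+", sigma_ppm = 0, seed = 7))
#' @export
simulate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) {
    withr::with_seed(spec$seed, .simulate_spectrum_impl(spec))
  } else {
    .simulate_spectrum_impl(spec)
  }
}

#' Write a synthetic spectrum as a minimal mzML file
#'
#' Emits a two-scan run -- one MS1 scan holding a single precursor point and
#' one profile-mode MS2 scan holding the simulated points, with the
#' precursor m/z recorded in the MS2 metadata -- via mzR. [read_mzml()]
#' round-trips the point arrays exactly.
#'
#' @param points Profile points (`mz`, `intensity`), e.g. from
#'   [simulate_spectrum()]; truth columns, when present, can be written to a
#'   sidecar table.
#' @param path Output mzML path (overwritten if present).
#' @param precursor_mz Precursor m/z stored in the MS2 scan metadata.
#' @param precursor_intensity Intensity of the single MS1 precursor point.
#' @param truth_path Optional path for a sidecar csv with the ground-truth
#'   columns (`mz`, `intensity`, `true_formula`, `true_mz`, `is_noise`).
#' @return `path`, invisibly.
#' @export
write_synthetic_mzml <- function(points, path, precursor_mz,
                                 precursor_intensity = 1e4,
                                 truth_path = NULL) {
  .check_points(points)
  stopifnot(precursor_mz > 0)
  points <- dplyr::arrange(tibble::as_tibble(points), .data$mz)
  if (file.exists(path)) file.remove(path)
  n <- nrow(points)
  hdr <- data.frame(
    seqNum = 1:2, acquisitionNum = 1:2, msLevel = c(1L, 2L),
    polarity = c(1L, 1L), peaksCount = c(1L, n),
    totIonCurrent = c(precursor_intensity, sum(points$intensity)),
    retentionTime = c(1, 2),
    basePeakMZ = c(precursor_mz, points$mz[which.max(points$intensity)]),
    basePeakIntensity = c(precursor_intensity, max(points$intensity)),
    collisionEnergy = c(NA_real_, 35),
    ionisationEnergy = c(0, 0),
    lowMZ = c(precursor_mz, min(points$mz)),
    highMZ = c(precursor_mz, max(points$mz)),
    precursorScanNum = c(0L, 1L),
    precursorMZ = c(0, precursor_mz),
    precursorCharge = c(0L, 1L),
    precursorIntensity = c(0, precursor_intensity),
    mergedScan = c(0L, 0L), mergedResultScanNum = c(0L, 0L),
    mergedResultStartScanNum = c(0L, 0L), mergedResultEndScanNum = c(0L, 0L),
    injectionTime = c(0, 0),
    filterString = c(NA_character_, NA_character_),
    spectrumId = c("scan=1", "scan=2"),
    centroided = c(FALSE, FALSE),
    ionMobilityDriftTime = c(NA_real_, NA_real_),
    isolationWindowTargetMZ = c(NA_real_, precursor_mz),
    isolationWindowLowerOffset = c(NA_real_, 0.5),
    isolationWindowUpperOffset = c(NA_real_, 0.5),
    scanWindowLowerLimit = c(NA_real_, NA_real_),
    scanWindowUpperLimit = c(NA_real_, NA_real_)
  )
  pk <- list(
    cbind(mz = precursor_mz, intensity = precursor_intensity),
    cbind(mz = points$mz, intensity = points$intensity)
  )
  mzR::writeMSData(pk, file = path, header = hdr)
  if (!is.null(truth_path)) {
    truth_cols <- intersect(
      c("mz", "intensity", "true_formula", "true_mz", "is_noise"),
      names(points)
    )
    readr::write_csv(points[truth_cols], truth_path, progress = FALSE)
  }
  invisible(path)
}
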