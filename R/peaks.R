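# Profile-mode peak statistics: raw (m/z, intensity) points are filtered,
# clustered into peaks, and each peak keeps the information centroiding
# normally discards -- a per-peak confidence interval on its m/z.

.check_points <- function(points) {
  if (!is.data.frame(points) || !all(c("mz", "intensity") %in% names(points))) {
    abort("`points` must be a data frame with columns `mz` and `intensity`.")
  }
  if (any(points$mz <= 0)) abort("All m/z values must be positive.")
  if (any(points$intensity < 0)) abort("Intensities must be non-negative.")
  invisible(points)
}

#' Remove signal points below the noise threshold
#'
#' @param points Data frame of profile points with columns `mz` and
#'   `intensity` (extra columns are preserved).
#' @param noise_threshold Intensity threshold in counts (>= 0). Points with
#'   intensity greater than or equal to the threshold are kept, in their
#'   original order. The threshold mainly controls how many points enter the
#'   clustering step, and with it the run time.
#' @return The filtered tibble.
#' @examples
#' pts <- tibble::tibble(mz = c(100, 101), intensity = c(5, 50))
#' filter_noise(pts, 10)
#' @export
filter_noise <- function(points, noise_threshold) {
  .check_points(points)
  if (!is.numeric(noise_threshold) || noise_threshold < 0) {
    abort("`noise_threshold` must be a non-negative number.")
  }
  tibble::as_tibble(points) |> dplyr::filter(.data$intensity >= noise_threshold)
}

#' Cluster sorted profile points into peaks by relative m/z gap
#'
#' Consecutive points belong to the same peak while their m/z gap does not
#' exceed `gap_ppm` parts per million of the local m/z; a larger gap starts a
#' new cluster. Clusters are disjoint maximal runs covering the input.
#'
#' @inheritParams filter_noise
#' @param gap_ppm Maximum within-peak gap between consecutive points, in ppm.
#' @return The input tibble with an integer `cluster` column.
#' @examples
#' pts <- tibble::tibble(mz = c(100.0000, 100.0005, 100.2), intensity = 1)
#' cluster_points(pts, gap_ppm = 20)
#' @export
cluster_points <- function(points, gap_ppm) {
  .check_points(points)
  if (is.unsorted(points$mz)) {
    abort("`points` must be sorted by ascending m/z before clustering.")
  }
  mz <- points$mz
  if (length(mz) == 0L) {
    return(dplyr::mutate(tibble::as_tibble(points), cluster = integer(0)))
  }
  gaps <- diff(mz)
  new_cluster <- gaps > gap_ppm * head(mz, -1L) / 1e6
  tibble::as_tibble(points) |>
    dplyr::mutate(cluster = cumsum(c(1L, as.integer(new_cluster))))
}

#' Summarize one cluster of profile points into a peak
#'
#' The centroid is the intensity-weighted mean m/z (the full profile
#' information, not just the apex); the confidence interval is the two-sided
#' t-interval for the mean of the observed m/z values, expressed as a
#' half-width in ppm of the centroid. Normality of the m/z distribution --
#' the model assumption behind the interval -- is checked with a
#' Shapiro-Wilk test whenever the cluster has at least 3 distinct points.
#'
#' @param cluster Data frame of profile points (columns `mz`, `intensity`)
#'   forming one peak.
#' @param confidence_level Two-sided confidence level in (0, 1); default 0.95.
#' @param spectrum_total_intensity Total intensity of the spectrum the cluster
#'   came from, used for the relative intensity; defaults to the cluster's own
#'   total.
#' @param weighted Use the intensity-weighted centroid (default). `FALSE`
#'   gives the unweighted mean, for sensitivity checks.
#' @return One-row tibble: `measured_mz`, `ci_ppm` (NA for a single point,
#'   never coerced to zero), `n_points`, `total_intensity`,
#'   `relative_intensity_pct`, `shapiro_p` (NA when not computable).
#' @examples
#' cl <- tibble::tibble(mz = c(100.0000, 100.0001, 100.0002),
#'                      intensity = c(10, 20, 10))
#' estimate_peak(cl)
#' @export
estimate_peak <- function(cluster, confidence_level = 0.95,
                          spectrum_total_intensity = NULL, weighted = TRUE) {
  .check_points(cluster)
  n <- nrow(cluster)
  if (n == 0L) abort("`cluster` must contain at least one point.")
  if (confidence_level <= 0 || confidence_level >= 1) {
    abort("`confidence_level` must be strictly between 0 and 1.")
  }
  total <- sum(cluster$intensity)
  spectrum_total <- spectrum_total_intensity %||% total
  centroid <- if (weighted && total > 0) {
    weighted.mean(cluster$mz, cluster$intensity)
  } else {
    mean(cluster$mz)
  }
  ci_ppm <- NA_real_
  if (n >= 2L) {
    half_width <- qt(1 - (1 - confidence_level) / 2, df = n - 1L) *
      sd(cluster$mz) / sqrt(n)
    ci_ppm <- half_width / centroid * 1e6
  }
  shapiro_p <- NA_real_
  if (n >= 3L && length(unique(cluster$mz)) > 1L) {
    mzs <- cluster$mz
    if (n > 5000L) mzs <- mzs[round(seq(1L, n, length.out = 5000L))]
    shapiro_p <- shapiro.test(mzs)$p.value
  }
  tibble::tibble(
    measured_mz = centroid,
    ci_ppm = ci_ppm,
    n_points = n,
    total_intensity = total,
    relative_intensity_pct =
      if (spectrum_total > 0) 100 * total / spectrum_total else NA_real_,
    shapiro_p = shapiro_p
  )
}

#' Detect peaks in a profile-mode spectrum
#'
#' Full peak-model pipeline: noise filtering, gap clustering, and per-cluster
#' centroid/confidence-interval estimation. Relative intensities are percent
#' of the *raw* spectrum total (all input points, before any filtering), so
#' the reported percentages sum to 100 only when nothing was discarded.
#'
#' Clusters smaller than `min_points` carry too little information for the
#' t-interval and the normality test; they are kept only when their relative
#' intensity reaches `intensity_floor_pct` (an intensity-dominant small
#' cluster), with `ci_ppm` left NA -- the annotation step substitutes the
#' run's default tolerance for such peaks.
#'
#' @inheritParams filter_noise
#' @inheritParams cluster_points
#' @inheritParams estimate_peak
#' @param min_points Minimum cluster size for an unconditionally reported
#'   peak (default 3, the smallest size the Shapiro-Wilk test accepts).
#' @param intensity_floor_pct Relative-intensity floor (percent of spectrum
#'   total) above which an undersized cluster is still reported.
#' @return Tibble of peaks sorted by m/z with a `peak` id column, the
#'   [estimate_peak()] columns, and `normality_flag` (TRUE when the
#'   Shapiro-Wilk test rejects at p < 0.05; the peak is kept but flagged).
#' @examples
#' pts <- simulate_spectrum(simulation_spec("C6NH6+", seed = 1))
#' pick_peaks(pts, noise_threshold = 0)
#' @export
pick_peaks <- function(points, noise_threshold = 0, gap_ppm = 10,
                       confidence_level = 0.95, min_points = 3,
                       intensity_floor_pct = 1, weighted = TRUE) {
  .check_points(points)
  spectrum_total <- sum(points$intensity)
  kept <- filter_noise(points, noise_threshold) |> dplyr::arrange(.data$mz)
  clustered <- cluster_points(kept, gap_ppm)
  if (nrow(clustered) == 0L) {
    return(tibble::tibble(
      peak = integer(0), measured_mz = numeric(0), ci_ppm = numeric(0),
      n_points = integer(0), total_intensity = numeric(0),
      relative_intensity_pct = numeric(0), shapiro_p = numeric(0),
      normality_flag = logical(0)
    ))
  }
  peaks <- clustered |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(~ estimate_peak(
      .x, confidence_level = confidence_level,
      spectrum_total_intensity = spectrum_total, weighted = weighted
    )) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_points >= min_points |
                    .data$relative_intensity_pct >= intensity_floor_pct) |>
    dplyr::arrange(.data$measured_mz) |>
    dplyr::mutate(
      peak = dplyr::row_number(),
      normality_flag = !is.na(.data$shapiro_p) & .data$shapiro_p < 0.05
    ) |>
    dplyr::select("peak", "measured_mz", "ci_ppm", "n_points",
                  "total_intensity", "relative_intensity_pct", "shapiro_p",
                  "normality_flag")
  peaks
}
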