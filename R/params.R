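#' Run parameters for spectrum annotation
#'
#' Collects every tunable of the pipeline with its default. Values read from
#' a parameters file ([read_params()]) or given as arguments override the
#' defaults; command-line flags (see `inst/cli/fragnets.R`) override files.
#'
#' @param noise_threshold Intensity threshold in counts below which profile
#'   points are discarded (`NoiseTresInt` in the parameters file). Mostly a
#'   speed control; clustering plus the per-peak statistics are robust to
#'   moderate noise.
#' @param ionization `"+"` or `"-"`: sign of the charge carrier.
#' @param default_tol_ppm Matching tolerance (ppm) for peaks without their
#'   own confidence interval, and for centroided peak lists.
#' @param gap_ppm Clustering gap between consecutive profile points, in ppm.
#' @param confidence_level Two-sided level of the per-peak t-interval.
#' @param intensity_floor_pct Centroided mode keeps only peaks contributing
#'   more than this percentage of the total intensity; profile mode uses it
#'   to rescue intensity-dominant clusters smaller than
#'   `min_cluster_points`.
#' @param network_mode `"exact"` (enumerate all assignments) or `"greedy"`
#'   (hill climbing), see [select_best()].
#' @param network_cap Assignment cap for exact mode.
#' @param min_cluster_points Minimum points for an unconditionally reported
#'   peak.
#' @param ci_floor_ppm Lower bound on per-peak tolerances.
#' @param precursor_tol_da Scan-selection tolerance around the target
#'   precursor m/z, in Da (a typical quadrupole isolation half-width).
#' @param reject_isolated Reject a product-ion annotation that is consistent
#'   with no *other* product-ion annotation (edges to the precursor do not
#'   count, since every candidate is a sub-formula of the precursor by
#'   construction). Applied only when the network holds at least two
#'   annotated product ions; a sole product annotation keeps its formula.
#'   Set `FALSE` to keep isolated annotations.
#' @param weighted_centroid Intensity-weighted centroid (default) or plain
#'   mean.
#' @return A named list of class `fragnets_params`.
#' @examples
#' run_params(noise_threshold = 500, ionization = "+")
#' @export
run_params <- function(noise_threshold = 0,
                       ionization = "+",
                       default_tol_ppm = 10,
                       gap_ppm = 10,
                       confidence_level = 0.95,
                       intensity_floor_pct = 1,
                       network_mode = "exact",
                       network_cap = 1e6,
                       min_cluster_points = 3,
                       ci_floor_ppm = 0.5,
                       precursor_tol_da = 0.5,
                       reject_isolated = TRUE,
                       weighted_centroid = TRUE) {
  p <- list(
    noise_threshold = noise_threshold,
    ionization = .match_ionization(ionization),
    default_tol_ppm = default_tol_ppm,
    gap_ppm = gap_ppm,
    confidence_level = confidence_level,
    intensity_floor_pct = intensity_floor_pct,
    network_mode = match.arg(network_mode, c("exact", "greedy")),
    network_cap = network_cap,
    min_cluster_points = min_cluster_points,
    ci_floor_ppm = ci_floor_ppm,
    precursor_tol_da = precursor_tol_da,
    reject_isolated = isTRUE(reject_isolated),
    weighted_centroid = isTRUE(weighted_centroid)
  )
  numeric_fields <- c("noise_threshold", "default_tol_ppm", "gap_ppm",
                      "confidence_level", "intensity_floor_pct",
                      "network_cap", "min_cluster_points", "ci_floor_ppm",
                      "precursor_tol_da")
  for (f in numeric_fields) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0) {
      abort(sprintf("Parameter `%s` must be a single non-negative number.", f))
    }
  }
  if (p$confidence_level <= 0 || p$confidence_level >= 1) {
    abort("`confidence_level` must be strictly between 0 and 1.")
  }
  structure(p, class = c("fragnets_params", "list"))
}

#' @export
print.fragnets_params <- function(x, ...) {
  cat("<fragnets_params>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
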