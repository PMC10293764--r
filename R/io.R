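# Reading mzML runs, centroided peak lists and the two configuration
# tables; writing the results table. mzML parsing is delegated to mzR.

#' Read an mzML run
#'
#' @param path Path to an mzML file (profile or centroid spectra), e.g. a
#'   ProteoWizard msConvert export kept as raw as possible (profile mode, no
#'   filters).
#' @return Tibble with one row per scan: `scan`, `ms_level`,
#'   `precursor_mz` (NA for MS1), `total_intensity`, `centroided`, and a
#'   `points` list-column of (`mz`, `intensity`) tibbles.
#' @details A run without MS2 scans is returned with a notice; a run with
#'   only centroided spectra triggers a warning because per-peak confidence
#'   intervals cannot be estimated from centroids.
#' @examples
#' \donttest{
#' spec <- simulation_spec("C6NH6+", seed = 1)
#' f <- tempfile(fileext = ".mzML")
#' write_synthetic_mzml(simulate_spectrum(spec), f, precursor_mz = 92.0495)
#' read_mzml(f)
#' }
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  pts <- mzR::peaks(handle)
  if (is.matrix(pts)) pts <- list(pts)
  scans <- tibble::tibble(
    scan = hdr$seqNum,
    ms_level = hdr$msLevel,
    precursor_mz = ifelse(hdr$msLevel > 1L, hdr$precursorMZ, NA_real_),
    total_intensity = hdr$totIonCurrent,
    centroided = hdr$centroided,
    points = purrr::map(pts, function(m) {
      tibble::tibble(mz = m[, 1], intensity = m[, 2])
    })
  )
  if (!any(scans$ms_level == 2L)) {
    inform(sprintf("No MS2 scans in %s.", path))
  }
  if (nrow(scans) > 0L && isTRUE(all(scans$centroided))) {
    warn("All spectra are centroided; per-peak confidence-interval estimation is degraded.")
  }
  scans
}

#' Select the MS2 scan for a target precursor
#'
#' DDA spectra record the isolated precursor m/z per MS2 scan; the scan
#' whose precursor is nearest the target within `precursor_tol` is returned,
#' ties resolved by highest total intensity (deterministic).
#'
#' @param scans Scan tibble from [read_mzml()].
#' @param target_mz Target precursor m/z in Da.
#' @param precursor_tol Match tolerance in Da (default 0.5, a typical
#'   quadrupole isolation half-width).
#' @return The selected one-row scan tibble.
#' @export
select_ms2 <- function(scans, target_mz, precursor_tol = 0.5) {
  stopifnot(is.data.frame(scans), target_mz > 0)
  ms2 <- dplyr::filter(scans, .data$ms_level == 2L)
  if (nrow(ms2) == 0L) abort("No MS2 scans available.")
  d <- abs(ms2$precursor_mz - target_mz)
  hit <- which(d <= precursor_tol)
  if (length(hit) == 0L) {
    abort(sprintf(
      "No MS2 scan within %.3g Da of precursor m/z %.4f (nearest recorded precursor: %.4f).",
      precursor_tol, target_mz, ms2$precursor_mz[which.min(d)]
    ), class = "fragnets_no_scan")
  }
  ms2 <- ms2[hit, ]
  ms2 <- ms2[order(abs(ms2$precursor_mz - target_mz),
                   -ms2$total_intensity), ]
  ms2[1, ]
}

#' Read a centroided peak list
#'
#' Two-column delimited text (comma, semicolon, tab or whitespace), header
#' row optional; rows are sorted by ascending m/z.
#'
#' @param path Path to the peak list.
#' @return Tibble with columns `mz` and `intensity`.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("Peak list is empty: %s", path))
  first_vals <- strsplit(trimws(lines[1]), "[,;\t ]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first_vals))))
  body <- if (has_header) lines[-1] else lines
  if (length(body) == 0L) abort(sprintf("Peak list has no data rows: %s", path))
  rows <- lapply(seq_along(body), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]),
                                                 "[,;\t ]+")[[1]]))
    if (length(vals) < 1L || any(is.na(vals))) {
      abort(sprintf("Non-numeric value on line %d of %s.",
                    i + has_header, path))
    }
    c(vals[1], if (length(vals) >= 2L) vals[2] else 1)
  })
  m <- do.call(rbind, rows)
  tibble::tibble(mz = m[, 1], intensity = m[, 2]) |>
    dplyr::arrange(.data$mz)
}

#' Read maximum atomic subscripts from a csv table
#'
#' One row per element: `element,max_count` (header optional), e.g. `C,10`.
#' Heavy isotopes are written `[13C]`/`[34S]` (or `13C`/`34S`). Elements
#' outside the supported alphabet are rejected by name; negative bounds are
#' an error.
#'
#' @param path Path to the csv file.
#' @return Named integer vector of bounds suitable for
#'   [enumerate_formulas()].
#' @export
read_bounds <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, header = FALSE, strip.white = TRUE,
                         colClasses = "character")
  if (ncol(raw) < 2L) abort("Bounds file needs two columns: element,max_count.")
  if (suppressWarnings(is.na(as.numeric(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  vals <- suppressWarnings(as.numeric(raw[, 2]))
  if (any(is.na(vals))) {
    abort(sprintf("Non-numeric bound for element \"%s\".",
                  raw[which(is.na(vals))[1], 1]))
  }
  if (any(vals < 0)) {
    abort(sprintf("Negative bound for element \"%s\".",
                  raw[which(vals < 0)[1], 1]))
  }
  bounds <- setNames(vals, raw[, 1])
  .as_bounds(bounds) # validates element names
  bounds_int <- setNames(as.integer(vals), raw[, 1])
  bounds_int
}

#' Read run parameters from a csv table
#'
#' One row per parameter: `parameter,value` (header optional). Parameter
#' names are the [run_params()] argument names; `NoiseTresInt` is accepted
#' as an alias for `noise_threshold`. Missing parameters take the documented
#' defaults; unknown parameters produce a warning and are ignored.
#'
#' @param path Path to the csv file.
#' @return A [run_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, header = FALSE, strip.white = TRUE,
                         colClasses = "character")
  if (ncol(raw) < 2L) abort("Parameters file needs two columns: parameter,value.")
  if (tolower(raw[1, 1]) %in% c("parameter", "param", "name")) {
    raw <- raw[-1, , drop = FALSE]
  }
  aliases <- c(NoiseTresInt = "noise_threshold")
  known <- names(formals(run_params))
  args <- list()
  for (i in seq_len(nrow(raw))) {
    nm <- raw[i, 1]
    nm <- if (nm %in% names(aliases)) aliases[[nm]] else nm
    if (!nm %in% known) {
      warn(sprintf("Unknown parameter \"%s\" ignored.", raw[i, 1]))
      next
    }
    val <- raw[i, 2]
    if (nm %in% c("ionization", "network_mode")) {
      args[[nm]] <- val
    } else if (nm %in% c("reject_isolated", "weighted_centroid")) {
      args[[nm]] <- toupper(val) %in% c("TRUE", "T", "1", "YES")
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) abort(sprintf("Non-numeric value for parameter \"%s\".", nm))
      args[[nm]] <- num
    }
  }
  do.call(run_params, args)
}

# Report column headers, fixed order.
.RESULT_HEADERS <- c(
  "Molecular formula", "Mass error (ppm)", "Predicted m/z (Da)",
  "Measured m/z (Da)", "Confidence interval (ppm)",
  "Relative intensity (%)", "#Data points"
)

.format_results <- function(results) {
  dash <- "\u2013"
  fmt_num <- function(x, fmt) ifelse(is.na(x), "", sprintf(fmt, x))
  tibble::tibble(
    `Molecular formula` =
      ifelse(is.na(results$formula), dash, results$formula),
    `Mass error (ppm)` = fmt_num(results$mass_error_ppm, "%.1f"),
    `Predicted m/z (Da)` = fmt_num(results$predicted_mz, "%.7f"),
    `Measured m/z (Da)` = fmt_num(results$measured_mz, "%.7f"),
    `Confidence interval (ppm)` = fmt_num(results$ci_ppm, "%.1f"),
    `Relative intensity (%)` =
      fmt_num(results$relative_intensity_pct, "%.1f"),
    `#Data points` = ifelse(is.na(results$n_points), "",
                            as.character(results$n_points))
  )
}

#' Write the annotation results table
#'
#' Columns and headers follow the conventional report layout: molecular
#' formula (an en dash for unannotated peaks, with blank predicted m/z and
#' mass error), mass error in ppm (1 decimal), predicted and measured m/z
#' (7 decimals), per-peak confidence interval (ppm, 1 decimal), relative
#' intensity (percent, 1 decimal) and the number of profile points in the
#' peak. Identical inputs produce byte-identical files.
#'
#' @param x A `frag_annotation` or its [tidy.frag_annotation()] tibble.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  results <- if (inherits(x, "frag_annotation")) x$results else x
  if (!is.data.frame(results) || nrow(results) == 0L) {
    abort("`x` must contain at least one result row.")
  }
  out <- .format_results(results)
  names(out) <- .RESULT_HEADERS
  if (format == "csv") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}
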