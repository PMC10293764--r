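# Spectrum annotation: precursor enumeration -> per-peak candidate spaces ->
# fragments-network selection -> results table.

.log <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) inform(sprintf(fmt, ...))
}

#' Annotate an MS2 peak table by fragments-network selection
#'
#' The core annotation routine. Candidate formulas for the precursor are
#' enumerated at the precursor peak's tolerance; candidate spaces for the
#' product peaks follow their own per-peak tolerances ([fragment_space()]);
#' the assignment maximizing the network grade is selected
#' ([select_best()]); finally, product annotations that are chemically
#' consistent with no other product annotation are rejected when
#' `reject_isolated` is set (see [run_params()]).
#'
#' The precursor peak is a mandatory network node: the measured peak inside
#' the precursor window is used when present, otherwise a virtual node at
#' `target_mz` is added (it then does not appear among the reported rows).
#'
#' @param peaks Peak tibble from [pick_peaks()], or any tibble with columns
#'   `measured_mz` and optionally `ci_ppm`, `n_points`, `total_intensity`,
#'   `relative_intensity_pct`.
#' @param target_mz Target precursor m/z (the protonated adduct in positive
#'   mode, or the anion in negative mode).
#' @param bounds Maximum atomic subscripts, see [enumerate_formulas()].
#' @param params A [run_params()] list.
#' @param verbose Log the filtering funnel (points, peaks, candidates,
#'   networks) as messages.
#' @return A `frag_annotation` object; see [tidy.frag_annotation()] for the
#'   per-peak table and [glance.frag_annotation()] for the one-row summary.
#'   The per-peak `status` is one of `"precursor"`, `"annotated"`,
#'   `"no_candidate"`, `"inconsistent"` (rejected as isolated) or
#'   `"above_precursor"`.
#' @examples
#' peaks <- tibble::tibble(measured_mz = c(92.0496, 254.0603))
#' ann <- annotate(peaks, 254.0599,
#'                 bounds = c(C = 10, S = 1, O = 3, N = 3, H = 12))
#' tidy(ann)
#' @export
annotate <- function(peaks, target_mz, bounds, params = run_params(),
                     verbose = FALSE) {
  stopifnot(is.data.frame(peaks), "measured_mz" %in% names(peaks))
  if (!inherits(params, "fragnets_params")) params <- do.call(run_params, params)
  peaks <- tibble::as_tibble(peaks)
  if (!"ci_ppm" %in% names(peaks)) peaks$ci_ppm <- NA_real_
  if (!"n_points" %in% names(peaks)) peaks$n_points <- NA_integer_
  if (!"relative_intensity_pct" %in% names(peaks)) {
    peaks$relative_intensity_pct <- NA_real_
  }
  peaks <- dplyr::arrange(peaks, .data$measured_mz)
  peaks$peak <- seq_len(nrow(peaks))
  bound <- .as_bounds(bounds)

  # --- precursor node --------------------------------------------------------
  win <- params$default_tol_ppm
  in_win <- abs(peaks$measured_mz - target_mz) <=
    target_mz * win * 1e-6 + 1e-12
  prec_peak <- if (any(in_win)) {
    cand_rows <- peaks[in_win, ]
    cand_rows[order(abs(cand_rows$measured_mz - target_mz)), ][1, ]
  } else {
    NULL
  }
  prec_mz <- if (is.null(prec_peak)) target_mz else prec_peak$measured_mz
  prec_tol <- max(params$ci_floor_ppm,
                  if (is.null(prec_peak)) {
                    params$default_tol_ppm
                  } else if ("tol_ppm" %in% names(peaks) &&
                             !is.na(prec_peak$tol_ppm)) {
                    prec_peak$tol_ppm
                  } else if (!is.na(prec_peak$ci_ppm)) {
                    prec_peak$ci_ppm
                  } else {
                    params$default_tol_ppm
                  })
  prec_cand <- enumerate_formulas(prec_mz, prec_tol, bound, params$ionization)
  if (nrow(prec_cand) == 0L) {
    abort(sprintf(
      "No precursor candidate within %.3g ppm of m/z %.6f under the given bounds.",
      prec_tol, prec_mz
    ), class = "fragnets_no_precursor")
  }
  .log(verbose, "Precursor m/z %.6f: %d candidate(s) at %.2f ppm.",
       prec_mz, nrow(prec_cand), prec_tol)

  # --- product peaks and their candidate spaces ------------------------------
  cutoff <- prec_mz * (1 + prec_tol * 1e-6)
  prec_id <- if (is.null(prec_peak)) 0L else prec_peak$peak
  products <- dplyr::filter(peaks, .data$peak != prec_id)
  above <- dplyr::filter(products, .data$measured_mz > cutoff)
  below <- dplyr::filter(products, .data$measured_mz <= cutoff)
  .log(verbose, "%d product peak(s) below the precursor window, %d above (excluded).",
       nrow(below), nrow(above))

  frag_cand <- fragment_space(
    below, prec_cand, bound, params$ionization,
    default_tol_ppm = params$default_tol_ppm,
    ci_floor_ppm = params$ci_floor_ppm,
    precursor_mz = prec_mz, precursor_tol_ppm = prec_tol
  )
  prec_node <- dplyr::mutate(prec_cand, peak = prec_id, .before = 1L)
  candidates <- dplyr::bind_rows(prec_node, frag_cand)
  .log(verbose, "Candidates per annotatable peak: %s.",
       paste(table(candidates$peak), collapse = ", "))

  # --- network selection -----------------------------------------------------
  net <- select_best(candidates, mode = params$network_mode,
                     cap = params$network_cap)
  .log(verbose, "Selected network: grade %d over %d node(s) (%.6g assignments, %s mode).",
       net$grade, nrow(net$nodes), attr(net, "n_networks"), attr(net, "mode"))

  # --- isolation rejection ---------------------------------------------------
  rejected <- integer(0)
  product_nodes <- setdiff(net$nodes$peak, prec_id)
  if (params$reject_isolated && length(product_nodes) >= 2L) {
    pp_edges <- dplyr::filter(net$edges, .data$parent != prec_id,
                              .data$child != prec_id)
    degree <- table(factor(c(pp_edges$parent, pp_edges$child),
                           levels = product_nodes))
    rejected <- product_nodes[degree == 0L]
    if (length(rejected)) {
      .log(verbose, "Rejected %d isolated product annotation(s): peak(s) %s.",
           length(rejected), paste(rejected, collapse = ", "))
    }
  }

  # --- results table ---------------------------------------------------------
  assigned <- net$nodes
  results <- peaks |>
    dplyr::left_join(
      dplyr::select(assigned, "peak", "formula", "predicted_mz"),
      by = "peak"
    ) |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$peak == prec_id ~ "precursor",
        .data$measured_mz > cutoff ~ "above_precursor",
        .data$peak %in% rejected ~ "inconsistent",
        is.na(.data$formula) ~ "no_candidate",
        TRUE ~ "annotated"
      ),
      formula = ifelse(.data$status %in% c("annotated", "precursor"),
                       .data$formula, NA_character_),
      predicted_mz = ifelse(is.na(.data$formula), NA_real_,
                            .data$predicted_mz),
      mass_error_ppm = ifelse(
        is.na(.data$formula), NA_real_,
        mass_error_ppm(dplyr::coalesce(.data$predicted_mz, 1),
                       .data$measured_mz)
      )
    ) |>
    dplyr::select("peak", "measured_mz", "formula", "predicted_mz",
                  "mass_error_ppm", "ci_ppm", "relative_intensity_pct",
                  "n_points", "status")

  structure(
    list(
      results = results,
      network = net,
      candidates = candidates,
      precursor = list(
        peak = if (prec_id == 0L) NA_integer_ else prec_id,
        measured_mz = prec_mz,
        tol_ppm = prec_tol,
        formula = assigned$formula[assigned$peak == prec_id],
        candidates = prec_cand
      ),
      target_mz = target_mz,
      params = params,
      n_networks = attr(net, "n_networks"),
      mode = attr(net, "mode")
    ),
    class = c("frag_annotation", "list")
  )
}

#' Annotate a centroided peak list
#'
#' Convenience wrapper for already-centroided data (e.g. a public spectrum
#' record). The profile information needed for per-peak confidence intervals
#' is gone, so one fixed mass window is used for the whole spectrum:
#' `default_tol_ppm` parts per million *of the target precursor m/z*,
#' applied to every peak as an absolute window (for a 254 Da precursor at
#' 10 ppm, 0.0025 Da at every peak). Only peaks contributing more than
#' `intensity_floor_pct` of the total intensity are considered.
#'
#' @param peaklist Data frame with columns `mz` and `intensity` (see
#'   [read_peaklist()]).
#' @inheritParams annotate
#' @return A `frag_annotation` object.
#' @examples
#' pl <- tibble::tibble(mz = c(92.0496, 254.0603), intensity = 1)
#' ann <- annotate_centroided(pl, 254.0599,
#'                            bounds = c(C = 10, S = 1, O = 3, N = 3, H = 12))
#' glance(ann)
#' @export
annotate_centroided <- function(peaklist, target_mz, bounds,
                                params = run_params(), verbose = FALSE) {
  stopifnot(is.data.frame(peaklist),
            all(c("mz", "intensity") %in% names(peaklist)))
  if (!inherits(params, "fragnets_params")) params <- do.call(run_params, params)
  total <- sum(peaklist$intensity)
  peaks <- peaklist |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$mz) |>
    dplyr::transmute(
      measured_mz = .data$mz,
      ci_ppm = NA_real_,
      tol_ppm = params$default_tol_ppm * target_mz / .data$mz,
      n_points = 1L,
      total_intensity = .data$intensity,
      relative_intensity_pct = 100 * .data$intensity / total
    )
  kept <- dplyr::filter(peaks,
                        .data$relative_intensity_pct > params$intensity_floor_pct)
  .log(verbose, "Centroided mode: %d of %d peaks above the %.3g%% intensity floor.",
       nrow(kept), nrow(peaks), params$intensity_floor_pct)
  annotate(kept, target_mz, bounds, params, verbose = verbose)
}

#' Annotate a profile-mode spectrum end to end
#'
#' Runs [pick_peaks()] with the run parameters, then [annotate()].
#'
#' @param points Profile points (`mz`, `intensity`), e.g. one scan from
#'   [read_mzml()] or a [simulate_spectrum()] output.
#' @inheritParams annotate
#' @return A `frag_annotation` object.
#' @export
annotate_profile <- function(points, target_mz, bounds,
                             params = run_params(), verbose = FALSE) {
  if (!inherits(params, "fragnets_params")) params <- do.call(run_params, params)
  peaks <- pick_peaks(
    points,
    noise_threshold = params$noise_threshold,
    gap_ppm = params$gap_ppm,
    confidence_level = params$confidence_level,
    min_points = params$min_cluster_points,
    intensity_floor_pct = params$intensity_floor_pct,
    weighted = params$weighted_centroid
  )
  .log(verbose, "Profile mode: %d points -> %d peaks.", nrow(points),
       nrow(peaks))
  annotate(peaks, target_mz, bounds, params, verbose = verbose)
}

# ---- result-class methods ---------------------------------------------------

#' Tidy the per-peak annotation table
#'
#' @param x A `frag_annotation` from [annotate()].
#' @param ... Unused.
#' @return Tibble with one row per reported peak: `peak`, `measured_mz`,
#'   `formula` (NA when unannotated), `predicted_mz`, `mass_error_ppm`,
#'   `ci_ppm`, `relative_intensity_pct`, `n_points`, `status`.
#' @exportS3Method generics::tidy
#' @export
tidy.frag_annotation <- function(x, ...) x$results

#' One-row summary of an annotation
#'
#' @inheritParams tidy.frag_annotation
#' @return Tibble: `target_mz`, `precursor_formula`, `n_peaks`,
#'   `n_annotated` (formula-bearing rows incl. the precursor), `grade`,
#'   `max_edges`, `n_networks` (assignments considered), `total_error_ppm`,
#'   `mode`.
#' @exportS3Method generics::glance
#' @export
glance.frag_annotation <- function(x, ...) {
  n_nodes <- nrow(x$network$nodes)
  tibble::tibble(
    target_mz = x$target_mz,
    precursor_formula = x$precursor$formula %||% NA_character_,
    n_peaks = nrow(x$results),
    n_annotated = sum(!is.na(x$results$formula)),
    grade = x$network$grade,
    max_edges = n_nodes * (n_nodes - 1) %/% 2,
    n_networks = x$n_networks,
    total_error_ppm = x$network$total_error_ppm,
    mode = x$mode
  )
}

#' @export
print.frag_annotation <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<frag_annotation> target m/z %.4f -> %s | %d/%d peaks annotated | grade %d/%d\n",
    g$target_mz, g$precursor_formula, g$n_annotated, g$n_peaks,
    g$grade, g$max_edges
  ))
  print(x$results, ...)
  invisible(x)
}
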