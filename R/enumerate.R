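# Candidate molecular-formula enumeration: the chemical space of a target
# m/z within a ppm window, bounded by user-supplied maximum atomic
# subscripts. The search is an exact depth-first scan over isotope
# dimensions ordered by descending mass, pruning any branch whose reachable
# mass range cannot intersect the window.

.as_bounds <- function(bounds) {
  if (is.data.frame(bounds)) {
    nm <- names(bounds)
    el_col <- intersect(c("element", "isotope"), nm)[1]
    val_col <- intersect(c("max_count", "max", "value"), nm)[1]
    if (is.na(el_col) || is.na(val_col)) {
      abort("Bounds data frame needs an element column and a max_count column.")
    }
    bounds <- setNames(bounds[[val_col]], bounds[[el_col]])
  }
  if (!is.numeric(bounds) || is.null(names(bounds))) {
    abort("`bounds` must be a named vector (or data frame) of maximum atom counts.")
  }
  if (any(bounds < 0)) abort("Maximum atomic subscripts must be non-negative.")
  out <- setNames(integer(length(.ISO_DIMS)), .ISO_DIMS)
  for (nm in names(bounds)) {
    key <- gsub("\\[|\\]", "", nm)
    if (!key %in% names(.sym_to_dim)) {
      abort(sprintf("Unknown element symbol \"%s\" in bounds.", nm),
            class = "fragnets_parse_error")
    }
    out[[.sym_to_dim[[key]]]] <- as.integer(bounds[[nm]])
  }
  out
}

# DFS over dims (descending mass) collecting count vectors whose total mass
# falls inside [lo, hi].
.enumerate_counts <- function(lo, hi, bound) {
  active <- which(bound > 0L)
  if (length(active) == 0L) {
    return(matrix(integer(), 0, length(.ISO_DIMS),
                  dimnames = list(NULL, .ISO_DIMS)))
  }
  ord <- active[order(.ISO_MASS[active], decreasing = TRUE)]
  masses <- .ISO_MASS[ord]
  caps <- bound[ord]
  ndim <- length(ord)
  # max mass attainable from dimension d onwards
  max_rest <- rev(cumsum(rev(masses * caps)))
  acc <- vector("list", 64L)
  n_acc <- 0L
  counts <- integer(ndim)
  recurse <- function(d, partial) {
    if (d == ndim) {
      m <- masses[d]
      kmin <- max(0L, as.integer(ceiling((lo - partial) / m - 1e-9)))
      kmax <- min(caps[d], as.integer(floor((hi - partial) / m + 1e-9)))
      for (k in seq_len(max(0L, kmax - kmin + 1L)) + kmin - 1L) {
        total <- partial + k * m
        if (total >= lo && total <= hi) {
          counts[d] <<- k
          n_acc <<- n_acc + 1L
          acc[[n_acc]] <<- counts
        }
      }
      counts[d] <<- 0L
      return(invisible())
    }
    m <- masses[d]
    for (k in 0L:caps[d]) {
      p <- partial + k * m
      if (p > hi) break
      if (p + max_rest[d + 1L] < lo) next
      counts[d] <<- k
      recurse(d + 1L, p)
    }
    counts[d] <<- 0L
    invisible()
  }
  recurse(1L, 0)
  if (n_acc == 0L) {
    return(matrix(integer(), 0, length(.ISO_DIMS),
                  dimnames = list(NULL, .ISO_DIMS)))
  }
  found <- do.call(rbind, acc[seq_len(n_acc)])
  out <- matrix(0L, nrow(found), length(.ISO_DIMS),
                dimnames = list(NULL, .ISO_DIMS))
  out[, ord] <- found
  out
}

#' Enumerate candidate ion formulas for a target m/z
#'
#' Returns every formula within the subscript bounds whose singly charged ion
#' m/z lies in `target_mz * (1 +/- tol_ppm * 1e-6)`. The search is complete:
#' no formula inside the window and bounds is missed (see the brute-force
#' equivalence tests).
#'
#' @param target_mz Target m/z in Da (> 0).
#' @param tol_ppm Half-width of the matching window in ppm (> 0).
#' @param bounds Maximum atomic subscripts: a named vector such as
#'   `c(C = 10, S = 1, O = 3, N = 3, H = 12)` or a data frame with columns
#'   `element` and `max_count` (see [read_bounds()]). Heavy isotopes are
#'   written `"[13C]"`/`"[34S]"` (or `13C`/`34S`). Elements not listed are
#'   excluded (bound 0).
#' @param ionization `"+"` for cations (electron subtracted) or `"-"` for
#'   anions (electron added); the sign of the charge carrier only.
#' @return Tibble of candidates sorted by `error_ppm`: `formula`, `charge`,
#'   `predicted_mz`, `error_ppm` (|predicted - target| / target * 1e6), plus
#'   the isotope count columns. Empty bounds give an empty tibble, not an
#'   error.
#' @examples
#' enumerate_formulas(254.0603, 10, c(C = 10, S = 1, O = 3, N = 3, H = 12))
#' @export
enumerate_formulas <- function(target_mz, tol_ppm, bounds,
                               ionization = c("+", "-")) {
  ionization <- .match_ionization(ionization)
  if (!is.numeric(target_mz) || target_mz <= 0) {
    abort("`target_mz` must be positive.")
  }
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) abort("`tol_ppm` must be positive.")
  bound <- .as_bounds(bounds)
  charge <- if (ionization == "+") 1L else -1L
  lo_ion <- target_mz * (1 - tol_ppm * 1e-6)
  hi_ion <- target_mz * (1 + tol_ppm * 1e-6)
  # neutral-composition window: exact mass = ion m/z + charge * m_e
  counts <- .enumerate_counts(lo_ion + charge * .ELECTRON_MASS,
                              hi_ion + charge * .ELECTRON_MASS, bound)
  charges <- rep(charge, nrow(counts))
  predicted <- as.numeric(counts %*% .ISO_MASS) - charges * .ELECTRON_MASS
  tibble::tibble(
    formula = .format_counts(counts, charges),
    charge = charges,
    predicted_mz = predicted,
    error_ppm = abs(predicted - target_mz) / target_mz * 1e6
  ) |>
    dplyr::bind_cols(tibble::as_tibble(counts)) |>
    dplyr::arrange(.data$error_ppm, .data$formula)
}

.match_ionization <- function(ionization) {
  ionization <- as.character(ionization[1])
  if (ionization %in% c("-", "−")) ionization <- "-"
  if (!ionization %in% c("+", "-")) {
    abort("`ionization` must be \"+\" or \"-\".")
  }
  ionization
}

#' Candidate formulas for every product peak of an MS2 spectrum
#'
#' Each product peak is matched within its *own* tolerance: an explicit
#' `tol_ppm` column when present (centroided mode sets one), otherwise the
#' per-peak confidence interval `ci_ppm` when available (the point of
#' keeping profile data), otherwise `default_tol_ppm` -- always floored at
#' `ci_floor_ppm` to avoid zero-width windows. Candidates must be chemically
#' consistent (sub-formulas, [consistent()]) with at least one precursor
#' candidate. Peaks above the precursor window are dropped beforehand: only
#' product ions smaller than the precursor belong to the MS2 spectrum.
#'
#' @param peaks Tibble of peaks with columns `peak`, `measured_mz` and
#'   optionally `ci_ppm` (from [pick_peaks()]) and/or `tol_ppm`.
#' @param precursor_candidates Non-empty candidate tibble for the precursor
#'   ion (from [enumerate_formulas()]).
#' @inheritParams enumerate_formulas
#' @param default_tol_ppm Tolerance for peaks without a confidence interval.
#' @param ci_floor_ppm Lower bound applied to per-peak tolerances.
#' @param precursor_mz Measured precursor m/z defining the upper cutoff
#'   (defaults to the smallest precursor-candidate window that covers all
#'   precursor candidates).
#' @param precursor_tol_ppm Tolerance of the precursor window used for the
#'   cutoff.
#' @return Tibble of candidates with a leading `peak` column; peaks with no
#'   candidate simply contribute no rows.
#' @export
fragment_space <- function(peaks, precursor_candidates, bounds,
                           ionization = c("+", "-"), default_tol_ppm = 10,
                           ci_floor_ppm = 0.5, precursor_mz = NULL,
                           precursor_tol_ppm = default_tol_ppm) {
  ionization <- .match_ionization(ionization)
  if (is.null(precursor_candidates) || nrow(precursor_candidates) == 0L) {
    abort("`precursor_candidates` must contain at least one candidate.")
  }
  precursor_mz <- precursor_mz %||% max(precursor_candidates$predicted_mz)
  cutoff <- precursor_mz * (1 + precursor_tol_ppm * 1e-6)
  prec_counts <- .as_formula_set(precursor_candidates$formula)$counts
  bound <- .as_bounds(bounds)
  if (!"ci_ppm" %in% names(peaks)) peaks$ci_ppm <- NA_real_
  if (!"tol_ppm" %in% names(peaks)) peaks$tol_ppm <- NA_real_
  if (!"peak" %in% names(peaks)) peaks$peak <- seq_len(nrow(peaks))

  below <- dplyr::filter(peaks, .data$measured_mz <= cutoff)
  purrr::map_dfr(seq_len(nrow(below)), function(i) {
    mz <- below$measured_mz[i]
    tol <- max(ci_floor_ppm,
               if (!is.na(below$tol_ppm[i])) below$tol_ppm[i]
               else if (!is.na(below$ci_ppm[i])) below$ci_ppm[i]
               else default_tol_ppm)
    cand <- enumerate_formulas(mz, tol, bound, ionization)
    if (nrow(cand) == 0L) return(cand)
    cc <- .as_formula_set(cand$formula)$counts
    keep <- vapply(seq_len(nrow(cc)), function(j) {
      any(.consistent_counts(prec_counts,
                             cc[rep(j, nrow(prec_counts)), , drop = FALSE]))
    }, logical(1))
    dplyr::mutate(cand[keep, , drop = FALSE], peak = below$peak[i],
                  .before = 1L)
  })
}
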