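#' @importFrom rlang abort warn inform .data .env %||%
#' @importFrom stats qt sd shapiro.test weighted.mean setNames rnorm runif
#' @importFrom utils head
NULL

# ---- internal formula representation ----------------------------------------
# A set of formulas is carried as an integer count matrix (rows = formulas,
# columns = the 12 isotope dimensions in .ISO_DIMS order) plus a charge vector
# with values in {-1, 0, +1}.

.token_re <- "(\\[13C\\]|\\[34S\\]|Cl|Na|C|S|O|N|H|F|K|P)([0-9]*)"
.sym_to_dim <- c(
  "C" = "C", "[13C]" = "C13", "13C" = "C13", "C13" = "C13",
  "S" = "S", "[34S]" = "S34", "34S" = "S34", "S34" = "S34",
  "O" = "O", "N" = "N", "H" = "H",
  "Cl" = "Cl", "F" = "F", "K" = "K", "Na" = "Na", "P" = "P"
)

.parse_one <- function(text) {
  s <- trimws(text)
  charge <- 0L
  last <- substr(s, nchar(s), nchar(s))
  if (last %in% c("+", "\u207a")) {
    charge <- 1L
    s <- substr(s, 1L, nchar(s) - 1L)
  } else if (last %in% c("-", "\u2212", "\u207b")) {
    charge <- -1L
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  counts <- setNames(integer(length(.ISO_DIMS)), .ISO_DIMS)
  if (nchar(s) == 0L) {
    return(list(counts = counts, charge = charge))
  }
  m <- gregexpr(.token_re, s)[[1]]
  covered <- rep(FALSE, nchar(s))
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
    }
  }
  if (!all(covered)) {
    bad_at <- which(!covered)[1]
    # widen to the full unrecognized run for a readable message
    bad_end <- bad_at
    while (bad_end < nchar(s) && !covered[bad_end + 1L]) bad_end <- bad_end + 1L
    abort(sprintf(
      "Unknown element symbol \"%s\" in formula \"%s\".",
      substr(s, bad_at, bad_end), text
    ), class = "fragnets_parse_error")
  }
  toks <- regmatches(s, list(m))[[1]]
  syms <- sub(.token_re, "\\1", toks)
  nums <- sub(.token_re, "\\2", toks)
  nums <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
  for (i in seq_along(syms)) {
    dim <- .sym_to_dim[[syms[i]]]
    counts[[dim]] <- counts[[dim]] + nums[i]
  }
  list(counts = counts, charge = charge)
}

# Coerce formulas given as character, parse_formula() tibble, count matrix or
# a single named count vector into list(counts = matrix, charge = integer).
.as_formula_set <- function(x, charge = NULL) {
  if (is.character(x)) {
    parsed <- lapply(x, .parse_one)
    counts <- do.call(rbind, lapply(parsed, `[[`, "counts"))
    chg <- vapply(parsed, `[[`, integer(1), "charge")
    # an explicit charge argument fills in strings without a sign suffix
    if (!is.null(charge)) chg[chg == 0L] <- as.integer(charge)
    if (is.null(counts)) counts <- matrix(integer(), 0, length(.ISO_DIMS),
                                          dimnames = list(NULL, .ISO_DIMS))
    return(list(counts = counts, charge = chg))
  }
  if (is.data.frame(x)) {
    missing_dims <- setdiff(.ISO_DIMS, names(x))
    counts <- as.matrix(dplyr::bind_cols(
      x[intersect(.ISO_DIMS, names(x))],
      setNames(as.list(rep(0L, length(missing_dims))), missing_dims)
    )[.ISO_DIMS])
    chg <- if ("charge" %in% names(x)) as.integer(x$charge) else
      rep(charge %||% 0L, nrow(x))
    return(list(counts = counts, charge = chg))
  }
  if (is.matrix(x)) {
    stopifnot(identical(colnames(x), .ISO_DIMS))
    return(list(counts = x,
                charge = rep(charge %||% 0L, length.out = nrow(x))))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- setNames(integer(length(.ISO_DIMS)), .ISO_DIMS)
    bad <- setdiff(names(x), names(.sym_to_dim))
    if (length(bad)) {
      abort(sprintf("Unknown element symbol \"%s\".", bad[1]),
            class = "fragnets_parse_error")
    }
    for (nm in names(x)) {
      counts[[.sym_to_dim[[nm]]]] <- counts[[.sym_to_dim[[nm]]]] + as.integer(x[[nm]])
    }
    return(list(counts = matrix(counts, 1, dimnames = list(NULL, .ISO_DIMS)),
                charge = charge %||% 0L))
  }
  abort("Cannot interpret `x` as molecular formulas.")
}

.format_counts <- function(counts, charge) {
  apply_fmt <- function(i) {
    n <- counts[i, ]
    parts <- character(0)
    for (d in .ISO_DIMS) {
      if (n[[d]] > 0L) {
        parts <- c(parts, paste0(.ISO_LABEL[[d]],
                                 if (n[[d]] > 1L) n[[d]] else ""))
      }
    }
    suffix <- c("-", "", "+")[charge[i] + 2L]
    paste0(paste(parts, collapse = ""), suffix)
  }
  vapply(seq_len(nrow(counts)), apply_fmt, character(1))
}

# ---- exported operations ----------------------------------------------------

#' Parse molecular-formula strings into isotope count vectors
#'
#' Formulas use the field's plain notation, e.g. `"C10SO3N3H12+"`: an element
#' symbol followed by an optional subscript (omitted subscript means 1),
#' heavy isotopes bracketed (`[13C]`, `[34S]`), and a trailing `+` or `-`
#' marking a singly charged ion (absent for a neutral composition such as a
#' neutral loss).
#'
#' @param text Character vector of formulas.
#' @return A tibble with one row per input: `formula` (the canonical string,
#'   see [format_formula()]), `charge` (+1, -1 or 0), and one integer column
#'   per isotope dimension (`C`, `C13`, `S`, `S34`, `O`, `N`, `H`, `Cl`, `F`,
#'   `K`, `Na`, `P`).
#' @examples
#' parse_formula(c("C6NH6+", "C10SO3N3H12+", "[13C]C13ON2H13+"))
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text))
  fs <- .as_formula_set(text)
  tibble::tibble(
    formula = .format_counts(fs$counts, fs$charge),
    charge = fs$charge
  ) |>
    dplyr::bind_cols(tibble::as_tibble(fs$counts))
}

#' Format isotope counts as a canonical formula string
#'
#' Elements are emitted in the fixed order C, `[13C]`, S, `[34S]`, O, N, H,
#' then Cl, F, K, Na, P, so that equal formulas always render identically;
#' `format_formula(parse_formula(x)$formula)` is the identity on canonical
#' strings.
#'
#' @param x Formulas: a character vector, a [parse_formula()]-style data frame
#'   with count columns, or a named count vector (e.g. `c(C = 6, N = 1, H = 6)`).
#' @param charge Charge to use when `x` carries none (default 0).
#' @return Character vector of canonical formula strings.
#' @examples
#' format_formula(c(C = 10, S = 1, O = 3, N = 3, H = 12), charge = 1)
#' @export
format_formula <- function(x, charge = NULL) {
  fs <- .as_formula_set(x, charge = charge)
  .format_counts(fs$counts, fs$charge)
}

#' Exact (monoisotopic) mass of a formula
#'
#' Plain sum of monoisotopic atomic masses over the isotope count vector; no
#' electron correction is applied (see [ion_mz()] for ion m/z).
#'
#' @inheritParams format_formula
#' @return Numeric vector of masses in Da. The empty formula has mass 0.
#' @examples
#' exact_mass("C10SO3N3H12") # 254.0599374 Da
#' @export
exact_mass <- function(x) {
  fs <- .as_formula_set(x)
  as.numeric(fs$counts %*% .ISO_MASS)
}

#' m/z of a singly charged ion
#'
#' For charge +1 the ion is one electron lighter than its atomic composition;
#' for charge -1 one electron heavier. Only singly charged ions are supported.
#'
#' @inheritParams format_formula
#' @param charge Charge override for inputs without one (+1 or -1).
#' @return Numeric vector of ion m/z in Da.
#' @examples
#' ion_mz("C10SO3N3H12+") # 254.0593888 Da
#' @export
ion_mz <- function(x, charge = NULL) {
  fs <- .as_formula_set(x, charge = charge)
  if (any(abs(fs$charge) != 1L)) {
    abort("ion_mz() requires singly charged ions; got a neutral formula.",
          class = "fragnets_charge_error")
  }
  as.numeric(fs$counts %*% .ISO_MASS) - fs$charge * .ELECTRON_MASS
}

#' Mass error between a predicted and a measured m/z, in ppm
#'
#' @param predicted Predicted m/z (Da), must be positive.
#' @param measured Measured m/z (Da).
#' @return `|predicted - measured| / predicted * 1e6` (magnitude; rounding to
#'   one decimal happens only in the report written by [write_results()]).
#' @examples
#' mass_error_ppm(254.0593888, 254.0592743) # 0.45 ppm
#' @export
mass_error_ppm <- function(predicted, measured) {
  if (any(predicted <= 0)) {
    abort("`predicted` m/z must be positive.", class = "fragnets_value_error")
  }
  abs(predicted - measured) / predicted * 1e6
}

# Fast row-wise consistency on count matrices of equal dimension.
.consistent_counts <- function(parent_counts, child_counts) {
  d <- parent_counts - child_counts
  rowSums(d < 0L) == 0L & rowSums(d) > 0L
}

#' Chemical consistency between two ions
#'
#' Ion `child` is consistent with ion `parent` when fragmentation of `parent`
#' into `child` plus a neutral molecule balances atoms: every isotope count of
#' `parent` is at least that of `child`, the difference is not empty, and the
#' charges are equal (the charge stays on the fragment ion). Heavy isotopes
#' count as their own dimension: a fragment containing `[13C]` can only arise
#' from a parent containing `[13C]`.
#'
#' @param parent,child Formulas (character vectors or [parse_formula()]
#'   tibbles); recycled against each other.
#' @return Logical vector. A charge mismatch (or a neutral input) yields
#'   `FALSE`, not an error.
#' @examples
#' consistent("C10SO3N3H12+", "C6SO2NH6+") # TRUE, loss C4ON2H6
#' consistent("C6NH6+", "C6NH7+")          # FALSE, H would increase
#' @export
consistent <- function(parent, child) {
  p <- .as_formula_set(parent)
  c_ <- .as_formula_set(child)
  n <- max(nrow(p$counts), nrow(c_$counts))
  ip <- rep_len(seq_len(nrow(p$counts)), n)
  ic <- rep_len(seq_len(nrow(c_$counts)), n)
  ok_charge <- p$charge[ip] == c_$charge[ic] & abs(p$charge[ip]) == 1L
  ok_charge & .consistent_counts(p$counts[ip, , drop = FALSE],
                                 c_$counts[ic, , drop = FALSE])
}

#' Neutral loss of a consistent parent/child ion pair
#'
#' @inheritParams consistent
#' @return Character vector of neutral-loss formulas (charge 0). The loss
#'   satisfies `exact_mass(parent) = exact_mass(child) + exact_mass(loss)`.
#'   Inconsistent pairs are a contract violation and raise an error.
#' @examples
#' neutral_loss("C10SO3N3H12+", "C10ON3H10+") # "SO2H2"
#' @export
neutral_loss <- function(parent, child) {
  p <- .as_formula_set(parent)
  c_ <- .as_formula_set(child)
  n <- max(nrow(p$counts), nrow(c_$counts))
  ip <- rep_len(seq_len(nrow(p$counts)), n)
  ic <- rep_len(seq_len(nrow(c_$counts)), n)
  ok <- consistent(parent, child)
  if (!all(ok)) {
    abort("neutral_loss() requires consistent(parent, child) for every pair.",
          class = "fragnets_consistency_error")
  }
  d <- p$counts[ip, , drop = FALSE] - c_$counts[ic, , drop = FALSE]
  .format_counts(d, rep(0L, n))
}
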