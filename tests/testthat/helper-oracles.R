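# Shared fixtures (built in code) and independent brute-force oracles.

# Published worked examples: centroided MS2 peak lists, protonated-parent
# targets, parent-formula bounds, and the expected annotation column.
worked_examples <- list(
  carbamazepine = list(
    mz = c(194.0964, 237.1020, 238.1052),
    target = 237.1020,
    bounds = c(C = 15, O = 1, N = 2, H = 13, "13C" = 1),
    expected = c("C14NH12+", "C15ON2H13+", NA)
  ),
  sulfamethoxazole = list(
    mz = c(65.0382, 68.049, 92.0496, 93.0575, 99.0562, 108.046, 110.0605,
           146.071, 147.0791, 148.0864, 156.0119, 157.0146, 158.0078,
           160.0873, 188.0822, 254.0603),
    target = 254.0603,
    bounds = c(C = 10, S = 1, O = 3, N = 3, H = 12, "13C" = 1, "34S" = 1),
    expected = c("C5H5+", "C4NH6+", "C6NH6+", "C6NH7+", "C4ON2H7+",
                 "C6ONH6+", "C6ONH8+", "C8N3H8+", "C8N3H9+", "C8N3H10+",
                 "C6SO2NH6+", NA, NA, "C9N3H10+", "C10ON3H10+",
                 "C10SO3N3H12+")
  ),
  atenolol = list(
    mz = c(56.0491, 72.0804, 74.0597, 98.0973, 116.1079, 133.0651, 145.0648,
           162.0914, 164.0705, 173.0597, 178.0867, 180.1022, 190.0866,
           191.0898, 208.0976, 225.1239, 267.1709, 268.1747),
    target = 267.1709,
    bounds = c(C = 14, O = 3, N = 2, H = 23, "13C" = 1),
    expected = c("C3NH6+", "C4NH10+", "C3ONH8+", "C6NH12+", "C6ONH14+",
                 "C9OH9+", "C10OH9+", "C10ONH12+", "C9O2NH10+", "C11O2H9+",
                 "C10O2NH12+", "C10O2NH14+", "C11O2NH12+", NA, "C11O3NH14+",
                 "C11O3N2H17+", "C14O3N2H23+", NA)
  )
)

# The fragment ions of the sulfamethoxazole spectrum (ground truth for the
# synthetic end-to-end checks).
sulfa_fragments <- worked_examples$sulfamethoxazole$expected[
  !is.na(worked_examples$sulfamethoxazole$expected)
]

# Independent oracle: enumerate candidates by filtering a full subscript
# grid (no pruning, no recursion; only valid for small bounds).
grid_enumerate <- function(target_mz, tol_ppm, bounds, ionization = "+") {
  grids <- lapply(bounds, function(b) 0:b)
  g <- do.call(expand.grid, grids)
  mass <- as.matrix(g) %*% vapply(names(bounds), function(el) {
    isotope_masses()$mass_da[match(gsub("\\[|\\]", "", el),
                                   gsub("\\[|\\]", "",
                                        isotope_masses()$label))]
  }, numeric(1))
  charge <- if (ionization == "+") 1 else -1
  mz <- mass - charge * electron_mass()
  keep <- abs(mz - target_mz) <= target_mz * tol_ppm * 1e-6 & rowSums(g) > 0
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  sort(vapply(seq_len(nrow(g)), function(i) {
    v <- unlist(g[i, ])
    format_formula(v[v > 0], charge = charge)
  }, character(1)))
}

# Independent oracle: maximum network grade by full enumeration with
# pairwise consistent() calls on formula strings.
brute_best_grade <- function(candidates) {
  peaks <- unique(candidates$peak)
  sets <- lapply(peaks, function(p) candidates$formula[candidates$peak == p])
  idx <- do.call(expand.grid, lapply(sets, seq_along))
  best <- -1L
  for (r in seq_len(nrow(idx))) {
    forms <- vapply(seq_along(peaks), function(a) sets[[a]][idx[r, a]],
                    character(1))
    g <- 0L
    for (a in seq_along(forms)) {
      for (b in seq_along(forms)) {
        if (a < b && (consistent(forms[a], forms[b]) ||
                      consistent(forms[b], forms[a]))) {
          g <- g + 1L
        }
      }
    }
    best <- max(best, g)
  }
  best
}

# Random ion formula over C/H/O/N with at least one atom.
random_formula <- function(max_c = 6, max_h = 10, max_o = 3, max_n = 2) {
  repeat {
    v <- c(C = sample(0:max_c, 1), H = sample(0:max_h, 1),
           O = sample(0:max_o, 1), N = sample(0:max_n, 1))
    if (sum(v) > 0) return(format_formula(v[v > 0], charge = 1))
  }
}
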