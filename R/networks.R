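# Fragments networks: one candidate formula per peak (nodes) plus every
# chemically consistent pair among the assigned ions (edges). The network
# grade -- its number of edges -- is the selection criterion for the
# spectrum annotation.

#' Number of fragments networks generated by a candidate assignment
#'
#' One network per combination of per-peak annotations: the product of the
#' candidate counts. Five peaks with five candidates each generate 3125
#' networks. Peaks with zero candidates do not enter network construction
#' (they are reported unannotated) and must not be passed here.
#'
#' @param candidate_counts Integer vector of per-peak candidate counts, all
#'   >= 1.
#' @return The product, as a double (counts grow combinatorially).
#' @examples
#' count_networks(c(5, 5, 5, 5, 5)) # 3125
#' @export
count_networks <- function(candidate_counts) {
  if (length(candidate_counts) == 0L) return(0)
  if (any(candidate_counts < 1)) {
    abort("All candidate counts must be >= 1; exclude candidate-less peaks.")
  }
  prod(as.numeric(candidate_counts))
}

# Pairwise edges among assigned ions; rows of `counts` are node formulas.
.edges_from_counts <- function(counts, charges) {
  n <- nrow(counts)
  if (n < 2L) {
    return(data.frame(parent = integer(0), child = integer(0)))
  }
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  same_charge <- charges[i] == charges[j] & abs(charges[i]) == 1L
  i_parent <- .consistent_counts(counts[i, , drop = FALSE],
                                 counts[j, , drop = FALSE]) & same_charge
  j_parent <- .consistent_counts(counts[j, , drop = FALSE],
                                 counts[i, , drop = FALSE]) & same_charge
  data.frame(
    parent = c(i[i_parent], j[j_parent]),
    child = c(j[i_parent], i[j_parent])
  )
}

#' Build a fragments network from one assignment of candidates to peaks
#'
#' Edges connect every unordered pair of peaks whose assigned ions are
#' chemically consistent in one direction ([consistent()]); direction is
#' recorded (parent = the larger ion) but ignored for grading.
#'
#' @param assignment Tibble with one row per annotated peak: columns `peak`,
#'   `formula`, and optionally `measured_mz`, `predicted_mz`, `error_ppm`.
#' @return A `fragments_network` object: list with `nodes` (the assignment),
#'   `edges` (tibble `parent`, `child` peak ids, `loss` formula, `loss_mass`),
#'   `grade` (number of edges) and `total_error_ppm` (sum of |error_ppm| over
#'   nodes, NA when errors are absent).
#' @examples
#' asg <- tibble::tibble(peak = 1:3,
#'                       formula = c("C4H8+", "C3H6+", "C2H4+"))
#' build_network(asg)$grade # 3
#' @export
build_network <- function(assignment) {
  stopifnot(is.data.frame(assignment), "formula" %in% names(assignment))
  if (!"peak" %in% names(assignment)) {
    assignment$peak <- seq_len(nrow(assignment))
  }
  fs <- .as_formula_set(assignment$formula)
  e <- .edges_from_counts(fs$counts, fs$charge)
  loss_counts <- fs$counts[e$parent, , drop = FALSE] -
    fs$counts[e$child, , drop = FALSE]
  edges <- tibble::tibble(
    parent = assignment$peak[e$parent],
    child = assignment$peak[e$child],
    parent_formula = assignment$formula[e$parent],
    child_formula = assignment$formula[e$child],
    loss = if (nrow(e)) .format_counts(loss_counts, rep(0L, nrow(e)))
           else character(0),
    loss_mass = as.numeric(loss_counts %*% .ISO_MASS)
  )
  total_err <- if ("error_ppm" %in% names(assignment)) {
    sum(abs(assignment$error_ppm))
  } else {
    NA_real_
  }
  structure(
    list(
      nodes = tibble::as_tibble(assignment),
      edges = edges,
      grade = nrow(edges),
      total_error_ppm = total_err
    ),
    class = "fragments_network"
  )
}

#' @export
print.fragments_network <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf(
    "<fragments_network> %d nodes, grade %d (max %d), total |error| %s ppm\n",
    n, x$grade, n * (n - 1) %/% 2,
    ifelse(is.na(x$total_error_ppm), "NA",
           sprintf("%.2f", x$total_error_ppm))
  ))
  print(x$nodes, ...)
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @rdname build_network
#' @param x A `fragments_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.fragments_network <- function(x, ...) x$edges

#' @rdname build_network
#' @exportS3Method generics::glance
#' @export
glance.fragments_network <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble::tibble(
    n_nodes = n,
    grade = x$grade,
    max_edges = n * (n - 1) %/% 2,
    total_error_ppm = x$total_error_ppm
  )
}

# ---- selection --------------------------------------------------------------

# Precompute per-pair consistency matrices between candidate sets.
.pair_consistency <- function(counts_list, charge_list) {
  np <- length(counts_list)
  M <- vector("list", np * np)
  dim(M) <- c(np, np)
  for (a in seq_len(np - 1L)) {
    for (b in (a + 1L):np) {
      ca <- counts_list[[a]]; cb <- counts_list[[b]]
      ka <- nrow(ca); kb <- nrow(cb)
      ia <- rep(seq_len(ka), times = kb)
      ib <- rep(seq_len(kb), each = ka)
      same <- charge_list[[a]][ia] == charge_list[[b]][ib] &
        abs(charge_list[[a]][ia]) == 1L
      edge <- same & (
        .consistent_counts(ca[ia, , drop = FALSE], cb[ib, , drop = FALSE]) |
          .consistent_counts(cb[ib, , drop = FALSE], ca[ia, , drop = FALSE])
      )
      M[[a, b]] <- matrix(edge, ka, kb)
    }
  }
  M
}

.assignment_grade <- function(idx, M) {
  # idx: matrix n_assign x n_peaks of candidate indices
  np <- ncol(idx)
  grade <- numeric(nrow(idx))
  for (a in seq_len(np - 1L)) {
    for (b in (a + 1L):np) {
      grade <- grade + M[[a, b]][cbind(idx[, a], idx[, b])]
    }
  }
  grade
}

#' Select the most chemically consistent fragments network
#'
#' Enumerates (or greedily searches) the assignments of one candidate per
#' peak and returns the network of maximum grade. Ties are broken by minimum
#' total |error_ppm|, then lexicographically by the concatenated formula
#' strings, so the result is deterministic.
#'
#' @param candidates Tibble of candidates with columns `peak`, `formula`,
#'   `error_ppm` and optionally `predicted_mz`, `measured_mz` (e.g. from
#'   [fragment_space()]); peaks with no rows are simply not part of the
#'   network.
#' @param mode `"exact"` enumerates all assignments (refusing when their
#'   number exceeds `cap`); `"greedy"` seeds every peak with its
#'   minimum-error candidate and hill-climbs single-peak swaps to a local
#'   grade maximum, restarting from every single-candidate perturbation of
#'   the seed.
#' @param cap Maximum number of assignments exact mode will enumerate.
#' @return A [build_network()] object for the winning assignment, with
#'   attributes `n_networks` (assignments considered in exact mode) and
#'   `mode`.
#' @examples
#' cand <- dplyr::bind_rows(
#'   tibble::tibble(peak = 1, formula = c("C4H8+", "C3NH6+"),
#'                  error_ppm = c(1, 0.5)),
#'   tibble::tibble(peak = 2, formula = "C2H4+", error_ppm = 0.2)
#' )
#' select_best(cand)$grade
#' @export
select_best <- function(candidates, mode = c("exact", "greedy"), cap = 1e6) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(candidates),
            all(c("peak", "formula") %in% names(candidates)))
  if (nrow(candidates) == 0L) {
    abort("At least one peak must have a candidate.")
  }
  if (!"error_ppm" %in% names(candidates)) candidates$error_ppm <- 0
  peaks <- sort(unique(candidates$peak))
  sets <- lapply(peaks, function(p) {
    candidates[candidates$peak == p, , drop = FALSE]
  })
  counts_list <- lapply(sets, function(s) .as_formula_set(s$formula)$counts)
  charge_list <- lapply(sets, function(s) .as_formula_set(s$formula)$charge)
  k <- vapply(sets, nrow, integer(1))
  n_networks <- count_networks(k)
  M <- .pair_consistency(counts_list, charge_list)
  err_list <- lapply(sets, function(s) abs(s$error_ppm))

  if (mode == "exact") {
    if (n_networks > cap) {
      abort(sprintf(
        paste0("Exact selection over %d peaks would enumerate %.3g networks ",
               "(cap %.3g). Use mode = \"greedy\" or tighten tolerances."),
        length(peaks), n_networks, cap
      ), class = "fragnets_cap_error")
    }
    idx <- as.matrix(expand.grid(lapply(k, seq_len), KEEP.OUT.ATTRS = FALSE))
    grade <- .assignment_grade(idx, M)
    best_grade <- max(grade)
    top <- which(grade == best_grade)
    err <- numeric(length(top))
    for (a in seq_along(peaks)) err <- err + err_list[[a]][idx[top, a]]
    top <- top[err == min(err)]
    if (length(top) > 1L) {
      keys <- vapply(top, function(r) {
        paste(vapply(seq_along(peaks),
                     function(a) sets[[a]]$formula[idx[r, a]],
                     character(1)), collapse = "|")
      }, character(1))
      top <- top[order(keys)][1]
    }
    pick <- idx[top[1], ]
  } else {
    grade_of <- function(pick) {
      g <- 0L
      np <- length(pick)
      for (a in seq_len(np - 1L)) {
        for (b in (a + 1L):np) g <- g + M[[a, b]][pick[a], pick[b]]
      }
      g
    }
    err_of <- function(pick) {
      sum(vapply(seq_along(pick), function(a) err_list[[a]][pick[a]],
                 numeric(1)))
    }
    climb <- function(pick) {
      repeat {
        g0 <- grade_of(pick); e0 <- err_of(pick)
        improved <- FALSE
        for (a in seq_along(pick)) {
          for (c_ in seq_len(k[a])) {
            if (c_ == pick[a]) next
            trial <- pick; trial[a] <- c_
            g <- grade_of(trial)
            if (g > g0 || (g == g0 && err_of(trial) < e0)) {
              pick <- trial; g0 <- g; e0 <- err_of(trial); improved <- TRUE
            }
          }
        }
        if (!improved) return(pick)
      }
    }
    seed <- vapply(err_list, which.min, integer(1))
    best_pick <- climb(seed)
    best_g <- grade_of(best_pick); best_e <- err_of(best_pick)
    for (a in seq_along(peaks)) {
      for (c_ in seq_len(k[a])) {
        if (c_ == seed[a]) next
        start <- seed; start[a] <- c_
        res <- climb(start)
        g <- grade_of(res)
        if (g > best_g || (g == best_g && err_of(res) < best_e)) {
          best_pick <- res; best_g <- g; best_e <- err_of(res)
        }
      }
    }
    pick <- best_pick
  }

  assignment <- purrr::map_dfr(seq_along(peaks), function(a) {
    sets[[a]][pick[a], , drop = FALSE]
  })
  net <- build_network(assignment)
  attr(net, "n_networks") <- n_networks
  attr(net, "mode") <- mode
  net
}
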