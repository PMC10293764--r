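# Network combinatorics, grading, and best-network selection (exact vs
# brute force, greedy local optimality, tie-breaking).

test_that("count_networks is the product of candidate counts", {
  expect_equal(count_networks(c(5, 5, 5, 5, 5)), 3125)
  expect_equal(count_networks(1), 1)
  expect_equal(count_networks(c(2, 3, 4)), 24)
  expect_error(count_networks(c(2, 0)), "candidate")
})

test_that("build_network grades chains and unrelated pairs correctly", {
  chain <- tibble::tibble(peak = 1:4,
                          formula = c("C4H8+", "C3H6+", "C2H4+", "CH2+"))
  net <- build_network(chain)
  expect_equal(net$grade, 6) # 4 * 3 / 2, all pairwise consistent
  expect_equal(nrow(net$edges), net$grade)

  none <- build_network(tibble::tibble(peak = 1:2,
                                       formula = c("C2O2H2+", "C3NH7+")))
  expect_equal(none$grade, 0)

  pair <- build_network(tibble::tibble(
    peak = 1:2, formula = c("C10SO3N3H12+", "C6SO2NH6+")
  ))
  expect_equal(pair$grade, 1)
  expect_identical(pair$edges$parent_formula, "C10SO3N3H12+")
})

test_that("every edge carries a non-empty, mass-balancing neutral loss", {
  set.seed(19)
  for (i in 1:10) {
    asg <- tibble::tibble(peak = 1:5,
                          formula = vapply(1:5, function(j) random_formula(),
                                           character(1)))
    net <- build_network(asg)
    expect_lte(net$grade, 5 * 4 / 2)
    if (nrow(net$edges) > 0) {
      expect_true(all(nchar(net$edges$loss) > 0))
      expect_true(all(net$edges$loss_mass > 0))
      expect_equal(net$edges$loss,
                   neutral_loss(net$edges$parent_formula,
                                net$edges$child_formula))
    }
  }
})

test_that("grade never exceeds n(n-1)/2 over random assignments up to n = 8", {
  set.seed(29)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    asg <- tibble::tibble(
      peak = seq_len(n),
      formula = vapply(seq_len(n), function(j) random_formula(), character(1))
    )
    expect_lte(build_network(asg)$grade, n * (n - 1) / 2)
  }
})

test_that("exact selection matches brute-force enumeration on small instances", {
  set.seed(47)
  for (i in 1:30) {
    n_peaks <- sample(3:4, 1)
    cand <- purrr::map_dfr(seq_len(n_peaks), function(p) {
      k <- sample(2:4, 1)
      forms <- unique(vapply(seq_len(k), function(j) random_formula(),
                             character(1)))
      tibble::tibble(peak = p, formula = forms,
                     error_ppm = runif(length(forms), 0, 5))
    })
    expect_lte(count_networks(table(cand$peak)), 1e4)
    best <- select_best(cand, mode = "exact")
    expect_equal(best$grade, brute_best_grade(cand))
  }
})

test_that("ties are broken by grade, then total error, then formula strings", {
  # grade dominates: an inconsistent low-error pair loses to a chain
  cand <- dplyr::bind_rows(
    tibble::tibble(peak = 1, formula = c("C4H8+", "C3NH3+"),
                   error_ppm = c(5, 0.1)),
    tibble::tibble(peak = 2, formula = "C2H4+", error_ppm = 0.2)
  )
  best <- select_best(cand)
  expect_identical(best$nodes$formula[best$nodes$peak == 1], "C4H8+")

  # equal grade: lower total error wins
  cand2 <- dplyr::bind_rows(
    tibble::tibble(peak = 1, formula = c("C3H8+", "C2NH6+"),
                   error_ppm = c(1.2, 0.4)),
    tibble::tibble(peak = 2, formula = "C5O2H4+", error_ppm = 0)
  )
  best2 <- select_best(cand2)
  expect_identical(best2$nodes$formula[best2$nodes$peak == 1], "C2NH6+")
  expect_equal(best2$total_error_ppm, 0.4)

  # equal grade and error: lexicographic formula key, deterministically
  cand3 <- dplyr::bind_rows(
    tibble::tibble(peak = 1, formula = c("C2NH6+", "C3H8+"),
                   error_ppm = c(0.4, 0.4)),
    tibble::tibble(peak = 2, formula = "C5O2H4+", error_ppm = 0)
  )
  b3a <- select_best(cand3)
  b3b <- select_best(dplyr::arrange(cand3, dplyr::desc(formula)))
  expect_identical(b3a$nodes$formula[b3a$nodes$peak == 1], "C2NH6+")
  expect_identical(b3a$nodes$formula, b3b$nodes$formula)
})

test_that("exact mode over the cap errors and advises the greedy mode", {
  cand <- purrr::map_dfr(1:4, function(p) {
    tibble::tibble(peak = p,
                   formula = paste0("C", 1:10, "H", 2 * (1:10), "+"),
                   error_ppm = 1:10)
  })
  expect_error(select_best(cand, mode = "exact", cap = 100),
               "greedy", class = "fragnets_cap_error")
})

test_that("greedy selection reaches a single-swap local maximum", {
  set.seed(59)
  for (i in 1:10) {
    cand <- purrr::map_dfr(1:4, function(p) {
      forms <- unique(vapply(1:3, function(j) random_formula(),
                             character(1)))
      tibble::tibble(peak = p, formula = forms,
                     error_ppm = runif(length(forms)))
    })
    g_exact <- select_best(cand, mode = "exact")$grade
    net <- select_best(cand, mode = "greedy")
    expect_lte(net$grade, g_exact)
    # no single-candidate swap improves the grade
    for (p in unique(cand$peak)) {
      others <- net$nodes[net$nodes$peak != p, ]
      for (f in cand$formula[cand$peak == p]) {
        swapped <- dplyr::bind_rows(
          others, tibble::tibble(peak = p, formula = f, error_ppm = 0)
        )
        expect_lte(build_network(swapped)$grade, net$grade)
      }
    }
  }
})

test_that("adding a peak with a consistent candidate never lowers the grade", {
  base <- dplyr::bind_rows(
    tibble::tibble(peak = 1, formula = "C6O2NH10+", error_ppm = 1),
    tibble::tibble(peak = 2, formula = "C4ONH6+", error_ppm = 1)
  )
  g0 <- select_best(base)$grade
  extra <- dplyr::bind_rows(
    base, tibble::tibble(peak = 3, formula = "C2H4+", error_ppm = 1)
  )
  expect_gte(select_best(extra)$grade, g0)
})
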