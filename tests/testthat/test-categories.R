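test_that("categorize reproduces the five-class boundary scheme", {
  expect_equal(categorize(0.85), 5L) # highly favoured starts at 80%
  expect_equal(categorize(0.05), 1L) # unsuitable bounded above by 10%
  expect_equal(categorize(0.10), 2L) # boundary: "<10%" puts 0.10 in low use
  # all four printed boundaries, left-closed
  expect_equal(categorize(c(0.40, 0.60, 0.80)), c(3L, 4L, 5L))
  expect_equal(categorize(c(0, 1)), c(1L, 5L))
  # partition: a fine scan of [0,1] maps to exactly one class, monotonically
  f <- seq(0, 1, by = 0.001)
  k <- categorize(f)
  expect_true(all(k %in% 1:5))
  expect_true(all(diff(k) >= 0))
  expect_error(categorize(1.2), "fraction")
  expect_error(categorize(-0.1), "fraction")
})

test_that("suitable fractions per stratum are area-weighted", {
  # toy: 3 strata over 6 cells at two latitudes (different cell areas)
  g <- geo_grid(0, 3, 60, 62, 1)
  strata <- structure(list(
    grid = g,
    stratum = matrix(c(1, 1, 2, 2, 3, 3), 2, 3),
    zone = matrix(1, 2, 3), n_strata = 3L, n_zones = 1L,
    slice_label = "toy"), class = "strata_map")
  binary <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE), 2, 3)
  tab <- suitable_fraction_by_stratum(binary, strata)
  a_hi <- cell_area(61.5, 1) # row 1
  a_lo <- cell_area(60.5, 1) # row 2
  expect_equal(tab$fraction[tab$stratum == 1], a_hi / (a_hi + a_lo))
  expect_equal(tab$fraction[tab$stratum == 2], 1)
  expect_equal(tab$fraction[tab$stratum == 3], 0)
  expect_equal(tab$category, categorize(tab$fraction))

  # all suitable -> every fraction 1; absent stratum is logged and omitted
  tab1 <- suitable_fraction_by_stratum(matrix(TRUE, 2, 3), strata)
  expect_true(all(tab1$fraction == 1))
  strata2 <- strata; strata2$n_strata <- 5L
  expect_message(t2 <- suitable_fraction_by_stratum(binary, strata2),
                 "absent")
  expect_false(any(c(4, 5) %in% t2$stratum))

  expect_error(suitable_fraction_by_stratum(matrix(TRUE, 3, 3), strata),
               "misaligned")
})

test_that("apply_categories paints by stratum lookup", {
  g <- geo_grid(0, 4, 0, 4, 1)
  strat_m <- matrix(rep(1:4, each = 4), 4, 4)
  strat_m[1, 1] <- NA
  strata <- structure(list(grid = g, stratum = strat_m,
                           zone = matrix(1, 4, 4),
                           n_strata = 4L, n_zones = 1L),
                      class = "strata_map")
  tab <- data.frame(stratum = 1:4, fraction = c(0.05, 0.5, 0.85, 0.2))
  tab$category <- categorize(tab$fraction)
  cm <- apply_categories(strata, tab)
  # cellwise recomputation
  for (i in 1:4) for (j in 1:4) {
    s <- strat_m[i, j]
    if (is.na(s)) expect_true(is.na(cm$codes[i, j]))
    else expect_equal(cm$codes[i, j], categorize(tab$fraction[s]))
  }
  # constant-stratum map -> constant category map
  strata$stratum[] <- 2
  cm2 <- apply_categories(strata, tab)
  expect_true(all(cm2$codes == 3))
  # missing stratum errors with ids
  strata$stratum[] <- 9
  expect_error(apply_categories(strata, tab), "9")
})

test_that("ensemble combination: unanimity, adjacent ties, uncertainty", {
  as_map <- function(...) make_cat_map(matrix(c(...), 1, 1))
  comb <- function(members) combine_ensemble(lapply(members, as_map))$codes[1, 1]

  # unanimity (9 members)
  expect_equal(comb(rep(4, 9)), 4)
  # split agreement between adjacent categories -> joint class
  expect_equal(comb(c(rep(4, 4), rep(5, 4), 3)), 45)
  expect_equal(category_labels(45), "favoured/highly favoured")
  # split between very different suitabilities -> uncertain
  expect_equal(comb(c(rep(4, 4), rep(1, 4), 3)), 99)
  # >= 3-way tie -> uncertain
  expect_equal(comb(c(1, 2, 3)), 99)

  # exhaustive two-member enumeration: all 25 ordered pairs
  for (a in 1:5) for (b in 1:5) {
    got <- comb(c(a, b))
    want <- if (a == b) a
    else if (abs(a - b) == 1) 10 * min(a, b) + max(a, b)
    else 99
    expect_equal(got, want)
  }

  # identity for a single map; permutation invariance
  m <- make_cat_map(matrix(c(1, 3, 5, 2), 2, 2))
  expect_equal(combine_ensemble(list(m))$codes, m$codes)
  trio <- list(make_cat_map(matrix(c(1, 3, 5, 2), 2, 2)),
               make_cat_map(matrix(c(2, 3, 4, 2), 2, 2)),
               make_cat_map(matrix(c(1, 4, 4, 3), 2, 2)))
  expect_equal(combine_ensemble(trio)$codes,
               combine_ensemble(rev(trio))$codes)
  expect_error(combine_ensemble(list()), "at least one")
  # members must be base maps
  expect_error(combine_ensemble(list(as_map(45))), "base categories")
})

test_that("collapse table is applied verbatim and idempotently", {
  m <- make_cat_map(matrix(c(45, 34, 23, 13, 1, 5, 99, 12), 2, 4))
  out <- collapse_classes(m)
  expect_equal(out$codes[1, 1], 5) # highly favoured/favoured -> highly fav.
  expect_equal(out$codes[2, 1], 4) # favoured/utilised -> favoured
  expect_equal(out$codes[1, 2], 3) # low use/utilised -> utilised
  expect_equal(out$codes[2, 2], 2) # unsuitable/utilised -> low use
  # base categories and uncertain pass through
  expect_equal(out$codes[1, 3], 1)
  expect_equal(out$codes[2, 3], 5)
  expect_equal(out$codes[1, 4], 99)
  # the unprinted joint "unsuitable/low use" passes through unchanged
  expect_equal(out$codes[2, 4], 12)
  # idempotence
  expect_equal(collapse_classes(out)$codes, out$codes)
  # unknown class label errors
  bad <- make_cat_map(matrix(c(47, 1, 1, 1), 2, 2))
  expect_error(collapse_classes(bad), "unknown category")
})
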