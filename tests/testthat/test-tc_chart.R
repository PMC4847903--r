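test_that("forward mixture model reproduces published cell-line endpoints", {
  # pure stroma gives r = 1 regardless of tumor copy numbers
  for (p in list(tumor_cell_params(2, 4), tumor_cell_params(8, 1),
                 tumor_cell_params(4.15, 23.61)))
    expect_equal(forward_ratio(p, 0), 1)
  # pure tumor gives B/A: published DISH-derived values
  expect_equal(round(forward_ratio(tumor_cell_params(2.05, 4.25), 1), 2), 2.07)
  expect_equal(round(forward_ratio(tumor_cell_params(4.15, 23.61), 1), 2), 5.69)
  # undefined denominator: pure tumor with no CEP17 copies
  expect_error(forward_ratio(tumor_cell_params(0, 5), 1), "denominator")
})

test_that("boundary curves reduce to the published closed forms", {
  x <- seq(0, 1, by = 0.05)
  expect_equal(boundary_ratio(x, 2), x + 1)
  expect_equal(boundary_ratio(x, 8), (7 * x + 1) / (3 * x + 1))
  expect_equal(boundary_ratio(0.5, 8), 1.8)
  expect_error(boundary_ratio(0.5, 1.5), "A >= 2")
})

test_that("boundary curves converge exactly at (0,1) and (1,2)", {
  for (A in c(2, 3.7, 8, 20)) {
    expect_identical(boundary_ratio(0, A), 1)
    expect_identical(boundary_ratio(1, A), 2)
  }
})

test_that("boundary is monotone in A and in x", {
  x <- seq(0.05, 0.95, by = 0.05)
  a_grid <- seq(2, 8, by = 0.5)
  for (xi in x) {
    vals <- boundary_ratio(xi, a_grid)
    expect_true(all(diff(vals) >= 0))
  }
  for (A in a_grid)
    expect_true(all(diff(boundary_ratio(x, A)) > 0))
})

test_that("classification reproduces the published biopsy areas", {
  cases <- biopsy_fixture()
  got <- tc_classify(cases$r, cases$x)
  expect_equal(as.character(got$label),
               toupper(cases$published_area))
  expect_equal(sum(got$label == "POSITIVE"), 5L)
  expect_equal(sum(got$label == "EQUIVOCAL"), 6L)
  # a ratio below 1 is negative for any tumor content
  expect_equal(as.character(tc_classify(0.90, 0.30)$label), "NEGATIVE")
})

test_that("tumor content below the floor returns UNDETERMINED with warning", {
  expect_warning(got <- tc_classify(1.5, 0.01), "UNDETERMINED")
  expect_equal(as.character(got$label), "UNDETERMINED")
  # at the default floor 0.05 a call is still made
  expect_silent(got2 <- tc_classify(1.10, 0.087))
  expect_equal(as.character(got2$label), "EQUIVOCAL")
})

test_that("classification partitions the strip: exactly one label per point", {
  set.seed(11)
  r <- exp(runif(500, log(0.2), log(40)))
  x <- runif(500, 0.05, 1)
  got <- tc_classify(r, x)
  expect_false(any(is.na(got$label)))
  agree <- ifelse(r < got$boundary_low, "NEGATIVE",
                  ifelse(r >= got$boundary_high, "POSITIVE", "EQUIVOCAL"))
  expect_equal(as.character(got$label), agree)
})

test_that("mixture inversion reproduces published per-cell estimates", {
  expect_equal(round(estimate_ba_ratio(28.25, 0.414, 64 / 20), 2), 52.36)
  expect_equal(round(estimate_ba_ratio(1.49, 0.264, 60 / 20), 2), 2.40)
  expect_equal(round(estimate_ba_ratio(2.38, 0.517, 48 / 20), 2), 3.45)
  expect_equal(round(estimate_ba_ratio(1.95, 0.531, 62 / 20), 2), 2.49)
  # pure tumor: inversion is the measured ratio itself
  expect_equal(estimate_ba_ratio(3.3, 1, 5), 3.3)
  expect_error(estimate_ba_ratio(2, 0, 3), "x = 0|\\(0, 1\\]")
})

test_that("pure-tumor estimate B' = r * A matches published values", {
  expect_equal(round(estimate_b_prime(5.69, 4.15), 2), 23.61)
  expect_equal(round(estimate_b_prime(28.25, 3.2), 1), 90.4)
  expect_equal(estimate_b_prime(1, 2), 2)
})

test_that("inversion is the exact algebraic inverse of the forward model", {
  set.seed(7)
  A <- runif(2500, 0.5, 20)
  B <- runif(2500, 0, 100)
  x <- runif(2500, .Machine$double.eps, 1)
  for (i in seq_len(2500)) {
    r <- forward_ratio(tumor_cell_params(A[i], B[i]), x[i])
    if (r <= 0) next  # inversion domain requires a positive measured ratio
    expect_equal(estimate_ba_ratio(r, x[i], A[i]), B[i] / A[i],
                 tolerance = 1e-9)
  }
})

test_that("boundary theorem: the chart never miscalls a clear truth", {
  # brute force over the admissible grid: no B/A < 2 point is POSITIVE and
  # no B/A >= 2 point is NEGATIVE, for any A in [2, 8]
  a_grid <- seq(2, 8, by = 0.5)
  x_grid <- seq(0.05, 1, by = 0.05)
  ba_low <- seq(0.1, 1.99, by = 0.1)
  ba_high <- seq(2, 10, by = 0.5)
  for (A in a_grid) {
    for (ba in ba_low) {
      r <- forward_ratio(tumor_cell_params(A, ba * A), x_grid)
      labels <- tc_classify(r, x_grid)$label
      expect_false(any(labels == "POSITIVE"),
                   info = sprintf("A=%g B/A=%g", A, ba))
    }
    for (ba in ba_high) {
      r <- forward_ratio(tumor_cell_params(A, ba * A), x_grid)
      labels <- tc_classify(r, x_grid)$label
      expect_false(any(labels == "NEGATIVE"),
                   info = sprintf("A=%g B/A=%g", A, ba))
    }
  }
})

test_that("chart curves pass through the convergence points", {
  cfg <- tc_chart_config()
  curves <- chart_curves(cfg, a_values = c(3, 5), n_points = 11L)
  for (lab in unique(curves$curve)) {
    sub <- curves[curves$curve == lab, ]
    expect_equal(sub$r[sub$x == 0], 1, tolerance = 1e-12)
    expect_equal(sub$r[sub$x == 1], 2, tolerance = 1e-12)
  }
  two_pt <- chart_curves(cfg, n_points = 2L)
  expect_equal(sort(unique(two_pt$x)), c(0, 1))
  expect_error(chart_curves(cfg, a_values = 1.5), "A >= 2")
})

test_that("configuration guards its domain", {
  expect_error(tc_chart_config(a_min = 1), "a_min")
  expect_error(tc_chart_config(a_min = 5, a_max = 4), "a_min")
  cfg <- tc_chart_config(a_min = 2, a_max = 6)
  expect_equal(cfg$normal_copy, 2)
  got <- tc_classify(1.75, 0.5, cfg)  # boundary at A=6: 2 - 1/(4*0.5+2)... re-derive
  expect_equal(got$boundary_high, boundary_ratio(0.5, 6))
})
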