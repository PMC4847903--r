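test_that("expected concentrations follow the mixture and loading density", {
  stroma_only <- simulation_config(tumor_cell_params(5, 9), x = 0,
                                   cells_per_chamber = 0.25)
  expect_equal(unname(expected_lambdas(stroma_only)), c(0.5, 0.5))
  pure <- simulation_config(tumor_cell_params(2, 4), x = 1,
                            cells_per_chamber = 0.25)
  expect_equal(expected_lambdas(pure), c(target = 1.0, reference = 0.5))
})

test_that("expected-lambda ratio equals the forward model for random truths", {
  set.seed(5)
  for (i in 1:50) {
    p <- tumor_cell_params(runif(1, 1, 10), runif(1, 0, 40))
    cfg <- simulation_config(p, x = runif(1), cells_per_chamber = runif(1, 0.05, 1))
    lam <- expected_lambdas(cfg)
    expect_equal(unname(lam["target"] / lam["reference"]),
                 forward_ratio(p, cfg$x))
  }
})

test_that("panel simulation is seeded, deterministic, and degenerate at 0", {
  cfg <- simulation_config(tumor_cell_params(2, 4), x = 1, seed = 99L)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$target$positive, b$target$positive)
  expect_identical(a$reference$positive, b$reference$positive)
  # zero loading: no chamber can light up
  empty <- simulate_panel(simulation_config(tumor_cell_params(0, 0), x = 1,
                                            cells_per_chamber = 1e-12,
                                            seed = 1L))
  expect_equal(empty$target$positive, 0L)
  expect_warning(
    simulate_panel(simulation_config(tumor_cell_params(2, 200), x = 1,
                                     cells_per_chamber = 0.5, seed = 1L)),
    "saturation")
})

test_that("quantification recovers the known ratio from simulated counts", {
  # truth B/A = 2 at lambda_ref = 0.5, pooled over 100 panels (77,000
  # chambers); the estimate stays within 2.5% of 2 in at least 95% of
  # seeded replicates
  within <- vapply(1:1000, function(seed) {
    cfg <- simulation_config(tumor_cell_params(2, 4), x = 1,
                             cells_per_chamber = 0.25, n_panels = 100L,
                             seed = seed)
    counts <- simulate_panel(cfg)
    r <- dpcr_ratio(counts$target, counts$reference)$r
    abs(r - 2) / 2 <= 0.025
  }, logical(1))
  expect_gte(mean(within), 0.95)
})

test_that("ratio estimator bias is below 1% across the working range", {
  for (lam_ref in c(0.1, 0.5, 1.5)) {
    rs <- vapply(1:300, function(seed) {
      cfg <- simulation_config(tumor_cell_params(2, 4), x = 1,
                               cells_per_chamber = lam_ref / 2,
                               n_panels = 100L, seed = 7000L + seed)
      counts <- simulate_panel(cfg)
      dpcr_ratio(counts$target, counts$reference)$r
    }, numeric(1))
    expect_lt(abs(mean(rs) - 2) / 2, 0.01)
  }
})

test_that("mixture series follows the published bench validation lines", {
  h522 <- mixture_series(tumor_cell_params(2.05, 4.25),
                         fractions = c(seq(0.8, 0.1, by = -0.1), 1, 0))
  expect_equal(round(h522$expected_r[h522$tumor_fraction == 1], 2), 2.07)
  expect_equal(h522$expected_r[h522$tumor_fraction == 0], 1)
  skbr3 <- mixture_series(tumor_cell_params(4.15, 23.61), fractions = 1)
  expect_equal(round(skbr3$expected_r, 2), 5.69)
  # default series is the conventional eight volume-ratio steps
  expect_equal(mixture_series(tumor_cell_params(2, 2))$tumor_fraction,
               seq(0.8, 0.1, by = -0.1))
})

test_that("series fit recovers the per-cell HER2 copy number", {
  s <- mixture_series(tumor_cell_params(4.15, 23.61))
  expect_equal(fit_b_prime_series(s$tumor_fraction, s$expected_r, A = 4.15),
               23.61, tolerance = 1e-9)
  # single pure-tumor observation reduces to B' = r * A
  expect_equal(fit_b_prime_series(1, 5.69, A = 4.15),
               estimate_b_prime(5.69, 4.15))
  expect_error(fit_b_prime_series(c(0, 0), c(1, 1), A = 2), "unidentifiable")
})

test_that("series fit is nearly unbiased under measurement noise", {
  truth <- tumor_cell_params(4.15, 23.61)
  s <- mixture_series(truth)
  set.seed(2016)
  fits <- vapply(1:1000, function(i) {
    r_obs <- s$expected_r + rnorm(length(s$expected_r), 0, 0.05)
    fit_b_prime_series(s$tumor_fraction, r_obs, A = truth$A)
  }, numeric(1))
  expect_lt(abs(mean(fits) - truth$B) / truth$B, 0.02)
})

test_that("end-to-end label recovery is reliable for separated truths", {
  # B/A = 1 vs B/A = 4 at x = 0.5, pooled 77,000 chambers
  labels <- vapply(1:200, function(seed) {
    neg_cfg <- simulation_config(tumor_cell_params(2, 2), x = 0.5,
                                 n_panels = 100L, seed = seed)
    pos_cfg <- simulation_config(tumor_cell_params(2, 8), x = 0.5,
                                 n_panels = 100L, seed = 100000L + seed)
    neg <- simulate_panel(neg_cfg)
    pos <- simulate_panel(pos_cfg)
    r_neg <- dpcr_ratio(neg$target, neg$reference)$r
    r_pos <- dpcr_ratio(pos$target, pos$reference)$r
    as.character(tc_classify(r_neg, 0.5)$label) == "NEGATIVE" &&
      as.character(tc_classify(r_pos, 0.5)$label) == "POSITIVE"
  }, logical(1))
  expect_gte(mean(labels), 0.99)
})

test_that("simulated sample sheets drive the whole pipeline", {
  cfgs <- list(
    simulation_config(tumor_cell_params(2, 2), x = 0.6, n_panels = 10L,
                      seed = 41L),
    simulation_config(tumor_cell_params(2, 10), x = 0.6, n_panels = 10L,
                      seed = 42L))
  path <- withr::local_tempfile(fileext = ".csv")
  simulate_sample_sheet(cfgs, path)
  report <- run_pipeline(read_sample_sheet(path))
  expect_equal(report$tc_label, c("NEGATIVE", "POSITIVE"))
})
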