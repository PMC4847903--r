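# Seeded chamber-count simulator.
#
# Ground truth is a tumor/stroma mixture (per-cell copy numbers A, B; tumor
# content x) loaded onto a partitioned array at a mean of m cell-genome
# equivalents per chamber. Copies of each locus land in chambers as
# independent Poisson counts, a chamber is positive iff it received at least
# one copy, and chambers are independent — the standard digital-PCR occupancy
# model — so positive counts are Binomial(N, 1 - exp(-lambda)). The expected
# per-chamber copy concentrations are
#
#   lambda_reference = m (A x + 2 (1 - x)),   lambda_target = m (B x + 2 (1 - x)),
#
# whose ratio equals the forward mixture model exactly.

#' Simulation configuration
#'
#' Bundles the ground truth and array geometry for chamber-count simulation.
#' The default loading density of 0.25 genome equivalents per chamber puts
#' reference-locus occupancy near lambda = 0.5 for diploid material, the
#' "0-1 molecules per chamber" regime digital arrays are run in and the
#' magnitude observed on real 770-chamber panels (lambda roughly 0.3-1.8).
#'
#' @param params A [tumor_cell_params()]: the true per-cell copy numbers.
#' @param x True tumor content ratio in `[0, 1]`.
#' @param cells_per_chamber Mean cell-genome equivalents loaded per chamber,
#'   `m > 0` (default 0.25).
#' @param total_chambers Chambers per panel (default 770).
#' @param n_panels Panels per assay; counts are pooled over
#'   `total_chambers * n_panels` chambers (default 1).
#' @param seed Integer seed for the random stream; `NULL` uses the current
#'   stream. A single seed governs all randomness — no hidden entropy.
#' @return An object of class `"simulation_config"`.
#' @examples
#' simulation_config(tumor_cell_params(2, 4), x = 1, seed = 1)
#' @export
simulation_config <- function(params, x, cells_per_chamber = 0.25,
                              total_chambers = 770L, n_panels = 1L,
                              seed = NULL) {
  stopifnot(inherits(params, "tumor_cell_params"))
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop("tumor content 'x' must be a single value in [0, 1]", call. = FALSE)
  if (!is.finite(cells_per_chamber) || cells_per_chamber <= 0)
    stop("'cells_per_chamber' must be positive", call. = FALSE)
  if (!is.finite(total_chambers) || total_chambers < 1 ||
        total_chambers != round(total_chambers))
    stop("'total_chambers' must be a positive integer", call. = FALSE)
  if (!is.finite(n_panels) || n_panels < 1 || n_panels != round(n_panels))
    stop("'n_panels' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(params = params, x = x,
                 cells_per_chamber = cells_per_chamber,
                 total_chambers = as.integer(total_chambers),
                 n_panels = as.integer(n_panels),
                 seed = seed),
            class = "simulation_config")
}

#' Expected per-chamber concentrations under a simulation configuration
#'
#' @param config A [simulation_config()].
#' @return Named numeric vector `c(target = , reference = )` of expected
#'   mean copies per chamber. Their ratio equals
#'   `forward_ratio(config$params, config$x)` exactly.
#' @examples
#' expected_lambdas(simulation_config(tumor_cell_params(2, 4), x = 1))
#' @export
expected_lambdas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$cells_per_chamber
  x <- config$x
  stroma <- 2 * (1 - x)
  c(target = m * (config$params$B * x + stroma),
    reference = m * (config$params$A * x + stroma))
}

#' Simulate pooled chamber counts for a target/reference assay pair
#'
#' Draws positive-chamber counts `k ~ Binomial(N * n_panels, 1 - exp(-lambda))`
#' for the target and reference assays from the configuration's seeded
#' stream. Reproducible: the same configuration and seed give identical
#' counts.
#'
#' @param config A [simulation_config()].
#' @return A list with `target` and `reference` [panel_count()]s pooled over
#'   all panels.
#' @examples
#' simulate_panel(simulation_config(tumor_cell_params(2, 4), x = 1, seed = 7))
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lam <- expected_lambdas(config)
  p_pos <- 1 - exp(-lam)
  if (any(p_pos > 0.999))
    warning("loading density gives a saturation probability above 0.999 ",
            "for the ", paste(names(lam)[p_pos > 0.999], collapse = " and "),
            " assay; quantification will likely fail downstream",
            call. = FALSE)
  n_total <- config$total_chambers * config$n_panels
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- stats::rbinom(2L, n_total, p_pos)
  list(target = panel_count(k[1], n_total, panel = "simulated target"),
       reference = panel_count(k[2], n_total, panel = "simulated reference"))
}

#' Expected ratios along a stepwise DNA mixture series
#'
#' Emulates the bench validation in which genomic DNA of a tumor line is
#' mixed stepwise with diploid lymphoblastoid (LCL) DNA: the DNA mass
#' fraction of the tumor line plays the role of the tumor content ratio and
#' the expected measured ratio at each step is the forward mixture model.
#' (Mass fraction and cell fraction differ for aneuploid genomes; treating
#' the volume ratio as `x` is the convention the bench series uses and is
#' adopted here as a documented approximation.)
#'
#' @param params A [tumor_cell_params()] for the tumor line.
#' @param fractions Tumor DNA mass fractions in `[0, 1]`; defaults to the
#'   conventional eight-step series 0.8, 0.7, ..., 0.1.
#' @return A data frame with columns `tumor_fraction` and `expected_r`.
#' @examples
#' mixture_series(tumor_cell_params(2.05, 4.25))
#' @export
mixture_series <- function(params, fractions = seq(0.8, 0.1, by = -0.1)) {
  stopifnot(inherits(params, "tumor_cell_params"))
  if (any(!is.finite(fractions) | fractions < 0 | fractions > 1))
    stop("'fractions' must lie in [0, 1]", call. = FALSE)
  data.frame(tumor_fraction = fractions,
             expected_r = forward_ratio(params, fractions))
}

#' Fit the per-cell HER2 copy number to a mixture series
#'
#' Least-squares estimate of `B` from observed `(fraction, r)` pairs at known
#' per-cell CEP17 copy number `A`, extending the single-point pure-tumor
#' inversion `B' = r A` to a whole dilution series. Linearizing the mixture
#' model as `r (A x + 2 (1 - x)) = B x + 2 (1 - x)` makes the problem linear
#' in `B` with the closed form
#' `B = sum(x_i y_i) / sum(x_i^2)`, `y_i = r_i (A x_i + 2 (1 - x_i)) - 2 (1 - x_i)`.
#'
#' @param fractions Tumor DNA mass fractions in `[0, 1]`; at least one must
#'   be positive (a series observed only at fraction 0 carries no
#'   information about `B`).
#' @param r Observed ratios, same length as `fractions`.
#' @param A Known per-cell CEP17 copy number (`>= 2`).
#' @return The fitted `B` (scalar). For a single observation at fraction 1
#'   this equals `estimate_b_prime(r, A)`.
#' @examples
#' s <- mixture_series(tumor_cell_params(4.15, 23.61))
#' fit_b_prime_series(s$tumor_fraction, s$expected_r, A = 4.15)  # 23.61
#' @export
fit_b_prime_series <- function(fractions, r, A) {
  if (length(fractions) != length(r) || length(fractions) == 0L)
    stop("'fractions' and 'r' must be non-empty and of equal length",
         call. = FALSE)
  if (any(!is.finite(fractions) | fractions < 0 | fractions > 1))
    stop("'fractions' must lie in [0, 1]", call. = FALSE)
  if (length(A) != 1L || !is.finite(A) || A < 2)
    stop("'A' must be a single value >= 2", call. = FALSE)
  if (all(fractions == 0))
    stop("all fractions are 0: B is unidentifiable from pure stroma",
         call. = FALSE)
  stroma <- 2 * (1 - fractions)
  y <- r * (A * fractions + stroma) - stroma
  sum(fractions * y) / sum(fractions^2)
}

#' Write simulated runs as a sample sheet
#'
#' Simulates chamber counts for each configuration and writes them in the
#' CSV dialect consumed by [read_sample_sheet()], so the full quantification
#' and classification pipeline can be exercised end to end on synthetic data.
#'
#' @param configs A list of [simulation_config()]s (or a single one); each
#'   becomes one sample whose true tumor content is carried in the `x`
#'   column.
#' @param path File to write; `.tsv` extension selects tab separation.
#' @param sample_ids Optional character vector of sample names; defaults to
#'   `sim_1`, `sim_2`, ...
#' @return Invisibly, the data frame written.
#' @examples
#' cfg <- simulation_config(tumor_cell_params(2, 8), x = 0.5, seed = 3)
#' path <- tempfile(fileext = ".csv")
#' simulate_sample_sheet(cfg, path)
#' read_sample_sheet(path)
#' @export
simulate_sample_sheet <- function(configs, path, sample_ids = NULL) {
  if (inherits(configs, "simulation_config")) configs <- list(configs)
  stopifnot(length(configs) > 0L,
            all(vapply(configs, inherits, logical(1), "simulation_config")))
  if (is.null(sample_ids)) sample_ids <- paste0("sim_", seq_along(configs))
  rows <- lapply(seq_along(configs), function(i) {
    counts <- simulate_panel(configs[[i]])
    data.frame(sample_id = sample_ids[i],
               target_positive = counts$target$positive,
               reference_positive = counts$reference$positive,
               total_chambers = counts$target$total,
               x = configs[[i]]$x)
  })
  sheet <- do.call(rbind, rows)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(sheet, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(sheet)
}
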