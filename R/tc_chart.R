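# The Tumor Content (TC) chart: a tumor/stroma mixture model for bulk
# copy-number ratios.
#
# A clinical specimen is a mixture of cancer cells (tumor content ratio x,
# the fraction of nucleated cells that are cancerous) carrying A copies of
# the CEP17 reference locus and B copies of HER2 per cell, and diploid
# stromal cells carrying 2 copies of each. The bulk HER2/CEP17 ratio measured
# by digital PCR is then
#
#     r = (B x + 2 (1 - x)) / (A x + 2 (1 - x)).
#
# Amplification is defined per cell as B/A >= 2. Because A is unknown without
# in situ hybridization but is empirically confined to [2, 8] in gastric
# cancer, the B/A = 2 iso-curves at the extreme A values partition the (x, r)
# plane into a negative area (below r = x + 1, where B/A < 2 for every
# admissible A), a positive area (at or above r = (7x + 1)/(3x + 1), where
# B/A >= 2 for every admissible A), and an equivocal band between them.

#' Per-cancer-cell copy numbers
#'
#' Bundles the per-cell CEP17 copy number `A` and HER2 copy number `B` of the
#' (assumed homogeneous) cancer-cell population.
#'
#' @param A CEP17 copies per cancer cell (non-negative).
#' @param B HER2 copies per cancer cell (non-negative).
#' @return An object of class `"tumor_cell_params"`.
#' @examples
#' tumor_cell_params(A = 2.05, B = 4.25)
#' @export
tumor_cell_params <- function(A, B) {
  if (length(A) != 1L || length(B) != 1L)
    stop("'A' and 'B' must be single values", call. = FALSE)
  if (!is.finite(A) || A < 0) stop("'A' must be >= 0", call. = FALSE)
  if (!is.finite(B) || B < 0) stop("'B' must be >= 0", call. = FALSE)
  structure(list(A = A, B = B), class = "tumor_cell_params")
}

#' @export
print.tumor_cell_params <- function(x, ...) {
  cat(sprintf("Per-cancer-cell copy numbers: CEP17 A = %g, HER2 B = %g (B/A = %.3g)\n",
              x$A, x$B, if (x$A > 0) x$B / x$A else NA_real_))
  invisible(x)
}

#' TC chart configuration
#'
#' Holds the decision-boundary parameters of the TC chart. The per-cell CEP17
#' copy number `A` of a specimen is generally unknown; the chart brackets it
#' by `a_min` and `a_max`. Defaults are 2 (diploid) and 8 (above the maximum
#' observed clinically, with a safety margin). Stromal cells are fixed at two
#' copies of each locus; the boundary derivations hard-code diploid stroma,
#' so this is not configurable.
#'
#' @param a_min Lower bound on per-cell CEP17 copies; the negative boundary
#'   is the B/A = 2 iso-curve at this value. Must satisfy `2 <= a_min < a_max`.
#' @param a_max Upper bound on per-cell CEP17 copies; the positive boundary
#'   is the iso-curve at this value.
#' @param x_floor Minimum tumor content ratio for a confident call (default
#'   0.05). Below it the equivocal band collapses toward the point (0, 1) and
#'   classification returns `UNDETERMINED` with a warning.
#' @return An object of class `"tc_chart_config"`.
#' @examples
#' tc_chart_config()
#' tc_chart_config(a_max = 6)  # tighter bracket if aneusomy is known mild
#' @export
tc_chart_config <- function(a_min = 2, a_max = 8, x_floor = 0.05) {
  if (!is.finite(a_min) || !is.finite(a_max) || a_min < 2 || a_min >= a_max)
    stop("'a_min' and 'a_max' must satisfy 2 <= a_min < a_max", call. = FALSE)
  if (!is.finite(x_floor) || x_floor < 0 || x_floor > 1)
    stop("'x_floor' must be in [0, 1]", call. = FALSE)
  structure(list(a_min = a_min, a_max = a_max, x_floor = x_floor,
                 normal_copy = 2),
            class = "tc_chart_config")
}

#' @export
print.tc_chart_config <- function(x, ...) {
  cat(sprintf(paste0(
    "TC chart configuration: CEP17 bracket A in [%g, %g], diploid stroma,\n",
    "  undetermined below tumor content x = %g\n"),
    x$a_min, x$a_max, x$x_floor))
  invisible(x)
}

tc_labels <- c("NEGATIVE", "EQUIVOCAL", "POSITIVE", "UNDETERMINED")

#' Forward mixture model: bulk ratio from per-cell copy numbers
#'
#' Evaluates the tumor/stroma mixture model
#' \deqn{r = \frac{B x + 2 (1 - x)}{A x + 2 (1 - x)}}
#' for a specimen with tumor content ratio `x` whose cancer cells carry `A`
#' CEP17 and `B` HER2 copies and whose stromal cells are diploid. At `x = 0`
#' (pure stroma) the ratio is 1 for any copy numbers; at `x = 1` (pure tumor)
#' it is `B/A`.
#'
#' @param params A [tumor_cell_params()].
#' @param x Tumor content ratio(s) in `[0, 1]`; vectorized.
#' @return Numeric vector of expected bulk HER2/CEP17 ratios.
#' @examples
#' forward_ratio(tumor_cell_params(2.05, 4.25), x = 1)   # 2.07
#' forward_ratio(tumor_cell_params(4.15, 23.61), x = 1)  # 5.69
#' @export
forward_ratio <- function(params, x) {
  stopifnot(inherits(params, "tumor_cell_params"))
  if (any(!is.finite(x) | x < 0 | x > 1))
    stop("tumor content 'x' must lie in [0, 1]", call. = FALSE)
  denom <- params$A * x + 2 * (1 - x)
  if (any(denom <= 0))
    stop("mixture denominator A*x + 2*(1 - x) is not positive ",
         "(pure tumor with zero CEP17 copies?)", call. = FALSE)
  (params$B * x + 2 * (1 - x)) / denom
}

#' Decision-boundary curve of the TC chart
#'
#' The B/A = 2 iso-curve at per-cell CEP17 copy number `A`:
#' \deqn{r(x; A) = 2 - \frac{2 (1 - x)}{(A - 2) x + 2}.}
#' At `A = 2` it reduces to the straight line `r = x + 1` (the negative
#' boundary); at `A = 8` to `r = (7x + 1)/(3x + 1)` (the positive boundary).
#' Every curve passes through (0, 1) and (1, 2) and is non-decreasing in `A`
#' at fixed `x`.
#'
#' @param x Tumor content ratio(s) in `[0, 1]`; vectorized.
#' @param A Per-cell CEP17 copy number, `A >= 2` (the derivation's domain);
#'   vectorized (recycled against `x`).
#' @return Numeric vector of boundary ratios.
#' @examples
#' boundary_ratio(0.5, A = 2)  # 1.5, the line x + 1
#' boundary_ratio(0.5, A = 8)  # 1.8, the curve (7x+1)/(3x+1)
#' @export
boundary_ratio <- function(x, A) {
  if (any(!is.finite(x) | x < 0 | x > 1))
    stop("tumor content 'x' must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(A) | A < 2))
    stop("boundary curves are defined for CEP17 copy number A >= 2",
         call. = FALSE)
  2 - 2 * (1 - x) / ((A - 2) * x + 2)
}

#' Classify samples on the TC chart
#'
#' Places measured points (`r`, `x`) into the amplification areas of the TC
#' chart: `NEGATIVE` below the lower boundary (`r < r(x; a_min)`, so B/A < 2
#' for every admissible A), `POSITIVE` at or above the upper boundary
#' (`r >= r(x; a_max)`, so B/A >= 2 for every admissible A), and `EQUIVOCAL`
#' in the half-open band between them, where the call depends on the unknown
#' per-cell CEP17 copy number. Samples with tumor content below
#' `config$x_floor` are returned as `UNDETERMINED` with a warning: as `x`
#' approaches 0 both boundaries collapse to `r = 1` and no meaningful call
#' exists.
#'
#' @param r Measured HER2/CEP17 copy-number ratio(s), positive; vectorized.
#' @param x Tumor content ratio(s) in `[0, 1]`, recycled against `r`.
#' @param config A [tc_chart_config()].
#' @return A data frame of class `"tc_classification"` with one row per
#'   sample and columns `r`, `x`, `label` (factor with levels `NEGATIVE`,
#'   `EQUIVOCAL`, `POSITIVE`, `UNDETERMINED`), `boundary_low` and
#'   `boundary_high` (the two boundary curves evaluated at the sample's `x`).
#' @examples
#' tc_classify(r = c(2.38, 1.39, 0.90), x = c(0.517, 0.341, 0.30))
#' @export
tc_classify <- function(r, x, config = tc_chart_config()) {
  stopifnot(inherits(config, "tc_chart_config"))
  if (any(!is.finite(r) | r <= 0))
    stop("measured ratio 'r' must be positive", call. = FALSE)
  if (any(!is.finite(x) | x < 0 | x > 1))
    stop("tumor content 'x' must lie in [0, 1]", call. = FALSE)
  n <- max(length(r), length(x))
  r <- rep_len(r, n)
  x <- rep_len(x, n)
  low <- boundary_ratio(x, config$a_min)
  high <- boundary_ratio(x, config$a_max)
  # half-open band (low <= r < high), with ties going to the less-negative
  # category; comparisons carry a relative tolerance so points that sit on a
  # boundary algebraically are not pushed across it by floating-point error
  eps <- 1e-9 * pmax(1, r)
  label <- ifelse(r < low - eps, "NEGATIVE",
                  ifelse(r >= high - eps, "POSITIVE", "EQUIVOCAL"))
  undetermined <- x < config$x_floor
  if (any(undetermined)) {
    label[undetermined] <- "UNDETERMINED"
    warning(sum(undetermined), " sample(s) with tumor content below ",
            config$x_floor,
            " returned UNDETERMINED: the decision band collapses toward ",
            "(0, 1) and no confident call is possible", call. = FALSE)
  }
  structure(
    data.frame(r = r, x = x,
               label = factor(label, levels = tc_labels),
               boundary_low = low, boundary_high = high),
    class = c("tc_classification", "data.frame")
  )
}

#' Invert the mixture model for the per-cell copy-number ratio
#'
#' Given a measured bulk ratio `r`, tumor content `x`, and a per-cell CEP17
#' copy number `A` (typically the average CEP17 signal count per nucleus from
#' DISH), solves the mixture model for the per-cell HER2/CEP17 ratio:
#' \deqn{B/A = r + \frac{2 (r - 1)(1 - x)}{A x}.}
#' This is the exact algebraic inverse of [forward_ratio()] at known `A`.
#' At `x = 1` it reduces to `B/A = r`.
#'
#' @param r Measured bulk HER2/CEP17 ratio(s), positive; vectorized.
#' @param x Tumor content ratio(s) in `(0, 1]`; `x = 0` carries no tumor
#'   signal and is an error.
#' @param A Per-cell CEP17 copy number(s), positive.
#' @return Numeric vector of estimated per-cell B/A ratios.
#' @examples
#' estimate_ba_ratio(r = 28.25, x = 0.414, A = 3.2)  # 52.36
#' @export
estimate_ba_ratio <- function(r, x, A) {
  if (any(!is.finite(r) | r <= 0))
    stop("measured ratio 'r' must be positive", call. = FALSE)
  if (any(!is.finite(x) | x <= 0 | x > 1))
    stop("inversion requires tumor content 'x' in (0, 1]; x = 0 carries ",
         "no tumor signal to invert", call. = FALSE)
  if (any(!is.finite(A) | A <= 0))
    stop("per-cell CEP17 copy number 'A' must be positive", call. = FALSE)
  r + 2 * (r - 1) * (1 - x) / (A * x)
}

#' Estimated per-cell HER2 copy number under the pure-tumor convention
#'
#' The pure-tumor (`x = 1`) inversion `B' = r * A`: the per-cell HER2 copy
#' number implied by a measured ratio when the specimen is treated as pure
#' tumor. Used where DISH cannot count clustered HER2 signals directly.
#'
#' @param r Measured HER2/CEP17 ratio(s), positive.
#' @param A Per-cell CEP17 copy number(s), positive.
#' @return Numeric vector of estimated HER2 copies per cell.
#' @examples
#' estimate_b_prime(r = 5.69, A = 4.15)  # 23.61
#' @export
estimate_b_prime <- function(r, A) {
  if (any(!is.finite(r) | r <= 0))
    stop("measured ratio 'r' must be positive", call. = FALSE)
  if (any(!is.finite(A) | A <= 0))
    stop("per-cell CEP17 copy number 'A' must be positive", call. = FALSE)
  r * A
}

#' Sample the TC chart's boundary curves for plotting
#'
#' Evaluates the B/A = 2 iso-curves at the requested per-cell CEP17 copy
#' numbers, plus the two decision boundaries of `config`, on a regular grid
#' of tumor content values.
#'
#' @param config A [tc_chart_config()].
#' @param a_values Per-cell CEP17 copy numbers (all `>= 2`) for additional
#'   iso-curves; may be empty.
#' @param n_points Number of grid points per curve (`>= 2`).
#' @return A data frame with columns `x`, `r`, `curve` (a label such as
#'   `"A=4"`), and `role` (`"negative_boundary"`, `"positive_boundary"` or
#'   `"iso"`).
#' @examples
#' head(chart_curves(tc_chart_config(), a_values = 4, n_points = 5))
#' @export
chart_curves <- function(config = tc_chart_config(), a_values = numeric(),
                         n_points = 201L) {
  stopifnot(inherits(config, "tc_chart_config"))
  if (length(n_points) != 1L || !is.finite(n_points) || n_points < 2)
    stop("'n_points' must be an integer >= 2", call. = FALSE)
  if (length(a_values) && any(!is.finite(a_values) | a_values < 2))
    stop("iso-curves are defined for CEP17 copy number A >= 2", call. = FALSE)
  grid <- seq(0, 1, length.out = as.integer(n_points))
  one <- function(A, role) {
    data.frame(x = grid, r = boundary_ratio(grid, A),
               curve = sprintf("A=%g", A), role = role)
  }
  curves <- list(one(config$a_min, "negative_boundary"),
                 one(config$a_max, "positive_boundary"))
  extra <- setdiff(a_values, c(config$a_min, config$a_max))
  curves <- c(curves, lapply(extra, one, role = "iso"))
  out <- do.call(rbind, curves)
  rownames(out) <- NULL
  out
}
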