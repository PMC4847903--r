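# Digital PCR chamber-count quantification.
#
# A digital array partitions template DNA across N reaction chambers (770 per
# panel on the microfluidic arrays this package targets) at limiting dilution,
# so that each chamber holds 0-1 molecules in expectation. Counting positive
# chambers k and inverting the Poisson occupancy law gives the mean copies per
# chamber, lambda = -ln(1 - k/N), and the ratio of two such estimates for a
# target (HER2) and reference (CEP17) assay gives the bulk copy-number ratio r.

#' Positive/total chamber counts for one digital-array assay
#'
#' Constructs a validated chamber-count record for a single assay on one or
#' more pooled panels of a partitioned digital PCR array.
#'
#' @param positive Number of chambers with positive signal, `k`. Non-negative
#'   integer, at most `total`.
#' @param total Total number of reaction chambers, `N`. Positive integer;
#'   defaults to 770, one full panel of the targeted microfluidic array.
#' @param panel Optional label naming the panel or assay; used in error
#'   messages (e.g. saturation) so a failing panel can be identified.
#'
#' @return An object of class `"panel_count"`: a list with elements
#'   `positive`, `total` and `panel`.
#' @seealso [poisson_lambda()], [dpcr_ratio()], [aggregate_panels()]
#' @examples
#' panel_count(383, 770, panel = "LCL HER2")
#' @export
panel_count <- function(positive, total = 770L, panel = NULL) {
  if (length(positive) != 1L || length(total) != 1L)
    stop("'positive' and 'total' must be single values", call. = FALSE)
  if (!is.finite(positive) || !is.finite(total))
    stop("chamber counts must be finite numbers", call. = FALSE)
  if (positive != round(positive) || total != round(total))
    stop("chamber counts must be whole numbers", call. = FALSE)
  if (total <= 0)
    stop("total chambers must be a positive integer, got ", total,
         call. = FALSE)
  if (positive < 0)
    stop("positive chambers must be non-negative, got ", positive,
         call. = FALSE)
  if (positive > total)
    stop("positive chambers (", positive, ") exceed total chambers (",
         total, ")", call. = FALSE)
  structure(
    list(positive = as.integer(positive), total = as.integer(total),
         panel = panel),
    class = "panel_count"
  )
}

#' @export
print.panel_count <- function(x, ...) {
  lab <- if (is.null(x$panel)) "" else paste0(" [", x$panel, "]")
  cat(sprintf("Digital PCR panel count%s: %d positive of %d chambers\n",
              lab, x$positive, x$total))
  invisible(x)
}

panel_label <- function(count) {
  if (is.null(count$panel)) {
    sprintf("%d/%d chambers", count$positive, count$total)
  } else {
    count$panel
  }
}

#' Poisson-corrected mean copies per chamber
#'
#' Inverts the Poisson occupancy law for a partitioned digital PCR assay: with
#' molecules distributed independently across `N` chambers and a chamber
#' scored positive when it received at least one molecule, the maximum
#' likelihood estimate of the mean copies per chamber is
#' \deqn{\hat\lambda = -\ln(1 - k/N).}
#'
#' The confidence interval is a delta-method (Wald) interval on the lambda
#' scale with \eqn{Var(\hat\lambda) \approx p / (N (1 - p))}, `p = k/N`. At
#' `k = 0` the estimate and interval collapse to zero.
#'
#' @param count A [panel_count()].
#' @param conf_level Confidence level for the interval (default 0.95).
#'
#' @return An object of class `"concentration_estimate"`: a list with
#'   `lambda`, `ci_low`, `ci_high`, `conf_level` and `source` (the input
#'   `panel_count`).
#' @examples
#' poisson_lambda(panel_count(385, 770))  # half occupancy: lambda = ln 2
#' @export
poisson_lambda <- function(count, conf_level = 0.95) {
  if (!inherits(count, "panel_count"))
    count <- panel_count(count$positive, count$total, count$panel)
  k <- count$positive
  n <- count$total
  if (k == n)
    stop("panel '", panel_label(count), "' is saturated (all ", n,
         " chambers positive); lambda is unbounded and the sample must be ",
         "diluted and re-run", call. = FALSE)
  lam <- -log1p(-k / n)
  # Var(lambda-hat) = p / (N (1 - p)) = k / (N (N - k)); zero width at k = 0.
  # computed in double: N (N - k) overflows integer arithmetic on pooled runs
  se <- sqrt(k / (as.numeric(n) * (n - k)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(lambda = lam,
         ci_low = max(0, lam - z * se),
         ci_high = lam + z * se,
         conf_level = conf_level,
         source = count),
    class = "concentration_estimate"
  )
}

#' @export
print.concentration_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Mean copies per chamber: %.*f (%g%% CI %.*f-%.*f) from %s\n",
              digits, x$lambda, 100 * x$conf_level, digits, x$ci_low,
              digits, x$ci_high, panel_label(x$source)))
  invisible(x)
}

#' Target/reference copy-number ratio from chamber counts
#'
#' Computes the target-to-reference copy-number ratio
#' `r = lambda_target / lambda_reference` from the Poisson-corrected
#' per-chamber concentrations of two assays run on the same sample, e.g.
#' HER2 over CEP17. The confidence interval is obtained by the delta method
#' on `log r`, adding the squared relative standard errors of the two
#' lambda estimates.
#'
#' @param target A [panel_count()] for the target assay (HER2).
#' @param reference A [panel_count()] for the reference assay (CEP17).
#' @param conf_level Confidence level for the interval (default 0.95).
#'
#' @return An object of class `"dpcr_ratio"`: a list with `r`, `ci_low`,
#'   `ci_high`, `conf_level`, and the two `"concentration_estimate"`s as
#'   `target` and `reference`.
#' @examples
#' # reproduces the published cell-line ratio 0.95 for a diploid line
#' dpcr_ratio(panel_count(383, 770), panel_count(398, 770))
#' @export
dpcr_ratio <- function(target, reference, conf_level = 0.95) {
  ref_est <- poisson_lambda(reference, conf_level)
  if (ref_est$source$positive == 0L)
    stop("reference assay '", panel_label(ref_est$source),
         "' has no positive chambers; the copy-number ratio is undefined",
         call. = FALSE)
  tgt_est <- poisson_lambda(target, conf_level)
  r <- tgt_est$lambda / ref_est$lambda
  # delta method on log r: relative variances of the two lambdas add
  rel_var <- function(est) {
    k <- est$source$positive
    n <- est$source$total
    if (k == 0L) return(0)
    k / (as.numeric(n) * (n - k)) / est$lambda^2
  }
  se_log <- sqrt(rel_var(tgt_est) + rel_var(ref_est))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(r = r,
         ci_low = r * exp(-z * se_log),
         ci_high = r * exp(z * se_log),
         conf_level = conf_level,
         target = tgt_est,
         reference = ref_est),
    class = "dpcr_ratio"
  )
}

#' @export
print.dpcr_ratio <- function(x, ...) {
  cat(sprintf("Target/reference copy-number ratio: %.2f (%g%% CI %.2f-%.2f)\n",
              x$r, 100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Pool chamber counts across panels
#'
#' Combines several panels of the same assay into one pooled count by summing
#' positive and total chambers. At equal loading the chambers of all panels
#' are exchangeable, so pooling before a single Poisson correction is the
#' efficient estimator (as opposed to averaging per-panel lambdas).
#'
#' @param counts A list of [panel_count()] objects (or a single one).
#'
#' @return A single pooled `"panel_count"`.
#' @examples
#' aggregate_panels(list(panel_count(100, 770), panel_count(50, 770)))
#' @export
aggregate_panels <- function(counts) {
  if (inherits(counts, "panel_count")) counts <- list(counts)
  if (!is.list(counts) || length(counts) == 0L)
    stop("'counts' must be a non-empty list of panel_count objects",
         call. = FALSE)
  counts <- lapply(counts, function(p) {
    if (!inherits(p, "panel_count"))
      stop("all elements must be panel_count objects", call. = FALSE)
    p
  })
  labels <- unique(unlist(lapply(counts, function(p) p$panel)))
  panel_count(
    sum(vapply(counts, function(p) p$positive, integer(1))),
    sum(vapply(counts, function(p) p$total, integer(1))),
    panel = if (length(labels) == 1L) labels else NULL
  )
}
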