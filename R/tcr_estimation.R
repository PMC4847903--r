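# Tumor content ratio (TCR) estimation from nucleus counts.
#
# TCR is the fraction of nucleated cells in the examined region that are
# cancer cells. Production pipelines obtain it by image analysis of an
# H&E-stained section, separating cancerous from non-cancerous nuclei by
# nucleus size (cancer nuclei are enlarged). Here that step is a simple
# size-threshold classifier on a tabulated nucleus-size feature, with Otsu's
# two-class variance criterion as the automatic threshold.

#' Tumor content ratio from nucleus counts
#'
#' @param n_cancer Number of cancerous nuclei counted.
#' @param n_total Total number of nucleated cells counted (`>= 1`).
#' @return An object of class `"tcr_estimate"`: a list with `x`
#'   (`n_cancer / n_total`), `n_cancer`, `n_total`.
#' @examples
#' tcr_from_counts(341, 1000)  # x = 0.341
#' @export
tcr_from_counts <- function(n_cancer, n_total) {
  for (v in list(n_cancer, n_total))
    if (length(v) != 1L || !is.finite(v) || v != round(v))
      stop("nucleus counts must be single whole numbers", call. = FALSE)
  if (n_total < 1)
    stop("'n_total' must be at least 1", call. = FALSE)
  if (n_cancer < 0 || n_cancer > n_total)
    stop("'n_cancer' must lie in [0, n_total]", call. = FALSE)
  structure(list(x = n_cancer / n_total,
                 n_cancer = as.integer(n_cancer),
                 n_total = as.integer(n_total)),
            class = "tcr_estimate")
}

#' @export
print.tcr_estimate <- function(x, ...) {
  cat(sprintf("Tumor content ratio: %.3f (%d cancerous of %d nuclei)\n",
              x$x, x$n_cancer, x$n_total))
  invisible(x)
}

#' Otsu threshold on a numeric feature
#'
#' Picks the cut maximizing between-class variance of the two induced
#' groups, evaluated at the midpoints between consecutive distinct sorted
#' values. Deterministic and assumption-light; suited to bimodal
#' nucleus-size distributions.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return The threshold (a scalar); values `>=` it fall in the upper class.
#' @examples
#' otsu_threshold(c(rnorm(50, 30, 3), rnorm(50, 80, 3)))
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  u <- sort(unique(values))
  if (length(u) < 2L)
    stop("need at least two distinct values to threshold", call. = FALSE)
  cuts <- (u[-1] + u[-length(u)]) / 2
  n <- length(values)
  best <- -Inf
  thr <- cuts[1]
  for (t in cuts) {
    hi <- values >= t
    n1 <- sum(hi)
    if (n1 == 0L || n1 == n) next
    # between-class variance: w0 w1 (mu0 - mu1)^2
    bc <- (n1 / n) * (1 - n1 / n) * (mean(values[hi]) - mean(values[!hi]))^2
    if (bc > best) {
      best <- bc
      thr <- t
    }
  }
  thr
}

#' Classify nuclei by size and derive the tumor content ratio
#'
#' Labels each nucleus `cancer` when its size is at or above the threshold,
#' `non_cancer` otherwise, and returns the induced TCR. With
#' `threshold = "auto"` the cut is chosen by [otsu_threshold()] (requires at
#' least 10 nuclei); a manual numeric threshold is always available.
#'
#' @param sizes Numeric vector of nucleus sizes (area, arbitrary units > 0).
#' @param threshold `"auto"` or a numeric cut in size units.
#' @return A list of class `"nucleus_classification"` with `labels` (factor
#'   `non_cancer`/`cancer` per nucleus), `threshold` (the cut used), and
#'   `tcr` (a [tcr_from_counts()] estimate).
#' @examples
#' classify_nuclei(c(5, 5, 5, 15, 15), threshold = 10)  # x = 0.4
#' @export
classify_nuclei <- function(sizes, threshold = "auto") {
  if (length(sizes) == 0L)
    stop("no nucleus records supplied", call. = FALSE)
  if (any(!is.finite(sizes) | sizes <= 0))
    stop("nucleus sizes must be positive numbers", call. = FALSE)
  if (identical(threshold, "auto")) {
    if (length(sizes) < 10L)
      stop("automatic thresholding needs at least 10 nuclei; ",
           "supply a manual threshold", call. = FALSE)
    threshold <- otsu_threshold(sizes)
  } else if (!is.numeric(threshold) || length(threshold) != 1L ||
               !is.finite(threshold)) {
    stop("'threshold' must be \"auto\" or a single number", call. = FALSE)
  }
  cancer <- sizes >= threshold
  structure(
    list(labels = factor(ifelse(cancer, "cancer", "non_cancer"),
                         levels = c("non_cancer", "cancer")),
         threshold = threshold,
         tcr = tcr_from_counts(sum(cancer), length(sizes))),
    class = "nucleus_classification"
  )
}

#' @export
print.nucleus_classification <- function(x, ...) {
  cat(sprintf("Nucleus size classification: threshold %.3g, ", x$threshold))
  print(x$tcr)
  invisible(x)
}
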