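# Dual-probe in situ hybridization (DISH) scoring and IHC concordance.
#
# DISH counts HER2 and CEP17 signals per cancer nucleus under bright-field
# microscopy, conventionally over 20 non-overlapping nuclei. The totals give
# the per-cell averages (avg CEP17 = the measured A used by the TC chart
# inversion) and the HER2/CEP17 ratio, which are classified by the
# ASCO/CAP-derived rules.

#' Total DISH signal counts over scored nuclei
#'
#' @param her2_signals Total HER2 signals over the scored nuclei
#'   (non-negative integer).
#' @param cep17_signals Total CEP17 signals (non-negative integer).
#' @param n_cells Number of scored cancer nuclei (positive integer,
#'   default 20, the conventional scoring depth).
#' @return An object of class `"dish_count"`.
#' @examples
#' dish_count(85, 41)  # 20 nuclei of an aneusomic, mildly amplified line
#' @export
dish_count <- function(her2_signals, cep17_signals, n_cells = 20L) {
  for (v in list(her2_signals, cep17_signals, n_cells))
    if (length(v) != 1L || !is.finite(v) || v != round(v))
      stop("DISH counts must be single whole numbers", call. = FALSE)
  if (her2_signals < 0 || cep17_signals < 0)
    stop("signal counts must be non-negative", call. = FALSE)
  if (n_cells < 1)
    stop("'n_cells' must be a positive integer", call. = FALSE)
  structure(list(her2_signals = as.integer(her2_signals),
                 cep17_signals = as.integer(cep17_signals),
                 n_cells = as.integer(n_cells)),
            class = "dish_count")
}

#' Per-cell DISH metrics
#'
#' Converts total signal counts to the three scoring quantities: the
#' HER2/CEP17 ratio, the average HER2 signals per cell, and the average CEP17
#' signals per cell. The last is the measured per-cell CEP17 copy number `A`
#' consumed by [estimate_ba_ratio()]. Values are kept at full precision;
#' rounding is a presentation concern only.
#'
#' @param count A [dish_count()].
#' @return An object of class `"dish_metrics"`: a list with `ratio`,
#'   `avg_her2`, `avg_cep17` and the source `count`.
#' @examples
#' dish_metrics(dish_count(85, 41, 20))  # ratio 2.07, A = 2.05, B = 4.25
#' @export
dish_metrics <- function(count) {
  stopifnot(inherits(count, "dish_count"))
  if (count$cep17_signals == 0L)
    stop("no CEP17 signals scored; the HER2/CEP17 ratio is undefined",
         call. = FALSE)
  structure(
    list(ratio = count$her2_signals / count$cep17_signals,
         avg_her2 = count$her2_signals / count$n_cells,
         avg_cep17 = count$cep17_signals / count$n_cells,
         source = count),
    class = "dish_metrics"
  )
}

#' @export
print.dish_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "DISH metrics over %d nuclei: HER2/CEP17 ratio %.2f, ",
    "%.1f HER2 and %.1f CEP17 signals/cell\n"),
    x$source$n_cells, x$ratio, x$avg_her2, x$avg_cep17))
  invisible(x)
}

#' Classify DISH metrics by the ASCO/CAP-derived rules
#'
#' `POSITIVE` if the HER2/CEP17 ratio is at least 2.0 and/or the average HER2
#' copy number is at least 6.0 signals/cell (inclusive or); otherwise
#' `EQUIVOCAL` if the average HER2 copy number is in `[4.0, 6.0)`; otherwise
#' `NEGATIVE`. Thresholds are applied to full-precision values, never to
#' rounded ones.
#'
#' @param metrics A [dish_metrics()] object, or a numeric HER2/CEP17 ratio
#'   (then `avg_her2` must be given).
#' @param avg_her2 Average HER2 signals per cell, when `metrics` is numeric.
#' @return Factor with levels `NEGATIVE`, `EQUIVOCAL`, `POSITIVE`.
#' @examples
#' classify_dish(dish_metrics(dish_count(132, 87)))  # POSITIVE on avg 6.6
#' @export
classify_dish <- function(metrics, avg_her2 = NULL) {
  if (inherits(metrics, "dish_metrics")) {
    ratio <- metrics$ratio
    avg_her2 <- metrics$avg_her2
  } else {
    ratio <- metrics
    if (is.null(avg_her2))
      stop("supply 'avg_her2' when 'metrics' is a bare ratio", call. = FALSE)
  }
  if (any(!is.finite(ratio) | ratio < 0) || any(!is.finite(avg_her2) | avg_her2 < 0))
    stop("DISH metrics must be non-negative numbers", call. = FALSE)
  n <- max(length(ratio), length(avg_her2))
  ratio <- rep_len(ratio, n)
  avg_her2 <- rep_len(avg_her2, n)
  label <- ifelse(ratio >= 2 | avg_her2 >= 6, "POSITIVE",
                  ifelse(avg_her2 >= 4, "EQUIVOCAL", "NEGATIVE"))
  factor(label, levels = c("NEGATIVE", "EQUIVOCAL", "POSITIVE"))
}

#' Tally per-nucleus HER2 signals with capped clusters
#'
#' HER2 signals in highly amplified nuclei form clusters whose individual
#' dots cannot be resolved; scoring convention caps them at 7, 14 or 21
#' signals for small, medium and large clusters respectively. This helper
#' maps per-nucleus records of discrete dots plus an optional cluster size
#' class to the per-nucleus total, for building a [dish_count()] from raw
#' scoring sheets.
#'
#' @param discrete_dots Integer vector of individually countable signals per
#'   nucleus.
#' @param cluster_class Character vector per nucleus: `"none"`, `"small"`,
#'   `"medium"` or `"large"`.
#' @return Integer vector of per-nucleus signal totals.
#' @examples
#' her2_cluster_total(c(3, 2, 0), c("none", "small", "large"))  # 3, 9, 21
#' @export
her2_cluster_total <- function(discrete_dots,
                               cluster_class = rep("none", length(discrete_dots))) {
  if (any(!is.finite(discrete_dots) | discrete_dots < 0 |
            discrete_dots != round(discrete_dots)))
    stop("'discrete_dots' must be non-negative whole numbers", call. = FALSE)
  caps <- c(none = 0L, small = 7L, medium = 14L, large = 21L)
  if (!all(cluster_class %in% names(caps)))
    stop("'cluster_class' values must be one of ",
         paste(names(caps), collapse = ", "), call. = FALSE)
  as.integer(discrete_dots) + caps[rep_len(cluster_class, length(discrete_dots))]
}

#' Validate IHC membrane-staining scores
#'
#' Coerces to the four-level Dako scale: 0 (no membrane staining), 1+, 2+
#' (equivocal), 3+ (complete intense circumferential staining).
#'
#' @param score Character or factor vector of scores.
#' @return Factor with levels `0`, `1+`, `2+`, `3+`.
#' @examples
#' ihc_score(c("0", "2+", "3+"))
#' @export
ihc_score <- function(score) {
  levels <- c("0", "1+", "2+", "3+")
  score <- trimws(as.character(score))
  bad <- !is.na(score) & !(score %in% levels)
  if (any(bad))
    stop("invalid IHC score(s): ", paste(unique(score[bad]), collapse = ", "),
         "; expected 0, 1+, 2+ or 3+", call. = FALSE)
  factor(score, levels = levels)
}

#' Cross-tabulate IHC (and optionally DISH) against TC-chart areas
#'
#' Builds the concordance table between HER2-IHC scores and TC-chart
#' classifications, optionally stratified by DISH labels, conserving one
#' count per sample.
#'
#' @param ihc Vector of IHC scores (coerced via [ihc_score()]).
#' @param tc Vector of TC-chart labels (as from `tc_classify()$label`).
#' @param dish Optional vector of DISH labels (as from [classify_dish()]).
#' @return A contingency `table`: IHC score (by DISH label if given) in rows,
#'   TC-chart area in columns.
#' @examples
#' concordance_table(c("3+", "2+"), c("POSITIVE", "EQUIVOCAL"))
#' @export
concordance_table <- function(ihc, tc, dish = NULL) {
  ihc <- ihc_score(ihc)
  tc <- factor(as.character(tc), levels = tc_labels)
  if (length(ihc) != length(tc))
    stop("'ihc' and 'tc' must have the same length", call. = FALSE)
  if (any(is.na(tc)))
    stop("invalid TC-chart label(s); expected ",
         paste(tc_labels, collapse = ", "), call. = FALSE)
  if (is.null(dish)) {
    table(ihc = ihc, tc_chart = tc)
  } else {
    dish <- factor(as.character(dish),
                   levels = c("NEGATIVE", "EQUIVOCAL", "POSITIVE"))
    if (length(dish) != length(tc))
      stop("'dish' must match the length of 'tc'", call. = FALSE)
    table(ihc = ihc, dish = dish, tc_chart = tc)
  }
}
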