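# Sample-sheet ingestion, the per-sample pipeline, reporting, and TC chart
# rendering.

sheet_numeric_cols <- c("target_positive", "reference_positive",
                        "total_chambers", "x", "n_cancer", "n_total",
                        "her2_signals", "cep17_signals", "n_cells", "r")

#' Read a digital PCR sample sheet
#'
#' Reads a CSV or TSV sample sheet, one row per panel (rows sharing a
#' `sample_id` are pooled by the pipeline). Mandatory column: `sample_id`.
#' Chamber counts come as `target_positive`, `reference_positive`,
#' `total_chambers`; alternatively a measured ratio may be supplied directly
#' in an `r` column (e.g. when re-analyzing published ratios). Tumor content
#' comes either as `x` or as nucleus counts `n_cancer`, `n_total`. Optional
#' DISH/IHC columns: `her2_signals`, `cep17_signals`, `n_cells`, `ihc_score`.
#'
#' @param path Path to the sheet; the separator is chosen by extension
#'   (`.tsv` = tab, otherwise comma) unless `format` is given.
#' @param format `"csv"`, `"tsv"`, or `NULL` to infer from the extension.
#' @return A validated data frame of class `"sample_sheet"`.
#' @examples
#' sheet <- system.file("extdata", "biopsy_cases.csv", package = "tcchart")
#' head(read_sample_sheet(sheet))
#' @export
read_sample_sheet <- function(path, format = NULL) {
  if (!file.exists(path))
    stop("sample sheet not found: ", path, call. = FALSE)
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "tsv") "tsv" else "csv"
  sep <- switch(match.arg(format, c("csv", "tsv")), csv = ",", tsv = "\t")
  sheet <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = TRUE,
                             colClasses = NA, encoding = "UTF-8")
  validate_sample_sheet(sheet, path)
}

validate_sample_sheet <- function(sheet, origin = "sample sheet") {
  if (!"sample_id" %in% names(sheet))
    stop(origin, ": mandatory column 'sample_id' is missing", call. = FALSE)
  has_counts <- all(c("target_positive", "reference_positive",
                      "total_chambers") %in% names(sheet))
  if (!has_counts && !"r" %in% names(sheet))
    stop(origin, ": need either chamber-count columns (target_positive, ",
         "reference_positive, total_chambers) or a measured ratio column 'r'",
         call. = FALSE)
  for (col in intersect(sheet_numeric_cols, names(sheet))) {
    v <- sheet[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad))
        stop(origin, ": non-numeric value '", v[bad[1]], "' in column '",
             col, "', row ", bad[1], call. = FALSE)
      v <- parsed
    }
    count_cols <- c("target_positive", "reference_positive", "total_chambers",
                    "n_cancer", "n_total", "her2_signals", "cep17_signals",
                    "n_cells")
    if (col %in% count_cols) {
      bad <- which(!is.na(v) & v < 0)
      if (length(bad))
        stop(origin, ": negative count ", v[bad[1]], " in column '", col,
             "', row ", bad[1], call. = FALSE)
    }
    sheet[[col]] <- v
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Write a sample sheet
#'
#' Writes a sheet in the dialect [read_sample_sheet()] consumes; a
#' write-then-read round trip preserves all values.
#'
#' @param sheet A data frame (typically of class `"sample_sheet"`).
#' @param path Destination; `.tsv` extension selects tab separation.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(sheet, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_sample <- function(rows, config) {
  out <- list(r = NA_real_, r_ci_low = NA_real_, r_ci_high = NA_real_,
              lambda_target = NA_real_, lambda_reference = NA_real_,
              x = NA_real_, tc_label = NA_character_,
              boundary_low = NA_real_, boundary_high = NA_real_,
              dish_ratio = NA_real_, avg_her2 = NA_real_,
              avg_cep17 = NA_real_, dish_label = NA_character_,
              ba_ratio = NA_real_, b_prime = NA_real_,
              ihc = NA_character_, error = NA_character_)

  # measured ratio: direct r wins, else pooled chamber counts
  if ("r" %in% names(rows) && any(!is.na(rows$r))) {
    out$r <- rows$r[!is.na(rows$r)][1]
    if (out$r <= 0) stop("measured ratio 'r' must be positive")
  } else {
    panels_t <- lapply(seq_len(nrow(rows)), function(i)
      panel_count(rows$target_positive[i], rows$total_chambers[i],
                  panel = paste0(rows$sample_id[i], " target")))
    panels_r <- lapply(seq_len(nrow(rows)), function(i)
      panel_count(rows$reference_positive[i], rows$total_chambers[i],
                  panel = paste0(rows$sample_id[i], " reference")))
    est <- dpcr_ratio(aggregate_panels(panels_t), aggregate_panels(panels_r))
    out$r <- est$r
    out$r_ci_low <- est$ci_low
    out$r_ci_high <- est$ci_high
    out$lambda_target <- est$target$lambda
    out$lambda_reference <- est$reference$lambda
  }

  # tumor content: direct x wins, else nucleus counts
  if ("x" %in% names(rows) && any(!is.na(rows$x))) {
    out$x <- rows$x[!is.na(rows$x)][1]
    if (out$x < 0 || out$x > 1) stop("tumor content 'x' must lie in [0, 1]")
  } else if (all(c("n_cancer", "n_total") %in% names(rows)) &&
               any(!is.na(rows$n_cancer))) {
    i <- which(!is.na(rows$n_cancer))[1]
    out$x <- tcr_from_counts(rows$n_cancer[i], rows$n_total[i])$x
  } else {
    stop("no tumor content: supply 'x' or nucleus counts 'n_cancer'/'n_total'")
  }

  cls <- suppressWarnings(tc_classify(out$r, out$x, config))
  out$tc_label <- as.character(cls$label)
  out$boundary_low <- cls$boundary_low
  out$boundary_high <- cls$boundary_high

  if (all(c("her2_signals", "cep17_signals") %in% names(rows)) &&
        any(!is.na(rows$her2_signals))) {
    i <- which(!is.na(rows$her2_signals))[1]
    n_cells <- if ("n_cells" %in% names(rows) && !is.na(rows$n_cells[i]))
      rows$n_cells[i] else 20L
    met <- dish_metrics(dish_count(rows$her2_signals[i],
                                   rows$cep17_signals[i], n_cells))
    out$dish_ratio <- met$ratio
    out$avg_her2 <- met$avg_her2
    out$avg_cep17 <- met$avg_cep17
    out$dish_label <- as.character(classify_dish(met))
    if (out$x > 0) {
      out$ba_ratio <- estimate_ba_ratio(out$r, out$x, met$avg_cep17)
      out$b_prime <- estimate_b_prime(out$r, met$avg_cep17)
    }
  }
  if ("ihc_score" %in% names(rows) && any(!is.na(rows$ihc_score)))
    out$ihc <- as.character(ihc_score(rows$ihc_score[!is.na(rows$ihc_score)][1]))
  out
}

#' Run the full classification pipeline over a sample sheet
#'
#' Per sample: pool panel rows and quantify the copy-number ratio (or take a
#' directly supplied `r`), resolve the tumor content ratio, classify on the
#' TC chart, and — where DISH counts are present — compute the per-cell B/A
#' inversion and the pure-tumor estimate B'. Samples that fail validation are
#' flagged in the `error` column rather than aborting the batch. The result
#' is deterministic given the inputs.
#'
#' @param sheet A data frame as returned by [read_sample_sheet()].
#' @param config A [tc_chart_config()].
#' @return A data frame of class `"sample_report"`, one row per sample, with
#'   the measured ratio and interval, tumor content, TC-chart label and
#'   boundary values, DISH metrics and label, `ba_ratio`, `b_prime`, IHC
#'   score, and an `error` column (`NA` on success).
#' @examples
#' sheet <- read_sample_sheet(
#'   system.file("extdata", "biopsy_cases.csv", package = "tcchart"))
#' run_pipeline(sheet)[, c("sample_id", "r", "x", "tc_label")]
#' @export
run_pipeline <- function(sheet, config = tc_chart_config()) {
  if (!is.data.frame(sheet))
    stop("'sheet' must be a data frame", call. = FALSE)
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  stopifnot(inherits(config, "tc_chart_config"))
  ids <- unique(sheet$sample_id)
  reports <- lapply(ids, function(id) {
    rows <- sheet[sheet$sample_id == id, , drop = FALSE]
    res <- tryCatch(resolve_sample(rows, config), error = function(e) {
      out <- list(r = NA_real_, r_ci_low = NA_real_, r_ci_high = NA_real_,
                  lambda_target = NA_real_, lambda_reference = NA_real_,
                  x = NA_real_, tc_label = NA_character_,
                  boundary_low = NA_real_, boundary_high = NA_real_,
                  dish_ratio = NA_real_, avg_her2 = NA_real_,
                  avg_cep17 = NA_real_, dish_label = NA_character_,
                  ba_ratio = NA_real_, b_prime = NA_real_,
                  ihc = NA_character_, error = conditionMessage(e))
      out
    })
    cbind(data.frame(sample_id = id), as.data.frame(res))
  })
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("sample_report", "data.frame")
  out
}

#' Write classification reports
#'
#' Writes a human-readable TSV with the field's presentation rounding
#' (ratios to 2 decimals, tumor content to 3, per-cell estimates to 2) and,
#' optionally, a machine-readable JSON at full precision. Byte-identical for
#' identical inputs.
#'
#' @param report A `"sample_report"` from [run_pipeline()].
#' @param path Destination TSV path.
#' @param json_path Optional destination for the full-precision JSON.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "sample_report"))
  pretty <- report
  for (col in c("r", "r_ci_low", "r_ci_high", "dish_ratio", "ba_ratio",
                "b_prime"))
    pretty[[col]] <- round(pretty[[col]], 2)
  pretty$x <- round(pretty$x, 3)
  for (col in c("lambda_target", "lambda_reference", "avg_her2", "avg_cep17",
                "boundary_low", "boundary_high"))
    pretty[[col]] <- round(pretty[[col]], 4)
  utils::write.table(pretty, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(unclass(report))[names(report)],
                         json_path, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

# Hybrid vertical axis: linear up to `break_at`, logarithmic above, with a
# continuous first derivative at the break. Mirrors how amplification charts
# keep the diagnostically dense band around r = 1-2.5 readable while still
# showing extreme ratios.
tc_axis_trans <- function(break_at = 2.5) {
  scales::trans_new(
    name = "tc_hybrid",
    transform = function(r) ifelse(r <= break_at, r,
                                   break_at + break_at * log(r / break_at)),
    inverse = function(y) ifelse(y <= break_at, y,
                                 break_at * exp((y - break_at) / break_at)),
    domain = c(1e-6, Inf)
  )
}

#' Render the TC chart
#'
#' Draws the TC chart: the negative boundary `r = x + 1`, the positive
#' boundary `r = (7x + 1)/(3x + 1)` (for the default CEP17 bracket), the
#' shaded equivocal band between them, and the sample points — colored by
#' DISH label and shaped by IHC score when available. The vertical axis is
#' linear up to `r = 2.5` and logarithmic above, so both the decision band
#' and highly amplified samples stay readable.
#'
#' @param report A `"sample_report"` from [run_pipeline()], or `NULL` for a
#'   chart with boundaries only.
#' @param config A [tc_chart_config()].
#' @param path Optional output file (`.svg`, `.png`, `.pdf`); written with
#'   [ggplot2::ggsave()].
#' @param axis_break Ratio at which the vertical axis switches from linear
#'   to logarithmic (default 2.5).
#' @return The ggplot object, invisibly if `path` is given.
#' @examples
#' sheet <- read_sample_sheet(
#'   system.file("extdata", "biopsy_cases.csv", package = "tcchart"))
#' render_chart(run_pipeline(sheet))
#' @export
render_chart <- function(report = NULL, config = tc_chart_config(),
                         path = NULL, axis_break = 2.5) {
  stopifnot(inherits(config, "tc_chart_config"))
  curves <- chart_curves(config, n_points = 301L)
  band <- data.frame(
    x = curves$x[curves$role == "negative_boundary"],
    low = curves$r[curves$role == "negative_boundary"],
    high = curves$r[curves$role == "positive_boundary"])
  # negative boundary in red, positive in purple, equivocal band shaded
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                         fill = "grey88") +
    ggplot2::geom_line(ggplot2::aes(y = .data$low), color = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$high), color = "purple3")
  if (!is.null(report) && nrow(report)) {
    pts <- as.data.frame(report[!is.na(report$r) & !is.na(report$x), ,
                                drop = FALSE])
    if (nrow(pts)) {
      pts$dish_label <- ifelse(is.na(pts$dish_label), "none", pts$dish_label)
      pts$ihc <- ifelse(is.na(pts$ihc), "none", pts$ihc)
      p <- p + ggplot2::geom_point(
        data = pts,
        ggplot2::aes(x = .data$x, y = .data$r, color = .data$dish_label,
                     shape = .data$ihc),
        size = 2.5) +
        ggplot2::scale_color_manual(
          values = c(POSITIVE = "red", EQUIVOCAL = "purple",
                     NEGATIVE = "blue", none = "black"),
          name = "DISH") +
        ggplot2::scale_shape_manual(
          values = c("3+" = 18, "2+" = 17, "1+" = 4, "0" = 3, none = 16),
          name = "IHC")
    }
  }
  p <- p +
    ggplot2::scale_y_continuous(trans = tc_axis_trans(axis_break),
                                breaks = c(0.5, 1, 1.5, 2, 2.5, 5, 10, 30, 100)) +
    ggplot2::labs(x = "Tumor content ratio x",
                  y = "HER2/CEP17 ratio r (digital PCR)") +
    ggplot2::theme_classic()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 5)
    return(invisible(p))
  }
  p
}

#' Bundled example data
#'
#' `example_cell_lines()` returns published DISH signal counts and digital
#' PCR chamber counts for three reference lines: a diploid lymphoblastoid
#' cell line (LCL, the stroma surrogate), the mildly HER2-amplified lung line
#' H522, and the highly amplified breast line SK-BR-3.
#' `example_biopsy_cases()` returns the published measurements for eleven
#' gastric cancer biopsy specimens — tumor content, measured digital PCR
#' ratio, DISH signal counts, IHC score — together with the published
#' TC-chart area and per-cell estimates for cross-checking.
#'
#' @return A data frame.
#' @examples
#' example_cell_lines()
#' head(example_biopsy_cases())
#' @export
example_cell_lines <- function() {
  utils::read.csv(system.file("extdata", "cell_lines.csv",
                              package = "tcchart"),
                  stringsAsFactors = FALSE)
}

#' @rdname example_cell_lines
#' @export
example_biopsy_cases <- function() {
  utils::read.csv(system.file("extdata", "biopsy_cases.csv",
                              package = "tcchart"),
                  stringsAsFactors = FALSE)
}
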