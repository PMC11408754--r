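# Error statistics for depth/concentration predictions: per-sample mean
# absolute error over a support, cohort mean +/- SD, and paired significance
# tests between models.

#' Per-sample depth and concentration errors
#'
#' Mean absolute per-pixel error over the chosen support. The default
#' support is the ground-truth footprint (pixels with true depth > 0);
#' `"union"` adds pixels where the prediction is positive, `"full"` uses
#' the whole image.
#'
#' @param pred An `sfdi_prediction` (or list with `depth_mm`,
#'   `concentration`).
#' @param truth An `sfdi_gt` on the same grid.
#' @param support `"footprint"`, `"union"`, or `"full"`.
#' @return List of class `sfdi_sample_error`: `depth_error_mm`,
#'   `conc_error_ugml`, `support`, `n_pixels`.
#' @export
sample_error <- function(pred, truth,
                         support = c("footprint", "union", "full")) {
  support <- match.arg(support)
  if (!identical(dim(pred$depth_mm), dim(truth$depth_mm))) {
    stop("prediction and truth maps are not co-registered")
  }
  mask <- switch(support,
                 footprint = truth$depth_mm > 0,
                 union = truth$depth_mm > 0 | pred$depth_mm > 0,
                 full = array(TRUE, dim = dim(truth$depth_mm)))
  if (!any(mask)) stop("empty error support")
  structure(list(
    depth_error_mm = mean(abs(pred$depth_mm[mask] - truth$depth_mm[mask])),
    conc_error_ugml = mean(abs(pred$concentration[mask] -
                                 truth$concentration[mask])),
    support = support, n_pixels = sum(mask)), class = "sfdi_sample_error")
}

#' Cohort error summary (mean +/- SD)
#'
#' @param errors A list of `sfdi_sample_error` objects or a data.frame with
#'   `depth_error_mm` and `conc_error_ugml` columns.
#' @param sd_type `"sample"` (divisor n-1) or `"population"` (divisor n).
#' @return List of class `sfdi_cohort`: per-sample errors plus
#'   `depth_mean`, `depth_sd`, `conc_mean`, `conc_sd`, `n`.
#' @export
cohort_stats <- function(errors, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!is.data.frame(errors)) {
    errors <- do.call(rbind, lapply(errors, function(e) {
      data.frame(depth_error_mm = e$depth_error_mm,
                 conc_error_ugml = e$conc_error_ugml)
    }))
  }
  n <- nrow(errors)
  stopifnot(n >= 1)
  sdv <- function(x) {
    if (n == 1) return(if (sd_type == "population") 0 else NA_real_)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((n - 1) / n) else s
  }
  structure(list(errors = errors, n = n,
                 depth_mean = mean(errors$depth_error_mm),
                 depth_sd = sdv(errors$depth_error_mm),
                 conc_mean = mean(errors$conc_error_ugml),
                 conc_sd = sdv(errors$conc_error_ugml),
                 sd_type = sd_type), class = "sfdi_cohort")
}

#' @export
print.sfdi_cohort <- function(x, ...) {
  cat(sprintf("n = %d: depth error %.3g (%.3g) mm, concentration error %.3g (%.3g) ug/mL\n",
              x$n, x$depth_mean, x$depth_sd, x$conc_mean, x$conc_sd))
  invisible(x)
}

#' Write / read a cohort report
#'
#' Per-sample errors go to CSV; the summary (and any attached test results)
#' to JSON next to it.
#'
#' @param cohort An `sfdi_cohort`.
#' @param csv_path Output CSV path (JSON summary written alongside).
#' @return `write_cohort` invisibly returns `csv_path`; `read_cohort`
#'   rebuilds the cohort from the CSV.
#' @export
write_cohort <- function(cohort, csv_path) {
  utils::write.csv(cohort$errors, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(n = cohort$n, depth_mean = cohort$depth_mean,
         depth_sd = cohort$depth_sd, conc_mean = cohort$conc_mean,
         conc_sd = cohort$conc_sd, sd_type = cohort$sd_type),
    sidecar_path(csv_path), digits = I(17), auto_unbox = TRUE)
  invisible(csv_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(csv_path) {
  cohort_stats(utils::read.csv(csv_path))
}

#' Paired significance test between two models' per-sample errors
#'
#' Two-sided paired Wilcoxon signed-rank test (exact for n < 25 when there
#' are no ties, normal approximation otherwise). A paired t-test is
#' available behind `method = "t"`. All-zero differences return p = 1 with
#' a warning.
#'
#' @param errors_a,errors_b Equal-length numeric vectors of paired
#'   per-sample errors (n >= 5).
#' @param method `"wilcoxon"` or `"t"`.
#' @return The p-value.
#' @export
paired_test <- function(errors_a, errors_b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  stopifnot(length(errors_a) == length(errors_b), length(errors_a) >= 5)
  d <- errors_a - errors_b
  if (all(d == 0)) {
    warning("all paired differences are zero (complete ties); p = 1")
    return(1)
  }
  if (method == "t") {
    return(stats::t.test(errors_a, errors_b, paired = TRUE)$p.value)
  }
  exact <- length(d) < 25 && !any(d == 0) && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(errors_a, errors_b, paired = TRUE,
                       exact = exact, correct = !exact)$p.value)
}
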