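# Evaluation reports: per-cell tables (columns Area, Prediction, TP, FP, FN,
# Precision, Recall, F1), instance summaries, export and method comparison.

#' Evaluate a prediction against a ground truth
#'
#' Runs instance matching, per-cell lumen-area pixel metrics, instance-level
#' confusion statistics, the high-accuracy cell fraction and the FN
#' size-class histogram, and bundles them with provenance.
#'
#' @param gt,pred normalized label maps of identical dimensions.
#' @param cfg a [match_config()].
#' @param pixel_scale optional pixels-to-square-micron scale factor; when
#'   given, per-cell areas are also reported in square microns
#'   (`gt_area_um2`, `pred_area_um2`). Pure pass-through.
#' @param name label for the prediction (default "prediction").
#' @param gt_path,pred_path optional input paths recorded as provenance.
#' @return object of class `qwa_eval`: `match` (the `qwa_match`), `per_cell`
#'   ([cell_pixel_metrics()] table), `instance` (one-row `qwa_prf`),
#'   `pixel` (pooled pixel PRF over matched cells),
#'   `high_accuracy_fraction`, `fn_histogram`, `provenance`.
#' @export
evaluate_segmentation <- function(gt, pred, cfg = match_config(),
                                  pixel_scale = NULL, name = "prediction",
                                  gt_path = NA_character_,
                                  pred_path = NA_character_) {
  res <- match_instances(gt, pred, cfg)
  per_cell <- cell_pixel_metrics(gt, pred, res)
  if (!is.null(pixel_scale)) {
    per_cell$gt_area_um2 <- per_cell$gt_area * pixel_scale
    per_cell$pred_area_um2 <- per_cell$pred_area * pixel_scale
  }
  inst <- instance_confusion(res)
  pixel <- prf_from_counts(sum(per_cell$tp), sum(per_cell$fp), sum(per_cell$fn))
  haf <- if (nrow(per_cell)) high_accuracy_fraction(per_cell) else NA_real_
  hist <- tryCatch(fn_size_histogram(gt, res), error = function(e) NULL)
  structure(list(match = res, per_cell = per_cell, instance = inst,
                 pixel = pixel, high_accuracy_fraction = haf,
                 fn_histogram = hist,
                 provenance = list(name = name, gt_path = gt_path,
                                   pred_path = pred_path,
                                   config = unclass(cfg),
                                   config_hash = config_hash(cfg),
                                   package_version =
                                     as.character(utils::packageVersion("qwaseg")))),
            class = "qwa_eval")
}

# md5 of the serialized config (written via a temp file; tools::md5sum is
# file-based)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' @export
print.qwa_eval <- function(x, ...) {
  cat("Segmentation evaluation:", x$provenance$name, "\n")
  print(x$match)
  i <- x$instance
  cat(sprintf("  instance precision %.2f  recall %.2f  F1 %.2f\n",
              i$precision, i$recall, i$f1))
  if (nrow(x$per_cell)) {
    p <- x$pixel
    cat(sprintf("  lumen pixels (pooled) precision %.2f  recall %.2f  F1 %.2f\n",
                p$precision, p$recall, p$f1))
    cat(sprintf("  cells with F1 >= 0.9: %.1f%%\n", 100 * x$high_accuracy_fraction))
  }
  invisible(x)
}

# the canonical per-cell report table (display columns)
per_cell_report_table <- function(per_cell) {
  data.frame(Area = per_cell$gt_area, Prediction = per_cell$pred_area,
             TP = per_cell$tp, FP = per_cell$fp, FN = per_cell$fn,
             Precision = per_cell$precision, Recall = per_cell$recall,
             F1 = per_cell$f1)
}

#' Export an evaluation report
#'
#' `csv` writes `<path>_per_cell.csv` (columns Area, Prediction, TP, FP, FN,
#' Precision, Recall, F1 at full precision; round to 2 decimals for display),
#' `<path>_summary.csv` and `<path>_fn_histogram.csv`. `json` writes a single
#' `<path>.json` that [import_report()] reloads losslessly.
#'
#' @param report a `qwa_eval`.
#' @param path output path stem (csv) or file path (json).
#' @param format `"csv"` or `"json"`.
#' @return written file path(s), invisibly.
#' @export
export_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "qwa_eval"))
  if (format == "csv") {
    f1 <- paste0(path, "_per_cell.csv")
    f2 <- paste0(path, "_summary.csv")
    f3 <- paste0(path, "_fn_histogram.csv")
    write.csv(per_cell_report_table(report$per_cell), f1, row.names = FALSE)
    s <- data.frame(
      level = c("instance", "lumen_pixels"),
      tp = c(report$instance$tp, report$pixel$tp),
      fp = c(report$instance$fp, report$pixel$fp),
      fn = c(report$instance$fn, report$pixel$fn),
      precision = c(report$instance$precision, report$pixel$precision),
      recall = c(report$instance$recall, report$pixel$recall),
      f1 = c(report$instance$f1, report$pixel$f1))
    s$high_accuracy_fraction <- c(NA, report$high_accuracy_fraction)
    write.csv(s, f2, row.names = FALSE)
    if (!is.null(report$fn_histogram)) {
      hh <- report$fn_histogram
      write.csv(data.frame(bin_lo = head(hh$bin_edges, -1),
                           bin_hi = tail(hh$bin_edges, -1),
                           fn_count = hh$fn_counts), f3, row.names = FALSE)
    }
    return(invisible(c(f1, f2, f3)))
  }
  obj <- list(
    per_cell = report$per_cell,
    instance = unclass(report$instance),
    pixel = unclass(report$pixel),
    high_accuracy_fraction = report$high_accuracy_fraction,
    fn_histogram = if (is.null(report$fn_histogram)) NULL else
      unclass(report$fn_histogram),
    match = list(matched = report$match$matched, fn = report$match$fn,
                 fp = report$match$fp,
                 excluded_gt = report$match$excluded_gt,
                 excluded_pred = report$match$excluded_pred,
                 n_gt = report$match$n_gt, n_pred = report$match$n_pred),
    provenance = report$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Reload a JSON evaluation report
#'
#' @param path file written by `export_report(..., format = "json")`.
#' @return list mirroring the exported structure (data.frames restored).
#' @export
import_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("per_cell")) x[[nm]] <- as.data.frame(x[[nm]])
  x$match$matched <- as.data.frame(x$match$matched)
  x$match$fn <- as.data.frame(x$match$fn)
  x$match$fp <- as.data.frame(x$match$fp)
  x
}

#' Compare several segmentation methods against one ground truth
#'
#' @param gt normalized label map.
#' @param predictions named list of label maps, one per method; all must
#'   match `gt`'s dimensions (a mismatch error names the offending method).
#' @param cfg a [match_config()].
#' @return data.frame, one row per method in input order: instance
#'   precision/recall/F1, pooled lumen-pixel precision/recall/F1 and the
#'   high-accuracy cell fraction.
#' @export
compare_methods <- function(gt, predictions, cfg = match_config()) {
  if (is.null(names(predictions)) || any(!nzchar(names(predictions))))
    stop("predictions must be a named list")
  rows <- lapply(names(predictions), function(nm) {
    p <- predictions[[nm]]
    if (!all(dim(p) == dim(gt)))
      stop("prediction '", nm, "' dimensions differ from ground truth")
    ev <- evaluate_segmentation(gt, p, cfg, name = nm)
    data.frame(method = nm,
               instance_precision = ev$instance$precision,
               instance_recall = ev$instance$recall,
               instance_f1 = ev$instance$f1,
               lumen_precision = ev$pixel$precision,
               lumen_recall = ev$pixel$recall,
               lumen_f1 = ev$pixel$f1,
               high_accuracy_fraction = ev$high_accuracy_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
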