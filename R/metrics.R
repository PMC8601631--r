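# Precision / recall / F1 at instance and pixel level, per-cell lumen-area
# accuracy, aggregates, FN size-class histograms, high-accuracy fraction.

#' Precision, recall and F1 from confusion counts
#'
#' `recall = TP / (TP + FN)` estimates missed cells, `precision =
#' TP / (TP + FP)` estimates redundant cells, and F1 is their harmonic mean
#' `2 * P * R / (P + R)`. True negatives are deliberately absent: with no
#' census of all non-target cells the TN cell count is undefined. Degenerate
#' denominators yield 0 by convention (conservative: an empty prediction
#' scores 0, not 1).
#'
#' @param tp,fp,fn non-negative counts (vectorized).
#' @return data.frame of class `qwa_prf` with columns `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
prf_from_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(data.frame(tp = tp, fp = fp, fn = fn,
                       precision = precision, recall = recall, f1 = f1),
            class = c("qwa_prf", "data.frame"))
}

#' Per-cell lumen-area pixel metrics
#'
#' For each matched (gt, pred) pair: TP = pixels in both lumina, FP = pixels
#' only in the prediction, FN = pixels only in the ground truth, plus the
#' derived precision/recall/F1. The identities `tp + fn = gt_area` and
#' `tp + fp = pred_area` hold for every row.
#'
#' @param gt,pred the label maps the result was computed from.
#' @param result a [match_instances()] result.
#' @param pairs optional 2-column matrix/data.frame of (gt_id, pred_id) pairs
#'   to restrict to; each must be matched in `result`, otherwise an error.
#' @return data.frame with columns `gt_id`, `pred_id`, `gt_area` (the report
#'   table's "Area"), `pred_area` ("Prediction"), `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`; one row per pair, ordered by `gt_id`.
#' @export
cell_pixel_metrics <- function(gt, pred, result, pairs = NULL) {
  stopifnot(inherits(result, "qwa_match"))
  m <- result$matched
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2) stop("pairs must have two columns (gt_id, pred_id)")
    key <- paste(m$gt_id, m$pred_id)
    want <- paste(pairs[, 1], pairs[, 2])
    if (!all(want %in% key))
      stop("pair(s) not matched in result: ",
           paste(setdiff(want, key), collapse = "; "))
    m <- m[match(want, key), , drop = FALSE]
  }
  ag <- result$gt_areas; ap <- result$pred_areas
  tp <- m$intersection
  out <- data.frame(gt_id = m$gt_id, pred_id = m$pred_id,
                    gt_area = ag[m$gt_id], pred_area = ap[m$pred_id],
                    tp = tp, fp = ap[m$pred_id] - tp, fn = ag[m$gt_id] - tp)
  prf <- prf_from_counts(out$tp, out$fp, out$fn)
  out$precision <- prf$precision; out$recall <- prf$recall; out$f1 <- prf$f1
  rownames(out) <- NULL
  out
}

#' Instance-level confusion statistics of a match result
#'
#' TP = matched pairs, FP = all false-positive predictions (spurious,
#' disconnected-positive fragments, merged predictions), FN = all
#' false-negative cells (missed, merged negatives, split victims).
#'
#' @param result a `qwa_match`.
#' @return one-row `qwa_prf` data.frame.
#' @export
instance_confusion <- function(result) {
  stopifnot(inherits(result, "qwa_match"))
  prf_from_counts(nrow(result$matched), nrow(result$fp), nrow(result$fn))
}

#' Aggregate per-image evaluation statistics
#'
#' @param per_image_results list of per-image results; each element either a
#'   `qwa_eval` (from [evaluate_segmentation()]) or a list with elements
#'   `instance` (one-row `qwa_prf`) and `per_cell` (a [cell_pixel_metrics()]
#'   data.frame).
#' @param mode `"macro"`: unweighted mean of per-image instance
#'   precision/recall/F1; `"micro"`: PRF recomputed from pooled instance
#'   counts; `"per_cell"`: mean of pixel precision/recall/F1 over all matched
#'   cells of all images.
#' @return one-row data.frame with columns `mode`, `precision`, `recall`,
#'   `f1` (plus pooled counts for `micro`).
#' @export
aggregate_summary <- function(per_image_results,
                              mode = c("macro", "micro", "per_cell")) {
  mode <- match.arg(mode)
  if (!length(per_image_results)) stop("need at least one result")
  get <- function(r, what) {
    if (inherits(r, "qwa_eval")) r[[what]] else r[[what]]
  }
  if (mode == "macro") {
    inst <- do.call(rbind, lapply(per_image_results, get, "instance"))
    data.frame(mode = "macro", precision = mean(inst$precision),
               recall = mean(inst$recall), f1 = mean(inst$f1))
  } else if (mode == "micro") {
    inst <- do.call(rbind, lapply(per_image_results, get, "instance"))
    p <- prf_from_counts(sum(inst$tp), sum(inst$fp), sum(inst$fn))
    data.frame(mode = "micro", tp = p$tp, fp = p$fp, fn = p$fn,
               precision = p$precision, recall = p$recall, f1 = p$f1)
  } else {
    cells <- do.call(rbind, lapply(per_image_results, get, "per_cell"))
    if (!nrow(cells)) stop("no matched cells to aggregate")
    data.frame(mode = "per_cell", precision = mean(cells$precision),
               recall = mean(cells$recall), f1 = mean(cells$f1))
  }
}

#' Fraction of matched cells in the highest accuracy class
#'
#' The share of matched cells whose per-cell lumen-area F1 reaches the
#' threshold (default 0.9).
#'
#' @param cells a [cell_pixel_metrics()] data.frame (>= 1 row).
#' @param threshold F1 cutoff, default 0.9.
#' @return real in \[0, 1\].
#' @export
high_accuracy_fraction <- function(cells, threshold = 0.9) {
  if (!nrow(cells)) stop("empty cell table")
  mean(cells$f1 >= threshold)
}

#' Size-class histogram of missed cells
#'
#' Bins false-negative ground-truth cells by lumen pixel area, over bin edges
#' spanning the areas of all non-excluded ground-truth cells, to show in
#' which size classes detection fails.
#'
#' @param gt ground-truth label map.
#' @param result matching result for `gt`.
#' @param n_bins number of bins (default 10).
#' @param binning `"equal_width"` (default) or `"quantile"` edges.
#' @return list of class `qwa_fn_histogram`: `bin_edges` (length
#'   `n_bins + 1`), `fn_counts`, `total_fn`.
#' @export
fn_size_histogram <- function(gt, result, n_bins = 10,
                              binning = c("equal_width", "quantile")) {
  binning <- match.arg(binning)
  stopifnot(inherits(result, "qwa_match"))
  ag <- result$gt_areas
  alive <- setdiff(seq_along(ag), result$excluded_gt)
  if (!length(alive)) stop("no non-excluded ground-truth cells")
  areas <- ag[alive]
  rng <- range(areas)
  edges <- if (binning == "equal_width") {
    seq(rng[1], rng[2], length.out = n_bins + 1)
  } else {
    as.numeric(quantile(areas, probs = seq(0, 1, length.out = n_bins + 1),
                        type = 1))
  }
  edges <- unique(edges)
  if (length(edges) < 2) edges <- c(edges, edges + 1)
  fn_areas <- ag[result$fn$gt_id]
  cuts <- cut(fn_areas, breaks = edges, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(cuts))
  structure(list(bin_edges = edges, fn_counts = counts,
                 total_fn = length(fn_areas)),
            class = "qwa_fn_histogram")
}

#' @export
print.qwa_fn_histogram <- function(x, ...) {
  cat("FN size-class histogram (", x$total_fn, " missed cells)\n", sep = "")
  lo <- head(x$bin_edges, -1); hi <- tail(x$bin_edges, -1)
  for (i in seq_along(x$fn_counts))
    cat(sprintf("  [%8.1f, %8.1f] px: %d\n", lo[i], hi[i], x$fn_counts[i]))
  invisible(x)
}
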