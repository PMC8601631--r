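# Instance matching: assign every ground-truth and predicted cell to exactly
# one evaluation category (matched / fn / fp subcategory / excluded).

#' Matching configuration
#'
#' @param iou_threshold minimum intersection-over-union for a matched pair
#'   (default 0.5, which makes matches unique: no two predictions can both
#'   overlap one cell with IoU >= 0.5).
#' @param containment_fraction majority-containment fraction used to detect
#'   split fragments and merged cells (default 0.5): a fragment belongs to a
#'   cell when more than this fraction of its own area lies inside it.
#' @param border_exclusion exclude border-clipped (incomplete) cells and the
#'   predictions accounted for by them (default `TRUE`).
#' @return object of class `qwa_match_config`.
#' @export
match_config <- function(iou_threshold = 0.5, containment_fraction = 0.5,
                         border_exclusion = TRUE) {
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must be in (0, 1]")
  if (!is.numeric(containment_fraction) || containment_fraction <= 0 ||
      containment_fraction > 1)
    stop("containment_fraction must be in (0, 1]")
  structure(list(iou_threshold = iou_threshold,
                 containment_fraction = containment_fraction,
                 border_exclusion = isTRUE(border_exclusion)),
            class = "qwa_match_config")
}

#' Pairwise intersection table of two label maps
#'
#' Sparse table of pixel intersections between ground-truth and predicted
#' instances; a row exists iff the pair overlaps by at least one pixel.
#' IoU is derived as `inter / (gt_area + pred_area - inter)`.
#'
#' @param gt,pred label maps of identical dimensions.
#' @return data.frame with columns `gt_id`, `pred_id`, `intersection`, `iou`,
#'   ordered by (gt_id, pred_id).
#' @export
intersection_table <- function(gt, pred) {
  validate_labelmap(gt); validate_labelmap(pred)
  if (!all(dim(gt) == dim(pred)))
    stop("gt and pred dimensions differ: ", paste(dim(gt), collapse = "x"),
         " vs ", paste(dim(pred), collapse = "x"))
  both <- gt > 0L & pred > 0L
  empty <- data.frame(gt_id = integer(0), pred_id = integer(0),
                      intersection = integer(0), iou = numeric(0))
  if (!any(both)) return(empty)
  g <- gt[both]; p <- pred[both]
  np1 <- max(p) + 1
  key <- as.numeric(g) * np1 + p
  tab <- table(key)
  k <- as.numeric(names(tab))
  gt_id <- as.integer(k %/% np1)
  pred_id <- as.integer(k %% np1)
  inter <- as.integer(tab)
  ag <- instance_areas(gt); ap <- instance_areas(pred)
  out <- data.frame(gt_id = gt_id, pred_id = pred_id, intersection = inter,
                    iou = inter / (ag[gt_id] + ap[pred_id] - inter))
  out[order(out$gt_id, out$pred_id), , drop = FALSE]
}

#' Match predicted cells to ground-truth cells
#'
#' Every non-excluded instance ends in exactly one category. The procedure:
#' \enumerate{
#'   \item Border exclusion (optional): ground-truth cells touching the image
#'     frame are excluded as incomplete; predictions touching the frame, or
#'     whose majority pixel mass lies inside excluded cells, are excluded too
#'     so that border clipping never produces spurious errors.
#'   \item Greedy one-to-one matching of candidate pairs with IoU at or above
#'     the threshold, in descending IoU order (ties: smaller gt id, then
#'     smaller pred id). At the default threshold 0.5 this equals the optimal
#'     assignment.
#'   \item Split detection: an unmatched cell whose area is jointly covered
#'     (IoU of the fragment union with the cell above threshold) by two or
#'     more unmatched predictions, each majority-contained in it, is a
#'     \emph{disconnected positive} case: the fragments become FP
#'     (`disconnected_positive`), the cell FN (`disconnected_victim`).
#'   \item Merge detection: a still-unmatched prediction that jointly covers
#'     two or more unmatched cells, each with its own majority inside the
#'     prediction, is a \emph{merged negative} case: the cells become FN
#'     (`merged_negative`), the prediction FP (`merged_prediction`).
#'   \item Residual unmatched cells are FN (`missed`); residual predictions
#'     FP (`spurious`).
#' }
#'
#' @param gt,pred normalized label maps of identical dimensions.
#' @param cfg a [match_config()].
#' @return object of class `qwa_match`: list with data.frames `matched`
#'   (`gt_id`, `pred_id`, `iou`, `intersection`), `fn` (`gt_id`, `reason`),
#'   `fp` (`pred_id`, `reason`), integer vectors `excluded_gt`,
#'   `excluded_pred`, plus `n_gt`, `n_pred`, `gt_areas`, `pred_areas`, `cfg`.
#' @export
match_instances <- function(gt, pred, cfg = match_config()) {
  validate_labelmap(gt, normalized = TRUE)
  validate_labelmap(pred, normalized = TRUE)
  if (!all(dim(gt) == dim(pred))) stop("gt and pred dimensions differ")
  stopifnot(inherits(cfg, "qwa_match_config"))
  tau <- cfg$iou_threshold; kap <- cfg$containment_fraction

  ag <- instance_areas(gt); ap <- instance_areas(pred)
  ng <- length(ag); np <- length(ap)
  it <- intersection_table(gt, pred)

  ex_g <- integer(0); ex_p <- integer(0)
  if (cfg$border_exclusion) {
    ex_g <- find_incomplete(gt)
    ex_p <- find_incomplete(pred)
    if (length(ex_g) && nrow(it)) {
      # predictions with majority mass inside excluded gt cells
      inside <- it[it$gt_id %in% ex_g, , drop = FALSE]
      if (nrow(inside)) {
        mass <- tapply(inside$intersection, inside$pred_id, sum)
        pid <- as.integer(names(mass))
        ex_p <- union(ex_p, pid[as.numeric(mass) > kap * ap[pid]])
      }
    }
    ex_p <- sort(ex_p)
  }

  alive_g <- setdiff(seq_len(ng), ex_g)
  alive_p <- setdiff(seq_len(np), ex_p)
  cand <- it[it$gt_id %in% alive_g & it$pred_id %in% alive_p, , drop = FALSE]

  # greedy one-to-one by descending IoU
  m <- cand[cand$iou >= tau, , drop = FALSE]
  m <- m[order(-m$iou, m$gt_id, m$pred_id), , drop = FALSE]
  used_g <- logical(ng); used_p <- logical(np)
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    g <- m$gt_id[i]; p <- m$pred_id[i]
    if (!used_g[g] && !used_p[p]) { keep[i] <- TRUE; used_g[g] <- used_p[p] <- TRUE }
  }
  matched <- m[keep, c("gt_id", "pred_id", "iou", "intersection"), drop = FALSE]
  matched <- matched[order(matched$gt_id), , drop = FALSE]
  rownames(matched) <- NULL

  un_g <- setdiff(alive_g, matched$gt_id)
  un_p <- setdiff(alive_p, matched$pred_id)
  fn <- data.frame(gt_id = integer(0), reason = character(0))
  fp <- data.frame(pred_id = integer(0), reason = character(0))

  # split detection
  free <- cand[cand$gt_id %in% un_g & cand$pred_id %in% un_p, , drop = FALSE]
  for (g in un_g) {
    rows <- free[free$gt_id == g &
                 free$intersection > kap * ap[free$pred_id], , drop = FALSE]
    if (nrow(rows) >= 2) {
      si <- sum(rows$intersection); sa <- sum(ap[rows$pred_id])
      if (si / (ag[g] + sa - si) >= tau) {
        fn <- rbind(fn, data.frame(gt_id = g, reason = "disconnected_victim"))
        fp <- rbind(fp, data.frame(pred_id = rows$pred_id,
                                   reason = "disconnected_positive"))
      }
    }
  }
  un_g <- setdiff(un_g, fn$gt_id)
  un_p <- setdiff(un_p, fp$pred_id)

  # merge detection
  free <- cand[cand$gt_id %in% un_g & cand$pred_id %in% un_p, , drop = FALSE]
  for (p in un_p) {
    rows <- free[free$pred_id == p &
                 free$intersection > kap * ag[free$gt_id], , drop = FALSE]
    if (nrow(rows) >= 2) {
      si <- sum(rows$intersection); sa <- sum(ag[rows$gt_id])
      if (si / (ap[p] + sa - si) >= tau) {
        fp <- rbind(fp, data.frame(pred_id = p, reason = "merged_prediction"))
        fn <- rbind(fn, data.frame(gt_id = rows$gt_id,
                                   reason = "merged_negative"))
      }
    }
  }
  un_g <- setdiff(un_g, fn$gt_id)
  un_p <- setdiff(un_p, fp$pred_id)

  if (length(un_g)) fn <- rbind(fn, data.frame(gt_id = un_g, reason = "missed"))
  if (length(un_p)) fp <- rbind(fp, data.frame(pred_id = un_p, reason = "spurious"))
  fn <- fn[order(fn$gt_id), , drop = FALSE]; rownames(fn) <- NULL
  fp <- fp[order(fp$pred_id), , drop = FALSE]; rownames(fp) <- NULL

  structure(list(matched = matched, fn = fn, fp = fp,
                 excluded_gt = as.integer(ex_g), excluded_pred = as.integer(ex_p),
                 n_gt = ng, n_pred = np, gt_areas = ag, pred_areas = ap,
                 cfg = cfg),
            class = "qwa_match")
}

#' Transpose a match result
#'
#' Returns the result of evaluating the two maps with roles reversed
#' (prediction treated as reference): matched pairs are transposed, FP and FN
#' lists are exchanged, and split/merge subcategories swap
#' (`disconnected_positive` <-> `merged_negative`,
#' `disconnected_victim` <-> `merged_prediction`, `missed` <-> `spurious`).
#'
#' @param result a `qwa_match`.
#' @return a `qwa_match` equal to `match_instances(pred, gt, cfg)`.
#' @export
swap_roles <- function(result) {
  stopifnot(inherits(result, "qwa_match"))
  fn2p <- c(missed = "spurious", merged_negative = "disconnected_positive",
            disconnected_victim = "merged_prediction")
  fp2n <- c(spurious = "missed", disconnected_positive = "merged_negative",
            merged_prediction = "disconnected_victim")
  matched <- result$matched[c("pred_id", "gt_id", "iou", "intersection")]
  names(matched)[1:2] <- c("gt_id", "pred_id")
  matched <- matched[order(matched$gt_id), , drop = FALSE]
  rownames(matched) <- NULL
  fn <- data.frame(gt_id = result$fp$pred_id,
                   reason = unname(fp2n[result$fp$reason]))
  fp <- data.frame(pred_id = result$fn$gt_id,
                   reason = unname(fn2p[result$fn$reason]))
  fn <- fn[order(fn$gt_id), , drop = FALSE]; rownames(fn) <- NULL
  fp <- fp[order(fp$pred_id), , drop = FALSE]; rownames(fp) <- NULL
  structure(list(matched = matched, fn = fn, fp = fp,
                 excluded_gt = result$excluded_pred,
                 excluded_pred = result$excluded_gt,
                 n_gt = result$n_pred, n_pred = result$n_gt,
                 gt_areas = result$pred_areas, pred_areas = result$gt_areas,
                 cfg = result$cfg),
            class = "qwa_match")
}

#' @export
print.qwa_match <- function(x, ...) {
  cat("Cell instance match result\n")
  cat(sprintf("  ground truth: %d cells (%d excluded at border)\n",
              x$n_gt, length(x$excluded_gt)))
  cat(sprintf("  predictions : %d cells (%d excluded at border)\n",
              x$n_pred, length(x$excluded_pred)))
  cat(sprintf("  matched (TP): %d\n", nrow(x$matched)))
  if (nrow(x$fn)) {
    tb <- table(x$fn$reason)
    cat(sprintf("  FN: %d (%s)\n", nrow(x$fn),
                paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  } else cat("  FN: 0\n")
  if (nrow(x$fp)) {
    tb <- table(x$fp$reason)
    cat(sprintf("  FP: %d (%s)\n", nrow(x$fp),
                paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  } else cat("  FP: 0\n")
  invisible(x)
}
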