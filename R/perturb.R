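# Planned error injection: derive a prediction from a ground truth with an
# exactly known set of instance errors, so the matcher can be tested against
# a constructed truth rather than a probabilistic one. Construction rules are
# chosen so that, at the default matching thresholds (IoU 0.5, containment
# 0.5), every injected error is classified unambiguously:
#   * split fragments are capped at 0.45 of the parent area (no fragment can
#     reach IoU 0.5 on its own);
#   * merge partners have equal pixel areas (the merged blob has IoU < 0.5
#     with either partner but >= 0.5 with their union);
#   * spurious blobs keep >= 2 px clearance from every true cell;
#   * erosion/dilation is bounded so the perturbed cell stays matched.

#' Perturbation plan
#'
#' @param n_delete cells removed entirely (expected `missed`).
#' @param n_spurious background blobs added (expected `spurious`).
#' @param n_split cells cut into two fragments (expected one
#'   `disconnected_victim` + two `disconnected_positive` each).
#' @param n_merge adjacent equal-area cell pairs bridged into one prediction
#'   (expected two `merged_negative` + one `merged_prediction` each).
#' @param n_erode,erode_px cells shrunk by a disc of radius `erode_px`
#'   (stay matched; per-cell FN pixels only).
#' @param n_dilate,dilate_px cells grown into the background by a disc of
#'   radius `dilate_px` (stay matched; per-cell FP pixels only).
#' @param seed integer seed driving all random choices.
#' @return list of class `qwa_perturbation_plan`.
#' @export
perturbation_plan <- function(n_delete = 0, n_spurious = 0, n_split = 0,
                              n_merge = 0, n_erode = 0, erode_px = 1,
                              n_dilate = 0, dilate_px = 1, seed = 1) {
  cnt <- c(n_delete, n_spurious, n_split, n_merge, n_erode, n_dilate)
  if (any(cnt < 0) || any(cnt != floor(cnt))) stop("counts must be non-negative integers")
  if (n_erode > 0 && erode_px < 1) stop("erode_px must be >= 1")
  if (n_dilate > 0 && dilate_px < 1) stop("dilate_px must be >= 1")
  structure(list(n_delete = n_delete, n_spurious = n_spurious,
                 n_split = n_split, n_merge = n_merge,
                 n_erode = n_erode, erode_px = erode_px,
                 n_dilate = n_dilate, dilate_px = dilate_px, seed = seed),
            class = "qwa_perturbation_plan")
}

# connectivity check on a pixel set (rows/cols), 8-connected
is_single_component <- function(rows, cols) {
  r0 <- min(rows); c0 <- min(cols)
  m <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  m[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  n_instances(binary_mask_to_labelmap(m, 8)) == 1L
}

#' Perturb a ground truth according to a plan
#'
#' Only interior (non-border-touching) cells are perturbed; border cells are
#' copied verbatim and end up excluded on both sides. The returned `expected`
#' counts are the exact categories [match_instances()] must report at the
#' default [match_config()].
#'
#' @param gt normalized label map.
#' @param plan a [perturbation_plan()].
#' @return list: `pred` (normalized label map), `expected` (named integer
#'   vector: `matched`, `fn_missed`, `fn_disconnected_victim`,
#'   `fn_merged_negative`, `fp_spurious`, `fp_disconnected_positive`,
#'   `fp_merged_prediction`, `excluded_gt`, `excluded_pred`). Errors when the
#'   plan is infeasible for the scene.
#' @export
perturb_labelmap <- function(gt, plan) {
  validate_labelmap(gt, normalized = TRUE)
  stopifnot(inherits(plan, "qwa_perturbation_plan"))
  set.seed(plan$seed)
  h <- nrow(gt); w <- ncol(gt)
  border <- find_incomplete(gt)
  interior <- setdiff(seq_len(n_instances(gt)), border)
  need <- plan$n_delete + plan$n_split + 2 * plan$n_merge +
    plan$n_erode + plan$n_dilate
  if (need > length(interior))
    stop("infeasible plan: needs ", need, " interior cells, scene has ",
         length(interior))
  inst <- extract_instances(gt)
  areas <- inst$area
  pred <- gt
  pool <- sample(interior)               # randomized, seed-driven
  take <- function(n, ok = function(id) TRUE) {
    got <- integer(0)
    while (length(got) < n) {
      cand <- setdiff(pool, got)
      cand <- cand[vapply(cand, ok, TRUE)]
      if (!length(cand)) stop("infeasible plan: not enough suitable cells")
      got <- c(got, cand[1])
    }
    pool <<- setdiff(pool, got)
    got
  }

  # ---- merges: pairs of equal-area nearby interior cells ----
  merge_pairs <- list()
  if (plan$n_merge > 0) {
    for (k in seq_len(plan$n_merge)) {
      found <- FALSE
      for (a in pool) {
        partners <- pool[pool != a & areas[pool] == areas[a]]
        if (!length(partners)) next
        d <- sqrt((inst$centroid_row[partners] - inst$centroid_row[a])^2 +
                  (inst$centroid_col[partners] - inst$centroid_col[a])^2)
        for (b in partners[order(d)][seq_len(min(3, length(partners)))]) {
          br <- bridge_pixels(gt, pred, inst, a, b)
          if (is.null(br)) next
          A <- areas[a] + areas[b]; nb <- nrow(br)
          # classification guarantees at tau = kappa = 0.5
          if (areas[a] / (A + nb) >= 0.5 || areas[b] / (A + nb) >= 0.5) next
          if (A / (A + nb) < 0.5) next
          pred[pred == b] <- a
          if (nb) pred[br] <- a
          merge_pairs[[k]] <- c(a, b)
          pool <- setdiff(pool, c(a, b))
          found <- TRUE
          break
        }
        if (found) break
      }
      if (!found) stop("infeasible plan: no bridgeable equal-area cell pair left")
    }
  }

  # ---- splits: cut a band through the middle of the longer axis ----
  if (plan$n_split > 0) {
    next_id <- max(pred) + 1L
    done <- 0
    for (id in pool) {
      if (done == plan$n_split) break
      cut <- split_cell(pred, id, next_id)
      if (is.null(cut)) next
      pred <- cut
      next_id <- next_id + 1L
      pool <- setdiff(pool, id)
      done <- done + 1
    }
    if (done < plan$n_split) stop("infeasible plan: not enough splittable cells")
  }

  # ---- deletions ----
  if (plan$n_delete > 0) {
    del <- take(plan$n_delete)
    pred[pred %in% del] <- 0L
  }

  # ---- erosions ----
  if (plan$n_erode > 0) {
    done <- 0
    for (id in pool) {
      if (done == plan$n_erode) break
      er <- erode_cell(pred, id, plan$erode_px)
      if (is.null(er)) next
      pred <- er; pool <- setdiff(pool, id); done <- done + 1
    }
    if (done < plan$n_erode) stop("infeasible plan: not enough erodible cells")
  }

  # ---- dilations (into free background only) ----
  if (plan$n_dilate > 0) {
    done <- 0
    for (id in pool) {
      if (done == plan$n_dilate) break
      di <- dilate_cell(gt, pred, id, plan$dilate_px)
      if (is.null(di)) next
      pred <- di; pool <- setdiff(pool, id); done <- done + 1
    }
    if (done < plan$n_dilate) stop("infeasible plan: not enough dilatable cells")
  }

  # ---- spurious blobs: >= 2 px from any gt cell, clear of all predictions ----
  if (plan$n_spurious > 0) {
    gt_halo <- EBImage::dilate(gt > 0L, EBImage::makeBrush(5, "box")) > 0
    for (k in seq_len(plan$n_spurious)) {
      placed <- FALSE
      for (try in 1:300) {
        r0 <- sample.int(h - 4L, 1) + 2L; c0 <- sample.int(w - 4L, 1) + 2L
        rows <- (r0 - 2L):(r0 + 2L); cols <- (c0 - 2L):(c0 + 2L)
        if (any(gt_halo[rows, cols]) || any(pred[rows, cols] > 0L)) next
        pred[(r0 - 1L):(r0 + 1L), (c0 - 1L):(c0 + 1L)] <- max(pred) + 1L
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible plan: no room for spurious blob ", k)
    }
  }

  pred <- normalize_labels(pred)
  expected <- c(
    matched = length(interior) - plan$n_delete - plan$n_split - 2L * plan$n_merge,
    fn_missed = plan$n_delete,
    fn_disconnected_victim = plan$n_split,
    fn_merged_negative = 2L * plan$n_merge,
    fp_spurious = plan$n_spurious,
    fp_disconnected_positive = 2L * plan$n_split,
    fp_merged_prediction = plan$n_merge,
    excluded_gt = length(border),
    excluded_pred = length(border))
  list(pred = pred, expected = expected)
}

# thin bridge of background pixels between two cells; NULL if none usable
bridge_pixels <- function(gt, pred, inst, a, b) {
  p1 <- c(inst$centroid_row[a], inst$centroid_col[a])
  p2 <- c(inst$centroid_row[b], inst$centroid_col[b])
  n <- max(2L, ceiling(2 * sqrt(sum((p1 - p2)^2))))
  t <- seq(0, 1, length.out = n)
  rr <- round(p1[1] + t * (p2[1] - p1[1])) + 1L   # centroids are 0-based
  cc <- round(p1[2] + t * (p2[2] - p1[2])) + 1L
  # thicken by one pixel each side, clip, keep free background
  pts <- unique(rbind(cbind(rr, cc), cbind(rr + 1L, cc), cbind(rr, cc + 1L)))
  ok <- pts[, 1] >= 1 & pts[, 1] <= nrow(gt) & pts[, 2] >= 1 & pts[, 2] <= ncol(gt)
  pts <- pts[ok, , drop = FALSE]
  free <- gt[pts] == 0L & pred[pts] == 0L
  pts <- pts[free, , drop = FALSE]
  # refuse if the straight path crosses a third cell's pixels heavily
  line_ids <- gt[cbind(rr[rr >= 1 & rr <= nrow(gt)], cc[rr >= 1 & rr <= nrow(gt)])]
  other <- setdiff(unique(line_ids[line_ids > 0L]), c(a, b))
  if (length(other)) return(NULL)
  pts
}

# cut cell `id` into two fragments each <= 0.45 of its area; second fragment
# gets `new_id`; NULL if the cell cannot be cut cleanly
split_cell <- function(pred, id, new_id) {
  px <- which(pred == id, arr.ind = TRUE)
  A <- nrow(px)
  if (A < 24) return(NULL)
  span_r <- diff(range(px[, 1])); span_c <- diff(range(px[, 2]))
  axis <- if (span_r >= span_c) 1L else 2L
  coord <- px[, axis]
  tabs <- table(coord)
  vals <- as.integer(names(tabs)); cnt <- as.integer(tabs)
  cum <- cumsum(cnt)
  lo_i <- max(which(cum <= 0.45 * A), 0L)
  if (lo_i == 0L) return(NULL)
  rev_cum <- rev(cumsum(rev(cnt)))
  hi_i <- min(which(rev_cum <= 0.45 * A), Inf)
  if (!is.finite(hi_i) || hi_i <= lo_i + 1L) return(NULL)
  f1 <- coord <= vals[lo_i]
  f2 <- coord >= vals[hi_i]
  a1 <- sum(f1); a2 <- sum(f2); cut <- A - a1 - a2
  if (a1 < 4 || a2 < 4) return(NULL)
  if ((A - cut) / A < 0.5) return(NULL)          # union must still reach IoU 0.5
  if (!is_single_component(px[f1, 1], px[f1, 2])) return(NULL)
  if (!is_single_component(px[f2, 1], px[f2, 2])) return(NULL)
  pred[px[!(f1 | f2), , drop = FALSE]] <- 0L
  pred[px[f2, , drop = FALSE]] <- new_id
  pred
}

# erode cell in place; NULL if it would unmatch, vanish or fragment
erode_cell <- function(pred, id, r) {
  px <- which(pred == id, arr.ind = TRUE)
  pad <- r + 1L
  r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(nrow(pred), max(px[, 1]) + pad)
  c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(ncol(pred), max(px[, 2]) + pad)
  m <- pred[r0:r1, c0:c1, drop = FALSE] == id
  er <- EBImage::erode(m, EBImage::makeBrush(2L * r + 1L, "disc")) > 0
  A <- sum(m); Ae <- sum(er)
  if (Ae < 4 || Ae / A < 0.55) return(NULL)      # must stay safely matched
  pe <- which(er, arr.ind = TRUE)
  if (!is_single_component(pe[, 1], pe[, 2])) return(NULL)
  sub <- pred[r0:r1, c0:c1]
  sub[m] <- 0L
  sub[er] <- id
  pred[r0:r1, c0:c1] <- sub
  pred
}

# dilate cell into free background (never into other gt or predicted cells)
dilate_cell <- function(gt, pred, id, r) {
  px <- which(pred == id, arr.ind = TRUE)
  pad <- r + 1L
  r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(nrow(pred), max(px[, 1]) + pad)
  c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(ncol(pred), max(px[, 2]) + pad)
  m <- pred[r0:r1, c0:c1, drop = FALSE] == id
  di <- EBImage::dilate(m, EBImage::makeBrush(2L * r + 1L, "disc")) > 0
  grow <- di & !m &
    gt[r0:r1, c0:c1, drop = FALSE] == 0L &
    pred[r0:r1, c0:c1, drop = FALSE] == 0L
  A <- sum(m); Ad <- A + sum(grow)
  if (A / Ad < 0.55) return(NULL)                # must stay safely matched
  sub <- pred[r0:r1, c0:c1]
  sub[grow] <- id
  pred[r0:r1, c0:c1] <- sub
  pred
}
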