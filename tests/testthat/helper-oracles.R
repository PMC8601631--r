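# Independent oracles and small fixture builders used across the suite.
# These deliberately use different algorithms from the package internals
# (stack-based flood fill vs graph components, per-pixel double loops vs
# vectorized tables, exhaustive search vs greedy matching).

# stack-based flood fill connected components, raster-order ids
flood_fill_labels <- function(mask, connectivity = 8) {
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {   # raster scan (row-major)
    if (!mask[r, cc] || lab[r, cc] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; ccc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= h && ccc >= 1 && ccc <= w &&
            mask[rr, ccc] && lab[rr, ccc] == 0L) {
          lab[rr, ccc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, ccc)
        }
      }
    }
  }
  lab
}

# per-pixel double-loop intersection counts
intersection_oracle <- function(gt, pred) {
  counts <- list()
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    g <- gt[i, j]; p <- pred[i, j]
    if (g > 0L && p > 0L) {
      k <- paste(g, p)
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  if (!length(counts)) {
    return(data.frame(gt_id = integer(0), pred_id = integer(0),
                      intersection = integer(0)))
  }
  ks <- do.call(rbind, strsplit(names(counts), " "))
  out <- data.frame(gt_id = as.integer(ks[, 1]), pred_id = as.integer(ks[, 2]),
                    intersection = unlist(counts, use.names = FALSE))
  out[order(out$gt_id, out$pred_id), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive optimal one-to-one assignment maximizing (pair count, total IoU)
exhaustive_match <- function(it, tau) {
  cand <- it[it$iou >= tau, , drop = FALSE]
  if (!nrow(cand)) return(cand[0, c("gt_id", "pred_id")])
  gts <- unique(cand$gt_id)
  best <- list(count = -1L, iou = -Inf, rows = integer(0))
  recurse <- function(gi, used_p, rows) {
    if (gi > length(gts)) {
      tot <- if (length(rows)) sum(cand$iou[rows]) else 0
      if (length(rows) > best$count ||
          (length(rows) == best$count && tot > best$iou + 1e-12)) {
        best <<- list(count = length(rows), iou = tot, rows = rows)
      }
      return(invisible())
    }
    opts <- which(cand$gt_id == gts[gi] & !(cand$pred_id %in% used_p))
    for (o in opts) recurse(gi + 1L, c(used_p, cand$pred_id[o]), c(rows, o))
    recurse(gi + 1L, used_p, rows)        # leave this gt unmatched
  }
  recurse(1L, integer(0), integer(0))
  out <- cand[best$rows, c("gt_id", "pred_id"), drop = FALSE]
  out[order(out$gt_id), , drop = FALSE]
}

# small label map of non-overlapping random rectangles (interior by default)
random_rect_map <- function(h, w, n, min_side = 4, max_side = 10,
                            margin = 2) {
  lab <- matrix(0L, h, w)
  id <- 0L
  for (i in seq_len(n)) {
    for (try in 1:60) {
      sh <- sample(min_side:max_side, 1); sw <- sample(min_side:max_side, 1)
      r0 <- sample(seq.int(1 + margin, max(1 + margin, h - sh - margin)), 1)
      c0 <- sample(seq.int(1 + margin, max(1 + margin, w - sw - margin)), 1)
      rr <- r0:(r0 + sh - 1L); cc <- c0:(c0 + sw - 1L)
      if (max(rr) > h - margin || max(cc) > w - margin) next
      pad_r <- max(1, r0 - 1):min(h, max(rr) + 1)
      pad_c <- max(1, c0 - 1):min(w, max(cc) + 1)
      if (any(lab[pad_r, pad_c] > 0L)) next
      id <- id + 1L
      lab[rr, cc] <- id
      break
    }
  }
  normalize_labels(lab)
}

# prediction derived from a gt map: jitter/resize most cells, drop and add a few
jittered_prediction <- function(gt, keep_prob = 0.85, extra = 2) {
  h <- nrow(gt); w <- ncol(gt)
  inst <- extract_instances(gt)
  pred <- matrix(0L, h, w)
  id <- 0L
  for (i in inst$id) {
    if (runif(1) > keep_prob) next
    dr <- sample(-2:2, 1); dc <- sample(-2:2, 1)
    px <- which(gt == i, arr.ind = TRUE)
    rr <- px[, 1] + dr; cc <- px[, 2] + dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    if (!any(ok)) next
    id <- id + 1L
    sel <- cbind(rr[ok], cc[ok])
    free <- pred[sel] == 0L
    pred[sel[free, , drop = FALSE]] <- id
  }
  for (e in seq_len(extra)) {
    sh <- sample(3:6, 1); sw <- sample(3:6, 1)
    r0 <- sample(seq_len(max(1, h - sh)), 1); c0 <- sample(seq_len(max(1, w - sw)), 1)
    sel <- as.matrix(expand.grid(r0:(r0 + sh - 1L), c0:(c0 + sw - 1L)))
    free <- pred[sel] == 0L
    if (any(free)) {
      id <- id + 1L
      pred[sel[free, , drop = FALSE]] <- id
    }
  }
  normalize_labels(pred)
}

# small conifer scene for perturbation tests
small_conifer <- function(seed, n_rings = 2, cells_per_ring = 6, n_files = 6) {
  generate_scene(wood_type_config("conifer", n_rings = n_rings,
                                  cells_per_ring = cells_per_ring,
                                  n_files = n_files, seed = seed))
}

# category counts of a match result, in the perturbation-oracle layout
match_category_counts <- function(res) {
  c(matched = nrow(res$matched),
    fn_missed = sum(res$fn$reason == "missed"),
    fn_disconnected_victim = sum(res$fn$reason == "disconnected_victim"),
    fn_merged_negative = sum(res$fn$reason == "merged_negative"),
    fp_spurious = sum(res$fp$reason == "spurious"),
    fp_disconnected_positive = sum(res$fp$reason == "disconnected_positive"),
    fp_merged_prediction = sum(res$fp$reason == "merged_prediction"),
    excluded_gt = length(res$excluded_gt),
    excluded_pred = length(res$excluded_pred))
}

# Table-4 worked-example geometry: one pair per map
table4_underestimated <- function() {
  gt <- matrix(0L, 60, 80); gt[6:40, 6:54] <- 1L          # 35 x 49 = 1715 px
  pred <- matrix(0L, 60, 80)
  pred[6:15, 6:53] <- 1L; pred[16, 6:7] <- 1L             # 482 px inside gt
  list(gt = gt, pred = pred)
}

table4_overestimated <- function() {
  gt <- matrix(0L, 50, 60); gt[21:25, 21:37] <- 1L        # 5 x 17 = 85 px
  pred <- matrix(0L, 50, 60); pred[16:35, 16:45] <- 1L    # 20 x 30 = 600 px
  list(gt = gt, pred = pred)
}
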