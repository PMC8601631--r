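# Colour-coded error maps: visual comparison of a prediction against the
# ground truth, classifying every instance and every pixel of matched cells.

#' Error-map colour palette
#'
#' Categories: per-pixel classes of matched cells (`tp_pixel` light green,
#' `fn_pixel` dark green, `fp_pixel` orange), whole-instance fills
#' (`fn_instance` blue for missed cells, `fp_instance` red for spurious
#' predictions and merged-prediction extents, `disconnected_positive` magenta
#' for split fragments, `merged_negative` cyan for cells lost in a merge,
#' `incomplete` gray for border-clipped cells), and `background` black.
#' All colours must be pairwise distinct.
#'
#' @param ... named category overrides, each an RGB integer triple 0-255.
#' @return named list of RGB triples, class `qwa_palette`.
#' @export
error_palette <- function(...) {
  pal <- list(
    tp_pixel = c(144, 238, 144),   # light green
    fn_pixel = c(0, 100, 0),       # dark green
    fp_pixel = c(255, 165, 0),     # orange
    fn_instance = c(0, 0, 255),    # blue
    fp_instance = c(255, 0, 0),    # red
    disconnected_positive = c(255, 0, 255),  # magenta
    merged_negative = c(0, 255, 255),        # cyan
    incomplete = c(128, 128, 128), # gray
    background = c(0, 0, 0)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(pal))
  if (length(bad)) stop("unknown palette categories: ", paste(bad, collapse = ", "))
  pal[names(ov)] <- lapply(ov, function(v) as.integer(v))
  key <- vapply(pal, paste, "", collapse = ",")
  if (anyDuplicated(key)) stop("palette colours must be pairwise distinct")
  structure(pal, class = "qwa_palette")
}

#' Render an error map
#'
#' Paints, in this precedence order (later layers overwrite earlier ones):
#' incomplete (excluded) cells and predictions; spurious predictions and
#' merged-prediction extents (`fp_instance`); missed cells and split victims
#' (`fn_instance`); split fragments (`disconnected_positive`, drawn over
#' their victim so only the cut pixels stay `fn_instance`); cells lost in a
#' merge (`merged_negative`, drawn over the merged prediction so only its
#' bridging pixels stay `fp_instance`); and finally the per-pixel TP/FN/FP
#' classes of matched cells. With a base image the overlay is alpha-blended;
#' [color_census()] requires the unblended form. A legend strip of colour
#' swatches (category order as in [error_palette()]) is appended below the
#' map and excluded from the census via the `legend_rows` attribute.
#'
#' @param gt,pred label maps.
#' @param result the [match_instances()] result for them.
#' @param palette an [error_palette()].
#' @param base optional RGB base image (same height/width) to blend over.
#' @param alpha blend weight of the overlay when `base` is given (default 0.6).
#' @param legend append the swatch strip (default `TRUE`).
#' @return height x width x 3 integer array with attributes `legend_rows`
#'   (number of appended legend rows) and `legend_order`.
#' @export
render_error_map <- function(gt, pred, result, palette = error_palette(),
                             base = NULL, alpha = 0.6, legend = TRUE) {
  stopifnot(inherits(result, "qwa_match"))
  if (!all(dim(gt) == dim(pred))) stop("gt and pred dimensions differ")
  if (!is.null(base) && !all(dim(base)[1:2] == dim(gt)))
    stop("base image dimensions differ from the maps")
  h <- nrow(gt); w <- ncol(gt)
  cat_id <- matrix(0L, h, w)             # index into palette order
  cats <- names(palette)
  ci <- function(nm) match(nm, cats)

  paint_ids <- function(map, ids, category) {
    if (length(ids)) cat_id[map %in% ids] <<- ci(category)
  }
  cat_id[] <- ci("background")
  paint_ids(gt, result$excluded_gt, "incomplete")
  paint_ids(pred, result$excluded_pred, "incomplete")
  paint_ids(pred, result$fp$pred_id[result$fp$reason == "spurious"], "fp_instance")
  paint_ids(pred, result$fp$pred_id[result$fp$reason == "merged_prediction"], "fp_instance")
  paint_ids(gt, result$fn$gt_id[result$fn$reason %in%
                                c("missed", "disconnected_victim")], "fn_instance")
  paint_ids(pred, result$fp$pred_id[result$fp$reason == "disconnected_positive"],
            "disconnected_positive")
  paint_ids(gt, result$fn$gt_id[result$fn$reason == "merged_negative"],
            "merged_negative")
  if (nrow(result$matched)) {
    gm <- gt %in% result$matched$gt_id
    pm <- pred %in% result$matched$pred_id
    cat_id[gm & pm] <- ci("tp_pixel")
    cat_id[gm & !pm] <- ci("fn_pixel")
    cat_id[!gm & pm] <- ci("fp_pixel")
  }

  lut <- do.call(rbind, palette)         # k x 3
  img <- array(0L, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(lut[cat_id, ch], h, w)

  if (!is.null(base)) {
    keep <- cat_id == ci("background")
    for (ch in 1:3) {
      layer <- img[, , ch]
      blended <- round((1 - alpha) * base[, , ch] + alpha * layer)
      blended[keep] <- base[, , ch][keep]
      img[, , ch] <- blended
    }
  }
  storage.mode(img) <- "integer"

  legend_rows <- 0L
  if (legend) {
    strip_h <- 12L
    strip <- array(0L, c(strip_h * length(cats), w, 3))
    sw <- max(1L, min(w, 40L))
    for (i in seq_along(cats)) {
      rows <- ((i - 1L) * strip_h + 1L):(i * strip_h)
      for (ch in 1:3) strip[rows, seq_len(sw), ch] <- palette[[i]][ch]
    }
    out <- array(0L, c(h + dim(strip)[1], w, 3))
    out[seq_len(h), , ] <- img
    out[h + seq_len(dim(strip)[1]), , ] <- strip
    img <- out
    legend_rows <- dim(strip)[1]
  }
  attr(img, "legend_rows") <- legend_rows
  attr(img, "legend_order") <- cats
  img
}

#' Per-category pixel census of a rendered error map
#'
#' Counts the pixels of each palette category in an *unblended* render
#' (blending changes colours and breaks exact matching). Legend rows are
#' excluded using the `legend_rows` attribute. The counts reconcile with the
#' matching/metrics pixel counts: `tp_pixel`/`fn_pixel`/`fp_pixel` equal the
#' summed per-cell TP/FN/FP of matched cells, and the instance-fill
#' categories cover exactly their instances' pixels.
#'
#' @param map a [render_error_map()] output (no `base`).
#' @param palette the palette it was rendered with.
#' @return named integer vector of pixel counts per category. Errors if a
#'   pixel colour is not in the palette.
#' @export
color_census <- function(map, palette = error_palette()) {
  lr <- attr(map, "legend_rows")
  if (!is.null(lr) && lr > 0) map <- map[seq_len(dim(map)[1] - lr), , , drop = FALSE]
  key <- as.numeric(map[, , 1]) * 65536 + as.numeric(map[, , 2]) * 256 +
    as.numeric(map[, , 3])
  pal_key <- vapply(palette, function(v)
    as.numeric(v[1]) * 65536 + as.numeric(v[2]) * 256 + as.numeric(v[3]), 0)
  idx <- match(as.vector(key), pal_key)
  if (anyNA(idx)) {
    bad <- unique(as.vector(key)[is.na(idx)])[1]
    stop(sprintf("pixel colour (%d,%d,%d) not in palette (blended render?)",
                 bad %/% 65536L, (bad %/% 256L) %% 256L, bad %% 256L))
  }
  counts <- tabulate(idx, nbins = length(palette))
  setNames(as.integer(counts), names(palette))
}
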