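# Model-agnostic tiled inference: cut an image into overlapping tiles, run a
# pluggable segmentation backend per tile, and stitch tile outputs back into
# one whole-image label map. A dual-resolution merge (for ring-porous
# species, where earlywood vessels dwarf the tile-scale latewood vessels)
# combines a fine pass with a coarse half-resolution pass through a size
# gate plus IoU deduplication.

#' Tile geometry specification
#'
#' @param tile_height,tile_width tile size in px (default 1000 x 1000; use
#'   `preset = "ringporous"` for the 2000 x 3000 large-vessel geometry).
#' @param overlap shared pixels between adjacent tiles (default 100; must be
#'   smaller than both tile dimensions).
#' @param preset optional `"standard"` or `"ringporous"` shortcut.
#' @return list of class `qwa_tile_spec`.
#' @export
tile_spec <- function(tile_height = 1000, tile_width = 1000, overlap = 100,
                      preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("standard", "ringporous"))
    if (preset == "ringporous") { tile_height <- 2000; tile_width <- 3000 }
  }
  if (overlap >= min(tile_height, tile_width))
    stop("overlap must be smaller than both tile dimensions")
  if (min(tile_height, tile_width) < 1) stop("tile dimensions must be positive")
  structure(list(tile_height = as.integer(tile_height),
                 tile_width = as.integer(tile_width),
                 overlap = as.integer(overlap)),
            class = "qwa_tile_spec")
}

#' Dual-resolution merge configuration
#'
#' @param size_gate instance area (px) at and above which the coarse
#'   (large-vessel) pass is authoritative; below it the fine pass is.
#' @param dedup_iou IoU at/above which two instances are duplicates
#'   (default 0.5).
#' @param scale_factor downscale factor of the coarse pass (default 2: half
#'   resolution, doubled field of view).
#' @return list of class `qwa_dual_scale_config`.
#' @export
dual_scale_config <- function(size_gate, dedup_iou = 0.5, scale_factor = 2) {
  if (scale_factor < 1) stop("scale_factor must be >= 1")
  structure(list(size_gate = size_gate, dedup_iou = dedup_iou,
                 scale_factor = scale_factor),
            class = "qwa_dual_scale_config")
}

tile_starts <- function(extent, tile, overlap) {
  if (extent <= tile) return(1L)
  s <- seq.int(1L, extent - tile + 1L, by = tile - overlap)
  last <- extent - tile + 1L
  if (s[length(s)] != last) s <- c(s, last)
  as.integer(s)
}

#' Cut an image into overlapping tiles
#'
#' Tiles cover the image completely; adjacent tiles share `overlap` pixels;
#' when the image is larger than the tile, trailing tiles are shifted so that
#' every tile is full size and ends at the image edge; an image smaller than
#' the tile yields a single clipped tile.
#'
#' @param image H x W x 3 array or H x W matrix.
#' @param spec a [tile_spec()].
#' @return list of `list(image =, offset =)`; `offset` is the 0-based
#'   (row, col) of the tile's top-left pixel.
#' @export
make_tiles <- function(image, spec = tile_spec()) {
  stopifnot(inherits(spec, "qwa_tile_spec"))
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (h < 1 || w < 1) stop("image must be at least 1x1")
  rs <- tile_starts(h, spec$tile_height, spec$overlap)
  cs <- tile_starts(w, spec$tile_width, spec$overlap)
  out <- list()
  for (r0 in rs) for (c0 in cs) {
    r1 <- min(h, r0 + spec$tile_height - 1L)
    c1 <- min(w, c0 + spec$tile_width - 1L)
    tl <- if (length(d) == 3L) image[r0:r1, c0:c1, , drop = FALSE]
          else image[r0:r1, c0:c1, drop = FALSE]
    out[[length(out) + 1L]] <- list(image = tl, offset = c(r0 - 1L, c0 - 1L))
  }
  out
}

# internal: instance list of a tile output in global coordinates
tile_instances <- function(labels, offset, conf, dims, tile_idx) {
  n <- n_instances(labels)
  if (n == 0L) return(list())
  th <- nrow(labels); tw <- ncol(labels)
  H <- dims[1]
  res <- vector("list", n)
  px <- which(labels > 0L, arr.ind = TRUE)
  ids <- labels[labels > 0L]
  for (i in seq_len(n)) {
    p <- px[ids == i, , drop = FALSE]
    gr <- p[, 1] + offset[1]; gc <- p[, 2] + offset[2]
    # clipped: touches a tile edge that is strictly inside the image
    edges <- c(top = min(p[, 1]) == 1L, bottom = max(p[, 1]) == th,
               left = min(p[, 2]) == 1L, right = max(p[, 2]) == tw)
    interior_edge <- c(offset[1] + 1L > 1L, offset[1] + th < dims[1],
                       offset[2] + 1L > 1L, offset[2] + tw < dims[2])
    res[[i]] <- list(pix = (gc - 1L) * H + gr,    # global linear indices
                     conf = conf[i], tile = tile_idx,
                     clipped = any(edges & interior_edge),
                     bbox = c(min(gr), max(gr), min(gc), max(gc)))
  }
  res
}

#' Stitch tile outputs into a whole-image label map
#'
#' Instances fully inside a single tile are kept verbatim. Duplicate
#' detections of one cell in an overlap zone (IoU at/above `dedup_iou`) keep
#' the higher-confidence copy. Instances clipped by a tile edge lying inside
#' the image are kept only from a tile that contains them fully; if no tile
#' does, the clipped pieces are merged by pixel union. Output ids are
#' renumbered 1..N in raster order.
#'
#' @param tile_outputs list of `list(labels =, offset =, confidence =)`;
#'   `offset` 0-based (row, col); `confidence` per-id vector (defaults to 1).
#' @param dims `c(height, width)` of the full image.
#' @param dedup_iou duplicate IoU threshold (default 0.5).
#' @return normalized label map of size `dims`.
#' @export
stitch <- function(tile_outputs, dims, dedup_iou = 0.5) {
  H <- as.integer(dims[1]); W <- as.integer(dims[2])
  inst <- list()
  for (k in seq_along(tile_outputs)) {
    to <- tile_outputs[[k]]
    if (any(to$offset < 0) ||
        to$offset[1] + nrow(to$labels) > H || to$offset[2] + ncol(to$labels) > W)
      stop("tile ", k, " exceeds image bounds")
    conf <- to$confidence
    if (is.null(conf)) conf <- rep(1, n_instances(to$labels))
    inst <- c(inst, tile_instances(to$labels, to$offset, conf, c(H, W), k))
  }
  n <- length(inst)
  out <- matrix(0L, H, W)
  if (n == 0L) return(out)

  # overlap graph between instances of different tiles
  edges <- integer(0)
  if (n > 1) {
    bb <- do.call(rbind, lapply(inst, `[[`, "bbox"))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (inst[[i]]$tile == inst[[j]]$tile) next
      if (bb[i, 1] > bb[j, 2] || bb[j, 1] > bb[i, 2] ||
          bb[i, 3] > bb[j, 4] || bb[j, 3] > bb[i, 4]) next
      ov <- length(intersect(inst[[i]]$pix, inst[[j]]$pix))
      if (ov == 0L) next
      iou <- ov / (length(inst[[i]]$pix) + length(inst[[j]]$pix) - ov)
      if (iou >= dedup_iou || inst[[i]]$clipped || inst[[j]]$clipped)
        edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership

  kept <- list()
  for (cm in seq_len(max(comp))) {
    members <- which(comp == cm)
    uncl <- members[!vapply(members, function(i) inst[[i]]$clipped, TRUE)]
    if (length(uncl)) {
      confs <- vapply(uncl, function(i) inst[[i]]$conf, 0)
      pick <- uncl[order(-confs, uncl)][1]
      kept[[length(kept) + 1L]] <- inst[[pick]]
    } else {
      pix <- unique(unlist(lapply(members, function(i) inst[[i]]$pix)))
      kept[[length(kept) + 1L]] <- list(pix = pix,
                                        conf = max(vapply(members, function(i)
                                          inst[[i]]$conf, 0)))
    }
  }
  # paint in increasing confidence so higher confidence wins residual overlaps
  ord <- order(vapply(kept, `[[`, 0, "conf"))
  for (i in seq_along(ord)) out[kept[[ord[i]]]$pix] <- i
  normalize_labels(out)
}

#' Merge fine and coarse segmentation passes
#'
#' Keeps fine-pass instances below the size gate and coarse-pass instances at
#' or above it; fine-pass instances at/above the gate are retained as a
#' fallback when no coarse duplicate exists (so large cells are never
#' silently dropped if the coarse pass fails). Cross-pass duplicates (IoU at
#' or above `dedup_iou`) are resolved by confidence.
#'
#' @param fine `list(labels =, confidence =)` full-resolution output.
#' @param coarse_upsampled same structure, coarse pass already upsampled to
#'   identical dimensions (see [upscale_labelmap()]).
#' @param cfg a [dual_scale_config()].
#' @return normalized label map.
#' @export
merge_dual_scale <- function(fine, coarse_upsampled, cfg) {
  stopifnot(inherits(cfg, "qwa_dual_scale_config"))
  if (!all(dim(fine$labels) == dim(coarse_upsampled$labels)))
    stop("fine and coarse label maps must have identical dimensions")
  H <- nrow(fine$labels)
  grab <- function(out, pass) {
    n <- n_instances(out$labels)
    if (n == 0L) return(list())
    conf <- out$confidence
    if (is.null(conf)) conf <- rep(1, n)
    px <- which(out$labels > 0L)
    ids <- out$labels[px]
    lapply(seq_len(n), function(i)
      list(pix = px[ids == i], conf = conf[i], pass = pass,
           area = sum(ids == i)))
  }
  fi <- grab(fine, "fine")
  co <- grab(coarse_upsampled, "coarse")
  cand <- c(Filter(function(x) x$area < cfg$size_gate, fi),
            Filter(function(x) x$area >= cfg$size_gate, co))
  # fallback: large fine instances with no coarse duplicate
  kept_coarse <- Filter(function(x) x$pass == "coarse", cand)
  for (x in Filter(function(x) x$area >= cfg$size_gate, fi)) {
    dup <- any(vapply(kept_coarse, function(y) {
      ov <- length(intersect(x$pix, y$pix))
      ov / (x$area + y$area - ov) >= cfg$dedup_iou
    }, TRUE))
    if (!dup) cand[[length(cand) + 1L]] <- x
  }
  # cross-pass dedup by confidence
  n <- length(cand)
  drop <- logical(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (drop[i] || drop[j] || cand[[i]]$pass == cand[[j]]$pass) next
      ov <- length(intersect(cand[[i]]$pix, cand[[j]]$pix))
      if (ov == 0L) next
      if (ov / (cand[[i]]$area + cand[[j]]$area - ov) >= cfg$dedup_iou) {
        if (cand[[i]]$conf >= cand[[j]]$conf) drop[j] <- TRUE else drop[i] <- TRUE
      }
    }
  }
  cand <- cand[!drop]
  out <- matrix(0L, H, ncol(fine$labels))
  ord <- order(vapply(cand, `[[`, 0, "conf"))
  for (i in seq_along(ord)) out[cand[[ord[i]]]$pix] <- i
  normalize_labels(out)
}

#' Nearest-neighbour upscale of a label map
#'
#' @param map label map.
#' @param factor integer upscale factor.
#' @param dims optional `c(height, width)` to crop/pad the result to.
#' @return label map of size `dim(map) * factor` (or `dims`).
#' @export
upscale_labelmap <- function(map, factor, dims = NULL) {
  factor <- as.integer(factor)
  up <- map[rep(seq_len(nrow(map)), each = factor),
            rep(seq_len(ncol(map)), each = factor), drop = FALSE]
  if (!is.null(dims)) {
    out <- matrix(0L, dims[1], dims[2])
    r <- min(nrow(up), dims[1]); cl <- min(ncol(up), dims[2])
    out[seq_len(r), seq_len(cl)] <- up[seq_len(r), seq_len(cl)]
    up <- out
  }
  storage.mode(up) <- "integer"
  up
}

#' Downscale an RGB image by integer factor (block mean)
#' @param image H x W x 3 array.
#' @param factor integer >= 1.
#' @return downscaled integer array.
#' @export
downscale_image <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  h <- (dim(image)[1] %/% factor) * factor
  w <- (dim(image)[2] %/% factor) * factor
  out <- array(0L, c(h %/% factor, w %/% factor, 3))
  for (ch in 1:3) {
    m <- image[seq_len(h), seq_len(w), ch]
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = h %/% factor)
    m2 <- t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = w %/% factor))
    out[, , ch] <- round(m2)
  }
  storage.mode(out) <- "integer"
  out
}

#' Classical watershed baseline segmenter
#'
#' A trained-weights-free reference backend: grayscale conversion, automatic
#' threshold for the bright lumina (two-stage Otsu, see
#' [otsu_threshold()]), morphological opening,
#' distance-transform watershed to split touching lumina, and an area filter.
#' Per-instance confidence is the instance's distance-transform peak height
#' normalized by the image-wide maximum.
#'
#' @param image H x W x 3 RGB array.
#' @param params list of optional parameters: `threshold` (fixed grayscale
#'   cut in \[0,1\]; default `NULL` = Otsu), `opening_radius` (default 2),
#'   `min_area` (default 20), `max_area` (default `Inf`),
#'   `watershed_tolerance` (default 1).
#' @return `list(labels =, confidence =)`; a constant image yields an empty
#'   map, not an error.
#' @export
baseline_segment <- function(image, params = list()) {
  p <- utils::modifyList(list(threshold = NULL, opening_radius = 2,
                              min_area = 20, max_area = Inf,
                              watershed_tolerance = 1), params)
  g <- (0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]) / 255
  if (diff(range(g)) < 1e-6)
    return(list(labels = matrix(0L, nrow(g), ncol(g)), confidence = numeric(0)))
  th <- if (is.null(p$threshold)) auto_lumen_threshold(g) else p$threshold
  fg <- g > th
  if (p$opening_radius > 0) {
    br <- EBImage::makeBrush(2L * as.integer(p$opening_radius) + 1L, "disc")
    fg <- EBImage::opening(fg, br) > 0
  }
  if (!any(fg))
    return(list(labels = matrix(0L, nrow(g), ncol(g)), confidence = numeric(0)))
  dm <- EBImage::distmap(fg)
  lab <- EBImage::watershed(dm, tolerance = p$watershed_tolerance)
  lab <- matrix(as.integer(lab), nrow(g), ncol(g))
  areas <- instance_areas(lab)
  bad <- which(areas < p$min_area | areas > p$max_area)
  if (length(bad)) lab[lab %in% bad] <- 0L
  lab <- normalize_labels(lab)
  n <- n_instances(lab)
  conf <- numeric(n)
  if (n > 0) {
    peak <- tapply(dm[lab > 0L], lab[lab > 0L], max)
    conf <- as.numeric(peak) / max(dm)
  }
  list(labels = lab, confidence = conf)
}

#' Automatic lumen threshold of an RGB image's luminance
#'
#' Wood-section luminance is typically trimodal (dark walls, mid-tone
#' tissue, bright lumina), where plain Otsu tends to pick the wall-vs-rest
#' split. This helper applies Otsu a second time to the upper class when
#' that class is itself clearly spread out, isolating the bright lumen
#' mode; on genuinely bimodal images it reduces to plain Otsu. Computing the
#' threshold once on the whole image and passing it as the baseline's fixed
#' `threshold` also makes tiled runs consistent: per-tile thresholds drift
#' on tiles that contain no lumina.
#'
#' @param image H x W x 3 RGB array.
#' @return scalar threshold in \[0, 1\].
#' @export
otsu_threshold <- function(image) {
  g <- (0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]) / 255
  auto_lumen_threshold(g)
}

auto_lumen_threshold <- function(g) {
  th1 <- EBImage::otsu(g)
  upper <- g[g > th1]
  if (length(upper) > 100 && diff(range(upper)) > 0.15) {
    th2 <- EBImage::otsu(matrix(upper, ncol = 1), range = range(upper))
    frac <- mean(upper > th2)
    if (frac > 0.05 && frac < 0.95 && th2 - th1 > 0.05) return(th2)
  }
  th1
}

#' Baseline backend closure for [run_pipeline()]
#' @param params see [baseline_segment()].
#' @return function `(image) -> list(labels, confidence)` with a `name`
#'   attribute.
#' @export
baseline_backend <- function(params = list()) {
  f <- function(image) baseline_segment(image, params)
  attr(f, "name") <- "baseline"
  f
}

#' Run tiled (optionally dual-scale) segmentation on a whole image
#'
#' Tiles the image, applies the backend per tile, stitches. With a
#' `dual_scale` config a second pass runs on the image downscaled by
#' `scale_factor` (doubled field of view for large earlywood vessels), its
#' output is upscaled, and the passes are merged through [merge_dual_scale()].
#'
#' @param image H x W x 3 RGB array.
#' @param backend function `(image) -> list(labels, confidence)`, e.g.
#'   [baseline_backend()].
#' @param spec a [tile_spec()].
#' @param dual_scale optional [dual_scale_config()].
#' @param dedup_iou stitching duplicate threshold (default 0.5).
#' @return normalized whole-image label map.
#' @export
run_pipeline <- function(image, backend, spec = tile_spec(),
                         dual_scale = NULL, dedup_iou = 0.5) {
  dims <- dim(image)[1:2]
  seg_pass <- function(img) {
    tiles <- make_tiles(img, spec)
    outs <- lapply(tiles, function(t) {
      r <- backend(t$image)
      list(labels = r$labels, offset = t$offset, confidence = r$confidence)
    })
    stitch(outs, dim(img)[1:2], dedup_iou)
  }
  fine_lab <- seg_pass(image)
  if (is.null(dual_scale)) return(fine_lab)
  f <- dual_scale$scale_factor
  small <- downscale_image(image, f)
  coarse_lab <- upscale_labelmap(seg_pass(small), f, dims)
  conf_of <- function(lab) rep(1, n_instances(lab))
  merge_dual_scale(list(labels = fine_lab, confidence = conf_of(fine_lab)),
                   list(labels = coarse_lab,
                        confidence = rep(0.9, n_instances(coarse_lab))),
                   dual_scale)
}
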