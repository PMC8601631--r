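#' @importFrom stats setNames runif rnorm quantile
#' @importFrom utils write.csv read.csv head tail
NULL

# Label maps are plain integer matrices: 0 = background, each positive id one
# cell instance. Images are height x width x 3 integer arrays, channels 0-255.
# Pixel coordinates exposed to users are 0-based (x = column, y = row, origin
# top-left); R matrices are indexed 1-based internally.

#' Validate a label map
#'
#' A label map is a 2D integer matrix in which 0 marks background and every
#' positive integer identifies the lumen pixels of one cell instance. A
#' *normalized* label map uses the gap-free id set `1..N`.
#'
#' @param x matrix to validate.
#' @param normalized if `TRUE`, additionally require ids to be exactly `1..N`.
#' @return `x`, invisibly, as an integer matrix. Errors on violation.
#' @export
validate_labelmap <- function(x, normalized = FALSE) {
  if (!is.matrix(x) || length(x) == 0L)
    stop("label map must be a non-empty matrix")
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
    stop("label map values must be non-negative integers")
  if (normalized) {
    ids <- sort(unique(x[x > 0]))
    if (length(ids) && !identical(as.integer(ids), seq_len(length(ids))))
      stop("label map ids are not the gap-free set 1..N")
  }
  storage.mode(x) <- "integer"
  invisible(x)
}

#' Renumber label-map ids to 1..N in raster-scan order
#'
#' Ids are reassigned so that the instance whose first pixel is encountered
#' first in a row-major raster scan (top-left origin) gets id 1, and so on.
#' Pixel geometry is unchanged.
#'
#' @param x label map (integer matrix).
#' @return integer matrix with ids `1..N`.
#' @export
normalize_labels <- function(x) {
  validate_labelmap(x)
  storage.mode(x) <- "integer"
  v <- as.integer(t(x))                  # row-major order
  ids <- unique(v[v > 0L])
  if (!length(ids)) return(x)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- x
  nz <- x > 0L
  out[nz] <- lut[x[nz]]
  out
}

#' Number of instances in a label map
#' @param x label map.
#' @return integer count of distinct positive ids.
#' @export
n_instances <- function(x) length(unique(x[x > 0L]))

#' Pixel areas of label-map instances
#' @param x label map with normalized ids 1..N.
#' @return integer vector of length N; element i is the pixel area of id i.
#' @export
instance_areas <- function(x) {
  validate_labelmap(x)
  pos <- x[x > 0L]
  if (!length(pos)) return(integer(0))
  tabulate(pos, nbins = max(pos))
}

#' Label connected foreground regions of a binary mask
#'
#' Each maximal connected region of `TRUE` pixels receives a distinct id; ids
#' are assigned in raster-scan order of each region's first-encountered pixel,
#' so the output is deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8): whether diagonal neighbours connect.
#' @return normalized label map (integer matrix).
#' @export
binary_mask_to_labelmap <- function(mask, connectivity = 8) {
  if (!is.matrix(mask) || length(mask) == 0L)
    stop("mask must be a non-empty matrix")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)                      # column-major linear indices
  lab <- matrix(0L, h, w)
  if (!length(fg)) return(lab)

  vid <- integer(h * w)                  # linear index -> vertex id
  vid[fg] <- seq_along(fg)

  edge_pairs <- function(dr, dc) {
    rs <- seq_len(h - dr)
    cs <- if (dc >= 0) seq_len(w - dc) else seq.int(1 - dc, w)
    a <- mask[rs, cs, drop = FALSE]
    b <- mask[rs + dr, cs + dc, drop = FALSE]
    hit <- which(a & b)
    if (!length(hit)) return(NULL)
    # recover (row, col) of 'a' cells within the submatrix
    r <- (hit - 1L) %% length(rs) + 1L
    cc <- (hit - 1L) %/% length(rs) + 1L
    r0 <- rs[r]; c0 <- cs[cc]
    cbind(vid[(c0 - 1L) * h + r0], vid[(c0 + dc - 1L) * h + r0 + dr])
  }

  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  el <- do.call(rbind, lapply(offs, function(o) edge_pairs(o[1], o[2])))

  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el) && nrow(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  normalize_labels(lab)
}

#' Instance table of a label map
#'
#' One row per instance id with area, bounding box, border contact and
#' centroid. Bounding-box fields are 0-based inclusive pixel coordinates
#' (`x` = column, `y` = row); centroids are 0-based real coordinates.
#'
#' @param map normalized label map.
#' @return data.frame with columns `id`, `area`, `min_x`, `min_y`, `max_x`,
#'   `max_y`, `touches_border`, `centroid_row`, `centroid_col`, sorted by id.
#' @export
extract_instances <- function(map) {
  validate_labelmap(map, normalized = TRUE)
  h <- nrow(map); w <- ncol(map)
  nz <- which(map > 0L)
  if (!length(nz)) {
    return(data.frame(id = integer(0), area = integer(0),
                      min_x = integer(0), min_y = integer(0),
                      max_x = integer(0), max_y = integer(0),
                      touches_border = logical(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  ids <- map[nz]
  r <- (nz - 1L) %% h + 1L
  cc <- (nz - 1L) %/% h + 1L
  n <- max(ids)
  area <- tabulate(ids, n)
  min_r <- as.integer(tapply(r, ids, min)); max_r <- as.integer(tapply(r, ids, max))
  min_c <- as.integer(tapply(cc, ids, min)); max_c <- as.integer(tapply(cc, ids, max))
  data.frame(
    id = seq_len(n),
    area = area,
    min_x = min_c - 1L, min_y = min_r - 1L,
    max_x = max_c - 1L, max_y = max_r - 1L,
    touches_border = min_r == 1L | max_r == h | min_c == 1L | max_c == w,
    centroid_row = as.numeric(tapply(r - 1L, ids, mean)),
    centroid_col = as.numeric(tapply(cc - 1L, ids, mean))
  )
}

#' Bounding boxes of label-map instances
#'
#' The box of an id is the minimal axis-aligned rectangle containing all of
#' its pixels, reported as 0-based inclusive min/max X (column) and Y (row)
#' coordinates.
#'
#' @param map normalized label map.
#' @return data.frame with columns `id`, `min_x`, `min_y`, `max_x`, `max_y`.
#' @export
labelmap_to_boxes <- function(map) {
  inst <- extract_instances(map)
  inst[c("id", "min_x", "min_y", "max_x", "max_y")]
}

#' Ids of instances clipped by the image border
#'
#' An instance is *incomplete* when at least one of its pixels lies on the
#' outermost row or column frame; such cells are excluded from evaluation
#' because their true lumen extent is unknowable.
#'
#' @param map label map.
#' @return integer vector of border-touching ids (sorted).
#' @export
find_incomplete <- function(map) {
  validate_labelmap(map)
  h <- nrow(map); w <- ncol(map)
  frame <- c(map[1, ], map[h, ], map[, 1], map[, w])
  sort(unique(frame[frame > 0L]))
}
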