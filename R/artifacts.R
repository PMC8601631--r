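# Slide-artifact injection: corrupts the *image* of a synthetic scene inside
# recorded regions while leaving the ground-truth label map untouched (the
# ground truth marks true lumina regardless of image quality).

#' Artifact configuration
#'
#' Counts/intensities for the catalogue of slide and acquisition artifacts:
#' dust particles, overlapping/folded tissue, stains of variable intensity,
#' paraffin drops, broken cell walls, blurred regions and an uneven
#' illumination gradient. All zero by default.
#'
#' @param dust_particles number of small dark pollution blobs.
#' @param overlapping_tissue number of translucent folded-tissue bands.
#' @param stains number of colour-solution stain discs.
#' @param stain_intensity stain blend weight in (0, 1], default 0.5.
#' @param paraffin_drops number of bright translucent paraffin discs.
#' @param broken_walls number of wall segments erased (wall breaks).
#' @param blur_regions number of rectangular out-of-focus regions.
#' @param illumination_gradient multiplicative left-to-right light falloff in
#'   \[0, 1); 0 disables.
#' @param seed integer seed, default 1.
#' @return list of class `qwa_artifact_config`.
#' @export
artifact_config <- function(dust_particles = 0, overlapping_tissue = 0,
                            stains = 0, stain_intensity = 0.5,
                            paraffin_drops = 0, broken_walls = 0,
                            blur_regions = 0, illumination_gradient = 0,
                            seed = 1) {
  cnt <- c(dust_particles, overlapping_tissue, stains, paraffin_drops,
           broken_walls, blur_regions)
  if (any(cnt < 0)) stop("artifact counts must be non-negative")
  structure(list(dust_particles = dust_particles,
                 overlapping_tissue = overlapping_tissue, stains = stains,
                 stain_intensity = stain_intensity,
                 paraffin_drops = paraffin_drops, broken_walls = broken_walls,
                 blur_regions = blur_regions,
                 illumination_gradient = illumination_gradient, seed = seed),
            class = "qwa_artifact_config")
}

#' Inject slide artifacts into a synthetic scene
#'
#' Alters image pixels inside recorded regions only; the label map is never
#' modified. Each region records its type, bounding box and the ground-truth
#' ids it overlaps.
#'
#' @param scene a [generate_scene()] result.
#' @param cfg an [artifact_config()].
#' @return the scene with a corrupted `image` and an `artifacts` data.frame
#'   (`type`, `min_x`, `min_y`, `max_x`, `max_y` 0-based inclusive,
#'   `overlapped_ids` comma-separated gt ids under the region).
#' @export
inject_artifacts <- function(scene, cfg) {
  stopifnot(inherits(scene, "qwa_scene"), inherits(cfg, "qwa_artifact_config"))
  set.seed(cfg$seed)
  img <- scene$image
  labels <- scene$labels
  h <- dim(img)[1]; w <- dim(img)[2]
  regions <- list()
  add_region <- function(type, rows, cols, mask = NULL) {
    if (is.null(mask)) {
      sub <- labels[rows, cols, drop = FALSE]
    } else {
      sub <- labels * 0L; sub[mask] <- labels[mask]
    }
    ids <- sort(unique(sub[sub > 0L]))
    regions[[length(regions) + 1L]] <<- data.frame(
      type = type, min_x = min(cols) - 1L, min_y = min(rows) - 1L,
      max_x = max(cols) - 1L, max_y = max(rows) - 1L,
      overlapped_ids = paste(ids, collapse = ","))
  }
  blend_disc <- function(r0, c0, rad, colr, wgt) {
    off <- disc_offsets(rad)
    rr <- r0 + off$dr; cc <- c0 + off$dc
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    idx <- cbind(rr[ok], cc[ok])
    for (ch in 1:3) {
      m <- img[, , ch]
      m[idx] <- round((1 - wgt) * m[idx] + wgt * colr[ch])
      img[, , ch] <<- m
    }
    add_region_disc(r0, c0, rad)
  }
  add_region_disc <- function(r0, c0, rad) {
    rows <- max(1, r0 - rad):min(h, r0 + rad)
    cols <- max(1, c0 - rad):min(w, c0 + rad)
    list(rows = rows, cols = cols)
  }

  for (i in seq_len(cfg$dust_particles)) {
    r0 <- sample.int(h, 1); c0 <- sample.int(w, 1); rad <- sample(2:5, 1)
    rc <- blend_disc(r0, c0, rad, c(40, 35, 30), 0.9)
    add_region("dust", rc$rows, rc$cols)
  }
  for (i in seq_len(cfg$overlapping_tissue)) {
    r0 <- sample.int(h, 1)
    band <- max(1, r0 - 12):min(h, r0 + 12)
    for (ch in 1:3)
      img[band, , ch] <- round(0.55 * img[band, , ch] + 0.45 * RENDER$tissue[ch] * 0.6)
    add_region("overlapping_tissue", band, seq_len(w))
  }
  for (i in seq_len(cfg$stains)) {
    r0 <- sample.int(h, 1); c0 <- sample.int(w, 1)
    rad <- sample(15:35, 1)
    rc <- blend_disc(r0, c0, rad, c(150, 60, 120), cfg$stain_intensity)
    add_region("stain", rc$rows, rc$cols)
  }
  for (i in seq_len(cfg$paraffin_drops)) {
    r0 <- sample.int(h, 1); c0 <- sample.int(w, 1)
    rad <- sample(10:20, 1)
    rc <- blend_disc(r0, c0, rad, c(250, 250, 245), 0.6)
    add_region("paraffin", rc$rows, rc$cols)
  }
  if (cfg$broken_walls > 0) {
    # erase short wall segments between lumina: paint lumen colour over walls
    wallpx <- which(labels == 0L, arr.ind = TRUE)
    for (i in seq_len(cfg$broken_walls)) {
      p <- wallpx[sample.int(nrow(wallpx), 1), ]
      rows <- max(1, p[1] - 1):min(h, p[1] + 1)
      cols <- max(1, p[2] - 4):min(w, p[2] + 4)
      sel <- labels[rows, cols, drop = FALSE] == 0L
      for (ch in 1:3) {
        m <- img[rows, cols, ch]
        m[sel] <- RENDER$lumen[ch]
        img[rows, cols, ch] <- m
      }
      add_region("broken_wall", rows, cols)
    }
  }
  for (i in seq_len(cfg$blur_regions)) {
    r0 <- sample.int(h, 1); c0 <- sample.int(w, 1)
    rows <- max(1, r0 - 25):min(h, r0 + 25)
    cols <- max(1, c0 - 25):min(w, c0 + 25)
    br <- EBImage::makeBrush(9, shape = "Gaussian", sigma = 3)
    for (ch in 1:3) {
      sub <- img[rows, cols, ch]
      img[rows, cols, ch] <- round(EBImage::filter2(sub / 255, br) * 255)
    }
    add_region("blur", rows, cols)
  }
  if (cfg$illumination_gradient > 0) {
    g <- 1 - cfg$illumination_gradient * (seq_len(w) - 1) / max(1, w - 1)
    for (ch in 1:3)
      img[, , ch] <- round(sweep(img[, , ch], 2, g, "*"))
    add_region("illumination_gradient", seq_len(h), seq_len(w))
  }
  img[] <- pmin(pmax(img, 0L), 255L)
  storage.mode(img) <- "integer"
  scene$image <- img
  scene$artifacts <- if (length(regions)) do.call(rbind, regions) else
    data.frame(type = character(0), min_x = integer(0), min_y = integer(0),
               max_x = integer(0), max_y = integer(0),
               overlapped_ids = character(0))
  scene
}
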