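# Synthetic wood-section generator: renders caricature transversal sections
# (dark walls, bright lumina, mid-tone tissue, additive noise) with exact
# ground truth for the four wood porosity types, plus non-target structures
# (rays, pits, resin canals, fiber texture) drawn in the image only.

RENDER <- list(
  tissue = c(205, 185, 170),
  wall = c(70, 50, 60),
  lumen = c(245, 242, 232),
  ray = c(175, 150, 140),
  resin = c(225, 215, 185),
  noise_sd = 3
)

#' Wood-type configuration for the synthetic generator
#'
#' Defaults emulate the anatomy of each porosity type at a scale where one
#' pixel is roughly 1 micron: conifer tracheids drawn as rectangular lattices
#' whose lumen width shrinks monotonically from earlywood to latewood within
#' each ring; diffuse-porous fields of uniformly sized round vessels;
#' semi-diffuse fields with a gradual earlywood-to-latewood size transition;
#' ring-porous rings with a distinct large-vessel row followed by small
#' scattered latewood vessels.
#'
#' @param porosity `"conifer"`, `"diffuse"`, `"semidiffuse"` or `"ringporous"`.
#' @param n_rings number of growth rings (default 3).
#' @param cells_per_ring cells (tracheid columns, or vessels) per ring
#'   (default: 12 conifer, 20 diffuse/semidiffuse, 3 large + 22 small
#'   ring-porous; for ring-porous a length-2 vector `c(large, small)`).
#' @param n_files conifer only: number of radial files (cell rows), default 14.
#' @param base_lumen earlywood lumen size in px (conifer rectangle side /
#'   vessel diameter; defaults 16 conifer, 18 diffuse/semidiffuse,
#'   c(46, 10) ring-porous).
#' @param shrink earlywood-to-latewood lumen shrink factor in (0, 1]
#'   (defaults 0.45 conifer, 1 diffuse, 0.55 semidiffuse).
#' @param wall minimum wall thickness between lumina in px (default 4).
#' @param ray_density expected rays per 100 px of image height (default 0.8).
#' @param pit_density conifer only: pit chambers per cell wall, probability
#'   (default 0.15).
#' @param resin_canal_prob conifer only: probability of one resin canal per
#'   ring (default 0.2).
#' @param fiber_texture draw background fiber speckle (default `TRUE`).
#' @param scalariform_prob diffuse/semidiffuse only: probability that a
#'   vessel is crossed by thin scalariform bars (drawn in the image; the
#'   vessel remains ONE ground-truth instance) (default 0.1).
#' @param seed integer random seed (default 1).
#' @return list of class `qwa_wood_config`.
#' @export
wood_type_config <- function(porosity = c("conifer", "diffuse", "semidiffuse",
                                          "ringporous"),
                             n_rings = 3, cells_per_ring = NULL,
                             n_files = 14, base_lumen = NULL, shrink = NULL,
                             wall = 4, ray_density = 0.8, pit_density = 0.15,
                             resin_canal_prob = 0.2, fiber_texture = TRUE,
                             scalariform_prob = 0.1, seed = 1) {
  porosity <- match.arg(porosity)
  if (is.null(cells_per_ring))
    cells_per_ring <- switch(porosity, conifer = 12, diffuse = 20,
                             semidiffuse = 20, ringporous = c(3, 22))
  if (is.null(base_lumen))
    base_lumen <- switch(porosity, conifer = 16, diffuse = 18,
                         semidiffuse = 18, ringporous = c(46, 10))
  if (is.null(shrink))
    shrink <- switch(porosity, conifer = 0.45, diffuse = 1,
                     semidiffuse = 0.55, ringporous = 1)
  if (shrink <= 0 || shrink > 1) stop("shrink must be in (0, 1]")
  if (any(c(n_rings, cells_per_ring, n_files, base_lumen, wall) < 1))
    stop("counts and sizes must be positive")
  structure(list(porosity = porosity, n_rings = n_rings,
                 cells_per_ring = cells_per_ring, n_files = n_files,
                 base_lumen = base_lumen, shrink = shrink, wall = wall,
                 ray_density = ray_density, pit_density = pit_density,
                 resin_canal_prob = resin_canal_prob,
                 fiber_texture = fiber_texture,
                 scalariform_prob = scalariform_prob, seed = seed),
            class = "qwa_wood_config")
}

# disc pixel offsets of radius r (euclidean)
disc_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2 + 0.25, , drop = FALSE]
}

# paint a filled disc into integer matrix m (value v), clipped to bounds
paint_disc <- function(m, r0, c0, radius, v) {
  off <- disc_offsets(radius)
  rr <- r0 + off$dr; cc <- c0 + off$dc
  ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  m[cbind(rr[ok], cc[ok])] <- v
  m
}

#' Generate a synthetic wood-section scene
#'
#' Renders the image and its exact ground truth. The label map marks only the
#' target-cell lumina (tracheids/vessels); non-target structures (rays,
#' pits, resin canals, fiber texture, scalariform bars) appear in the image
#' but never in the label map. Deterministic for a fixed `seed`.
#'
#' @param cfg a [wood_type_config()].
#' @return list of class `qwa_scene`: `image` (H x W x 3 integer array),
#'   `labels` (normalized label map), `nontargets` (data.frame of non-target
#'   annotations: `type`, `row`, `col`, `size`), `meta` (per-instance
#'   bookkeeping, incl. `large_vessel` flag for ring-porous scenes), `cfg`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "qwa_wood_config"))
  set.seed(cfg$seed)
  out <- switch(cfg$porosity,
    conifer = scene_conifer(cfg),
    diffuse = scene_porous(cfg, gradient = FALSE, large_row = FALSE),
    semidiffuse = scene_porous(cfg, gradient = TRUE, large_row = FALSE),
    ringporous = scene_porous(cfg, gradient = FALSE, large_row = TRUE))
  out$cfg <- cfg
  class(out) <- "qwa_scene"
  out
}

# conifer: lattice of rectangular lumina; per ring, lumen width shrinks
# monotonically along the growth (column) axis
scene_conifer <- function(cfg) {
  k <- cfg$cells_per_ring[1]
  wall <- cfg$wall
  widths <- pmax(4L, round(cfg$base_lumen *
                             cfg$shrink ^ (seq(0, 1, length.out = k))))
  pitch_r <- cfg$base_lumen + wall
  ring_w <- sum(widths + wall)
  margin <- 6L
  h <- as.integer(cfg$n_files * pitch_r + 2 * margin)
  w <- as.integer(cfg$n_rings * ring_w + 2 * margin)
  labels <- matrix(0L, h, w)
  walls <- matrix(FALSE, h, w)
  id <- 0L
  meta <- list()
  for (ring in seq_len(cfg$n_rings)) {
    x0 <- margin + (ring - 1L) * ring_w
    for (j in seq_len(k)) {
      cw <- widths[j]
      cx <- x0 + if (j > 1) sum(widths[1:(j - 1)] + wall) else 0L
      for (i in seq_len(cfg$n_files)) {
        cy <- margin + (i - 1L) * pitch_r
        ch <- cfg$base_lumen - round((cfg$base_lumen - cw) / 2)  # mildly flattened latewood
        rr <- (cy + wall):(cy + wall + ch - 1L)
        cc <- (cx + wall):(cx + wall + cw - 1L)
        rr <- rr[rr >= 1 & rr <= h]; cc <- cc[cc >= 1 & cc <= w]
        if (!length(rr) || !length(cc)) next
        id <- id + 1L
        labels[rr, cc] <- id
        walls[pmax(1, min(rr) - wall):pmin(h, max(rr) + wall),
              pmax(1, min(cc) - wall):pmin(w, max(cc) + wall)] <- TRUE
        meta[[id]] <- data.frame(id = id, ring = ring, pos = j,
                                 large_vessel = FALSE)
      }
    }
  }
  walls[labels > 0L] <- FALSE
  nt <- draw_nontargets(h, w, cfg, labels)
  img <- render_scene(labels, walls, nt$overlay, cfg)
  norm <- normalize_labels(labels)
  list(image = img, labels = norm, nontargets = nt$ann,
       meta = remap_meta(labels, norm, do.call(rbind, meta)))
}

# renumber meta$id through the raster-order normalization permutation
remap_meta <- function(labels_raw, labels_norm, meta) {
  if (is.null(meta) || !nrow(meta)) return(meta)
  first_px <- match(seq_len(max(labels_raw)), labels_raw)
  new_of_old <- labels_norm[first_px]
  meta$id <- new_of_old[meta$id]
  meta <- meta[order(meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

# hardwood vessel fields (diffuse / semidiffuse / ringporous)
scene_porous <- function(cfg, gradient, large_row) {
  wall <- cfg$wall
  if (large_row) {
    n_large <- cfg$cells_per_ring[1]
    n_small <- cfg$cells_per_ring[2]
    r_large <- round(cfg$base_lumen[1] / 2)
    r_small <- round(cfg$base_lumen[2] / 2)
    h <- as.integer(n_large * (2 * r_large + 2 * wall) + 20)
    # latewood zone wide enough for the requested small-vessel count
    box <- (2L * (r_small + wall) + 1L)^2
    lw_width <- ceiling(2.5 * n_small * box / h)
    ring_w <- as.integer(2 * (r_large + wall) + 10 + lw_width +
                           r_small + wall + 4)
  } else {
    n_small <- cfg$cells_per_ring[1]
    r_small <- round(cfg$base_lumen[1] / 2)
    ring_w <- as.integer(ceiling(sqrt(n_small)) * (2 * r_small + 2 * wall) + 10)
    h <- as.integer(ring_w * 1.2)
  }
  margin <- 6L
  w <- as.integer(cfg$n_rings * ring_w + 2 * margin)
  labels <- matrix(0L, h, w)
  walls <- matrix(FALSE, h, w)
  id <- 0L
  meta <- list()
  place <- function(r0, c0, radius, ring, large) {
    # reject if too close to an existing lumen or the border
    pad <- radius + wall
    if (r0 - pad < 1 || r0 + pad > h || c0 - pad < 1 || c0 + pad > w)
      return(FALSE)
    box <- labels[(r0 - pad):(r0 + pad), (c0 - pad):(c0 + pad)]
    if (any(box > 0L)) return(FALSE)
    id <<- id + 1L
    labels <<- paint_disc(labels, r0, c0, radius, id)
    walls <<- paint_disc(walls, r0, c0, radius + wall, TRUE)
    meta[[id]] <<- data.frame(id = id, ring = ring, pos = NA_integer_,
                              large_vessel = large)
    TRUE
  }
  # random darts first, deterministic grid scan as fallback; error when the
  # requested cells genuinely do not fit
  place_somewhere <- function(rows, cols, rad, ring, large) {
    for (try in 1:80) {
      r0 <- sample(rows, 1); c0 <- sample(cols, 1)
      if (place(r0, c0, rad, ring, large)) return(invisible(TRUE))
    }
    for (c0 in seq(min(cols), max(cols), by = 2)) {
      for (r0 in seq(min(rows), max(rows), by = 2)) {
        if (place(r0, c0, rad, ring, large)) return(invisible(TRUE))
      }
    }
    stop("infeasible geometry: cannot place a vessel of radius ", rad,
         " in ring ", ring)
  }
  for (ring in seq_len(cfg$n_rings)) {
    x0 <- margin + (ring - 1L) * ring_w
    if (large_row) {
      # earlywood: one column of large vessels at the ring start
      ys <- round(seq(r_large + wall + 2, h - r_large - wall - 2,
                      length.out = n_large))
      for (y in ys) {
        if (!place(y, x0 + r_large + wall + 2L, r_large, ring, TRUE))
          stop("infeasible geometry: large vessels do not fit")
      }
      lw_x <- (x0 + 2 * (r_large + wall) + 6L):(x0 + ring_w - r_small - wall)
      for (i in seq_len(n_small))
        place_somewhere(seq_len(h), lw_x, r_small, ring, FALSE)
    } else {
      for (i in seq_len(n_small)) {
        frac <- (i - 1) / max(1, n_small - 1)
        rad <- if (gradient)
          max(3L, round(r_small * (cfg$shrink + (1 - cfg$shrink) * (1 - frac))))
        else r_small
        cx_lo <- x0 + rad + wall
        cx_hi <- x0 + ring_w - rad - wall
        # gradient scenes place shrinking vessels progressively later in the ring
        if (gradient) {
          span <- cx_hi - cx_lo
          cx_lo <- cx_lo + round(frac * span * 0.6)
        }
        place_somewhere(seq_len(h), seq.int(cx_lo, max(cx_lo, cx_hi)), rad,
                        ring, FALSE)
      }
    }
  }
  walls[labels > 0L] <- FALSE
  nt <- draw_nontargets(h, w, cfg, labels)
  # scalariform bars: thin wall-coloured bars across some vessels (image only)
  if (cfg$porosity %in% c("diffuse", "semidiffuse") && cfg$scalariform_prob > 0) {
    ids <- unique(labels[labels > 0L])
    barred <- ids[runif(length(ids)) < cfg$scalariform_prob]
    for (b in barred) {
      px <- which(labels == b, arr.ind = TRUE)
      rows <- seq(min(px[, 1]) + 2, max(px[, 1]) - 2, by = 3)
      sel <- px[px[, 1] %in% rows, , drop = FALSE]
      nt$overlay$bars <- rbind(nt$overlay$bars, sel)
      nt$ann <- rbind(nt$ann, data.frame(type = "scalariform", row = mean(px[, 1]),
                                         col = mean(px[, 2]), size = b))
    }
  }
  img <- render_scene(labels, walls, nt$overlay, cfg)
  norm <- normalize_labels(labels)
  list(image = img, labels = norm, nontargets = nt$ann,
       meta = remap_meta(labels, norm, do.call(rbind, meta)))
}

# non-target structures drawn in the image only
draw_nontargets <- function(h, w, cfg, labels) {
  ann <- data.frame(type = character(0), row = numeric(0), col = numeric(0),
                    size = numeric(0))
  overlay <- list(ray = matrix(FALSE, h, w), resin = matrix(FALSE, h, w),
                  pits = NULL, bars = NULL, speckle = cfg$fiber_texture)
  n_rays <- stats::rpois(1, cfg$ray_density * h / 100)
  if (n_rays > 0) {
    for (i in seq_len(n_rays)) {
      r0 <- sample.int(h, 1)
      band <- max(1, r0 - 1):min(h, r0 + 1)
      free <- labels[band, , drop = FALSE] == 0L
      m <- overlay$ray
      m[band, ][free] <- TRUE
      overlay$ray <- m
      ann <- rbind(ann, data.frame(type = "ray", row = r0, col = w / 2, size = w))
    }
  }
  if (cfg$porosity == "conifer") {
    if (runif(1) < cfg$resin_canal_prob) {
      r0 <- sample.int(h, 1); c0 <- sample.int(w, 1)
      overlay$resin <- paint_disc(overlay$resin, r0, c0, 9L, TRUE)
      ann <- rbind(ann, data.frame(type = "resin_canal", row = r0, col = c0, size = 9))
    }
    wallpx <- which(labels == 0L)
    n_pits <- round(cfg$pit_density * n_instances(labels))
    if (n_pits > 0 && length(wallpx)) {
      sel <- sample(wallpx, min(n_pits, length(wallpx)))
      overlay$pits <- cbind((sel - 1L) %% h + 1L, (sel - 1L) %/% h + 1L)
      ann <- rbind(ann, data.frame(type = "pit", row = overlay$pits[, 1],
                                   col = overlay$pits[, 2], size = 1))
    }
  }
  list(ann = ann, overlay = overlay)
}

# compose RGB image from layers + additive noise
render_scene <- function(labels, walls, overlay, cfg) {
  h <- nrow(labels); w <- ncol(labels)
  img <- array(0, c(h, w, 3))
  lum <- labels > 0L
  for (ch in 1:3) {
    m <- matrix(RENDER$tissue[ch], h, w)
    if (isTRUE(overlay$speckle)) {
      spots <- matrix(runif(h * w) < 0.06, h, w) & !lum & !walls
      m[spots] <- m[spots] - 25
    }
    m[overlay$ray & !lum & !walls] <- RENDER$ray[ch]
    m[walls] <- RENDER$wall[ch]
    m[lum] <- RENDER$lumen[ch]
    if (any(overlay$resin)) m[overlay$resin & !lum] <- RENDER$resin[ch]
    if (!is.null(overlay$pits)) m[overlay$pits] <- RENDER$lumen[ch] - 30
    if (!is.null(overlay$bars)) m[overlay$bars] <- RENDER$wall[ch] + 30
    m <- m + rnorm(h * w, 0, RENDER$noise_sd)
    img[, , ch] <- pmin(pmax(round(m), 0), 255)
  }
  storage.mode(img) <- "integer"
  img
}

#' @export
print.qwa_scene <- function(x, ...) {
  cat(sprintf("Synthetic %s scene: %dx%d px, %d target cells, %d non-target annotations\n",
              x$cfg$porosity, nrow(x$labels), ncol(x$labels),
              n_instances(x$labels), nrow(x$nontargets)))
  invisible(x)
}
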