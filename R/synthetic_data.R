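# ---------------------------------------------------------------------------
# Synthetic co-culture generator.
#
# Emulates the acquisition the quantification method was designed for: a
# confluent lawn of acceptor cells (membrane shells + nuclei), one donor
# cell imaged with about half its volume at detector saturation, punctate
# supra-threshold transfer signal inside neighbouring acceptors with known
# painted intensities, sub-threshold autofluorescence, and 2D well mosaics
# for acquisition-side ROI selection.  Every generator is deterministic
# given its seed and returns complete ground truth.
# ---------------------------------------------------------------------------

#' Specification of a synthetic acceptor-cell lawn
#'
#' Defaults emulate the published acquisition geometry: 512 x 512 pixels in
#' xy, z-spacing 1.01 um. The xy pixel size is not part of the published
#' settings and defaults to 0.45 um, the pixel size a 40x / zoom 1.7
#' 512-pixel field (~230 um) implies. Cells are Voronoi columns in a slab
#' (a confluent monolayer on a substrate).
#'
#' @param shape `(nz, ny, nx)` voxel grid.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param n_cells number of acceptor cells (>= 1).
#' @param mean_cell_diameter mean cell diameter in um; controls the minimum
#'   nucleus spacing of the Poisson-disc placement.
#' @param membrane_intensity grayscale value of the membrane shell.
#' @param nucleus_intensity grayscale value of nuclear ellipsoids.
#' @param background_noise_max upper bound of the uniform DiD
#'   autofluorescence; must stay below the transfer threshold in force so
#'   noise can never be counted as transfer.
#' @param seed integer RNG seed.
#' @return An object of class `lawn_spec`.
#' @export
lawn_spec <- function(shape = c(50, 512, 512),
                      voxel_size = c(1.01, 0.45, 0.45),
                      n_cells = 60,
                      mean_cell_diameter = 20,
                      membrane_intensity = 200,
                      nucleus_intensity = 220,
                      background_noise_max = 50,
                      seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 4), n_cells >= 1,
            background_noise_max >= 0, membrane_intensity > 0,
            nucleus_intensity > 0)
  structure(list(shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 n_cells = as.integer(n_cells),
                 mean_cell_diameter = mean_cell_diameter,
                 membrane_intensity = membrane_intensity,
                 nucleus_intensity = nucleus_intensity,
                 background_noise_max = background_noise_max,
                 seed = as.integer(seed)),
            class = "lawn_spec")
}

# Poisson-disc (dart-throwing) placement of n points with minimum
# separation, inside [margin, extent - margin] x [margin, extent - margin].
poisson_disc_2d <- function(n, extent_y, extent_x, min_sep, margin) {
  pts <- matrix(numeric(0), ncol = 2)
  attempts <- 0L
  max_attempts <- 4000L * n
  while (nrow(pts) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    p <- c(runif(1, margin, extent_y - margin),
           runif(1, margin, extent_x - margin))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= min_sep^2)
      pts <- rbind(pts, p)
  }
  if (nrow(pts) < n)
    stop("cannot place ", n, " non-overlapping nuclei in the given extent")
  pts
}

# z index range of the cell slab: cells occupy the central ~70% of the
# stack, leaving dark medium above and substrate-side space below.
slab_range <- function(nz) {
  lo <- max(2L, as.integer(round(0.15 * nz)))
  hi <- min(nz - 1L, as.integer(round(0.85 * nz)))
  c(lo, hi)
}

#' Generate a confluent acceptor-cell lawn with ground-truth labels
#'
#' Nucleus centres are placed by Poisson-disc sampling in xy; cells are the
#' 2D Voronoi regions of the centres extruded through a z-slab (columnar
#' cells on a virtual substrate). The membrane channel carries a bright
#' 1-2 voxel shell at every inter-cell boundary plus sealing planes at the
#' slab top and bottom; the nuclei channel carries bright ellipsoids; the
#' DiD channel carries uniform sub-threshold noise.
#'
#' @param spec a [lawn_spec].
#' @return A list of class `codeit_lawn` with elements `channels` (a
#'   [channel_set]), `labels` (integer ground-truth label array), `centers`
#'   (nucleus centres, um), `slab` (z index range), `spec`.
#' @export
generate_lawn <- function(spec) {
  stopifnot(inherits(spec, "lawn_spec"))
  with_seed(spec$seed, generate_lawn_impl(spec))
}

generate_lawn_impl <- function(spec) {
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  vz <- spec$voxel_size[1]; vy <- spec$voxel_size[2]; vx <- spec$voxel_size[3]
  extent_y <- (ny - 1) * vy
  extent_x <- (nx - 1) * vx
  min_sep <- 0.6 * spec$mean_cell_diameter
  nuc_r_xy <- 0.2 * spec$mean_cell_diameter          # um
  margin <- nuc_r_xy + vy
  centers <- poisson_disc_2d(spec$n_cells, extent_y, extent_x, min_sep, margin)

  # nearest-centre (Voronoi) label per xy pixel, distances in um
  yy <- (seq_len(ny) - 1) * vy
  xx <- (seq_len(nx) - 1) * vx
  best_d2 <- matrix(Inf, ny, nx)
  label2d <- matrix(0L, ny, nx)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer((yy - centers[k, 1])^2, (xx - centers[k, 2])^2, "+")
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    label2d[upd] <- k
  }

  slab <- slab_range(nz)
  labels <- array(0L, spec$shape)
  for (z in slab[1]:slab[2]) labels[z, , ] <- label2d

  # membrane: both-sided shell where the 2D label changes, at every slab z,
  # plus full sealing planes at the slab faces (apical/basal cell surface)
  shift_differs <- function(m, dy, dx) {
    s <- matrix(0L, ny, nx)
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
    s[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    s != m & s != 0L
  }
  border2d <- shift_differs(label2d, 1, 0) | shift_differs(label2d, -1, 0) |
    shift_differs(label2d, 0, 1) | shift_differs(label2d, 0, -1) |
    shift_differs(label2d, 1, 1) | shift_differs(label2d, 1, -1) |
    shift_differs(label2d, -1, 1) | shift_differs(label2d, -1, -1)
  membrane <- array(0, spec$shape)
  for (z in slab[1]:slab[2]) {
    sl <- membrane[z, , ]
    sl[border2d] <- spec$membrane_intensity
    membrane[z, , ] <- sl
  }
  membrane[slab[1], , ] <- spec$membrane_intensity
  membrane[slab[2], , ] <- spec$membrane_intensity

  # nuclei: ellipsoids at the cell centres, mid-slab
  nuclei <- array(0, spec$shape)
  zc <- (slab[1] + slab[2]) / 2
  nuc_r_z <- min(nuc_r_xy, (slab[2] - slab[1]) * vz * 0.35)
  zz_um <- (seq_len(nz) - 1) * vz
  zc_um <- (zc - 1) * vz
  for (k in seq_len(nrow(centers))) {
    zi <- which(abs(zz_um - zc_um) <= nuc_r_z)
    yi <- which(abs(yy - centers[k, 1]) <= nuc_r_xy)
    xi <- which(abs(xx - centers[k, 2]) <= nuc_r_xy)
    d2 <- outer(((zz_um[zi] - zc_um) / nuc_r_z)^2,
                outer(((yy[yi] - centers[k, 1]) / nuc_r_xy)^2,
                      ((xx[xi] - centers[k, 2]) / nuc_r_xy)^2, "+"), "+")
    sub <- nuclei[zi, yi, xi, drop = FALSE]
    sub[d2 <= 1] <- spec$nucleus_intensity
    nuclei[zi, yi, xi] <- sub
  }

  did <- array(floor(runif(prod(spec$shape), 0,
                           spec$background_noise_max + 1)), spec$shape)
  did[did > spec$background_noise_max] <- spec$background_noise_max

  ch <- channel_set(
    nuclei = voxel_stack(nuclei, spec$voxel_size),
    membrane = voxel_stack(membrane, spec$voxel_size),
    did = voxel_stack(did, spec$voxel_size))
  structure(list(channels = ch, labels = labels, centers = centers,
                 slab = slab, spec = spec),
            class = "codeit_lawn")
}

#' Generate a donor-free control stack
#'
#' Identical construction to [generate_lawn]; never paints a donor, so no
#' DiD voxel exceeds the background noise ceiling. Optionally adds a few
#' dim sub-threshold puncta mimicking background structures.
#'
#' @param spec a [lawn_spec].
#' @param n_dim_puncta number of sub-threshold puncta to add.
#' @param dim_intensity their grayscale value; must stay at or below the
#'   transfer threshold in force.
#' @return A `codeit_lawn` (see [generate_lawn]).
#' @export
generate_control_stack <- function(spec, n_dim_puncta = 0, dim_intensity = 80) {
  lawn <- generate_lawn(spec)
  if (n_dim_puncta > 0) {
    with_seed(spec$seed + 1L, {
      did <- lawn$channels$did$intensities
      idx <- which(lawn$labels > 0L)
      pick <- sample(idx, n_dim_puncta)
      did[pick] <- dim_intensity
      lawn$channels$did <- voxel_stack(did, spec$voxel_size)
    })
  }
  lawn
}

#' Specification of donor and transfer signal to paint into a lawn
#'
#' @param donor_label ground-truth label of the cell acting as donor.
#' @param puncta data.frame with columns `cell` (target label), `z`, `y`,
#'   `x` (centre, um), `radius` (um), `intensity` (grayscale, must exceed
#'   the transfer threshold).
#' @param donor_saturated_fraction fraction of the donor volume painted at
#'   `scale_max` (default 0.5: donors are acquired with about half their
#'   volume saturated).
#' @param donor_rim_intensity sub-saturation intensity of the remaining
#'   donor volume (default 180), so donor detection cannot rely on
#'   saturation alone.
#' @return An object of class `transfer_spec`.
#' @export
transfer_spec <- function(donor_label, puncta = NULL,
                          donor_saturated_fraction = 0.5,
                          donor_rim_intensity = 180) {
  if (is.null(puncta))
    puncta <- data.frame(cell = integer(0), z = numeric(0), y = numeric(0),
                         x = numeric(0), radius = numeric(0),
                         intensity = numeric(0))
  stopifnot(donor_saturated_fraction > 0, donor_saturated_fraction <= 1,
            all(c("cell", "z", "y", "x", "radius", "intensity") %in%
                  names(puncta)))
  structure(list(donor_label = as.integer(donor_label), puncta = puncta,
                 donor_saturated_fraction = donor_saturated_fraction,
                 donor_rim_intensity = donor_rim_intensity),
            class = "transfer_spec")
}

# voxel indices of a sphere (centre and radius in um)
sphere_voxels <- function(center, radius, shape, voxel_size) {
  zz <- (seq_len(shape[1]) - 1) * voxel_size[1]
  yy <- (seq_len(shape[2]) - 1) * voxel_size[2]
  xx <- (seq_len(shape[3]) - 1) * voxel_size[3]
  zi <- which(abs(zz - center[1]) <= radius)
  yi <- which(abs(yy - center[2]) <= radius)
  xi <- which(abs(xx - center[3]) <= radius)
  if (!length(zi) || !length(yi) || !length(xi)) return(integer(0))
  g <- expand.grid(z = zi, y = yi, x = xi)
  d2 <- (zz[g$z] - center[1])^2 + (yy[g$y] - center[2])^2 +
    (xx[g$x] - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  g$z + shape[1] * (g$y - 1L) + shape[1] * shape[2] * (g$x - 1L)
}

#' Paint a donor cell and ground-truth transfer puncta into a lawn
#'
#' The donor's saturated fraction is painted as a coherent ball of voxels
#' nearest the cell centroid (detector saturation concentrates in the cell
#' body), the remainder at a sub-saturation rim level. Each punctum is a
#' sphere of constant intensity; puncta must lie entirely inside their
#' target cell, clear of the dilated donor mask, and above the transfer
#' threshold, so the painted sums are exactly recoverable.
#'
#' @param lawn a `codeit_lawn` from [generate_lawn].
#' @param spec a [transfer_spec].
#' @param did_threshold transfer threshold the puncta must exceed.
#' @param scale_max donor saturation level.
#' @return A list of class `codeit_truth_stack`: `channels`, `labels`,
#'   `donor_label`, and `truth`, a data.frame with per-cell ground-truth
#'   `volume_um3`, `transfer_voxels` and `transfer_intensity`.
#' @export
paint_donor_and_transfer <- function(lawn, spec, did_threshold = 100,
                                     scale_max = 255) {
  stopifnot(inherits(lawn, "codeit_lawn"), inherits(spec, "transfer_spec"))
  labels <- lawn$labels
  shape <- dim(labels)
  vs <- lawn$spec$voxel_size
  if (!spec$donor_label %in% labels)
    stop("donor_label ", spec$donor_label, " not present in label map")
  did <- lawn$channels$did$intensities

  # donor: saturated ball nearest the centroid, rim elsewhere
  didx <- which(labels == spec$donor_label)
  z <- ((didx - 1L) %% shape[1]) * vs[1]
  y <- (((didx - 1L) %/% shape[1]) %% shape[2]) * vs[2]
  x <- ((didx - 1L) %/% (shape[1] * shape[2])) * vs[3]
  ctr <- c(mean(z), mean(y), mean(x))
  d2 <- (z - ctr[1])^2 + (y - ctr[2])^2 + (x - ctr[3])^2
  n_sat <- ceiling(spec$donor_saturated_fraction * length(didx))
  ord <- order(d2)
  did[didx[ord[seq_len(n_sat)]]] <- scale_max
  if (n_sat < length(didx))
    did[didx[ord[(n_sat + 1):length(didx)]]] <- spec$donor_rim_intensity

  donor_dil <- dilate_mask(labels == spec$donor_label, se_box(1L))

  mx <- max(labels)
  t_vox <- integer(mx); t_int <- numeric(mx)
  pn <- spec$puncta
  if (nrow(pn)) {
    if (any(pn$intensity <= did_threshold))
      stop("punctum intensity must exceed the transfer threshold")
    for (i in seq_len(nrow(pn))) {
      vox <- sphere_voxels(c(pn$z[i], pn$y[i], pn$x[i]), pn$radius[i],
                           shape, vs)
      if (!length(vox)) stop("punctum ", i, " renders to zero voxels")
      if (any(labels[vox] != pn$cell[i]))
        stop("punctum ", i, " leaves its target cell (label ", pn$cell[i], ")")
      if (pn$cell[i] == spec$donor_label || any(donor_dil[vox]))
        stop("punctum ", i, " overlaps the (dilated) donor")
      did[vox] <- pn$intensity[i]
      t_vox[pn$cell[i]] <- t_vox[pn$cell[i]] + length(vox)
      t_int[pn$cell[i]] <- t_int[pn$cell[i]] + length(vox) * pn$intensity[i]
    }
  }
  vols <- label_counts(labels) * prod(vs)
  truth <- data.frame(cell_label = seq_len(mx), volume_um3 = vols,
                      transfer_voxels = t_vox, transfer_intensity = t_int)
  channels <- lawn$channels
  channels$did <- voxel_stack(did, vs)
  structure(list(channels = channels, labels = labels,
                 donor_label = spec$donor_label, truth = truth,
                 slab = lawn$slab, spec = lawn$spec),
            class = "codeit_truth_stack")
}

#' Draw a random, valid transfer specification for a lawn
#'
#' Picks as donor the cell nearest the stack centre among cells large
#' enough that half their volume exceeds the donor volume filter, then
#' scatters puncta at interior voxels of other acceptor cells. Punctum
#' centres keep a Chebyshev clearance of `radius + 2` voxels from any
#' cell boundary, so +-1 voxel segmentation errors cannot reassign
#' ground-truth transfer, and puncta never touch the dilated donor.
#'
#' @param lawn a `codeit_lawn`.
#' @param n_target_cells number of acceptor cells to receive puncta.
#' @param puncta_per_cell puncta painted into each target cell.
#' @param radius punctum radius in um.
#' @param intensities intensity range to sample from (grayscale).
#' @param min_donor_volume minimum donor-cell volume in um^3 (default
#'   2200: half of it must clear the 1000 um^3 donor filter).
#' @param seed RNG seed.
#' @return A [transfer_spec].
#' @export
random_transfer_spec <- function(lawn, n_target_cells = 5, puncta_per_cell = 2,
                                 radius = 0.9, intensities = c(150, 255),
                                 min_donor_volume = 2200, seed = 1) {
  stopifnot(inherits(lawn, "codeit_lawn"))
  labels <- lawn$labels
  shape <- dim(labels)
  vs <- lawn$spec$voxel_size
  vols <- label_counts(labels) * prod(vs)
  big <- which(vols >= min_donor_volume)
  if (!length(big)) stop("no cell large enough to act as donor")
  cen <- label_centroids(labels)
  ctr_um <- (shape - 1) / 2 * vs
  d <- sqrt(((cen[big, "z"] - 1) * vs[1] - ctr_um[1])^2 +
              ((cen[big, "y"] - 1) * vs[2] - ctr_um[2])^2 +
              ((cen[big, "x"] - 1) * vs[3] - ctr_um[3])^2)
  donor <- big[which.min(d)]

  r_vox <- ceiling(radius / min(vs))
  interior <- !cpp_label_boundary(labels, shape, 26L) & labels > 0L
  dim(interior) <- shape
  for (i in seq_len(r_vox + 1L)) interior <- erode_mask(interior, se_box(1L))

  with_seed(seed, {
    cand_cells <- setdiff(which(tabulate(labels[interior], max(labels)) >=
                                  4 * puncta_per_cell), donor)
    if (length(cand_cells) < n_target_cells)
      stop("not enough acceptor cells with safe interior voxels")
    targets <- sample(cand_cells, n_target_cells)
    rows <- list()
    for (cl in targets) {
      vox <- which(interior & labels == cl)
      placed <- matrix(numeric(0), ncol = 3)
      tries <- 0L
      while (nrow(placed) < puncta_per_cell && tries < 200L) {
        tries <- tries + 1L
        v <- sample(vox, 1L)
        p <- c((((v - 1L) %% shape[1])) * vs[1],
               ((((v - 1L) %/% shape[1]) %% shape[2])) * vs[2],
               (((v - 1L) %/% (shape[1] * shape[2]))) * vs[3])
        if (nrow(placed) == 0 ||
            min(colSums((t(placed) - p)^2)) >= (2 * radius + 2 * min(vs))^2) {
          placed <- rbind(placed, p)
          rows[[length(rows) + 1L]] <-
            data.frame(cell = cl, z = p[1], y = p[2], x = p[3],
                       radius = radius,
                       intensity = sample(seq(intensities[1], intensities[2]), 1L))
        }
      }
    }
    transfer_spec(donor, do.call(rbind, rows))
  })
}

# ---------------------------------------------------------------------------
# Well mosaics
# ---------------------------------------------------------------------------

#' Specification of a synthetic 2D well mosaic
#'
#' @param extent well side length in um; must be a multiple of `tile_um`.
#' @param tile_um tile (scan-field) width in um (default 775, the published
#'   field distance of the low-resolution screen).
#' @param tile_px tile width in pixels.
#' @param donor_xy matrix of donor stage positions (x, y) in um.
#' @param nuclei_xy matrix of nucleus stage positions (x, y) in um.
#' @param seed RNG seed (used only by renderers that add noise).
#' @return An object of class `well_spec`.
#' @export
well_spec <- function(extent = 2325, tile_um = 775, tile_px = 128,
                      donor_xy = NULL, nuclei_xy = NULL, seed = 1) {
  if (abs(extent / tile_um - round(extent / tile_um)) > 1e-9)
    stop("well extent must be an integer multiple of the tile size")
  donor_xy <- if (is.null(donor_xy)) matrix(numeric(0), ncol = 2)
  else as.matrix(donor_xy)
  nuclei_xy <- if (is.null(nuclei_xy)) matrix(numeric(0), ncol = 2)
  else as.matrix(nuclei_xy)
  for (m in list(donor_xy, nuclei_xy))
    if (nrow(m) && (any(m < 0) || any(m > extent)))
      stop("positions must lie inside the well [0, extent]")
  structure(list(extent = extent, tile_um = tile_um, tile_px = as.integer(tile_px),
                 donor_xy = donor_xy, nuclei_xy = nuclei_xy,
                 seed = as.integer(seed)),
            class = "well_spec")
}

#' Draw a random well layout
#'
#' Donors are placed with a minimum mutual clearance; nuclei uniformly.
#' The default nucleus count gives a density comfortably above the
#' 15-nuclei-in-200-um acquisition requirement.
#'
#' @param n_donors,n_nuclei counts.
#' @param min_donor_sep minimum donor-donor distance in um.
#' @param extent,tile_um,tile_px as in [well_spec].
#' @param seed RNG seed.
#' @return A [well_spec] with positions filled in.
#' @export
random_well_spec <- function(n_donors = 4, n_nuclei = 1500,
                             min_donor_sep = 420, extent = 2325,
                             tile_um = 775, tile_px = 128, seed = 1) {
  with_seed(seed, {
    margin <- 30
    donors <- if (n_donors > 0)
      poisson_disc_2d(n_donors, extent, extent, min_donor_sep, margin)[, 2:1,
                                                                       drop = FALSE]
    else matrix(numeric(0), ncol = 2)
    nuclei <- cbind(runif(n_nuclei, 0, extent), runif(n_nuclei, 0, extent))
    well_spec(extent, tile_um, tile_px, donor_xy = donors,
              nuclei_xy = nuclei, seed = seed)
  })
}

#' Render a well mosaic as low-resolution tiles with ground truth
#'
#' Nuclei are rendered as Gaussian spots in the nuclear channel (donors get
#' a nucleus too), donors as bright discs in the DiD channel. The image is
#' cut into a row-major grid of `tile_um`-wide tiles as the microscope
#' would scan them.
#'
#' @param spec a [well_spec].
#' @return A list: `tiles` (row-major list of `list(nuclei, did)` pixel
#'   matrices), `layout` (grid rows/cols, tile size, stage origin, um per
#'   pixel), `truth` (the ground-truth positions).
#' @export
generate_well_mosaic <- function(spec) {
  stopifnot(inherits(spec, "well_spec"))
  ntiles <- as.integer(round(spec$extent / spec$tile_um))
  um_per_px <- spec$tile_um / spec$tile_px
  npx <- ntiles * spec$tile_px
  nuc <- matrix(0, npx, npx)   # [row = y, col = x]
  did <- matrix(0, npx, npx)
  px_centers <- (seq_len(npx) - 0.5) * um_per_px

  add_gauss <- function(img, x, y, sigma, peak) {
    w <- 3 * sigma
    xi <- which(abs(px_centers - x) <= w)
    yi <- which(abs(px_centers - y) <= w)
    if (!length(xi) || !length(yi)) return(img)
    g <- outer(exp(-(px_centers[yi] - y)^2 / (2 * sigma^2)),
               exp(-(px_centers[xi] - x)^2 / (2 * sigma^2)))
    img[yi, xi] <- pmax(img[yi, xi], peak * g)
    img
  }
  add_disc <- function(img, x, y, radius, peak) {
    xi <- which(abs(px_centers - x) <= radius)
    yi <- which(abs(px_centers - y) <= radius)
    if (!length(xi) || !length(yi)) return(img)
    d2 <- outer((px_centers[yi] - y)^2, (px_centers[xi] - x)^2, "+")
    sub <- img[yi, xi, drop = FALSE]
    sub[d2 <= radius^2] <- peak
    img[yi, xi] <- sub
    img
  }
  for (i in seq_len(nrow(spec$nuclei_xy)))
    nuc <- add_gauss(nuc, spec$nuclei_xy[i, 1], spec$nuclei_xy[i, 2],
                     sigma = 3.5, peak = 220)
  for (i in seq_len(nrow(spec$donor_xy))) {
    nuc <- add_gauss(nuc, spec$donor_xy[i, 1], spec$donor_xy[i, 2],
                     sigma = 3.5, peak = 220)
    did <- add_disc(did, spec$donor_xy[i, 1], spec$donor_xy[i, 2],
                    radius = 8, peak = 255)
  }
  nuc <- round(nuc); did <- round(did)
  tiles <- vector("list", ntiles * ntiles)
  k <- 0L
  for (r in seq_len(ntiles)) for (cc in seq_len(ntiles)) {
    k <- k + 1L
    ri <- ((r - 1L) * spec$tile_px + 1L):(r * spec$tile_px)
    ci <- ((cc - 1L) * spec$tile_px + 1L):(cc * spec$tile_px)
    tiles[[k]] <- list(nuclei = nuc[ri, ci], did = did[ri, ci])
  }
  list(tiles = tiles,
       layout = list(rows = ntiles, cols = ntiles, tile_um = spec$tile_um,
                     tile_px = spec$tile_px, origin = c(0, 0),
                     um_per_px = um_per_px),
       truth = list(donor_xy = spec$donor_xy, nuclei_xy = spec$nuclei_xy))
}
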