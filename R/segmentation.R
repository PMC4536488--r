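# ---------------------------------------------------------------------------
# CellSegm-style 3D segmentation of the acceptor lawn from the membrane
# channel: (1) edge-preserving anisotropic diffusion, (2) nucleus-based
# marker generation, (3) marker-controlled watershed on the membrane
# intensity, (4) classification of watershed regions into cells vs
# background.
# ---------------------------------------------------------------------------

#' Segmentation parameters
#'
#' The four-stage segmentation needs a handful of internal parameters that
#' are not part of the published method; they were tuned once against the
#' synthetic lawn generator and frozen here as defaults.
#'
#' @param smooth_iterations diffusion iterations (0 = no smoothing).
#' @param smooth_conductance edge-stopping conductance K (grayscale units);
#'   gradients well above K are preserved, gradients below are smoothed.
#' @param smooth_dt diffusion time step (stability requires <= 1/6 for the
#'   6-neighbour explicit scheme).
#' @param nucleus_threshold intensity above which nuclei-channel voxels are
#'   marker candidates.
#' @param nucleus_min_volume minimum nucleus volume in um^3; smaller
#'   components are debris, not markers.
#' @param background_intensity membrane intensity below which
#'   border-connected space is treated as the background marker.
#' @param min_boundary_intensity membrane intensity above which a region
#'   surface voxel counts as membrane-covered during classification.
#' @param min_boundary_coverage minimum fraction of a region's surface
#'   (boundary to other labels plus image-border faces) that must be
#'   membrane-covered for the region to be accepted as a cell. Cells are
#'   wrapped in membrane almost everywhere; medium regions are bounded
#'   largely by the bare image border.
#' @param max_region_volume maximum plausible single-cell volume in um^3.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_iterations = 4,
                                smooth_conductance = 30,
                                smooth_dt = 0.15,
                                nucleus_threshold = 100,
                                nucleus_min_volume = 30,
                                background_intensity = 30,
                                min_boundary_intensity = 100,
                                min_boundary_coverage = 0.6,
                                max_region_volume = 20000) {
  p <- list(smooth_iterations = as.integer(smooth_iterations),
            smooth_conductance = smooth_conductance,
            smooth_dt = smooth_dt,
            nucleus_threshold = nucleus_threshold,
            nucleus_min_volume = nucleus_min_volume,
            background_intensity = background_intensity,
            min_boundary_intensity = min_boundary_intensity,
            min_boundary_coverage = min_boundary_coverage,
            max_region_volume = max_region_volume)
  if (p$smooth_iterations < 0 || any(unlist(p[-1]) <= 0))
    stop("segmentation parameters must be positive")
  if (p$nucleus_min_volume >= p$max_region_volume)
    stop("nucleus_min_volume must be below max_region_volume")
  structure(p, class = "segmentation_params")
}

# shift a 3D array by one voxel along an axis, replicating the border
shift_rep <- function(a, axis, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]] + dir
  i[i < 1] <- 1L
  i[i > d[axis]] <- d[axis]
  idx[[axis]] <- i
  do.call(`[`, c(list(a), idx))
}

#' Edge-preserving anisotropic diffusion
#'
#' Perona-Malik diffusion with the exponential edge-stopping function
#' `exp(-(grad/K)^2)`, explicit 6-neighbour scheme on the voxel grid.
#' Smooths noise inside regions while preserving membrane edges, the
#' pre-processing step of the segmentation. Zero iterations is the
#' identity; output is clipped to [0, 255].
#'
#' @param stack an 8-bit [voxel_stack].
#' @param params a [segmentation_params].
#' @return the smoothed [voxel_stack].
#' @export
smooth_anisotropic <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (stack$scale_max != 255)
    stop("smoothing expects 8-bit data; apply normalize_to_8bit first")
  u <- stack$intensities * 1.0
  if (params$smooth_iterations == 0L) return(stack)
  K <- params$smooth_conductance
  dt <- params$smooth_dt
  for (it in seq_len(params$smooth_iterations)) {
    flux <- 0
    for (axis in 1:3) for (dir in c(-1L, 1L)) {
      g <- shift_rep(u, axis, dir) - u
      flux <- flux + exp(-(g / K)^2) * g
    }
    u <- u + dt * flux
  }
  u[u < 0] <- 0
  u[u > 255] <- 255
  voxel_stack(u, stack$voxel_size)
}

#' Generate watershed markers from the nuclei channel
#'
#' Thresholds the nuclear stain, labels 26-connected components, removes
#' components below the minimum nucleus volume, and adds one background
#' marker from low-membrane-intensity space connected to the axial faces
#' of the volume (the medium above and substrate below the lawn).
#'
#' @param nuclei 8-bit nuclei [voxel_stack].
#' @param params a [segmentation_params].
#' @param membrane optional membrane [voxel_stack] (smoothed); if supplied,
#'   a background marker is derived from it.
#' @return integer marker array; foreground markers 1..n, background marker
#'   (if any) carried as attribute `background_label` = n + 1.
#' @export
generate_markers <- function(nuclei, params = segmentation_params(),
                             membrane = NULL) {
  stopifnot(inherits(nuclei, "voxel_stack"))
  vv <- voxel_volume(nuclei)
  mask <- nuclei$intensities > params$nucleus_threshold
  comp <- label_components(mask, 26)
  if (max(comp) == 0L) stop("no markers: no supra-threshold nuclei found")
  vols <- label_counts(comp) * vv
  keep <- which(vols >= params$nucleus_min_volume)
  if (!length(keep)) stop("no markers: all nucleus components below minimum volume")
  relab <- integer(max(comp) + 1L)           # old label -> new, via +1 offset
  relab[keep + 1L] <- seq_along(keep)
  markers <- array(relab[comp + 1L], dim(comp))
  bg_label <- NA_integer_
  if (!is.null(membrane)) {
    nz <- dim(markers)[1]
    dark <- membrane$intensities < params$background_intensity &
      nuclei$intensities <= params$nucleus_threshold
    dcomp <- label_components(dark, 6)
    face <- unique(c(dcomp[1, , ], dcomp[nz, , ]))
    face <- face[face > 0L]
    if (length(face)) {
      bg_label <- length(keep) + 1L
      markers[dcomp %in% face & markers == 0L] <- bg_label
    }
  }
  attr(markers, "background_label") <- bg_label
  attr(markers, "n_foreground") <- length(keep)
  markers
}

#' Marker-controlled watershed on the membrane channel
#'
#' Floods the membrane intensity as a topographic surface from the markers;
#' each foreground marker grows into exactly one region, the background
#' marker's region becomes label 0. Flooding order is by intensity, with
#' first-queued-first-served ties, so plateau (ridge) assignment is
#' deterministic and fronts advance fairly.
#'
#' @param membrane smoothed membrane [voxel_stack].
#' @param markers marker array from [generate_markers].
#' @return integer cell label array (class-free; 0 = background).
#' @export
watershed_cells <- function(membrane, markers) {
  stopifnot(inherits(membrane, "voxel_stack"))
  if (max(markers) == 0L) stop("markers are empty")
  d <- dim(markers)
  labs <- cpp_watershed(as.numeric(membrane$intensities),
                        as.integer(markers), d, 6L)
  dim(labs) <- d
  bg <- attr(markers, "background_label")
  if (!is.na(bg)) labs[labs == bg] <- 0L
  labs
}

#' Classify watershed regions into cells and background
#'
#' Rejects regions that cannot be cells: implausibly large volume, or
#' insufficient membrane signal over the region surface. The surface of a
#' region is its boundary to other labels plus its image-border faces; a
#' surface voxel is membrane-covered when the (smoothed) membrane exceeds
#' `min_boundary_intensity`. Cells are wrapped in membrane almost
#' everywhere; a region spanning the medium above the lawn is bounded
#' mostly by the image border and fails the coverage requirement.
#' Survivors are renumbered contiguously from 1. Idempotent.
#'
#' @param label_map watershed label array.
#' @param membrane membrane [voxel_stack] (smoothed).
#' @param params a [segmentation_params].
#' @return relabelled integer array.
#' @export
classify_regions <- function(label_map, membrane,
                             params = segmentation_params()) {
  stopifnot(inherits(membrane, "voxel_stack"))
  d <- dim(label_map)
  mx <- max(label_map)
  if (mx == 0L) stop("all regions rejected: label map is empty")
  vv <- voxel_volume(membrane)
  vols <- label_counts(label_map) * vv
  surf <- cpp_surface_coverage(as.integer(label_map),
                               as.numeric(membrane$intensities), d,
                               params$min_boundary_intensity, 26L)
  coverage <- ifelse(surf[, 1] > 0, surf[, 2] / pmax(surf[, 1], 1L), 0)
  keep <- which(vols > 0 & vols <= params$max_region_volume &
                  coverage >= params$min_boundary_coverage)
  if (!length(keep)) stop("all regions rejected: no plausible cells")
  relab <- integer(mx + 1L)
  relab[keep + 1L] <- seq_along(keep)
  array(relab[label_map + 1L], d)
}

#' Full four-stage cell segmentation
#'
#' Convenience orchestrator: anisotropic smoothing of the membrane channel,
#' marker generation from the nuclei channel, marker-controlled watershed,
#' region classification.
#'
#' @param channels a [channel_set].
#' @param params a [segmentation_params].
#' @return integer cell label array (0 = background).
#' @export
segment_cells <- function(channels, params = segmentation_params()) {
  stopifnot(inherits(channels, "channel_set"))
  mem <- smooth_anisotropic(channels$membrane, params)
  markers <- generate_markers(channels$nuclei, params, membrane = mem)
  labs <- watershed_cells(mem, markers)
  classify_regions(labs, mem, params)
}
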