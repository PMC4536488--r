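#' @useDynLib codeit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median aov t.test pchisq qnorm rnorm runif rlnorm setNames
#' @importFrom utils write.table read.delim head
NULL

# ---------------------------------------------------------------------------
# VoxelStack: one channel of a 3D acquisition.
# Axis order is fixed package-wide as (z, y, x); array dim = c(nz, ny, nx).
# All physical positions are index * voxel_size from the stack origin, in um.
# ---------------------------------------------------------------------------

#' Construct a voxel stack (one channel of a 3D image)
#'
#' A `voxel_stack` holds the voxel intensities of a single channel together
#' with the physical voxel dimensions in micrometres and the intensity scale.
#' Axis order is `(z, y, x)` throughout the package.
#'
#' @param intensities 3D numeric/integer array, dim `c(nz, ny, nx)`, all
#'   values in `[0, scale_max]`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres,
#'   strictly positive.
#' @param scale_max maximum representable intensity (255 for 8-bit data).
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensities, voxel_size, scale_max = 255) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array (z, y, x)")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive values (dz, dy, dx) in um")
  if (length(scale_max) != 1L || scale_max <= 0)
    stop("scale_max must be a single positive number")
  rng <- range(intensities)
  if (rng[1] < 0 || rng[2] > scale_max)
    stop("intensities must lie in [0, scale_max]")
  structure(
    list(intensities = intensities,
         voxel_size = as.numeric(voxel_size),
         scale_max = as.numeric(scale_max)),
    class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_stack> %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um, scale_max %g\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$scale_max))
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$intensities)

#' Physical volume of one voxel
#'
#' @param stack a [voxel_stack].
#' @return dz*dy*dx in cubic micrometres. Multiplying by a voxel count
#'   converts region sizes to the um^3 scale used by all volume filters.
#' @export
voxel_volume <- function(stack) {
  prod(stack$voxel_size)
}

#' Rescale a stack to the 8-bit intensity range
#'
#' Linear rescale from `scale_max` to 255 with round-half-up. All intensity
#' thresholds in this package are interpreted on the 8-bit (0..255) scale,
#' so deeper acquisitions must pass through this before quantification.
#' Identity for 8-bit input.
#'
#' @param stack a [voxel_stack] with `scale_max` 255, 4095 or 65535.
#' @return a [voxel_stack] with `scale_max = 255`.
#' @export
normalize_to_8bit <- function(stack) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (!stack$scale_max %in% c(255, 4095, 65535))
    stop("unsupported bit depth: scale_max must be 255, 4095 or 65535")
  if (stack$scale_max == 255) return(stack)
  v <- floor(stack$intensities * (255 / stack$scale_max) + 0.5)
  voxel_stack(v, stack$voxel_size, scale_max = 255)
}

# ---------------------------------------------------------------------------
# ChannelSet
# ---------------------------------------------------------------------------

#' Construct a channel set (all channels of one acquisition)
#'
#' Bundles the nuclear (Hoechst), membrane (WGA), transfer-marker (DiD) and
#' optional protein-marker (EGFP) channels of one field of view. All member
#' stacks must share shape and voxel size.
#'
#' @param nuclei,membrane,did [voxel_stack]s; required.
#' @param egfp optional [voxel_stack].
#' @return An object of class `channel_set`.
#' @export
channel_set <- function(nuclei, membrane, did, egfp = NULL) {
  ch <- list(nuclei = nuclei, membrane = membrane, did = did)
  if (!is.null(egfp)) ch$egfp <- egfp
  for (nm in names(ch)) {
    if (!inherits(ch[[nm]], "voxel_stack"))
      stop("channel '", nm, "' is not a voxel_stack")
    if (!identical(dim(ch[[nm]]$intensities), dim(nuclei$intensities)))
      stop("channel '", nm, "' shape differs from nuclei channel")
    if (!isTRUE(all.equal(ch[[nm]]$voxel_size, nuclei$voxel_size)))
      stop("channel '", nm, "' voxel size differs from nuclei channel")
  }
  structure(ch, class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  d <- dim(x$nuclei$intensities)
  cat(sprintf("<channel_set> channels: %s; %d x %d x %d (z,y,x)\n",
              paste(names(x), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# QuantConfig
# ---------------------------------------------------------------------------

#' Quantification configuration
#'
#' Holds every tunable threshold and limit of the transfer-quantification
#' and ROI-selection methods. Defaults are the published values of the
#' method where one is printed; intensity thresholds are on the 8-bit scale.
#'
#' @param did_threshold global transfer threshold for the DiD channel
#'   (grayscale units, default 100 of 256); signal strictly above it counts.
#' @param egfp_threshold global transfer threshold for the EGFP channel
#'   (100, with 160 as the documented alternative).
#' @param donor_min_volume minimum donor-object volume in um^3 (1000);
#'   smaller supra-threshold objects are discarded during donor definition.
#' @param cell_min_volume minimum acceptor-cell volume in um^3 (100);
#'   smaller watershed cells are excluded as presumed dead cells.
#' @param closing_radius radius (voxels) of the disc used to morphologically
#'   close the thresholded donor representation.
#' @param closing_3d apply the closing with a 3D ball instead of per-z-slice
#'   discs. Default `FALSE` (in-plane closing; conservative given z-anisotropy).
#' @param dilation_radius donor-mask dilation radius per axis in voxels (1,
#'   i.e. a 3x3x3 cube).
#' @param donor_intensity_threshold intensity above which DiD/EGFP signal is
#'   treated as donor-cell signal (default 250 of 255: donors are acquired
#'   with about half their volume saturated, so near-saturation is the
#'   donor signature).
#' @param exclusion_distance minimum distance in um from any other donor for
#'   a field to qualify (200, inclusive).
#' @param nuclei_radius radius in um of the cell-density check (200).
#' @param min_nuclei minimum nucleus count within `nuclei_radius` (15).
#' @param max_controls maximum number of random control positions (15).
#' @param donor_min_area_um2 minimum blob area in um^2 for calling a donor
#'   in the low-resolution well scan (not printed by the method; default 50).
#' @param field_extent side length in um of the high-resolution field
#'   footprint used for the ROI overlap rule (default 228, the field of a
#'   40x/zoom-1.7 512-pixel acquisition).
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(did_threshold = 100,
                         egfp_threshold = 100,
                         donor_min_volume = 1000,
                         cell_min_volume = 100,
                         closing_radius = 2,
                         closing_3d = FALSE,
                         dilation_radius = 1,
                         donor_intensity_threshold = 250,
                         exclusion_distance = 200,
                         nuclei_radius = 200,
                         min_nuclei = 15,
                         max_controls = 15,
                         donor_min_area_um2 = 50,
                         field_extent = 228) {
  cfg <- list(did_threshold = did_threshold,
              egfp_threshold = egfp_threshold,
              donor_min_volume = donor_min_volume,
              cell_min_volume = cell_min_volume,
              closing_radius = closing_radius,
              closing_3d = isTRUE(closing_3d),
              dilation_radius = dilation_radius,
              donor_intensity_threshold = donor_intensity_threshold,
              exclusion_distance = exclusion_distance,
              nuclei_radius = nuclei_radius,
              min_nuclei = min_nuclei,
              max_controls = max_controls,
              donor_min_area_um2 = donor_min_area_um2,
              field_extent = field_extent)
  num <- cfg[!vapply(cfg, is.logical, logical(1))]
  if (any(vapply(num, function(v) !is.numeric(v) || length(v) != 1 || v <= 0,
                 logical(1))))
    stop("all quant_config values must be single strictly positive numbers")
  if (did_threshold > 255 || egfp_threshold > 255 ||
      donor_intensity_threshold > 255)
    stop("intensity thresholds must not exceed the 8-bit scale maximum")
  structure(cfg, class = "quant_config")
}

#' Read / write a quantification configuration as YAML
#'
#' @param path file path.
#' @param cfg a [quant_config].
#' @return `read_quant_config` returns a [quant_config] with file values
#'   overriding the defaults.
#' @export
read_quant_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(quant_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(quant_config, vals)
}

#' @rdname read_quant_config
#' @export
write_quant_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "quant_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Stack I/O. Multi-page TIFF, pages ordered channel-major (all z of channel
# 1, then channel 2, ...), plus a YAML sidecar `<path>.yaml` carrying the
# metadata TIFF tags cannot: voxel size in um, channel count, scale_max.
# ---------------------------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a channel set to a multi-page TIFF plus metadata sidecar
#'
#' Pages are ordered channel-major in the channel order of the set; a YAML
#' sidecar (`<path>.yaml`) records channel names, voxel size and bit depth
#' so that [read_channel_set] can reconstruct the set without guessing.
#'
#' @param cs a [channel_set].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_channel_set <- function(cs, path) {
  stopifnot(inherits(cs, "channel_set"))
  scale_max <- cs$nuclei$scale_max
  if (!scale_max %in% c(255, 65535))
    stop("TIFF export supports 8-bit (255) and 16-bit (65535) data")
  bits <- if (scale_max == 255) 8L else 16L
  pages <- list()
  for (nm in names(cs)) {
    a <- cs[[nm]]$intensities
    for (z in seq_len(dim(a)[1]))
      pages[[length(pages) + 1L]] <- a[z, , ] / scale_max
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  yaml::write_yaml(list(channels = names(cs),
                        nz = dim(cs$nuclei$intensities)[1],
                        voxel_size = as.list(cs$nuclei$voxel_size),
                        scale_max = scale_max),
                   sidecar_path(path))
  invisible(path)
}

#' Read a multi-channel z-stack into a channel set
#'
#' Reads a multi-page TIFF whose pages are ordered channel-major. Metadata
#' (voxel size, channel count, bit depth) comes from the YAML sidecar
#' written by [write_channel_set], or must be supplied explicitly for
#' third-party files. A missing voxel size is an error, never a silent
#' default: every downstream volume filter is expressed in um^3.
#'
#' @param path TIFF path.
#' @param channel_map named integer vector mapping roles (`nuclei`,
#'   `membrane`, `did`, optionally `egfp`) to 1-based channel indices.
#' @param voxel_size `(dz, dy, dx)` in um; overrides/replaces sidecar
#'   metadata.
#' @param n_channels number of channels in the file; required when no
#'   sidecar is present.
#' @return A [channel_set]. 16-bit files yield stacks with
#'   `scale_max = 65535`; pass them through [normalize_to_8bit] before
#'   quantification.
#' @export
read_channel_set <- function(path, channel_map, voxel_size = NULL,
                             n_channels = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  required <- c("nuclei", "membrane", "did")
  if (!all(required %in% names(channel_map)))
    stop("channel_map must name roles: ",
         paste(setdiff(required, names(channel_map)), collapse = ", "))
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else NULL
  if (is.null(voxel_size)) voxel_size <- unlist(meta$voxel_size)
  if (is.null(voxel_size))
    stop("voxel size unavailable: no metadata sidecar and no explicit value")
  if (is.null(n_channels))
    n_channels <- if (!is.null(meta)) length(meta$channels) else NULL
  if (is.null(n_channels))
    stop("channel count unavailable: supply n_channels or a sidecar")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  scale_max <- 2^bits - 1
  if (length(pages) %% n_channels != 0)
    stop("page count ", length(pages), " not divisible by ", n_channels,
         " channels")
  nz <- length(pages) %/% n_channels
  if (any(channel_map < 1 | channel_map > n_channels))
    stop("channel index out of range")
  get_channel <- function(idx) {
    sl <- pages[((idx - 1L) * nz + 1L):(idx * nz)]
    a <- array(0, c(nz, nrow(sl[[1]]), ncol(sl[[1]])))
    for (z in seq_len(nz)) a[z, , ] <- round(sl[[z]] * scale_max)
    voxel_stack(a, voxel_size, scale_max = scale_max)
  }
  channel_set(nuclei = get_channel(channel_map[["nuclei"]]),
              membrane = get_channel(channel_map[["membrane"]]),
              did = get_channel(channel_map[["did"]]),
              egfp = if ("egfp" %in% names(channel_map))
                get_channel(channel_map[["egfp"]]) else NULL)
}

#' Write / read a cell label map as 16-bit TIFF
#'
#' @param labels integer 3D array of cell labels (0 = background).
#' @param path TIFF path.
#' @return `read_label_map` returns the integer label array.
#' @export
write_label_map <- function(labels, path) {
  pages <- lapply(seq_len(dim(labels)[1]), function(z) labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0L, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) a[z, , ] <- as.integer(round(pages[[z]] * 65535))
  a
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
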