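# ---------------------------------------------------------------------------
# Acquisition-side ROI selection over a tiled low-resolution well scan:
# assemble tiles into a super-image, find isolated single-donor positions
# with sufficient surrounding cell density, pick donor-free control
# positions, export stage coordinates.  Stage x maps to image columns,
# stage y to rows; pixel centre (row r, col c) sits at
# origin + (c - 0.5, r - 0.5) * um_per_px.
# ---------------------------------------------------------------------------

#' Assemble low-resolution tiles into a well super-image
#'
#' Tiles are placed row-major with no blending (scan fields abut). The
#' stage-coordinate mapping (origin, um per pixel) is stored with the
#' image.
#'
#' @param tiles row-major list of `list(nuclei, did)` pixel matrices, all
#'   the same size.
#' @param layout list with `rows`, `cols`, `tile_um`, and optional `origin`
#'   (stage um of the well corner, default `c(0, 0)`).
#' @return An object of class `super_image` with channels `nuclei`, `did`,
#'   plus `um_per_px`, `origin`, `extent`.
#' @export
assemble_superimage <- function(tiles, layout) {
  rows <- layout$rows; cols <- layout$cols
  if (length(tiles) != rows * cols)
    stop("missing tile: expected ", rows * cols, ", got ", length(tiles))
  tp <- dim(tiles[[1]]$nuclei)
  if (tp[1] != tp[2]) stop("tiles must be square")
  for (t in tiles)
    if (!identical(dim(t$nuclei), tp) || !identical(dim(t$did), tp))
      stop("inconsistent tile shapes")
  tile_px <- tp[1]
  nuc <- matrix(0, rows * tile_px, cols * tile_px)
  did <- matrix(0, rows * tile_px, cols * tile_px)
  k <- 0L
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    k <- k + 1L
    ri <- ((r - 1L) * tile_px + 1L):(r * tile_px)
    ci <- ((cc - 1L) * tile_px + 1L):(cc * tile_px)
    nuc[ri, ci] <- tiles[[k]]$nuclei
    did[ri, ci] <- tiles[[k]]$did
  }
  origin <- if (is.null(layout$origin)) c(0, 0) else layout$origin
  structure(list(nuclei = nuc, did = did,
                 um_per_px = layout$tile_um / tile_px,
                 origin = as.numeric(origin),
                 extent = c(cols, rows) * layout$tile_um),
            class = "super_image")
}

#' @export
print.super_image <- function(x, ...) {
  cat(sprintf("<super_image> %d x %d px, %.3g um/px, extent %g x %g um\n",
              nrow(x$nuclei), ncol(x$nuclei), x$um_per_px,
              x$extent[1], x$extent[2]))
  invisible(x)
}

# stage um of pixel centres along an axis
px_centers_um <- function(n, um_per_px, origin1) {
  origin1 + (seq_len(n) - 0.5) * um_per_px
}

#' Find donor-cell candidates in the low-resolution DiD channel
#'
#' Thresholds the DiD channel at the donor intensity level, labels
#' 8-connected blobs, drops blobs below the minimum area, and returns blob
#' centroids in stage um.
#'
#' @param si a [assemble_superimage] result.
#' @param cfg a [quant_config] (`donor_intensity_threshold`,
#'   `donor_min_area_um2`).
#' @return matrix with columns `x`, `y` (stage um); zero rows if none.
#' @export
find_donors_2d <- function(si, cfg = quant_config()) {
  stopifnot(inherits(si, "super_image"))
  m <- si$did > cfg$donor_intensity_threshold
  if (!any(m))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  a <- array(m, c(1L, dim(m)))                  # 26-conn with nz=1 = 8-conn
  comp <- label_components(a, 26)[1, , ]
  areas <- label_counts(comp) * si$um_per_px^2
  keep <- which(areas >= cfg$donor_min_area_um2)
  if (!length(keep))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  ys <- px_centers_um(nrow(comp), si$um_per_px, si$origin[2])
  xs <- px_centers_um(ncol(comp), si$um_per_px, si$origin[1])
  out <- t(vapply(keep, function(k) {
    w <- which(comp == k, arr.ind = TRUE)
    c(x = mean(xs[w[, 2]]), y = mean(ys[w[, 1]]))
  }, numeric(2)))
  out[order(out[, "y"], out[, "x"]), , drop = FALSE]
}

# nucleus positions (stage um) as intensity local maxima with minimum
# separation; greedy suppression in descending intensity order
detect_nuclei_2d <- function(si, intensity_threshold = 60, min_sep = 10) {
  img <- si$nuclei
  r <- max(1L, as.integer(ceiling(min_sep / si$um_per_px / 2)))
  nr <- nrow(img); nc <- ncol(img)
  mx <- img
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    mx <- pmax(mx, img[ys, xs])
  }
  cand <- which(img >= mx & img > intensity_threshold, arr.ind = TRUE)
  if (!nrow(cand)) return(matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))))
  ys <- px_centers_um(nr, si$um_per_px, si$origin[2])
  xs <- px_centers_um(nc, si$um_per_px, si$origin[1])
  pts <- cbind(x = xs[cand[, 2]], y = ys[cand[, 1]])
  o <- order(img[cand], -cand[, 1], -cand[, 2], decreasing = TRUE)
  pts <- pts[o, , drop = FALSE]
  acc <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (nrow(acc) == 0 ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= min_sep^2)
      acc <- rbind(acc, p)
  }
  colnames(acc) <- c("x", "y")
  acc
}

#' Count nuclei within a radius of a position
#'
#' Nuclei are detected as supra-threshold local intensity maxima with a
#' minimum mutual separation of about one nuclear diameter; a nucleus at
#' exactly the radius counts (inclusive boundary).
#'
#' @param si a `super_image`.
#' @param center `(x, y)` stage um.
#' @param radius um.
#' @return integer count.
#' @export
count_nuclei <- function(si, center, radius) {
  pts <- detect_nuclei_2d(si)
  if (!nrow(pts)) return(0L)
  sum((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 <= radius^2)
}

#' Select qualifying donor ROIs
#'
#' A donor qualifies if the nearest other donor is at least the exclusion
#' distance away (200 um, inclusive) and at least `min_nuclei` nuclei lie
#' within the density radius (200 um) of it.
#'
#' @param donors donor centroids from [find_donors_2d].
#' @param si the `super_image`.
#' @param cfg a [quant_config].
#' @return data.frame of class `roi_set`: `kind`, `x`, `y`,
#'   `nearest_donor_distance`, `nuclei_in_radius`, ordered by y then x.
#' @export
select_donor_rois <- function(donors, si, cfg = quant_config()) {
  nuclei <- detect_nuclei_2d(si)
  n <- nrow(donors)
  if (n == 0)
    return(empty_roi_set())
  nd <- vapply(seq_len(n), function(i) {
    if (n == 1) return(Inf)
    min(sqrt((donors[-i, 1] - donors[i, 1])^2 +
               (donors[-i, 2] - donors[i, 2])^2))
  }, numeric(1))
  nn <- vapply(seq_len(n), function(i) {
    if (!nrow(nuclei)) return(0L)
    sum((nuclei[, 1] - donors[i, 1])^2 + (nuclei[, 2] - donors[i, 2])^2 <=
          cfg$nuclei_radius^2)
  }, integer(1))
  keep <- nd >= cfg$exclusion_distance & nn >= cfg$min_nuclei
  out <- data.frame(kind = rep("donor", sum(keep)),
                    x = donors[keep, 1], y = donors[keep, 2],
                    nearest_donor_distance = nd[keep],
                    nuclei_in_radius = nn[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roi_set", "data.frame")
  out
}

empty_roi_set <- function() {
  out <- data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                    nearest_donor_distance = numeric(0),
                    nuclei_in_radius = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("roi_set", "data.frame")
  out
}

#' Select random donor-free control ROIs
#'
#' Rejection-samples positions uniformly over the well until `max_controls`
#' (15) are accepted or the attempt budget is exhausted. A position is
#' accepted if no donor lies within the exclusion distance, the nucleus
#' density requirement is met, and its square high-resolution field
#' footprint does not overlap any previously accepted footprint (donor or
#' control). Deterministic given the seed.
#'
#' @param si the `super_image`.
#' @param donors ALL donor centroids of the well (not only selected ones).
#' @param selected the selected donor `roi_set` (their footprints are kept
#'   clear).
#' @param cfg a [quant_config].
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling budget.
#' @return a `roi_set` of kind `"control"`, in acceptance order; may hold
#'   fewer than `max_controls` rows.
#' @export
select_control_rois <- function(si, donors, selected, cfg = quant_config(),
                                seed = 1, max_attempts = 4000) {
  nuclei <- detect_nuclei_2d(si)
  half <- cfg$field_extent / 2
  taken <- if (nrow(selected)) cbind(selected$x, selected$y)
  else matrix(numeric(0), ncol = 2)
  acc <- empty_roi_set()
  with_seed(seed, {
    attempts <- 0L
    while (nrow(acc) < cfg$max_controls && attempts < max_attempts) {
      attempts <- attempts + 1L
      p <- c(si$origin[1] + runif(1, half, si$extent[1] - half),
             si$origin[2] + runif(1, half, si$extent[2] - half))
      dd <- if (nrow(donors))
        min(sqrt((donors[, 1] - p[1])^2 + (donors[, 2] - p[2])^2)) else Inf
      if (dd < cfg$exclusion_distance) next
      nn <- if (nrow(nuclei))
        sum((nuclei[, 1] - p[1])^2 + (nuclei[, 2] - p[2])^2 <=
              cfg$nuclei_radius^2) else 0L
      if (nn < cfg$min_nuclei) next
      if (nrow(taken) &&
          any(abs(taken[, 1] - p[1]) < cfg$field_extent &
                abs(taken[, 2] - p[2]) < cfg$field_extent)) next
      taken <- rbind(taken, p)
      acc <- rbind(acc, data.frame(kind = "control", x = p[1], y = p[2],
                                   nearest_donor_distance = dd,
                                   nuclei_in_radius = nn,
                                   stringsAsFactors = FALSE))
    }
  })
  rownames(acc) <- NULL
  class(acc) <- c("roi_set", "data.frame")
  acc
}

#' Export acquisition coordinates as CSV
#'
#' Donors first (ordered by y then x), then controls in acceptance order.
#' Round-trips through [read_coordinates].
#'
#' @param rois a `roi_set` (or rbind of several).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_coordinates <- function(rois, path) {
  df <- as.data.frame(rois)
  don <- df[df$kind == "donor", , drop = FALSE]
  don <- don[order(don$y, don$x), , drop = FALSE]
  ctl <- df[df$kind == "control", , drop = FALSE]
  out <- rbind(don, ctl)
  names(out) <- c("kind", "x_um", "y_um", "nearest_donor_distance",
                  "nuclei_in_radius")
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_coordinates
#' @export
read_coordinates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Select all ROIs of a well
#'
#' Convenience orchestrator: find donors, filter them, then sample
#' controls.
#'
#' @param si the `super_image`.
#' @param cfg a [quant_config].
#' @param seed RNG seed for the control sampling.
#' @return a `roi_set` holding donor and control rows.
#' @export
select_rois <- function(si, cfg = quant_config(), seed = 1) {
  donors <- find_donors_2d(si, cfg)
  sel <- select_donor_rois(donors, si, cfg)
  ctl <- select_control_rois(si, donors, sel, cfg, seed = seed)
  out <- rbind(as.data.frame(sel), as.data.frame(ctl))
  rownames(out) <- NULL
  class(out) <- c("roi_set", "data.frame")
  out
}
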