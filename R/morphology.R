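# Thin R wrappers over the compiled morphology/labelling core.
# Structuring elements are integer offset matrices (dz, dy, dx), one row
# per element voxel, always including the origin.

se_box <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  as.matrix(g)
}

# 2D disc of radius r applied per z-slice (dz = 0)
se_disc2d <- function(r) {
  g <- expand.grid(dz = 0L, dy = -r:r, dx = -r:r)
  as.matrix(g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE])
}

# 3D ball of radius r (isotropic in voxel units)
se_ball <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  as.matrix(g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE])
}

dilate_mask <- function(mask, se) {
  d <- dim(mask)
  out <- cpp_dilate(as.logical(mask), d, storage_int(se))
  dim(out) <- d
  out
}

erode_mask <- function(mask, se) {
  d <- dim(mask)
  out <- cpp_erode(as.logical(mask), d, storage_int(se))
  dim(out) <- d
  out
}

close_mask <- function(mask, se) {
  erode_mask(dilate_mask(mask, se), se)
}

#' Label connected components of a binary 3D mask
#'
#' 26-connectivity by default (8-connectivity in-plane when `nz = 1`).
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return integer array of component labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  out <- cpp_label_components(as.logical(mask), d, as.integer(connectivity))
  dim(out) <- d
  out
}

storage_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}

# volumes (voxel counts) of all labels 1..max
label_counts <- function(labels) {
  mx <- max(labels)
  if (mx == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = mx)
}

# centroids (z, y, x voxel indices) of all labels; rows = label
label_centroids <- function(labels) {
  d <- dim(labels)
  mx <- max(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  z <- ((idx - 1L) %% d[1]) + 1L
  y <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  x <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  n <- tabulate(lab, nbins = mx)
  cbind(z = rowsum_vec(z, lab, mx) / n,
        y = rowsum_vec(y, lab, mx) / n,
        x = rowsum_vec(x, lab, mx) / n)
}

# sum `values` grouped by integer `groups` (1..nbins), zero-filled
rowsum_vec <- function(values, groups, nbins) {
  out <- numeric(nbins)
  s <- rowsum(as.numeric(values), groups)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
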