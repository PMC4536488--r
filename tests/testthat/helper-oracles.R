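# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately use plain voxel loops / exhaustive search and
# never call the code paths they check.

# per-cell supra-threshold voxel count and intensity sum by explicit
# triple loop: label = cell, outside the dilated donor, strictly above thr
oracle_quantify <- function(channel, labels, dilated_mask, threshold) {
  d <- dim(labels)
  mx <- max(labels)
  cnt <- integer(mx); s <- numeric(mx)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    l <- labels[z, y, x]
    if (l > 0L && !dilated_mask[z, y, x] && channel[z, y, x] > threshold) {
      cnt[l] <- cnt[l] + 1L
      s[l] <- s[l] + channel[z, y, x]
    }
  }
  list(voxels = cnt, intensity = s)
}

# exhaustive centroid-distance search for the pseudo-donor
oracle_pseudo_donor <- function(labels, voxel_size) {
  d <- dim(labels)
  ctr <- (d - 1) / 2 * voxel_size
  best <- NA_integer_; bestd <- Inf
  for (l in seq_len(max(labels))) {
    w <- which(labels == l, arr.ind = TRUE)
    if (!nrow(w)) next
    cen <- (colMeans(w) - 1) * voxel_size
    dd <- sum((cen - ctr)^2)
    if (dd < bestd) { bestd <- dd; best <- l }
  }
  best
}

# exhaustive donor-ROI filter: keep donors whose nearest other donor is
# >= exclusion distance and with >= min_nuclei detected nuclei in radius
oracle_donor_filter <- function(donors, nuclei, cfg) {
  keep <- logical(nrow(donors))
  for (i in seq_len(nrow(donors))) {
    ok_iso <- TRUE
    for (j in seq_len(nrow(donors))) {
      if (i == j) next
      if (sqrt(sum((donors[i, ] - donors[j, ])^2)) < cfg$exclusion_distance)
        ok_iso <- FALSE
    }
    nn <- 0L
    for (k in seq_len(nrow(nuclei)))
      if (sum((nuclei[k, ] - donors[i, ])^2) <= cfg$nuclei_radius^2)
        nn <- nn + 1L
    keep[i] <- ok_iso && nn >= cfg$min_nuclei
  }
  keep
}

# small fast lawn for unit tests
tiny_lawn <- function(seed = 1, n_cells = 6, shape = c(12, 64, 64)) {
  generate_lawn(lawn_spec(shape = shape, n_cells = n_cells,
                          mean_cell_diameter = 10, seed = seed))
}

# acceptance-scale lawn (the size the method was characterised at)
accept_lawn <- function(seed) {
  generate_lawn(lawn_spec(shape = c(20, 256, 256), n_cells = 50, seed = seed))
}

as_stack <- function(arr, voxel_size = c(1, 1, 1)) {
  voxel_stack(arr, voxel_size)
}

# per-cell best-overlap Jaccard of a segmentation against ground truth
jaccard_per_cell <- function(truth, labs) {
  vapply(seq_len(max(truth)), function(l) {
    gt <- truth == l
    ov <- table(labs[gt])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) return(0)
    cand <- as.integer(names(ov)[which.max(ov)])
    pr <- labs == cand
    sum(gt & pr) / sum(gt | pr)
  }, numeric(1))
}
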