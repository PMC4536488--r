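# ---------------------------------------------------------------------------
# Transfer quantification: donor detection, donor blanking, and per-
# acceptor-cell quantification of supra-threshold transferred signal.
# ---------------------------------------------------------------------------

# threshold + component-volume filter + morphological closing for one
# channel; returns the donor-cell representation mask
donor_channel_mask <- function(stack, cfg) {
  m <- stack$intensities > cfg$donor_intensity_threshold
  if (!any(m)) return(m)
  comp <- label_components(m, 26)
  vols <- label_counts(comp) * voxel_volume(stack)
  keep <- which(vols >= cfg$donor_min_volume)
  m <- array(comp %in% keep & comp > 0L, dim(comp))
  if (!any(m)) return(m)
  se <- if (cfg$closing_3d) se_ball(cfg$closing_radius)
  else se_disc2d(cfg$closing_radius)
  close_mask(m, se)
}

#' Detect the donor cell of a stack
#'
#' Donors are recognised by near-saturation signal: the channel is
#' thresholded at the donor intensity level, 26-connected components below
#' the minimum donor volume (1000 um^3) are discarded, and the surviving
#' representation is morphologically closed to fill internal holes. If an
#' EGFP channel exists, the union of the DiD and EGFP representations
#' approximates the donor. The watershed cell with the highest voxel
#' overlap to the approximation is united with it (OR) to form the donor
#' mask, which is then dilated by one voxel in all directions (3x3x3 cube)
#' so no donor-adjacent signal is counted in acceptors. If the
#' approximation is empty the stack is a control stack and the pseudo-donor
#' rule applies. Stacks whose donor components attach to two or more
#' different watershed cells are rejected (donor doublets are excluded from
#' the assay).
#'
#' @param did DiD [voxel_stack] (8-bit).
#' @param egfp optional EGFP [voxel_stack].
#' @param labels segmented cell label array.
#' @param cfg a [quant_config].
#' @return A list of class `donor_definition`: `mask`, `dilated_mask`,
#'   `donor_cell_label`, `is_control`, `weak_donor` (a supra-transfer-
#'   threshold but sub-donor-threshold blob of donor size was present;
#'   flagged for manual review).
#' @export
detect_donor <- function(did, egfp = NULL, labels, cfg = quant_config()) {
  stopifnot(inherits(did, "voxel_stack"))
  if (did$scale_max != 255)
    stop("donor detection expects 8-bit data; apply normalize_to_8bit first")
  d <- dim(labels)
  approx <- donor_channel_mask(did, cfg)
  if (!is.null(egfp)) approx <- approx | donor_channel_mask(egfp, cfg)

  weak <- FALSE
  if (!any(approx)) {
    # weak-donor check: donor-sized blob above the transfer threshold but
    # below the donor intensity level
    m2 <- did$intensities > cfg$did_threshold
    if (any(m2)) {
      comp2 <- label_components(m2, 26)
      weak <- any(label_counts(comp2) * voxel_volume(did) >=
                    cfg$donor_min_volume)
    }
    lab <- select_pseudo_donor(labels, did$voxel_size)
    mask <- labels == lab
    dilated <- dilate_mask(mask, se_box(cfg$dilation_radius))
    return(structure(list(mask = mask, dilated_mask = dilated,
                          donor_cell_label = lab, is_control = TRUE,
                          weak_donor = weak),
                     class = "donor_definition"))
  }

  # assign each donor component to its best-overlap watershed cell
  comp <- label_components(approx, 26)
  assigned <- integer(0)
  for (k in seq_len(max(comp))) {
    ov <- labels[comp == k]
    ov <- ov[ov > 0L]
    if (!length(ov)) next
    counts <- tabulate(ov, nbins = max(labels))
    assigned <- c(assigned, which.max(counts))  # ties -> lowest label
  }
  if (length(unique(assigned)) > 1L)
    stop("multiple donors: donor components attach to different cells; stack rejected")
  donor_cell <- if (length(assigned)) assigned[1] else {
    ov_all <- labels[approx & labels > 0L]
    if (!length(ov_all)) stop("donor approximation overlaps no segmented cell")
    which.max(tabulate(ov_all, nbins = max(labels)))
  }
  mask <- approx | (labels == donor_cell)
  dilated <- dilate_mask(mask, se_box(cfg$dilation_radius))
  structure(list(mask = mask, dilated_mask = dilated,
                 donor_cell_label = donor_cell, is_control = FALSE,
                 weak_donor = FALSE),
            class = "donor_definition")
}

#' Select the pseudo-donor cell of a control stack
#'
#' In a donor-free control stack the cell whose centre of mass (in um) is
#' closest to the geometric centre of the stack plays the donor's role, so
#' background is measured through the identical code path. Ties go to the
#' lowest label.
#'
#' @param labels cell label array.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return the selected cell label.
#' @export
select_pseudo_donor <- function(labels, voxel_size) {
  mx <- max(labels)
  if (mx == 0L) stop("no cells in label map")
  cen <- label_centroids(labels)
  present <- which(!is.nan(cen[, 1]) & label_counts(labels) > 0L)
  ctr <- (dim(labels) - 1) / 2 * voxel_size
  d2 <- ((cen[present, "z"] - 1) * voxel_size[1] - ctr[1])^2 +
    ((cen[present, "y"] - 1) * voxel_size[2] - ctr[2])^2 +
    ((cen[present, "x"] - 1) * voxel_size[3] - ctr[3])^2
  unname(present[which.min(d2)])
}

#' Quantify transferred signal per acceptor cell
#'
#' For every segmented cell except the donor: cells touching the lateral
#' (x/y) image boundary and cells below the minimum volume (100 um^3,
#' presumed dead) are excluded; for the rest, voxels strictly above the
#' global threshold, inside the cell and outside the dilated donor mask are
#' counted (transfer volume) and their grayscale values summed (integrated
#' transfer intensity). Supra-threshold signal outside all cells is
#' reported as unspecific transfer but never counted.
#'
#' @param channel transfer channel [voxel_stack] (DiD or EGFP, 8-bit).
#' @param labels cell label array aligned to the channel.
#' @param donor a `donor_definition` from [detect_donor].
#' @param threshold global transfer threshold (grayscale; strictly-above
#'   semantics).
#' @param cfg a [quant_config].
#' @param stack_id identifier carried into exports.
#' @return A list of class `stack_result`: `stack_id`, `is_control`,
#'   `weak_donor`, `records` (per-acceptor-cell data.frame), `totals`
#'   (summed voxels/intensity over included cells), `unspecific_intensity`,
#'   `unspecific_voxels`.
#' @export
quantify_transfer <- function(channel, labels, donor,
                              threshold = NULL, cfg = quant_config(),
                              stack_id = "stack") {
  stopifnot(inherits(channel, "voxel_stack"),
            inherits(donor, "donor_definition"))
  if (!identical(dim(channel$intensities), dim(labels)))
    stop("channel and label map shapes differ")
  if (is.null(threshold)) threshold <- cfg$did_threshold
  d <- dim(labels)
  mx <- max(labels)
  vv <- voxel_volume(channel)
  vols <- label_counts(labels) * vv

  touching <- unique(c(labels[, 1, ], labels[, d[2], ],
                       labels[, , 1], labels[, , d[3]]))
  touching <- touching[touching > 0L]

  supra <- channel$intensities > threshold & !donor$dilated_mask & labels > 0L
  idx <- which(supra)
  cnt <- tabulate(labels[idx], nbins = mx)
  ints <- rowsum_vec(channel$intensities[idx], labels[idx], mx)

  cells <- setdiff(which(vols > 0), donor$donor_cell_label)
  tb <- cells %in% touching
  small <- vols[cells] < cfg$cell_min_volume
  excluded <- tb | small
  reason <- ifelse(tb, "boundary", ifelse(small, "small_volume", ""))
  records <- data.frame(cell_label = cells,
                        volume_um3 = vols[cells],
                        transfer_voxels = cnt[cells],
                        transfer_intensity = ints[cells],
                        touches_boundary = tb,
                        excluded = excluded,
                        exclusion_reason = reason,
                        stringsAsFactors = FALSE)
  inc <- !records$excluded
  out_idx <- which(channel$intensities > threshold & labels == 0L &
                     !donor$dilated_mask)
  structure(list(stack_id = stack_id,
                 is_control = donor$is_control,
                 weak_donor = donor$weak_donor,
                 donor_cell_label = donor$donor_cell_label,
                 records = records,
                 totals = list(
                   transfer_voxels = sum(records$transfer_voxels[inc]),
                   transfer_intensity = sum(records$transfer_intensity[inc])),
                 unspecific_intensity = sum(channel$intensities[out_idx]),
                 unspecific_voxels = length(out_idx)),
            class = "stack_result")
}

#' @export
print.stack_result <- function(x, ...) {
  cat(sprintf("<stack_result> %s%s: %d acceptor cells (%d included), total transfer %g over %d voxels\n",
              x$stack_id, if (x$is_control) " [control]" else "",
              nrow(x$records), sum(!x$records$excluded),
              x$totals$transfer_intensity, x$totals$transfer_voxels))
  invisible(x)
}

#' Transfer signal density of a stack
#'
#' Ratio of integrated transfer intensity to the number of supra-threshold
#' voxels. Undefined (NA) for stacks without transfer signal — never
#' reported as 0.
#'
#' @param result a `stack_result`.
#' @return intensity per voxel, or `NA_real_`.
#' @export
signal_density <- function(result) {
  stopifnot(inherits(result, "stack_result"))
  if (result$totals$transfer_voxels == 0) return(NA_real_)
  result$totals$transfer_intensity / result$totals$transfer_voxels
}

results_header <- c("stack_id", "is_control", "weak_donor", "row_type",
                    "cell_label", "volume_um3", "transfer_voxels",
                    "transfer_intensity", "touches_boundary", "excluded",
                    "exclusion_reason")

#' Export stack results to a tab-separated text file
#'
#' One row per acceptor-cell record plus one TOTAL row per stack, ordered
#' by stack id then cell label; fixed, versioned header. The file
#' round-trips through [read_results] without loss.
#'
#' @param results list of `stack_result` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_results <- function(results, path) {
  if (!length(results)) stop("no results to export")
  rows <- lapply(results[order(vapply(results, `[[`, "", "stack_id"))],
                 function(r) {
    rec <- r$records[order(r$records$cell_label), , drop = FALSE]
    cell_rows <- data.frame(stack_id = r$stack_id, is_control = r$is_control,
                            weak_donor = r$weak_donor, row_type = "cell",
                            rec, stringsAsFactors = FALSE)
    total_row <- data.frame(stack_id = r$stack_id, is_control = r$is_control,
                            weak_donor = r$weak_donor, row_type = "total",
                            cell_label = NA_integer_, volume_um3 = NA_real_,
                            transfer_voxels = r$totals$transfer_voxels,
                            transfer_intensity = r$totals$transfer_intensity,
                            touches_boundary = NA, excluded = NA,
                            exclusion_reason = "",
                            stringsAsFactors = FALSE)
    rbind(cell_rows, total_row)
  })
  tab <- do.call(rbind, rows)[, results_header]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Segment and quantify one stack end-to-end
#'
#' @param channels a [channel_set] (8-bit).
#' @param cfg a [quant_config].
#' @param params a [segmentation_params].
#' @param channel which channel to quantify (`"did"` or `"egfp"`).
#' @param stack_id identifier for exports.
#' @return a `stack_result`.
#' @export
analyze_stack <- function(channels, cfg = quant_config(),
                          params = segmentation_params(),
                          channel = c("did", "egfp"), stack_id = "stack") {
  channel <- match.arg(channel)
  labs <- segment_cells(channels, params)
  donor <- detect_donor(channels$did, channels$egfp, labs, cfg)
  thr <- if (channel == "did") cfg$did_threshold else cfg$egfp_threshold
  quantify_transfer(channels[[channel]], labs, donor, thr, cfg, stack_id)
}
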