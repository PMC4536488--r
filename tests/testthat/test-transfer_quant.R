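# hand-built 3-cell label map with interior space for signal placement;
# cells 1 and 2 are interior, cell 3 touches the lateral image border
simple_scene <- function() {
  labels <- array(0L, c(6, 20, 20))
  labels[2:5, 3:8, 3:8] <- 1L
  labels[2:5, 3:8, 12:17] <- 2L
  labels[2:5, 12:19, 18:20] <- 3L
  did <- array(0, c(6, 20, 20))
  list(labels = labels, did = did, vs = c(1, 1, 1))
}

control_donor <- function(labels, vs = c(1, 1, 1), lab = NULL) {
  if (is.null(lab)) lab <- select_pseudo_donor(labels, vs)
  mask <- labels == lab
  structure(list(mask = mask,
                 dilated_mask = codeit:::dilate_mask(mask,
                                                     codeit:::se_box(1L)),
                 donor_cell_label = lab, is_control = TRUE,
                 weak_donor = FALSE),
            class = "donor_definition")
}

test_that("signal exactly at the threshold is never counted", {
  sc <- simple_scene()
  sc$did[sc$labels > 0L] <- 100            # == threshold everywhere
  donor <- control_donor(sc$labels)
  res <- quantify_transfer(as_stack(sc$did), sc$labels, donor, 100,
                           quant_config(), "s")
  expect_equal(res$totals$transfer_voxels, 0)
  expect_equal(res$totals$transfer_intensity, 0)
  # one grayscale unit above: counted
  sc$did[sc$labels > 0L] <- 101
  res2 <- quantify_transfer(as_stack(sc$did), sc$labels, donor, 100,
                            quant_config(), "s")
  expect_gt(res2$totals$transfer_voxels, 0)
})

test_that("per-cell readouts equal the brute-force triple-loop oracle", {
  for (seed in c(41, 42)) {
    lawn <- tiny_lawn(seed = seed, n_cells = 8, shape = c(14, 80, 80))
    ts <- random_transfer_spec(lawn, n_target_cells = 3, seed = seed)
    st <- paint_donor_and_transfer(lawn, ts)
    donor <- detect_donor(st$channels$did, NULL, st$labels, quant_config())
    res <- quantify_transfer(st$channels$did, st$labels, donor, 100,
                             quant_config(), "s")
    o <- oracle_quantify(st$channels$did$intensities, st$labels,
                         donor$dilated_mask, 100)
    expect_identical(res$records$transfer_voxels,
                     o$voxels[res$records$cell_label])
    expect_identical(res$records$transfer_intensity,
                     o$intensity[res$records$cell_label])
  }
})

test_that("no voxel of the dilated donor mask is ever counted", {
  sc <- simple_scene()
  # donor = cell 1; supra-threshold signal ONLY inside the 1-voxel dilated
  # rim around it (spilling into cell 2's side is impossible here; place
  # the rim voxels that fall into background and cell interiors)
  mask <- sc$labels == 1L
  dil <- codeit:::dilate_mask(mask, codeit:::se_box(1L))
  rim <- dil & !mask
  sc$did[rim] <- 240
  donor <- structure(list(mask = mask, dilated_mask = dil,
                          donor_cell_label = 1L, is_control = FALSE,
                          weak_donor = FALSE), class = "donor_definition")
  res <- quantify_transfer(as_stack(sc$did), sc$labels, donor, 100,
                           quant_config(), "s")
  expect_equal(res$totals$transfer_voxels, 0)
  expect_equal(res$totals$transfer_intensity, 0)
  expect_equal(res$unspecific_voxels, 0)   # rim is blanked, not unspecific
})

test_that("totals are non-increasing in the threshold", {
  lawn <- tiny_lawn(seed = 43, n_cells = 8, shape = c(14, 80, 80))
  ts <- random_transfer_spec(lawn, n_target_cells = 3, seed = 1)
  st <- paint_donor_and_transfer(lawn, ts)
  donor <- detect_donor(st$channels$did, NULL, st$labels, quant_config())
  prev_v <- Inf; prev_i <- Inf
  for (thr in c(60, 100, 150, 200, 255)) {
    r <- quantify_transfer(st$channels$did, st$labels, donor, thr,
                           quant_config(), "s")
    expect_lte(r$totals$transfer_voxels, prev_v)
    expect_lte(r$totals$transfer_intensity, prev_i)
    prev_v <- r$totals$transfer_voxels
    prev_i <- r$totals$transfer_intensity
  }
})

test_that("boundary and small-volume cells are excluded with zero contribution", {
  sc <- simple_scene()
  # cell 4: 80 voxels = 80 um^3 < 100 um^3, holding a punctum
  sc$labels[2:3, 12:15, 3:12] <- 4L
  sc$did[2, 13, 5] <- 200
  sc$did[3, 14, 20] <- 200          # inside boundary-touching cell 3
  sc$did[2, 5, 14] <- 200           # inside included cell 2
  donor <- control_donor(sc$labels, lab = 1L)
  res <- quantify_transfer(as_stack(sc$did), sc$labels, donor, 100,
                           quant_config(), "s")
  rec <- res$records
  expect_true(rec$excluded[rec$cell_label == 4])
  expect_equal(rec$exclusion_reason[rec$cell_label == 4], "small_volume")
  expect_true(rec$excluded[rec$cell_label == 3])
  expect_equal(rec$exclusion_reason[rec$cell_label == 3], "boundary")
  expect_false(rec$excluded[rec$cell_label == 2])
  # totals: only cell 2's punctum counts (conservation over included cells)
  expect_equal(res$totals$transfer_voxels, 1)
  expect_equal(res$totals$transfer_intensity, 200)
  inc <- !rec$excluded
  expect_equal(res$totals$transfer_intensity, sum(rec$transfer_intensity[inc]))
})

test_that("supra-threshold signal outside cells is unspecific, not counted", {
  sc <- simple_scene()
  sc$did[1, 1, 1] <- 250            # background voxel
  sc$did[2, 5, 5] <- 150            # inside cell 1
  donor <- control_donor(sc$labels, lab = 2L)
  res <- quantify_transfer(as_stack(sc$did), sc$labels, donor, 100,
                           quant_config(), "s")
  expect_equal(res$unspecific_voxels, 1)
  expect_equal(res$unspecific_intensity, 250)
  expect_equal(res$totals$transfer_intensity, 150)
})

test_that("donor detection: volume filter, control fallback, ground truth", {
  cfg <- quant_config()
  lawn <- tiny_lawn(seed = 44, n_cells = 8, shape = c(14, 80, 80))
  ts <- random_transfer_spec(lawn, n_target_cells = 2, seed = 1)
  st <- paint_donor_and_transfer(lawn, ts)
  donor <- detect_donor(st$channels$did, NULL, st$labels, cfg)
  expect_false(donor$is_control)
  expect_equal(donor$donor_cell_label, st$donor_label)
  expect_true(all(donor$mask[st$labels == st$donor_label]))

  # a bright speck under 1000 um^3 is discarded -> control stack
  a <- array(0, c(14, 80, 80))
  a[5:9, 10:19, 10:19] <- 255       # 500 voxels = 500 um^3 at (1,1,1)
  sp <- detect_donor(as_stack(a), NULL, lawn$labels, cfg)
  expect_true(sp$is_control)
  expect_false(sp$weak_donor)

  # no signal at all -> control with pseudo-donor
  ctrl <- generate_control_stack(lawn$spec)
  dc <- detect_donor(ctrl$channels$did, NULL, ctrl$labels, cfg)
  expect_true(dc$is_control)
  expect_equal(dc$donor_cell_label,
               select_pseudo_donor(ctrl$labels, ctrl$spec$voxel_size))

  # donor-sized blob above the transfer threshold but below the donor
  # level is flagged for review
  b <- array(0, c(14, 80, 80))
  b[3:12, 20:60, 20:60] <- 150
  wk <- detect_donor(as_stack(b), NULL, lawn$labels, cfg)
  expect_true(wk$is_control)
  expect_true(wk$weak_donor)
})

test_that("stacks with donor components in different cells are rejected", {
  labels <- array(0L, c(10, 40, 40))
  labels[2:9, 2:39, 2:19] <- 1L
  labels[2:9, 2:39, 20:39] <- 2L
  a <- array(0, c(10, 40, 40))
  a[3:8, 5:35, 4:12] <- 255         # donor blob in cell 1 (> 1000 um^3)
  a[3:8, 5:35, 26:34] <- 255        # second donor blob in cell 2
  expect_error(detect_donor(as_stack(a), NULL, labels, quant_config()),
               "multiple donors")
})

test_that("EGFP channel contributes to the donor approximation by union", {
  labels <- array(0L, c(10, 40, 40))
  labels[2:9, 2:39, 2:39] <- 1L
  did <- array(0, c(10, 40, 40))
  did[3:8, 5:20, 5:20] <- 255
  egfp <- array(0, c(10, 40, 40))
  egfp[3:8, 18:35, 18:35] <- 255
  dn <- detect_donor(as_stack(did), as_stack(egfp), labels, quant_config())
  expect_false(dn$is_control)
  # union covers both blobs
  expect_true(all(dn$mask[3:8, 5:20, 5:20]))
  expect_true(all(dn$mask[3:8, 18:35, 18:35]))
})

test_that("pseudo-donor selection matches the exhaustive oracle", {
  for (seed in c(45, 46)) {
    lawn <- tiny_lawn(seed = seed, n_cells = 8, shape = c(12, 64, 64))
    expect_equal(select_pseudo_donor(lawn$labels, lawn$spec$voxel_size),
                 oracle_pseudo_donor(lawn$labels, lawn$spec$voxel_size))
  }
  # two cells symmetric about the centre: documented lowest-label tie-break
  sym <- array(0L, c(3, 5, 9))
  sym[2, 3, 2] <- 2L
  sym[2, 3, 8] <- 1L
  expect_equal(select_pseudo_donor(sym, c(1, 1, 1)), 1L)
  # single cell
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_equal(select_pseudo_donor(one, c(1, 1, 1)), 1L)
})

test_that("signal density is intensity per voxel, missing when undefined", {
  sc <- simple_scene()
  donor <- control_donor(sc$labels, lab = 2L)
  sc$did[2, 4, 4:8] <- 200            # 10 voxels at 200 inside cell 1
  sc$did[2, 5, 4:8] <- 200
  res <- quantify_transfer(as_stack(sc$did), sc$labels, donor, 100,
                           quant_config(), "s")
  expect_equal(res$totals$transfer_voxels, 10)
  expect_equal(signal_density(res), 200)
  res0 <- quantify_transfer(as_stack(array(0, dim(sc$did))), sc$labels,
                            donor, 100, quant_config(), "s")
  expect_true(is.na(signal_density(res0)))
})

test_that("TSV export round-trips every number with stable ordering", {
  lawn <- tiny_lawn(seed = 47, n_cells = 8, shape = c(14, 80, 80))
  ts <- random_transfer_spec(lawn, n_target_cells = 3, seed = 2)
  st <- paint_donor_and_transfer(lawn, ts)
  donor <- detect_donor(st$channels$did, NULL, st$labels, quant_config())
  r1 <- quantify_transfer(st$channels$did, st$labels, donor, 100,
                          quant_config(), "stack_b")
  ctrl <- generate_control_stack(lawn$spec)
  dc <- detect_donor(ctrl$channels$did, NULL, ctrl$labels, quant_config())
  r2 <- quantify_transfer(ctrl$channels$did, ctrl$labels, dc, 100,
                          quant_config(), "stack_a")
  p <- withr::local_tempfile(fileext = ".tsv")
  export_results(list(r1, r2), p)
  tab <- read_results(p)
  expect_equal(tab$stack_id[1], "stack_a")  # ordered by stack id
  expect_true(all(tab$is_control[tab$stack_id == "stack_a"]))
  cells_b <- tab[tab$stack_id == "stack_b" & tab$row_type == "cell", ]
  expect_equal(cells_b$cell_label, sort(r1$records$cell_label))
  m <- merge(cells_b, r1$records, by = "cell_label")
  expect_equal(m$transfer_intensity.x, m$transfer_intensity.y)
  expect_equal(m$volume_um3.x, m$volume_um3.y)
  tot_b <- tab[tab$stack_id == "stack_b" & tab$row_type == "total", ]
  expect_equal(tot_b$transfer_intensity, r1$totals$transfer_intensity)
  # 1 stack with n cells -> n + 1 data rows
  expect_equal(nrow(tab), nrow(r1$records) + nrow(r2$records) + 2)
})

test_that("control stacks are quantified through the identical code path", {
  spec <- lawn_spec(shape = c(14, 80, 80), n_cells = 8,
                    mean_cell_diameter = 10, seed = 48)
  ctrl <- generate_control_stack(spec, n_dim_puncta = 5, dim_intensity = 90)
  donor <- detect_donor(ctrl$channels$did, NULL, ctrl$labels, quant_config())
  expect_true(donor$is_control)
  res <- quantify_transfer(ctrl$channels$did, ctrl$labels, donor, 100,
                           quant_config(), "ctrl")
  o <- oracle_quantify(ctrl$channels$did$intensities, ctrl$labels,
                       donor$dilated_mask, 100)
  expect_identical(res$records$transfer_voxels,
                   o$voxels[res$records$cell_label])
  expect_equal(res$totals$transfer_intensity, 0)  # all signal sub-threshold
})
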