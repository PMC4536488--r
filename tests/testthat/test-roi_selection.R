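make_si <- function(ws) {
  m <- generate_well_mosaic(ws)
  assemble_superimage(m$tiles, m$layout)
}

test_that("tile assembly obeys the size and coordinate contracts", {
  tiles <- lapply(1:4, function(i)
    list(nuclei = matrix(i, 100, 100), did = matrix(0, 100, 100)))
  si <- assemble_superimage(tiles, list(rows = 2, cols = 2, tile_um = 775))
  expect_equal(dim(si$nuclei), c(200, 200))
  # row-major placement: tile k value i fills its quadrant
  expect_equal(si$nuclei[1, 1], 1)
  expect_equal(si$nuclei[1, 200], 2)
  expect_equal(si$nuclei[200, 1], 3)
  expect_equal(si$nuclei[200, 200], 4)
  expect_equal(si$um_per_px, 7.75)
  expect_error(assemble_superimage(tiles[1:3],
                                   list(rows = 2, cols = 2, tile_um = 775)),
               "missing tile")
  tiles[[2]]$did <- matrix(0, 50, 100)
  expect_error(assemble_superimage(tiles,
                                   list(rows = 2, cols = 2, tile_um = 775)),
               "inconsistent")
})

test_that("donor blobs are recovered within one low-res pixel", {
  ws <- random_well_spec(n_donors = 3, n_nuclei = 300, seed = 51)
  si <- make_si(ws)
  found <- find_donors_2d(si)
  expect_equal(nrow(found), 3)
  truth <- ws$donor_xy[order(ws$donor_xy[, 2], ws$donor_xy[, 1]), ]
  expect_true(all(abs(found[, "x"] - truth[, 1]) <= si$um_per_px))
  expect_true(all(abs(found[, "y"] - truth[, 2]) <= si$um_per_px))
})

test_that("donor calling: empty wells and sub-area specks", {
  si0 <- make_si(well_spec(nuclei_xy = cbind(500, 500)))
  expect_equal(nrow(find_donors_2d(si0)), 0)
  # a single bright pixel is below the minimum blob area
  si0$did[100, 100] <- 255
  cfg <- quant_config(donor_min_area_um2 = 2 * si0$um_per_px^2)
  expect_equal(nrow(find_donors_2d(si0, cfg)), 0)
})

test_that("nucleus counting uses inclusive Euclidean distance", {
  g <- expand.grid(x = seq(920, 1080, by = 40), y = seq(920, 1040, by = 40))
  inner <- cbind(g$x, g$y)                                  # 20, within 200
  outer <- cbind(seq(100, 280, by = 20), seq(100, 280, by = 20))  # far away
  ws <- well_spec(donor_xy = NULL, nuclei_xy = rbind(inner, outer))
  si <- make_si(ws)
  expect_equal(count_nuclei(si, c(1000, 1000), 200), 20)
  # inclusive boundary: radius exactly the distance of a detected nucleus
  pts <- codeit:::detect_nuclei_2d(si)
  d <- sqrt((pts[, 1] - 1000)^2 + (pts[, 2] - 1000)^2)
  r <- max(d[d <= 200])
  expect_equal(count_nuclei(si, c(1000, 1000), r), sum(d <= r))
  # empty channel
  si$nuclei[] <- 0
  expect_equal(count_nuclei(si, c(1000, 1000), 200), 0)
})

test_that("donor ROI rules: isolation and cell density", {
  cfg <- quant_config()
  # two donors 150 um apart: both excluded
  nn <- cbind(runif(600, 0, 2325), runif(600, 0, 2325))
  ws <- well_spec(donor_xy = rbind(c(1000, 1000), c(1150, 1000)),
                  nuclei_xy = nn)
  si <- make_si(ws)
  donors <- find_donors_2d(si, cfg)
  expect_equal(nrow(donors), 2)
  expect_equal(nrow(select_donor_rois(donors, si, cfg)), 0)
  # isolated donor with too few nuclei in radius (13 lawn nuclei + the
  # donor's own nucleus = 14 < 15): excluded
  g13 <- expand.grid(x = seq(1120, 1280, by = 40), y = seq(1120, 1240, by = 60))
  sparse <- well_spec(donor_xy = cbind(1200, 1180),
                      nuclei_xy = cbind(g13$x[1:13], g13$y[1:13]))
  si2 <- make_si(sparse)
  donors2 <- find_donors_2d(si2, cfg)
  sel2 <- select_donor_rois(donors2, si2, cfg)
  expect_equal(nrow(sel2), 0)
})

test_that("selection equals the exhaustive brute-force filter", {
  cfg <- quant_config()
  for (seed in c(52, 53, 54)) {
    ws <- random_well_spec(n_donors = 5, n_nuclei = 1200,
                           min_donor_sep = 150, seed = seed)
    si <- make_si(ws)
    donors <- find_donors_2d(si, cfg)
    sel <- select_donor_rois(donors, si, cfg)
    keep <- oracle_donor_filter(donors, codeit:::detect_nuclei_2d(si), cfg)
    expected <- donors[keep, , drop = FALSE]
    expect_equal(nrow(sel), nrow(expected))
    if (nrow(sel)) {
      expect_equal(sort(sel$x), sort(unname(expected[, "x"])))
      expect_equal(sort(sel$y), sort(unname(expected[, "y"])))
    }
  }
})

test_that("increasing min_nuclei never adds a donor ROI", {
  ws <- random_well_spec(n_donors = 5, n_nuclei = 900, seed = 55)
  si <- make_si(ws)
  donors <- find_donors_2d(si)
  prev <- Inf
  for (mn in c(5, 15, 40, 200)) {
    n <- nrow(select_donor_rois(donors, si, quant_config(min_nuclei = mn)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("control ROIs: full quota in empty wells, all predicates hold", {
  cfg <- quant_config()
  ws <- random_well_spec(n_donors = 0, n_nuclei = 1500, seed = 56)
  si <- make_si(ws)
  ctl <- select_control_rois(si, find_donors_2d(si, cfg), empty <-
                               select_donor_rois(find_donors_2d(si, cfg),
                                                 si, cfg),
                             cfg, seed = 1)
  expect_equal(nrow(ctl), 15)      # up to 15, achievable here
  # determinism
  ctl2 <- select_control_rois(si, find_donors_2d(si, cfg), empty, cfg,
                              seed = 1)
  expect_identical(ctl, ctl2)
  expect_false(identical(ctl, select_control_rois(si, find_donors_2d(si, cfg),
                                                  empty, cfg, seed = 2)))
  # re-validate all three predicates brute-force
  nuclei <- codeit:::detect_nuclei_2d(si)
  for (i in seq_len(nrow(ctl))) {
    expect_gte(sum((nuclei[, 1] - ctl$x[i])^2 + (nuclei[, 2] - ctl$y[i])^2 <=
                     cfg$nuclei_radius^2), cfg$min_nuclei)
  }
  for (i in seq_len(nrow(ctl))) for (j in seq_len(nrow(ctl))) {
    if (i == j) next
    expect_true(abs(ctl$x[i] - ctl$x[j]) >= cfg$field_extent ||
                  abs(ctl$y[i] - ctl$y[j]) >= cfg$field_extent)
  }
})

test_that("controls respect donor exclusion zones and footprints", {
  cfg <- quant_config()
  ws <- random_well_spec(n_donors = 4, n_nuclei = 1500, min_donor_sep = 450,
                         seed = 57)
  si <- make_si(ws)
  donors <- find_donors_2d(si, cfg)
  sel <- select_donor_rois(donors, si, cfg)
  ctl <- select_control_rois(si, donors, sel, cfg, seed = 3)
  for (i in seq_len(nrow(ctl))) {
    expect_gte(min(sqrt((donors[, "x"] - ctl$x[i])^2 +
                          (donors[, "y"] - ctl$y[i])^2)),
               cfg$exclusion_distance)
    if (nrow(sel))
      expect_true(all(abs(sel$x - ctl$x[i]) >= cfg$field_extent |
                        abs(sel$y - ctl$y[i]) >= cfg$field_extent))
  }
})

test_that("coordinate export round-trips with stable ordering", {
  ws <- random_well_spec(n_donors = 3, n_nuclei = 1500, min_donor_sep = 450,
                         seed = 58)
  si <- make_si(ws)
  rois <- select_rois(si, quant_config(), seed = 4)
  p <- withr::local_tempfile(fileext = ".csv")
  export_coordinates(rois, p)
  back <- read_coordinates(p)
  expect_equal(nrow(back), nrow(rois))
  don <- back[back$kind == "donor", ]
  expect_equal(don$y_um, sort(don$y_um))
  expect_equal(back$x_um, c(rois$x[rois$kind == "donor"],
                            rois$x[rois$kind == "control"]))
  # empty set -> header-only file
  p2 <- withr::local_tempfile(fileext = ".csv")
  export_coordinates(codeit:::empty_roi_set(), p2)
  expect_equal(nrow(read_coordinates(p2)), 0)
})
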