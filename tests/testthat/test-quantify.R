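# hand-built 6x6 field with one cell whose 4-pixel mask covers known values
hand_field <- function(vals = c(3, 5, 7, 9), pixel_size_um = 0.6) {
  mros <- matrix(0, 6, 6)
  mros[cbind(c(2, 2, 3, 3), c(2, 3, 2, 3))] <- vals
  mito <- matrix(0, 6, 6); mito[2:3, 2:3] <- 10
  nuc <- matrix(0, 6, 6); nuc[5, 5] <- 1
  field <- field_image(nuc, mito, mros, pixel_size_um = pixel_size_um)
  lab <- matrix(0L, 6, 6); lab[2:3, 2:3] <- 1L
  seg <- structure(list(nucleus_labels = lab, cell_labels = lab,
                        mito_labels = lab, n_cells = 1L),
                   class = "segmentation_result")
  list(field = field, seg = seg)
}

test_that("masked reporter signal is the sum over the mask, exactly", {
  hf <- hand_field(c(3, 5, 7, 9))
  cells <- measure_cells(hf$field, hf$seg)
  expect_equal(cells$mros_signal, 24)        # 3+5+7+9
  expect_equal(cells$mito_rfu, 10)
  expect_equal(cells$mask_px, 4L)
})

test_that("mask area converts to um^2 through the pixel calibration", {
  lab <- matrix(0L, 10, 10); lab[3:7, 3:7] <- 1L   # 25-pixel mask
  m <- matrix(1, 10, 10)
  field <- field_image(m, m, m, pixel_size_um = 0.6)
  seg <- structure(list(nucleus_labels = lab, cell_labels = lab,
                        mito_labels = lab, n_cells = 1L),
                   class = "segmentation_result")
  cells <- measure_cells(field, seg)
  expect_equal(cells$mito_area_um2, 9)       # 25 x 0.36
})

test_that("an empty mask yields an all-zero measurement record", {
  hf <- hand_field()
  seg <- hf$seg
  seg$mito_labels <- matrix(0L, 6, 6)        # cell retained, mask empty
  cells <- measure_cells(hf$field, seg)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$mros_signal, 0)
  expect_equal(cells$mito_rfu, 0)
  expect_equal(cells$mito_area_um2, 0)
})

test_that("signal excludes non-mask pixels even when the field is bright", {
  hf <- hand_field(c(3, 5, 7, 9))
  f <- hf$field
  f$mros_ch[5:6, 5:6] <- 1e6                 # non-colocalised blob
  cells <- measure_cells(f, hf$seg)
  expect_equal(cells$mros_signal, 24)
  expect_gt(plate_reader_signal(f), 24)      # the bulk readout sees it
})

test_that("shape mismatches between field and segmentation are errors", {
  hf <- hand_field()
  m <- matrix(1, 7, 7)
  big <- field_image(m, m, m)
  expect_error(measure_cells(big, hf$seg), "shape")
})

test_that("well summaries average per-cell metrics", {
  cells <- data.frame(well_id = "B02", field_index = 0L, cell_id = 1:3,
                      mros_signal = c(10, 20, 30), mito_rfu = c(1, 2, 3),
                      mito_area_um2 = c(5, 5, 8), mask_px = c(5L, 5L, 8L))
  ws <- summarize_well(cells)
  expect_equal(ws$mean_mros_per_cell, 20)
  expect_equal(ws$n_cells, 3L)
  # single cell: summary equals the measurement
  expect_equal(summarize_well(cells[2, ])$mean_mros_per_cell, 20)
  # partitioning the same cells across fields changes nothing
  cells2 <- cells; cells2$field_index <- c(0L, 1L, 1L)
  expect_equal(summarize_well(cells2), ws)
  expect_error(summarize_well(cells[0, ]), "no cells")
})

test_that("percent-of-control follows the increase/reduction conventions", {
  expect_equal(percent_increase(1.477, 1), 47.7, tolerance = 1e-12)
  expect_equal(percent_increase(5, 5), 0)
  expect_equal(percent_reduction(0.6378, 1), 36.22, tolerance = 1e-12)
  expect_error(percent_increase(1, 0), "control mean is zero")
})

test_that("condition aggregation normalises to the control condition", {
  ws <- data.frame(
    well_id = c("B02", "C02", "B03", "C03"),
    mean_mros_per_cell = c(100, 110, 150, 160),
    mean_mito_rfu = 1, mean_mito_area_um2 = 1, n_cells = 10L,
    condition = c("basal", "basal", "oxLDL", "oxLDL"))
  agg <- aggregate_condition(ws, control = "basal")
  expect_equal(agg$percent_vs_control[agg$condition == "basal"], 0)
  expect_equal(agg$percent_vs_control[agg$condition == "oxLDL"],
               (155 / 105 - 1) * 100)
  expect_equal(agg$n_wells, c(2L, 2L))
  expect_equal(agg$sem_mros[1], sd(c(100, 110)) / sqrt(2))
  expect_error(aggregate_condition(ws, control = "vehicle"), "no valid wells")
})

test_that("plate-reader normalisation is (raw - blank) / protein", {
  rec <- data.frame(well_id = c("A01", "A02", "A03"),
                    raw_rfu = c(500, 100, 100),
                    protein_ug = c(80, 50, NA))
  out <- normalize_platereader(rec, blank_wells = "A03")
  expect_equal(out$normalized[out$well_id == "A01"], 5)   # (500-100)/80
  expect_equal(out$normalized[out$well_id == "A02"], 0)
  expect_error(normalize_platereader(rec[1:2, ], blank_wells = "Z01"),
               "not found")
  rec$protein_ug[1] <- -1
  expect_error(normalize_platereader(rec, blank_wells = "A03"),
               "protein")
})

test_that("relative viability normalises to the vehicle control", {
  rec <- data.frame(condition = rep(c("vehicle", "drug", "toxin"), each = 2),
                    luminescence = c(5000, 5000, 2500, 2500, 1185, 1185))
  rv <- relative_viability(rec, vehicle = "vehicle")
  expect_equal(rv$viability_percent[rv$condition == "vehicle"], 100)
  expect_equal(rv$viability_percent[rv$condition == "drug"], 50)
  expect_equal(rv$viability_percent[rv$condition == "toxin"], 23.7)
  # 23.7% viability is a 76.3% reduction
  expect_equal(100 - rv$viability_percent[rv$condition == "toxin"], 76.3)
  expect_error(relative_viability(rec, vehicle = "absent"), "absent")
})

test_that("simulated folds of 1.2 and 2.0 are recovered within 10 points", {
  lay <- plate_layout(data.frame(
    well_id = c("B02", "B03", "C02", "C03", "D02", "D03"),
    condition = rep(c("basal", "oxLDL"), 3),
    role = rep(c("negative_control", "positive_control"), 3)),
    fields_per_well = 6L)
  p <- synth_params(width = 224L, height = 224L, n_cells = 15L,
                    min_separation_px = 24, border_margin_px = 20)
  for (f in c(1.2, 2.0)) {
    eff <- list(basal = condition_effect(1), oxLDL = condition_effect(f))
    pl <- simulate_plate(lay, eff, params = p, seed = round(1000 * f))
    res <- run_pipeline(lay, pl, pipeline_params(bg_method = "parabola"))
    got <- res$per_condition$percent_vs_control[
      res$per_condition$condition == "oxLDL"]
    expect_lt(abs(got - 100 * (f - 1)), 10)
  }
})

test_that("non-specific signal moves bulk totals but barely the masked means", {
  p0 <- small_params(nonspecific_fraction = 0)
  p1 <- small_params(nonspecific_fraction = 0.4)
  a <- simulate_field(n_cells = 6, params = p0, seed = 61)
  b <- simulate_field(n_cells = 6, params = p1, seed = 61)
  expect_gt(plate_reader_signal(b$field), 1.2 * plate_reader_signal(a$field))
  ma <- summarize_well(measure_cells(a$field, segment_field(a$field)))
  mb <- summarize_well(measure_cells(b$field, segment_field(b$field)))
  expect_lt(abs(mb$mean_mros_per_cell - ma$mean_mros_per_cell) /
              ma$mean_mros_per_cell, 0.05)
})

test_that("reporter scaling is exactly linear through masked measurement", {
  sim <- simulate_field(n_cells = 4, params = small_params(), seed = 23)
  seg <- segment_field(sim$field)
  a <- measure_cells(sim$field, seg, bg = bg_none())
  f2 <- sim$field
  f2$mros_ch <- f2$mros_ch * 3
  b <- measure_cells(f2, seg, bg = bg_none())
  expect_equal(b$mros_signal, 3 * a$mros_signal, tolerance = 1e-12)
  expect_equal(b$mito_rfu, a$mito_rfu)
  expect_equal(b$mito_area_um2, a$mito_area_um2)
})
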