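test_that("an all-zero nuclear channel yields zero nuclei", {
  lab <- segment_nuclei(matrix(0, 80, 80))
  expect_true(all(lab == 0L))
  seg <- segment_field(field_image(matrix(0, 80, 80), matrix(0, 80, 80),
                                   matrix(0, 80, 80)))
  expect_equal(seg$n_cells, 0L)
})

test_that("well-separated synthetic nuclei are counted and located exactly", {
  for (seed in c(2, 12)) {
    sim <- simulate_field(n_cells = 6, params = small_params(), seed = seed)
    lab <- segment_nuclei(sim$field$nuclei_ch)
    expect_equal(max(lab), 6L)
    cen <- label_centroids(lab)
    d <- vapply(seq_len(nrow(cen)), function(i)
      min(sqrt((sim$truth$centres[, 1] - cen$x[i])^2 +
                 (sim$truth$centres[, 2] - cen$y[i])^2)), 0)
    expect_lt(max(d), 1)
  }
})

test_that("two nuclei closer than the merge distance are split by watershed", {
  img <- matrix(0, 80, 80)
  blob <- function(cx, cy, r = 6) {
    x <- row(img); y <- col(img)
    3000 * exp(-(((x - cx)^2 + (y - cy)^2) / r^2)^2)
  }
  img <- blob(38, 40) + blob(51, 40)   # touching pair, 13 px apart
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 2L)
  cen <- label_centroids(lab)
  expect_equal(sort(round(cen$x)), c(38, 51), tolerance = 0.05)
})

test_that("cell regions partition the foreground among the nuclei", {
  sim <- simulate_field(n_cells = 5, params = small_params(), seed = 4)
  nuc <- segment_nuclei(sim$field$nuclei_ch)
  cells <- assign_cell_regions(nuc, sim$field$mito_ch)
  expect_setequal(setdiff(unique(as.vector(cells)), 0L),
                  setdiff(unique(as.vector(nuc)), 0L))
  # nucleus pixels stay inside their own cell region
  idx <- nuc > 0
  expect_true(all(cells[idx] == nuc[idx]))
  # partition: per-cell areas sum to the total foreground area
  expect_equal(sum(tabulate(cells[cells > 0])), sum(cells > 0))
})

test_that("disjoint mitochondrial clouds go to the nearer nucleus", {
  sim <- simulate_field(n_cells = 5, params = small_params(), seed = 14)
  nuc <- segment_nuclei(sim$field$nuclei_ch)
  cells <- assign_cell_regions(nuc, sim$field$mito_ch)
  cen <- label_centroids(nuc)
  fg <- which(cells > 0)
  xs <- row(cells)[fg]; ys <- col(cells)[fg]
  nearest <- vapply(seq_along(fg), function(i)
    cen$label[which.min((cen$x - xs[i])^2 + (cen$y - ys[i])^2)], 0L)
  expect_gte(mean(nearest == cells[fg]), 0.99)
})

test_that("zero nuclei give an empty cell map with a warning", {
  expect_warning(
    cells <- assign_cell_regions(matrix(0L, 60, 60),
                                 matrix(runif(3600), 60, 60)),
    "no nuclei")
  expect_true(all(cells == 0L))
})

test_that("a zero mitochondrial channel gives empty masks for every cell", {
  sim <- simulate_field(n_cells = 4, params = small_params(), seed = 6)
  nuc <- segment_nuclei(sim$field$nuclei_ch)
  cells <- assign_cell_regions(nuc, sim$field$mito_ch)
  mask <- segment_mitochondria(matrix(0, 160, 160), cells)
  expect_true(all(mask == 0L))
})

test_that("segmented masks recover ground truth (IoU) and stay in-region", {
  sim <- simulate_field(n_cells = 6, params = small_params(), seed = 16)
  seg <- segment_field(sim$field)
  expect_equal(seg$n_cells, 6L)
  ious <- truth_mask_iou(sim$truth, seg)
  expect_true(all(ious >= 0.7))
  idx <- seg$mito_labels > 0
  expect_true(all(seg$mito_labels[idx] == seg$cell_labels[idx]))
})

test_that("segmentation is invariant to a global intensity rescale", {
  sim <- simulate_field(n_cells = 5, params = small_params(), seed = 8)
  f <- sim$field
  g <- field_image(f$nuclei_ch * 3.7, f$mito_ch * 3.7, f$mros_ch * 3.7)
  a <- segment_field(f)
  b <- segment_field(g)
  expect_identical(a$nucleus_labels, b$nucleus_labels)
  expect_identical(a$cell_labels, b$cell_labels)
  expect_identical(a$mito_labels, b$mito_labels)
})

test_that("raising the speckle floor never increases mask area", {
  sim <- simulate_field(n_cells = 5, params = small_params(), seed = 19)
  nuc <- segment_nuclei(sim$field$nuclei_ch)
  cells <- assign_cell_regions(nuc, sim$field$mito_ch)
  areas <- vapply(c(1L, 4L, 16L, 64L), function(mp)
    sum(segment_mitochondria(sim$field$mito_ch, cells,
                             segment_params(min_object_px = mp)) > 0), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("nucleus detection recovers the exact count across random fields", {
  p <- small_params()
  counts <- vapply(101:200, function(seed) {
    sim <- simulate_field(n_cells = 6, params = p, seed = seed)
    max(segment_nuclei(sim$field$nuclei_ch))
  }, 0L)
  expect_identical(counts, rep(6L, 100))
})
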