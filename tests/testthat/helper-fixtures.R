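# Small shared fixtures; everything is generated in code at test time.

# compact generator settings for fast unit tests
small_params <- function(...) {
  synth_params(width = 160L, height = 160L, n_cells = 6L,
               min_separation_px = 30, border_margin_px = 24, ...)
}

# minimal two-condition duplicate-well layout (+ optional background wells)
two_condition_layout <- function(fields_per_well = 2L, background = FALSE) {
  wells <- data.frame(
    well_id = c("B02", "B03", "C02", "C03"),
    condition = rep(c("basal", "oxLDL"), 2),
    role = rep(c("negative_control", "positive_control"), 2),
    stringsAsFactors = FALSE)
  if (background)
    wells <- rbind(wells, data.frame(
      well_id = c("D02", "D03"), condition = "background",
      role = "background_well"))
  plate_layout(wells, fields_per_well = fields_per_well)
}

# brute-force paraboloid opening over full neighbourhoods (quadratic cost);
# independent oracle for the separable implementation
brute_parabola_open <- function(img, curvature) {
  erode <- function(im) {
    n <- nrow(im); m <- ncol(im)
    out <- im
    for (i in seq_len(n)) for (j in seq_len(m)) {
      out[i, j] <- min(im + curvature *
                         outer((seq_len(n) - i)^2, (seq_len(m) - j)^2, "+"))
    }
    out
  }
  -erode(-erode(img))
}

# matched-by-centroid IoU between ground-truth masks and segmented masks
truth_mask_iou <- function(truth, seg) {
  cen <- label_centroids(seg$nucleus_labels)
  tml <- truth_mask_labels(truth)
  vapply(seq_len(truth$n_cells), function(i) {
    k <- which.min((cen$x - truth$centres[i, 1])^2 +
                     (cen$y - truth$centres[i, 2])^2)
    a <- tml == i
    b <- seg$mito_labels == cen$label[k]
    sum(a & b) / sum(a | b)
  }, 0)
}
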