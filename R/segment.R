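#' Segmentation parameters
#'
#' Defaults for the per-field segmentation chain: nuclei by Gaussian
#' smoothing, Otsu threshold, hole filling and a distance-transform
#' watershed to split touching nuclei; cell regions by nearest-nucleus
#' partition of the closed foreground; mitochondria by per-cell Otsu
#' thresholding with a global-quantile fallback. All thresholds are
#' relative, so segmentation is invariant to a global intensity rescale.
#'
#' @param min_area_px Nuclei smaller than this are discarded (the default
#'   25 px is about a third of the smallest plausible nucleus at 0.6 um/px).
#' @param smoothing_sigma Gaussian blur sigma (px) before nuclear threshold.
#' @param border_policy `"exclude"` drops nuclei touching the field border
#'   (their mitochondria may be clipped); `"keep"` retains them.
#' @param closing_radius Disc radius (px) of the morphological closing used
#'   to consolidate the cell-region foreground.
#' @param min_object_px Mitochondrial speckles below this size are removed.
#' @param threshold_method Per-cell mitochondrial threshold: `"otsu"`
#'   (default) or `"quantile"`.
#' @param fallback_quantile Quantile of in-region mitochondrial intensity
#'   used when a cell is too dim/uniform for a meaningful Otsu split (or
#'   when `threshold_method = "quantile"`).
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(min_area_px = 25L, smoothing_sigma = 2,
                           border_policy = c("exclude", "keep"),
                           closing_radius = 5L, min_object_px = 4L,
                           threshold_method = c("otsu", "quantile"),
                           fallback_quantile = 0.9) {
  border_policy <- match.arg(border_policy)
  threshold_method <- match.arg(threshold_method)
  stopifnot(min_area_px >= 1, smoothing_sigma >= 0, min_object_px >= 1,
            fallback_quantile > 0, fallback_quantile < 1)
  structure(as.list(environment()), class = "segment_params")
}

relabel_sequential <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

#' Segment nuclei from the nuclear-dye channel
#'
#' Gaussian smoothing, Otsu threshold (on the max-normalised image, hence
#' intensity-scale invariant), hole filling, distance-transform watershed to
#' split touching nuclei, then size filtering and optional exclusion of
#' border-touching nuclei.
#'
#' @param nuclei_ch Non-negative numeric matrix (nuclear channel).
#' @param params A [segment_params()].
#' @return Integer label matrix; 0 is background, labels are 1..n.
#' @export
segment_nuclei <- function(nuclei_ch, params = segment_params()) {
  stopifnot(is.matrix(nuclei_ch), all(is.finite(nuclei_ch)),
            all(nuclei_ch >= 0))
  mx <- max(nuclei_ch)
  if (mx == 0) return(matrix(0L, nrow(nuclei_ch), ncol(nuclei_ch)))
  img <- nuclei_ch / mx
  if (params$smoothing_sigma > 0)
    img <- EBImage::gblur(img, sigma = params$smoothing_sigma)
  th <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  # contrast guard: in a field with no stained nuclei (noise only) the Otsu
  # split sits within the noise floor; require it to clear the background
  # median by a robust margin (scale-invariant)
  med <- stats::median(img)
  mad_bg <- stats::mad(img)
  if (th - med < 10 * mad_bg)
    return(matrix(0L, nrow(nuclei_ch), ncol(nuclei_ch)))
  bw <- EBImage::fillHull(img > th)
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  sizes <- tabulate(lab)
  drop <- which(sizes < params$min_area_px)
  if (params$border_policy == "exclude") {
    nr <- nrow(lab); nc <- ncol(lab)
    border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    drop <- union(drop, setdiff(border, 0L))
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel_sequential(lab)
}

# nearest-nucleus-pixel label for every pixel (running-min over per-label
# distance maps; ties resolved to the lower label, deterministically)
nearest_nucleus_map <- function(nucleus_labels) {
  ids <- setdiff(sort(unique(as.vector(nucleus_labels))), 0L)
  best <- matrix(Inf, nrow(nucleus_labels), ncol(nucleus_labels))
  arg <- matrix(0L, nrow(nucleus_labels), ncol(nucleus_labels))
  for (k in ids) {
    dk <- EBImage::distmap(matrix(as.numeric(nucleus_labels != k),
                                  nrow(nucleus_labels)))
    upd <- dk < best
    best[upd] <- dk[upd]
    arg[upd] <- k
  }
  arg
}

#' Grow a cell region around each nucleus
#'
#' The foreground — union of the nuclei and the above-threshold (Otsu)
#' mitochondrial signal, consolidated by a morphological closing — is
#' partitioned among the nuclei by distance to the nearest nucleus, giving
#' one region per nucleus ("the mitochondrial region surrounding each
#' nucleus"). Regions are pairwise disjoint and cover the foreground.
#'
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @param mito_ch Mitochondrial-dye channel, same shape.
#' @param params A [segment_params()].
#' @return Integer label matrix with the same label set as `nucleus_labels`.
#' @export
assign_cell_regions <- function(nucleus_labels, mito_ch,
                                params = segment_params()) {
  stopifnot(identical(dim(nucleus_labels), dim(mito_ch)))
  if (!any(nucleus_labels > 0)) {
    warning("no nuclei: empty cell map")
    return(matrix(0L, nrow(nucleus_labels), ncol(nucleus_labels)))
  }
  mx <- max(mito_ch)
  fg <- nucleus_labels > 0
  if (mx > 0) {
    th <- EBImage::otsu(EBImage::Image(mito_ch / mx), range = c(0, 1))
    fg <- fg | (mito_ch / mx > th)
  }
  if (params$closing_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$closing_radius + 1L,
                                shape = "disc")
    fg <- EBImage::closing(fg, brush) > 0
  }
  vor <- nearest_nucleus_map(nucleus_labels)
  cell <- matrix(0L, nrow(mito_ch), ncol(mito_ch))
  cell[fg] <- vor[fg]
  # a nucleus always owns its own pixels
  cell[nucleus_labels > 0] <- nucleus_labels[nucleus_labels > 0]
  cell
}

# Otsu threshold of an intensity vector (256-level histogram via EBImage)
otsu_vec <- function(v) {
  mx <- max(v)
  if (mx <= 0 || length(unique(v)) < 3L) return(Inf)
  EBImage::otsu(EBImage::Image(matrix(v / mx, nrow = 1)),
                range = c(0, 1)) * mx
}

#' Per-cell mitochondrial mask from the mitochondrial channel
#'
#' Thresholds the mitochondrial channel within each cell region (per-cell
#' Otsu by default; a global in-region quantile is the fallback for cells
#' too dim or uniform to split) and removes connected speckles below
#' `min_object_px`. The mask is a subset of the cell region by construction
#' and carries the cell's label. A cell whose mask comes out empty is
#' retained (its measurements are zero).
#'
#' @param mito_ch Mitochondrial-dye channel.
#' @param cell_labels Label matrix from [assign_cell_regions()].
#' @param params A [segment_params()].
#' @return Integer label matrix of mitochondrial pixels.
#' @export
segment_mitochondria <- function(mito_ch, cell_labels,
                                 params = segment_params()) {
  stopifnot(identical(dim(mito_ch), dim(cell_labels)))
  ids <- setdiff(sort(unique(as.vector(cell_labels))), 0L)
  mask <- matrix(FALSE, nrow(mito_ch), ncol(mito_ch))
  if (length(ids)) {
    in_region <- mito_ch[cell_labels > 0]
    global_th <- if (length(in_region))
      stats::quantile(in_region, params$fallback_quantile, names = FALSE)
      else Inf
    for (k in ids) {
      idx <- which(cell_labels == k)
      v <- mito_ch[idx]
      th <- if (params$threshold_method == "otsu") otsu_vec(v) else Inf
      if (!is.finite(th)) th <- global_th
      mask[idx[v > th]] <- TRUE
    }
  }
  if (any(mask)) {
    comp <- EBImage::bwlabel(mask)
    sizes <- tabulate(comp)
    small <- which(sizes < params$min_object_px)
    if (length(small)) mask[comp %in% small] <- FALSE
  }
  out <- matrix(0L, nrow(mito_ch), ncol(mito_ch))
  out[mask] <- cell_labels[mask]
  out
}

#' Segment one field end to end
#'
#' @param field A [field_image()].
#' @param params A [segment_params()].
#' @return An object of class `segmentation_result` with `nucleus_labels`,
#'   `cell_labels`, `mito_labels` and `n_cells`.
#' @export
segment_field <- function(field, params = segment_params()) {
  stopifnot(inherits(field, "field_image"))
  nuc <- segment_nuclei(field$nuclei_ch, params)
  cells <- if (any(nuc > 0)) assign_cell_regions(nuc, field$mito_ch, params)
           else matrix(0L, nrow(nuc), ncol(nuc))
  mito <- segment_mitochondria(field$mito_ch, cells, params)
  structure(list(nucleus_labels = nuc, cell_labels = cells,
                 mito_labels = mito, n_cells = max(0L, max(nuc))),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d cell(s), %d mitochondrial px\n",
              x$n_cells, sum(x$mito_labels > 0)))
  invisible(x)
}

#' Centroids of a label map
#' @param labels Integer label matrix.
#' @return Data frame with `label`, `x`, `y` (pixel coordinates, 1-based).
#' @export
label_centroids <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!length(ids))
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  xs <- row(labels); ys <- col(labels)
  data.frame(
    label = ids,
    x = vapply(ids, function(k) mean(xs[labels == k]), 0),
    y = vapply(ids, function(k) mean(ys[labels == k]), 0))
}
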