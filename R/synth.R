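#' Synthetic-field generator parameters
#'
#' Defaults emulate a confluent-but-separated field of adherent endothelial
#' cells imaged at 20x: flat-top nuclear blobs, a granular perinuclear
#' mitochondrial network rendered as small anisotropic Gaussian kernels
#' scattered in an annulus around each nucleus, a smooth parabolic (dome)
#' illumination background on the superoxide-reporter channel, and
#' Poisson shot noise plus additive Gaussian read noise.
#'
#' @param width,height Field size in pixels (at least 64 x 64).
#' @param n_cells Cells per field; ~30 matches a sparse seeded well.
#' @param pixel_size_um Micrometres per pixel.
#' @param nucleus_radius_px,nucleus_radius_sd Mean and spread of nuclear radii.
#' @param min_separation_px Minimum nucleus-centre separation
#'   (rejection-sampled).
#' @param border_margin_px Margin kept free of nucleus centres so whole cells
#'   (including their mitochondrial annulus) lie inside the field.
#' @param nuclei_amp,mito_amp Peak intensities (arbitrary units on a 16-bit
#'   scale) of the nuclear blob and mitochondrial granules.
#' @param n_granules Mitochondrial granules per cell.
#' @param granule_sigma_px Range of granule Gaussian widths.
#' @param mito_annulus Inner and outer annulus radii in multiples of the
#'   nucleus radius; mitochondria are perinuclear, 1-3 radii out.
#' @param mask_level Fraction of `mito_amp` above which a pixel belongs to
#'   the ground-truth mitochondrial mask.
#' @param mros_ratio Reporter intensity per unit mitochondrial texture at
#'   scale factor s = 1.
#' @param bg_baseline,bg_amplitude Parabolic illumination background on the
#'   reporter channel: a dome `baseline + amplitude * (1 - r^2 / R^2)`
#'   centred on the field (R = centre-to-corner distance).
#' @param bg_cellwell_factor Multiplier on the background surface in
#'   cell-bearing wells (empty background wells keep factor 1). Cell-free
#'   wells systematically underestimate the background of wells holding
#'   cells — residual probe, conditioned medium and cellular
#'   autofluorescence add diffuse signal — which is exactly why subtracting
#'   an empty-well mean is a biased correction while a per-image filter is
#'   not.
#' @param poisson Apply Poisson shot noise to expected counts.
#' @param gauss_sd Additive Gaussian read-noise standard deviation.
#' @param nonspecific_fraction Fraction f of total reporter signal placed
#'   outside mitochondria (in a cytoplasmic disc), emulating non-specific
#'   probe oxidation; 0 disables it.
#' @param cyto_exponent The cytoplasmic (non-specific) component scales as
#'   `s^cyto_exponent`. The default 2 makes whole-field (plate-reader-like)
#'   fold changes exceed mitochondria-masked fold changes, reproducing the
#'   inflation of unmasked readouts by non-specific signal.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(width = 320L, height = 320L, n_cells = 30L,
                         pixel_size_um = 0.6,
                         nucleus_radius_px = 5, nucleus_radius_sd = 0.7,
                         min_separation_px = 26, border_margin_px = 22,
                         nuclei_amp = 3000, mito_amp = 1500,
                         n_granules = 70L, granule_sigma_px = c(1.1, 2.0),
                         mito_annulus = c(1.0, 3.0), mask_level = 0.15,
                         mros_ratio = 0.6,
                         bg_baseline = 80, bg_amplitude = 200,
                         bg_cellwell_factor = 1.5,
                         poisson = TRUE, gauss_sd = 8,
                         nonspecific_fraction = 0, cyto_exponent = 2) {
  stopifnot(width >= 64, height >= 64, n_cells >= 0,
            nonspecific_fraction >= 0, nonspecific_fraction < 1,
            gauss_sd >= 0, bg_amplitude >= 0, bg_baseline >= 0,
            bg_cellwell_factor > 0,
            mros_ratio > 0, mask_level > 0)
  structure(as.list(environment()), class = "synth_params")
}

#' Parabolic illumination surface of a synthetic field
#'
#' @param params A [synth_params()].
#' @param width,height Field size; defaults taken from `params`.
#' @return Matrix `bg_baseline + bg_amplitude * (1 - r^2/R^2)`.
#' @export
background_surface <- function(params, width = params$width,
                               height = params$height) {
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  R2 <- (cx - 1)^2 + (cy - 1)^2
  x <- matrix(seq_len(width), width, height)
  y <- matrix(seq_len(height), width, height, byrow = TRUE)
  params$bg_baseline +
    params$bg_amplitude * (1 - ((x - cx)^2 + (y - cy)^2) / R2)
}

# additive render of a kernel onto img within a local window, in place
add_kernel <- function(img, cx, cy, fun, radius) {
  w <- nrow(img); h <- ncol(img)
  x0 <- max(1L, floor(cx - radius)); x1 <- min(w, ceiling(cx + radius))
  y0 <- max(1L, floor(cy - radius)); y1 <- min(h, ceiling(cy + radius))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, length(xs), length(ys))
  dy <- matrix(ys - cy, length(xs), length(ys), byrow = TRUE)
  img[xs, ys] <- img[xs, ys] + fun(dx, dy)
  img
}

place_centres <- function(n, width, height, margin, min_sep, max_tries) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n) {
    if (tries >= max_tries)
      stop(sprintf(paste0(
        "could not place %d cells at separation %.1f px in a %dx%d field; ",
        "try fewer cells or a smaller min_separation_px"),
        n, min_sep, width, height), call. = FALSE)
    px <- stats::runif(1, margin, width - margin)
    py <- stats::runif(1, margin, height - margin)
    if (!length(cx) || all((cx - px)^2 + (cy - py)^2 >= min_sep^2)) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
    tries <- tries + 1L
  }
  cbind(x = cx, y = cy)
}

#' Simulate one three-channel field with ground truth
#'
#' Nuclei are non-overlapping flat-top blobs; the mitochondrial channel is a
#' granular perinuclear texture; the superoxide-reporter channel is
#' `s * mros_ratio * (mito texture)` on the mitochondrial mask, plus an
#' optional non-specific cytoplasmic component, the parabolic background
#' surface, and noise. The returned ground truth carries everything needed
#' to verify downstream stages analytically: cell centres and radii, the
#' true per-cell mitochondrial masks, noiseless per-cell texture sums, the
#' condition scale factor and the background coefficients.
#'
#' @param n_cells Number of cells to place.
#' @param s Condition-level scale factor on mitochondrial reporter intensity
#'   (>= 0); the quantity the assay estimates.
#' @param params A [synth_params()].
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param well_id,field_index Plate coordinates stamped on the image.
#' @param s_cyto Scale factor of the non-specific cytoplasmic component;
#'   defaults to `s^cyto_exponent`.
#' @param bg_scale Multiplier on the background surface of this field
#'   (see `bg_cellwell_factor`; [simulate_plate()] applies it to
#'   cell-bearing wells, leaving background wells at 1).
#' @param noise If `FALSE`, disables Poisson and Gaussian noise regardless
#'   of `params`.
#' @return `list(field = field_image, truth = synth_truth)`.
#' @export
simulate_field <- function(n_cells = params$n_cells, s = 1,
                           params = synth_params(), seed = NULL,
                           well_id = "A01", field_index = 0L,
                           s_cyto = NULL, bg_scale = 1, noise = TRUE) {
  stopifnot(n_cells >= 0, s >= 0, bg_scale >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  if (is.null(s_cyto)) s_cyto <- s^params$cyto_exponent
  w <- params$width; h <- params$height
  nuclei <- matrix(0, w, h); mito <- matrix(0, w, h)
  centres <- place_centres(n_cells, w, h, params$border_margin_px,
                           params$min_separation_px,
                           max_tries = 4000L * max(1L, n_cells))
  radii <- if (n_cells) pmin(pmax(stats::rnorm(
    n_cells, params$nucleus_radius_px, params$nucleus_radius_sd),
    0.7 * params$nucleus_radius_px), 1.3 * params$nucleus_radius_px)
    else numeric(0)

  masks <- vector("list", n_cells)
  texture_sum <- numeric(n_cells)
  texture_mask_sum <- numeric(n_cells)
  owner <- matrix(0L, w, h)      # mask pixel ownership (disjoint by max texture)
  best_tex <- matrix(0, w, h)
  for (i in seq_len(n_cells)) {
    cx <- centres[i, 1]; cy <- centres[i, 2]; r <- radii[i]
    amp <- params$nuclei_amp * stats::runif(1, 0.85, 1.15)
    nuclei <- add_kernel(nuclei, cx, cy,
                         function(dx, dy) amp * exp(-((dx^2 + dy^2) / r^2)^2),
                         radius = 2.5 * r)
    ng <- params$n_granules
    rad <- stats::runif(ng, params$mito_annulus[1] * r,
                        params$mito_annulus[2] * r)
    ang <- stats::runif(ng, 0, 2 * pi)
    sig <- stats::runif(ng, params$granule_sigma_px[1],
                        params$granule_sigma_px[2])
    gamp <- params$mito_amp * stats::runif(ng, 0.85, 1.15)
    # anisotropy: three flat-top kernels strung along the tangent
    off <- rep(c(-1, 0, 1), each = ng)
    kx <- cx + rad * cos(ang) + off * sig * (-sin(ang))
    ky <- cy + rad * sin(ang) + off * sig * cos(ang)
    ks <- rep(sig, 3); ka <- rep(gamp, 3)
    # render all kernels of the cell on a local patch at once
    half <- ceiling(params$mito_annulus[2] * r + 3 *
                      params$granule_sigma_px[2] + 2)
    x0 <- max(1L, floor(cx - half)); x1 <- min(w, ceiling(cx + half))
    y0 <- max(1L, floor(cy - half)); y1 <- min(h, ceiling(cy + half))
    xs <- x0:x1; ys <- y0:y1
    px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
    npx <- length(px)
    d2 <- (px - rep(kx, each = npx))^2 + (py - rep(ky, each = npx))^2
    q <- (d2 * rep(1 / ks^2, each = npx))^2
    patch <- matrix(exp(-pmin(matrix(q, npx), 50)) %*% ka,
                    length(xs), length(ys))
    cell_tex <- matrix(0, w, h)
    # overlapping granules saturate rather than stack, giving the
    # plateau-like filled network of a saturating dye
    cell_tex[xs, ys] <- pmin(patch, params$mito_amp)
    above <- which(cell_tex > params$mask_level * params$mito_amp)
    claim <- above[cell_tex[above] > best_tex[above]]
    best_tex[claim] <- cell_tex[claim]
    owner[claim] <- i
    texture_sum[i] <- sum(cell_tex)
    mito <- mito + cell_tex
  }
  for (i in seq_len(n_cells)) {
    masks[[i]] <- which(owner == i)
    texture_mask_sum[i] <- sum(mito[masks[[i]]])
  }

  # reporter signal is strictly mask-confined: s * ratio * (total
  # mitochondrial texture) on each cell's true mask (sub-mask texture tails
  # stay on the mitochondrial channel only), so the nonspecific fraction f
  # is exact and per-cell masked sums are analytic
  mros <- matrix(0, w, h)
  idx <- which(owner > 0L)
  mros[idx] <- s * params$mros_ratio * mito[idx]

  f <- params$nonspecific_fraction
  if (f > 0 && n_cells > 0) {
    # total non-specific signal: f/(1-f) x (in-mask total at s = 1),
    # scaled by its own factor s_cyto and spread over cytoplasmic discs
    total_in_unit <- params$mros_ratio * sum(texture_mask_sum)
    total_out <- (f / (1 - f)) * total_in_unit * s_cyto
    cyto <- matrix(0, w, h)
    for (i in seq_len(n_cells)) {
      r_out <- 1.15 * params$mito_annulus[2] * radii[i]
      cyto <- add_kernel(cyto, centres[i, 1], centres[i, 2],
                         function(dx, dy) as.numeric(dx^2 + dy^2 <= r_out^2),
                         radius = r_out + 1)
    }
    for (i in seq_len(n_cells)) cyto[masks[[i]]] <- 0
    npx <- sum(cyto > 0)
    if (npx > 0) mros <- mros + (cyto > 0) * (total_out / npx)
  }

  bg <- bg_scale * background_surface(params)
  mros <- mros + bg

  add_noise <- function(ch) {
    if (params$poisson) ch <- matrix(stats::rpois(length(ch), ch), w, h)
    if (params$gauss_sd > 0)
      ch <- ch + matrix(stats::rnorm(length(ch), 0, params$gauss_sd), w, h)
    pmax(ch, 0)
  }
  if (noise && (params$poisson || params$gauss_sd > 0)) {
    nuclei <- add_noise(nuclei); mito <- add_noise(mito)
    mros <- add_noise(mros)
  }

  truth <- structure(list(
    centres = centres, radii = radii, masks = masks,
    texture_sum = texture_sum, texture_mask_sum = texture_mask_sum,
    s = s, s_cyto = s_cyto, nonspecific_fraction = f,
    mros_ratio = params$mros_ratio,
    background = list(baseline = params$bg_baseline,
                      amplitude = params$bg_amplitude,
                      scale = bg_scale),
    n_cells = n_cells, dim = c(w, h)), class = "synth_truth")
  list(field = field_image(nuclei, mito, mros, well_id = well_id,
                           field_index = field_index,
                           pixel_size_um = params$pixel_size_um),
       truth = truth)
}

#' Ground-truth mitochondrial mask as a label map
#' @param truth A `synth_truth` from [simulate_field()].
#' @return Integer matrix; pixel value = owning cell index (0 background).
#' @export
truth_mask_labels <- function(truth) {
  stopifnot(inherits(truth, "synth_truth"))
  m <- matrix(0L, truth$dim[1], truth$dim[2])
  for (i in seq_along(truth$masks)) m[truth$masks[[i]]] <- i
  m
}

#' Per-condition effect specification
#'
#' @param s Scale factor on mitochondrial reporter intensity (1 = control
#'   level). The headline oxLDL effect corresponds to s = 1.477 vs basal.
#' @param s_cyto Optional scale of the non-specific cytoplasmic component
#'   (default `s^cyto_exponent` of the generator parameters).
#' @param viability Multiplier on cells per field (cytotoxicity emulation).
#' @return A list of class `condition_effect`.
#' @export
condition_effect <- function(s = 1, s_cyto = NULL, viability = 1) {
  stopifnot(s >= 0, viability >= 0, is.null(s_cyto) || s_cyto >= 0)
  structure(list(s = s, s_cyto = s_cyto, viability = viability),
            class = "condition_effect")
}

#' Four-parameter logistic (4PL) dose-response curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`; with `hill > 0`
#' the response falls from `top` towards `bottom` as dose increases.
#'
#' @param dose Dose(s), same units as `ic50` (conventionally nM).
#' @param top,bottom Upper and lower asymptotes.
#' @param ic50 Dose of half-maximal effect (> 0).
#' @param hill Hill slope.
#' @return Numeric response(s).
#' @export
four_param_logistic <- function(dose, top, bottom, ic50, hill) {
  stopifnot(all(dose > 0), ic50 > 0)
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Dose-series effects from a 4PL curve
#'
#' Maps each dosed condition to a reporter scale factor s lying on a 4PL
#' curve, for simulating drug screens with a known IC50.
#'
#' @param doses Named numeric vector: condition label -> dose (nM).
#' @param ic50,hill 4PL location and slope of the simulated drug.
#' @param top,bottom s at zero and saturating dose (top is typically the
#'   stimulated level, bottom the fully-rescued level).
#' @return Named list of [condition_effect()]s.
#' @export
dose_effects <- function(doses, ic50 = 100, hill = 1, top = 1.5, bottom = 1) {
  s <- four_param_logistic(doses, top, bottom, ic50, hill)
  stats::setNames(lapply(s, condition_effect), names(doses))
}

field_seed <- function(master, well_index, field_index) {
  ((as.double(master) %% 99991) * 20011 + well_index * 211 +
     field_index * 7) %% 2147483647
}

#' Simulate a whole plate from a layout and effect specification
#'
#' One field-image/ground-truth pair is generated per field per well.
#' Per-field seeds are derived deterministically from the master seed, so
#' replicate wells of one condition share condition parameters (identical
#' true s) but differ in realised cell placement and noise. Background wells
#' receive the background surface plus noise only (no cells).
#'
#' @param layout A [plate_layout()].
#' @param effects Named list of [condition_effect()]s covering every
#'   cell-bearing condition in the layout.
#' @param params A [synth_params()].
#' @param seed Master seed.
#' @param dir Optional directory: fields are written as
#'   `<well>_f<field>.tif` plus `truth.csv` and `layout.yaml`.
#' @param noise Passed to [simulate_field()].
#' @return A list of class `synth_plate`: `layout`, `fields` (named list
#'   `<well>_f<field>` of `field_image`s), `truths` (parallel list), and
#'   `truth_table` (one row per field: well, condition, s, n_cells).
#' @export
simulate_plate <- function(layout, effects, params = synth_params(),
                           seed = 1, dir = NULL, noise = TRUE) {
  stopifnot(inherits(layout, "plate_layout"))
  wells <- layout$wells[layout$wells$role != "empty", ]
  conds <- unique(wells$condition[wells$role != "background_well"])
  missing <- setdiff(conds, names(effects))
  if (length(missing))
    stop("conditions missing from effect spec: ",
         paste(missing, collapse = ", "), call. = FALSE)
  fields <- list(); truths <- list(); rows <- list()
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (wi in seq_len(nrow(wells))) {
    wspec <- wells[wi, ]
    is_bg <- wspec$role == "background_well"
    eff <- if (is_bg) condition_effect(s = 0, viability = 0)
           else effects[[wspec$condition]]
    n_cells <- round(params$n_cells * eff$viability)
    for (fi in seq_len(layout$fields_per_well) - 1L) {
      sim <- simulate_field(
        n_cells = n_cells, s = eff$s, params = params,
        seed = field_seed(seed, wi, fi), well_id = wspec$well_id,
        field_index = fi, s_cyto = eff$s_cyto,
        bg_scale = if (is_bg) 1 else params$bg_cellwell_factor,
        noise = noise)
      key <- sprintf("%s_f%d", wspec$well_id, fi)
      if (is.null(dir)) {
        fields[[key]] <- sim$field
      } else {
        write_field(sim$field, file.path(dir, field_file_name(
          wspec$well_id, fi)))
      }
      truths[[key]] <- sim$truth
      rows[[key]] <- data.frame(
        well_id = wspec$well_id, field_index = fi,
        condition = wspec$condition, role = wspec$role,
        s = sim$truth$s, s_cyto = sim$truth$s_cyto,
        n_cells = sim$truth$n_cells, stringsAsFactors = FALSE)
    }
  }
  truth_table <- do.call(rbind, rows)
  rownames(truth_table) <- NULL
  if (!is.null(dir)) {
    utils::write.csv(truth_table, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    save_layout(layout, file.path(dir, "layout.yaml"))
  }
  structure(list(layout = layout, params = params, seed = seed,
                 fields = fields, truths = truths,
                 truth_table = truth_table, dir = dir),
            class = "synth_plate")
}
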