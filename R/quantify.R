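#' Measure every cell of a segmented field
#'
#' The superoxide-reporter channel is background-corrected first, then for
#' each retained cell the reporter signal is summed strictly over the
#' cell's mitochondrial mask — non-specific fluorescence that does not
#' colocalise with the mitochondrial dye is excluded. The mitochondrial
#' channel (left uncorrected by default, as membrane potential is reported
#' in raw RFU) gives the membrane-potential proxy as the mean in-mask
#' intensity, and the mask pixel count gives the mitochondrial area in um^2.
#' A cell with an empty mask yields zeros for all three metrics.
#'
#' @param field A [field_image()].
#' @param seg The [segment_field()] result for this field.
#' @param bg A [background_model] applied to the reporter channel.
#' @param metric `"sum"` (default: per-cell summed reporter signal, the
#'   per-well metric then being a per-cell mean of sums) or `"mean"`
#'   (per-cell mean in-mask intensity).
#' @param correct_mito Also background-correct the mitochondrial channel
#'   before the membrane-potential readout (default `FALSE`).
#' @return Data frame with one row per cell: `well_id`, `field_index`,
#'   `cell_id`, `mros_signal`, `mito_rfu`, `mito_area_um2`, `mask_px`.
#' @export
measure_cells <- function(field, seg, bg = bg_none(),
                          metric = c("sum", "mean"), correct_mito = FALSE) {
  stopifnot(inherits(field, "field_image"),
            inherits(seg, "segmentation_result"))
  metric <- match.arg(metric)
  if (!identical(dim(field$mros_ch), dim(seg$cell_labels)))
    stop("segmentation shape does not match field", call. = FALSE)
  mros <- apply_background(bg, field$mros_ch)
  mito <- if (correct_mito) apply_background(bg, field$mito_ch)
          else field$mito_ch
  n <- seg$n_cells
  out <- data.frame(
    well_id = rep(field$well_id, n),
    field_index = rep(field$field_index, n),
    cell_id = seq_len(n),
    mros_signal = numeric(n), mito_rfu = numeric(n),
    mito_area_um2 = numeric(n), mask_px = integer(n),
    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  px2 <- field$pixel_size_um^2
  for (k in seq_len(n)) {
    idx <- which(seg$mito_labels == k)
    if (length(idx)) {
      out$mros_signal[k] <- if (metric == "sum") sum(mros[idx])
                            else mean(mros[idx])
      out$mito_rfu[k] <- mean(mito[idx])
      out$mito_area_um2[k] <- length(idx) * px2
      out$mask_px[k] <- length(idx)
    }
  }
  out
}

#' Summarise a well from its per-cell measurements
#'
#' The well metric is the per-cell mean: the total reporter signal in the
#' mitochondrial regions across all analysed cells, averaged by the number
#' of cells. Cells from all fields of the well are pooled, so the summary
#' is invariant to how cells are partitioned across fields.
#'
#' @param cells Per-cell data frame from [measure_cells()] (all fields of
#'   one well, row-bound).
#' @return One-row data frame: `well_id`, `mean_mros_per_cell`,
#'   `mean_mito_rfu`, `mean_mito_area_um2`, `n_cells`.
#' @export
summarize_well <- function(cells) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0)
    stop("no cells to summarise (no-cells well must be flagged upstream)",
         call. = FALSE)
  if (length(unique(cells$well_id)) != 1L)
    stop("cells from more than one well", call. = FALSE)
  data.frame(well_id = cells$well_id[1],
             mean_mros_per_cell = mean(cells$mros_signal),
             mean_mito_rfu = mean(cells$mito_rfu),
             mean_mito_area_um2 = mean(cells$mito_area_um2),
             n_cells = nrow(cells), stringsAsFactors = FALSE)
}

#' Percent increase / reduction relative to a control mean
#'
#' Increase is `(x / control - 1) * 100` (so a ratio of 1.477 reports
#' +47.7%); reduction is `(1 - x / control) * 100` (a ratio of 0.6378
#' reports a 36.22% reduction).
#'
#' @param x Condition mean(s).
#' @param control Control mean (non-zero).
#' @return Percent value(s).
#' @export
percent_increase <- function(x, control) {
  if (!is.finite(control) || control == 0)
    stop("control mean is zero: percent-of-control undefined", call. = FALSE)
  (x / control - 1) * 100
}

#' @rdname percent_increase
#' @export
percent_reduction <- function(x, control) -percent_increase(x, control)

#' Aggregate replicate wells into condition summaries
#'
#' Replicate wells of each condition are averaged; sd, sem and well counts
#' are recorded, and every condition's mean reporter signal is expressed as
#' a percent change versus the designated control condition
#' (`percent_vs_control` is 0 for the control itself by construction).
#'
#' @param well_summaries Data frame of [summarize_well()] rows with an added
#'   `condition` column (and optionally `flagged` for no-cells wells, which
#'   are excluded).
#' @param control Control condition label, present with at least one valid
#'   well.
#' @return Data frame with one row per condition.
#' @export
aggregate_condition <- function(well_summaries, control) {
  stopifnot(is.data.frame(well_summaries), "condition" %in%
              colnames(well_summaries))
  ws <- well_summaries
  if ("flagged" %in% names(ws)) ws <- ws[!ws$flagged, ]
  if (!control %in% ws$condition)
    stop("control condition '", control, "' has no valid wells",
         call. = FALSE)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v),
                       sem = stats::sd(v) / sqrt(length(v)))
  conds <- unique(ws$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    g <- ws[ws$condition == cc, ]
    m <- agg(g$mean_mros_per_cell)
    data.frame(condition = cc,
               mean_mros_per_cell = m[["mean"]],
               sd_mros = m[["sd"]], sem_mros = m[["sem"]],
               mean_mito_rfu = mean(g$mean_mito_rfu),
               mean_mito_area_um2 = mean(g$mean_mito_area_um2),
               n_wells = nrow(g), stringsAsFactors = FALSE)
  }))
  ctrl_mean <- out$mean_mros_per_cell[out$condition == control]
  out$percent_vs_control <- percent_increase(out$mean_mros_per_cell,
                                             ctrl_mean)
  out
}

#' Plate-reader normalisation: RFU per microgram protein
#'
#' Subtracts the mean blank (empty-well) fluorescence from each raw reading
#' and divides by the well's protein content, the standard normalisation
#' for microplate-reader superoxide assays.
#'
#' @param records Data frame with columns `well_id`, `raw_rfu`,
#'   `protein_ug` and optionally `condition`.
#' @param blank_wells Well ids of the cell-free blanks among `records`
#'   (their `protein_ug` may be NA), or
#' @param blank_values raw blank readings given directly.
#' @return `records` (blanks removed) with added `blank_mean_rfu` and
#'   `normalized` (= `(raw_rfu - blank_mean_rfu) / protein_ug`, RFU/ug).
#' @export
normalize_platereader <- function(records, blank_wells = NULL,
                                  blank_values = NULL) {
  stopifnot(is.data.frame(records),
            all(c("well_id", "raw_rfu", "protein_ug") %in% names(records)))
  if (is.null(blank_values)) {
    if (is.null(blank_wells) || !length(blank_wells))
      stop("no blank wells designated", call. = FALSE)
    blank_values <- records$raw_rfu[records$well_id %in% blank_wells]
    if (!length(blank_values))
      stop("designated blank wells not found in records", call. = FALSE)
    records <- records[!records$well_id %in% blank_wells, , drop = FALSE]
  }
  blank_mean <- mean(blank_values)
  bad <- !is.finite(records$protein_ug) | records$protein_ug <= 0
  if (any(bad))
    stop("missing or non-positive protein value for well(s): ",
         paste(records$well_id[bad], collapse = ", "), call. = FALSE)
  records$blank_mean_rfu <- blank_mean
  records$normalized <- (records$raw_rfu - blank_mean) / records$protein_ug
  records
}

#' Relative viability versus the vehicle control
#'
#' Condition-mean luminescence as a percentage of the vehicle-control mean
#' (100% = vehicle). A condition at 0.237x vehicle reads 23.7% viability,
#' i.e. a 76.3% reduction.
#'
#' @param records Data frame with columns `condition` and `luminescence`.
#' @param vehicle Vehicle-control condition label.
#' @return Data frame of `condition`, `mean_luminescence`,
#'   `viability_percent`.
#' @export
relative_viability <- function(records, vehicle) {
  stopifnot(is.data.frame(records),
            all(c("condition", "luminescence") %in% names(records)))
  if (!vehicle %in% records$condition)
    stop("vehicle condition '", vehicle, "' absent", call. = FALSE)
  means <- tapply(records$luminescence, records$condition, mean)
  veh <- means[[vehicle]]
  if (!is.finite(veh) || veh <= 0)
    stop("vehicle-control mean must be positive", call. = FALSE)
  data.frame(condition = names(means),
             mean_luminescence = as.numeric(means),
             viability_percent = 100 * as.numeric(means) / veh,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Whole-field reporter total (plate-reader emulation)
#'
#' Sums the uncorrected superoxide-reporter channel over the entire field,
#' emulating the unmasked bulk readout of a fluorescence plate reader
#' (which cannot exclude non-mitochondrial signal).
#'
#' @param field A [field_image()].
#' @return Scalar total intensity.
#' @export
plate_reader_signal <- function(field) {
  stopifnot(inherits(field, "field_image"))
  sum(field$mros_ch)
}
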