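#' Pipeline parameters
#'
#' @param bg_method Background correction for the reporter channel:
#'   `"parabola"` (sliding parabola, the default), `"well"` (fluorescence
#'   minus background well) or `"none"`.
#' @param parabola_curvature Paraboloid steepness for `"parabola"`.
#' @param control_condition Condition used as the percent-of-control
#'   reference; defaults to the layout's `negative_control` condition,
#'   falling back to `vehicle_control`.
#' @param metric Per-cell reporter metric, `"sum"` or `"mean"` (see
#'   [measure_cells()]).
#' @param correct_mito Background-correct the mitochondrial channel too
#'   (default leaves membrane-potential RFU raw).
#' @param segmentation A [segment_params()].
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(bg_method = c("parabola", "well", "none"),
                            parabola_curvature = 0.05,
                            control_condition = NULL,
                            metric = c("sum", "mean"),
                            correct_mito = FALSE,
                            segmentation = segment_params()) {
  bg_method <- match.arg(bg_method)
  metric <- match.arg(metric)
  structure(as.list(environment()), class = "pipeline_params")
}

plate_field_list <- function(images, layout) {
  if (inherits(images, "synth_plate")) {
    if (length(images$fields)) return(images$fields)
    if (!is.null(images$dir)) images <- images$dir
    else stop("synth_plate holds no fields in memory and no directory",
              call. = FALSE)
  }
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    paths <- list.files(images, pattern = "^[A-H][0-9]{2}_f[0-9]+\\.tif$",
                        full.names = TRUE)
    fields <- lapply(paths, read_field,
                     pixel_size_um = layout$pixel_size_um)
    names(fields) <- vapply(fields, function(f)
      sprintf("%s_f%d", f$well_id, f$field_index), "")
    return(fields)
  }
  stop("images must be a synth_plate or a directory of field TIFFs",
       call. = FALSE)
}

default_control <- function(layout) {
  w <- layout$wells
  for (role in c("negative_control", "vehicle_control", "positive_control")) {
    cc <- unique(w$condition[w$role == role])
    if (length(cc)) return(cc[1])
  }
  stop("no control condition in layout; set control_condition", call. = FALSE)
}

#' Run the full quantification pipeline over a plate
#'
#' For every cell-bearing well: segment each field (nuclei, cell regions,
#' mitochondrial masks), background-correct the reporter channel, measure
#' every cell, and summarise per well; replicate wells are then aggregated
#' per condition with percent-of-control normalisation, and each condition
#' is compared against the control with a Student t-test on well means
#' (plus one-way ANOVA with Dunnett comparisons when three or more
#' conditions are present). Wells with zero detected cells are flagged
#' `"no-cells"`, excluded from condition means, and reported with a
#' warning. The run is deterministic given fixed inputs and seed.
#'
#' @param layout A [plate_layout()].
#' @param images A `synth_plate` from [simulate_plate()], or a directory of
#'   `<well>_f<field>.tif` fields.
#' @param params A [pipeline_params()].
#' @param out_dir Optional output directory: writes `per_cell.csv`,
#'   `per_well.csv`, `per_condition.csv`, `stats.json` and `run_log.txt`.
#' @param seed Seed recorded in the log (the analysis itself consumes no
#'   randomness).
#' @return Invisibly, a list of class `pipeline_result`: `per_cell`,
#'   `per_well`, `per_condition`, `stats`, `bg_model`, `params`.
#' @export
run_pipeline <- function(layout, images, params = pipeline_params(),
                         out_dir = NULL, seed = NULL) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(params, "pipeline_params"))
  fields <- plate_field_list(images, layout)
  wells <- layout$wells[!layout$wells$role %in% c("background_well", "empty"), ]
  control <- params$control_condition %||% default_control(layout)

  bg_model <- switch(params$bg_method,
    parabola = bg_parabola(params$parabola_curvature),
    none = bg_none(),
    well = {
      bgw <- background_wells(layout)
      if (!length(bgw))
        stop("no background wells in layout while method = background_well",
             call. = FALSE)
      bgf <- fields[vapply(fields, function(f) f$well_id %in% bgw, TRUE)]
      bg_well(background_well_value(bgf))
    })

  per_cell <- list(); per_well <- list()
  for (wi in seq_len(nrow(wells))) {
    wspec <- wells[wi, ]
    wf <- fields[vapply(fields, function(f)
      identical(f$well_id, wspec$well_id), TRUE)]
    if (!length(wf)) next
    cells <- do.call(rbind, lapply(wf, function(f) {
      seg <- segment_field(f, params$segmentation)
      measure_cells(f, seg, bg = bg_model, metric = params$metric,
                    correct_mito = params$correct_mito)
    }))
    rownames(cells) <- NULL
    if (is.null(cells) || nrow(cells) == 0) {
      warning(sprintf("well %s: no cells detected in any field; flagged",
                      wspec$well_id))
      per_well[[wspec$well_id]] <- data.frame(
        well_id = wspec$well_id, mean_mros_per_cell = NA_real_,
        mean_mito_rfu = NA_real_, mean_mito_area_um2 = NA_real_,
        n_cells = 0L, condition = wspec$condition,
        dose_nM = wspec$dose_nM, flagged = TRUE, stringsAsFactors = FALSE)
      next
    }
    cells$condition <- wspec$condition
    per_cell[[wspec$well_id]] <- cells
    ws <- summarize_well(cells)
    ws$condition <- wspec$condition
    ws$dose_nM <- wspec$dose_nM
    ws$flagged <- FALSE
    per_well[[wspec$well_id]] <- ws
  }
  per_cell <- do.call(rbind, per_cell)
  per_well <- do.call(rbind, per_well)
  rownames(per_cell) <- rownames(per_well) <- NULL
  valid <- per_well[!per_well$flagged, ]
  per_condition <- aggregate_condition(valid, control = control)

  stats_out <- list(control_condition = control,
                    bg_method = params$bg_method)
  conds <- setdiff(unique(valid$condition), control)
  ctrl_vals <- valid$mean_mros_per_cell[valid$condition == control]
  tt <- list()
  for (cc in conds) {
    v <- valid$mean_mros_per_cell[valid$condition == cc]
    if (length(v) >= 2 && length(ctrl_vals) >= 2) {
      r <- group_t_test(v, ctrl_vals)
      tt[[cc]] <- list(test = r$test, statistic = r$statistic, df = r$df,
                       p = r$p, mean_difference = r$mean_difference,
                       ci95 = c(r$ci95_low, r$ci95_high), n = r$n,
                       percent_vs_control = percent_increase(
                         mean(v), mean(ctrl_vals)))
    }
  }
  stats_out$t_tests <- tt
  if (length(unique(valid$condition)) >= 3 &&
      all(table(valid$condition) >= 2)) {
    dn <- anova_dunnett(valid$mean_mros_per_cell, valid$condition, control)
    stats_out$anova <- list(f = dn$f_statistic, df = dn$df,
                            p = dn$p_anova)
    stats_out$dunnett <- dn$comparisons
  }
  dosed <- valid[!is.na(valid$dose_nM), ]
  if (length(unique(dosed$dose_nM)) >= 4) {
    resp <- 100 * dosed$mean_mros_per_cell / mean(ctrl_vals)
    fit <- fit_4pl(dosed$dose_nM, resp)
    stats_out$dose_response <- list(
      ic50_nM = fit$ic50_nM, ic50_se_nM = fit$ic50_se_nM,
      hill_slope = fit$hill_slope, top = fit$top, bottom = fit$bottom,
      converged = fit$converged, flags = fit$flags)
  }

  res <- structure(list(per_cell = per_cell, per_well = per_well,
                        per_condition = per_condition, stats = stats_out,
                        bg_model = bg_model, params = params),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(per_cell, file.path(out_dir, "per_cell.csv"),
                     row.names = FALSE)
    utils::write.csv(per_well, file.path(out_dir, "per_well.csv"),
                     row.names = FALSE)
    utils::write.csv(per_condition, file.path(out_dir, "per_condition.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    log_lines <- c(
      sprintf("mitoscreen %s",
              as.character(utils::packageVersion("mitoscreen"))),
      sprintf("seed: %s", if (is.null(seed)) "none" else seed),
      sprintf("bg_method: %s", params$bg_method),
      sprintf("parabola_curvature: %g", params$parabola_curvature),
      sprintf("metric: %s", params$metric),
      sprintf("control_condition: %s", control),
      sprintf("segmentation: %s", paste(
        names(params$segmentation), unlist(lapply(
          params$segmentation, paste, collapse = ",")),
        sep = "=", collapse = " ")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d cells, %d wells, %d conditions (%s)\n",
              if (is.null(x$per_cell)) 0L else nrow(x$per_cell),
              nrow(x$per_well), nrow(x$per_condition),
              x$stats$bg_method))
  print(x$per_condition, row.names = FALSE)
  invisible(x)
}
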