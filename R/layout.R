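#' Plate layouts
#'
#' A `plate_layout` maps the wells of a 96-well plate to experimental
#' conditions and roles. Each well carries exactly one condition label and a
#' role; wells sharing a condition are replicate wells and are averaged at
#' the condition level (duplicate and triplicate designs are both common).
#' `background_well` wells contain no cells and feed only the
#' fluorescence-minus-background-well correction; `empty` wells are ignored.
#'
#' @param wells A data frame with columns `well_id`, `condition`, `role`, and
#'   optionally `dose_nM` (NA when absent). Roles must be one of
#'   `negative_control`, `positive_control`, `vehicle_control`, `treatment`,
#'   `background_well`, `empty`. Doses (in nM) are only valid on `treatment`
#'   wells, i.e. on drug conditions.
#' @param fields_per_well Number of fields of view imaged per well. Ten is
#'   the package default; twenty is also common in HCS runs.
#' @param pixel_size_um Physical pixel calibration in micrometres per pixel.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(wells, fields_per_well = 10L, pixel_size_um = 0.6) {
  stopifnot(is.data.frame(wells))
  req <- c("well_id", "condition", "role")
  if (!all(req %in% names(wells)))
    stop("wells must have columns well_id, condition, role", call. = FALSE)
  if (!"dose_nM" %in% names(wells)) wells$dose_nM <- NA_real_
  wells <- wells[, c("well_id", "condition", "role", "dose_nM")]
  wells$well_id <- as.character(wells$well_id)
  wells$condition <- as.character(wells$condition)
  wells$role <- as.character(wells$role)
  wells$dose_nM <- as.numeric(wells$dose_nM)

  for (w in wells$well_id) check_well_id(w)
  dup <- wells$well_id[duplicated(wells$well_id)]
  if (length(dup))
    stop("duplicate well assignment: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(wells$role), well_roles())
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  # one condition per well is structural; conditions spanning several roles
  # are almost always layout typos
  tab <- unique(wells[wells$role != "empty", c("condition", "role")])
  if (anyDuplicated(tab$condition))
    stop("a condition maps to more than one role", call. = FALSE)
  has_dose <- !is.na(wells$dose_nM)
  if (any(has_dose & wells$role != "treatment"))
    stop("dose given on a non-drug (non-treatment) condition", call. = FALSE)
  if (any(has_dose & wells$dose_nM <= 0))
    stop("doses must be positive (nM)", call. = FALSE)
  stopifnot(fields_per_well >= 1, pixel_size_um > 0)
  structure(
    list(wells = wells, fields_per_well = as.integer(fields_per_well),
         pixel_size_um = pixel_size_um),
    class = "plate_layout")
}

well_roles <- function() {
  c("negative_control", "positive_control", "vehicle_control",
    "treatment", "background_well", "empty")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("plate_layout: %d wells, %d condition(s), %d field(s)/well\n",
              nrow(x$wells), length(replicate_groups(x)), x$fields_per_well))
  invisible(x)
}

#' Replicate wells per condition
#'
#' @param layout A [plate_layout()].
#' @return Named list mapping each cell-bearing condition to its replicate
#'   well ids (background and empty wells are excluded).
#' @export
replicate_groups <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$wells[!layout$wells$role %in% c("background_well", "empty"), ]
  split(w$well_id, w$condition)
}

#' Wells with the background (empty, cell-free) role
#' @param layout A [plate_layout()].
#' @return Character vector of well ids.
#' @export
background_wells <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  layout$wells$well_id[layout$wells$role == "background_well"]
}

#' Read a plate layout from a YAML config
#'
#' The config has top-level keys `fields_per_well`, `pixel_size_um` and
#' `wells`, the latter a list of `{well, condition, role, dose_nM}` entries.
#'
#' @param path Path to the YAML file.
#' @return A validated [plate_layout()].
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$wells) || !length(cfg$wells))
    stop("layout config has no wells", call. = FALSE)
  wells <- do.call(rbind, lapply(cfg$wells, function(w) {
    data.frame(well_id = w$well %||% w$well_id %||% NA_character_,
               condition = w$condition %||% NA_character_,
               role = w$role %||% "treatment",
               dose_nM = as.numeric(w$dose_nM %||% NA_real_),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(wells$well_id) || anyNA(wells$condition))
    stop("every well entry needs 'well' and 'condition'", call. = FALSE)
  plate_layout(wells,
               fields_per_well = cfg$fields_per_well %||% 10L,
               pixel_size_um = cfg$pixel_size_um %||% 0.6)
}

#' Write a plate layout to a YAML config
#' @param layout A [plate_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  wells <- lapply(seq_len(nrow(layout$wells)), function(i) {
    w <- layout$wells[i, ]
    e <- list(well = w$well_id, condition = w$condition, role = w$role)
    if (!is.na(w$dose_nM)) e$dose_nM <- w$dose_nM
    e
  })
  yaml::write_yaml(list(fields_per_well = layout$fields_per_well,
                        pixel_size_um = layout$pixel_size_um,
                        wells = wells), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled demonstration layout
#'
#' A 28-well drug-screen layout: seven conditions in duplicate (basal
#' negative control, oxLDL positive control, vehicle control, and one drug
#' at a four-point dose series), two cell-free background wells, and twelve
#' declared-empty wells.
#'
#' @param fields_per_well Fields of view per well.
#' @return A [plate_layout()].
#' @export
demo_layout <- function(fields_per_well = 10L) {
  cond <- data.frame(
    condition = c("basal", "oxLDL", "vehicle",
                  "drug_1nM", "drug_10nM", "drug_100nM", "drug_1uM"),
    role = c("negative_control", "positive_control", "vehicle_control",
             rep("treatment", 4)),
    dose_nM = c(NA, NA, NA, 1, 10, 100, 1000),
    stringsAsFactors = FALSE)
  wells <- data.frame(
    well_id = c(sprintf("B%02d", 2:8), sprintf("C%02d", 2:8)),
    condition = rep(cond$condition, 2),
    role = rep(cond$role, 2),
    dose_nM = rep(cond$dose_nM, 2), stringsAsFactors = FALSE)
  bg <- data.frame(well_id = c("D02", "D03"), condition = "background",
                   role = "background_well", dose_nM = NA_real_)
  empty <- data.frame(well_id = sprintf("E%02d", 1:12), condition = "unused",
                      role = "empty", dose_nM = NA_real_)
  plate_layout(rbind(wells, bg, empty), fields_per_well = fields_per_well)
}
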