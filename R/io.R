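#' Write simulated wells as a long-format plate CSV
#'
#' Writes the schema consumed by [read_plate_table()]: columns `time_h`,
#' `well`, `channel` (`OD`/`GFP`), `value`, one row per readout. A sidecar
#' well map (CSV) and, optionally, a YAML file with the generating ground
#' truth can be written alongside.
#'
#' @param sims named list of [simulate_batch()] results; names are well ids.
#' @param path output CSV path.
#' @param map_path optional path for the well-map CSV (`well`, `strain`,
#'   `reporter`).
#' @param strains,reporters optional character vectors (recycled) naming the
#'   strain and reporter of each well for the map.
#' @param truth_path optional path for a YAML sidecar with each well's
#'   generating parameters.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(sims, path, map_path = NULL,
                            strains = NULL, reporters = NULL,
                            truth_path = NULL) {
  stopifnot(is.list(sims), !is.null(names(sims)), all(nzchar(names(sims))))
  long <- purrr::imap(sims, function(s, w) {
    od <- tibble::tibble(time_h = s$time_h, well = w, channel = "OD",
                         value = s$od)
    if (all(is.na(s$gfp)) || is.null(s$gfp)) return(od)
    gfp <- tibble::tibble(time_h = s$time_h, well = w, channel = "GFP",
                          value = s$gfp)
    dplyr::bind_rows(od, gfp)
  })
  readr::write_csv(dplyr::bind_rows(long), path)
  if (!is.null(map_path)) {
    map <- tibble::tibble(
      well = names(sims),
      strain = rep_len(strains %||% names(sims), length(sims)),
      reporter = rep_len(reporters %||% NA_character_, length(sims)))
    readr::write_csv(map, map_path)
  }
  if (!is.null(truth_path)) {
    truth <- purrr::map(sims, function(s) {
      tr <- attr(s, "truth")
      list(genotype = unclass(tr$genotype)[!vapply(unclass(tr$genotype), is.null, TRUE)],
           od0 = tr$od0, glucose0 = tr$glucose0, acetate0 = tr$acetate0)
    })
    yaml::write_yaml(truth, truth_path)
  }
  invisible(path)
}

#' Read a long-format plate-reader table
#'
#' Parses a CSV with columns `time_h`, `well`, `channel` (`OD` and
#' optionally `GFP`) and `value` into one tidy row per well and time point,
#' validating the schema as it goes: missing columns, non-numeric values and
#' duplicated (well, time, channel) readouts raise errors naming the
#' offending rows or wells.
#'
#' @param path CSV path.
#' @param well_map optional data frame (or CSV path) with columns `well` and
#'   `strain` (extra columns such as `reporter` are carried along). When
#'   given, only mapped wells are kept and an unmapped OD-carrying well is
#'   an error.
#' @param calibration scalar applied to raw OD readouts (see
#'   [calibrate_od()]); the default 1 leaves stored values untouched, pass
#'   2.2 for raw plate-reader exports.
#' @return a tibble of class `plate_data`: `well`, `strain`, `time_h`, `od`,
#'   `gfp` (NA when no GFP channel), sorted by well and time.
#' @export
read_plate_table <- function(path, well_map = NULL, calibration = 1) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  needed <- c("time_h", "well", "channel", "value")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_diauxr(paste0("plate table is missing column(s): ",
                       paste(missing_cols, collapse = ", ")),
                "diauxr_parse_error")
  }
  for (col in c("time_h", "value")) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      stop_diauxr(sprintf("non-numeric `%s` at row(s) %s", col,
                          paste(utils::head(bad, 5), collapse = ", ")),
                  "diauxr_parse_error")
    }
  }
  dup <- duplicated(raw[c("well", "time_h", "channel")])
  if (any(dup)) {
    d <- raw[dup, ][1L, ]
    stop_diauxr(sprintf(
      "duplicated readout for well %s, channel %s at time %g h",
      d$well, d$channel, d$time_h), "diauxr_parse_error")
  }

  wide <- raw |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value") |>
    dplyr::arrange(.data$well, .data$time_h)
  if (!"OD" %in% names(wide)) {
    stop_diauxr("no OD channel present in the plate table",
                "diauxr_parse_error")
  }
  if (!"GFP" %in% names(wide)) wide$GFP <- NA_real_

  if (!is.null(well_map)) {
    if (is.character(well_map)) {
      well_map <- readr::read_csv(well_map, show_col_types = FALSE)
    }
    well_map <- tibble::as_tibble(well_map)
    unmapped <- setdiff(unique(wide$well), well_map$well)
    if (length(unmapped) > 0) {
      stop_diauxr(paste0("well(s) not in the well map: ",
                         paste(unmapped, collapse = ", ")),
                  "diauxr_parse_error")
    }
    wide <- dplyr::inner_join(wide, well_map, by = "well")
  } else {
    wide$strain <- wide$well
  }
  out <- wide |>
    dplyr::transmute(.data$well,
                     strain = as.character(.data$strain),
                     .data$time_h,
                     od = .data$OD * calibration,
                     gfp = .data$GFP) |>
    dplyr::bind_cols(wide[setdiff(names(wide),
                                  c("well", "strain", "time_h", "OD", "GFP"))])
  attr(out, "calibration") <- calibration
  class(out) <- c("plate_data", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
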