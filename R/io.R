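#' Slice-table CSV format
#'
#' The canonical on-disk exchange format for traced slice geometry is a
#' UTF-8 CSV with a header row and one row per contour:
#' `run_id, av_distance_mm, flow_ml_min, replicate, offset_mm, zone, polygon,
#' antenna_x, antenna_y, vessel_x, vessel_y, vessel_outer_radius_mm,
#' scale_mm_per_unit`. `zone` is `"WZ"` or `"RZ"`; `polygon` is a JSON array
#' of `[x, y]` millimetre pairs (full double precision, last vertex not
#' repeated). Exactly one WZ row per (run, offset) is required; RZ rows are
#' optional. Coordinates are stored calibrated (mm); `scale_mm_per_unit` is
#' provenance only.
#'
#' @name slice_table_format
NULL

slice_table_cols <- c("run_id", "av_distance_mm", "flow_ml_min", "replicate",
                      "offset_mm", "zone", "polygon", "antenna_x",
                      "antenna_y", "vessel_x", "vessel_y",
                      "vessel_outer_radius_mm", "scale_mm_per_unit")

#' Write a slice table to CSV
#'
#' @param slices A slice table tibble (list-column `polygon`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [slice_table_format], [read_slice_table()]
#' @export
write_slice_table <- function(slices, path) {
  missing_cols <- setdiff(setdiff(slice_table_cols, "polygon"), names(slices))
  if (length(missing_cols) > 0) {
    stop_data(paste0("slice table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  df <- slices
  df$polygon <- vapply(df$polygon, function(p) {
    as.character(jsonlite::toJSON(as_polygon(p, check_simple = FALSE),
                                  digits = I(17)))
  }, character(1))
  df <- df[order(df$run_id, df$offset_mm, df$zone), slice_table_cols]
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a slice table from CSV
#'
#' Reads and validates the [slice_table_format]: schema, parsable polygons
#' with at least 3 finite vertices, no duplicate (run, offset, zone), and a
#' white-zone contour for every (run, offset). Violations are reported with
#' the offending row or run.
#'
#' @param path Path to a slice-table CSV.
#' @return A slice table tibble sorted by run and offset, with `polygon` as
#'   a list of vertex matrices.
#' @export
read_slice_table <- function(path) {
  if (!file.exists(path)) stop_load(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    run_id = readr::col_character(),
    av_distance_mm = readr::col_double(),
    flow_ml_min = readr::col_double(),
    replicate = readr::col_integer(),
    offset_mm = readr::col_double(),
    zone = readr::col_character(),
    polygon = readr::col_character(),
    antenna_x = readr::col_double(),
    antenna_y = readr::col_double(),
    vessel_x = readr::col_double(),
    vessel_y = readr::col_double(),
    vessel_outer_radius_mm = readr::col_double(),
    scale_mm_per_unit = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(slice_table_cols, names(df))
  if (length(missing_cols) > 0) {
    stop_load(paste0("slice table CSV is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  if (!all(df$zone %in% c("WZ", "RZ"))) {
    bad <- which(!df$zone %in% c("WZ", "RZ"))[1]
    stop_load(sprintf("row %d: zone must be \"WZ\" or \"RZ\" (got \"%s\")",
                      bad, df$zone[bad]))
  }
  df$polygon <- purrr::imap(df$polygon, function(txt, i) {
    p <- tryCatch(jsonlite::fromJSON(txt),
                  error = function(e) NULL)
    if (is.null(p) || !is.matrix(p) || ncol(p) != 2 || nrow(p) < 3 ||
        any(!is.finite(p))) {
      stop_load(sprintf(
        "row %d: polygon does not parse to >= 3 finite [x, y] pairs", i))
    }
    unname(p)
  })
  key <- paste(df$run_id, df$offset_mm, df$zone)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop_load(sprintf("row %d: duplicate (run, offset, zone) = (%s, %g, %s)",
                      d, df$run_id[d], df$offset_mm[d], df$zone[d]))
  }
  # every (run, offset) needs a WZ contour
  all_key <- unique(df[, c("run_id", "offset_mm")])
  wz_key <- df[df$zone == "WZ", c("run_id", "offset_mm")]
  miss <- dplyr::anti_join(all_key, wz_key,
                           by = c("run_id", "offset_mm"))
  if (nrow(miss) > 0) {
    stop_load(sprintf("missing WZ contour for run %s at offset %g mm",
                      miss$run_id[1], miss$offset_mm[1]))
  }
  dplyr::arrange(df, .data$run_id, .data$offset_mm, .data$zone)
}

#' Write per-run reports to CSV or JSON
#'
#' Serializes a [stack_reports()] table (or any per-run report tibble)
#' deterministically: fixed column order, rows sorted by distance, flow and
#' replicate, floats at 6 significant digits, and the cooling portion
#' additionally as an integer percent column for tabulation.
#'
#' @param reports A report tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as_tibble(reports)
  ord <- intersect(c("av_distance_mm", "flow_ml_min", "replicate"), names(df))
  if (length(ord) > 0) {
    df <- dplyr::arrange(df, dplyr::across(dplyr::all_of(ord)))
  }
  if ("cooling_portion_pct" %in% names(df)) {
    df$cooling_portion_int <- as.integer(round(df$cooling_portion_pct))
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(df, path)
    } else {
      jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_load(paste0("cannot write reports to ", path))
  invisible(path)
}
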