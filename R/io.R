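# Tabular and volume I/O. CSV tables are comma-separated UTF-8 with a
# mandatory header row; numeric fields are serialized at full double
# precision (%.17g) so write -> read round trips are lossless.

MEASUREMENT_COLS <- c("eye_id", "location", "ascan_index",
                      "elm_peak_intensity", "subband_peak_intensity",
                      "ratio_pct", "axial_offset_um", "used_fallback",
                      "shadow_substituted", "unreliable", "status")

GRADING_COLS <- c("eye_id", "location", "auto_call", "majority_call",
                  "adjudicated")

csv_write_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

check_schema <- function(df, required, what, validate = list()) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s table: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")))
  for (col in names(validate)) {
    bad <- which(!validate[[col]](df[[col]]))
    if (length(bad))
      stop(sprintf("%s table: invalid values in column '%s' at row(s) %s",
                   what, col,
                   paste(utils::head(bad, 10), collapse = ", ")))
  }
  invisible(df)
}

#' Write / read a measurement table
#'
#' One row per eye x location with every A-scan measurement field. Reading
#' validates the schema and reports offending rows.
#'
#' @param measurements Data frame of measurements.
#' @param path CSV file path.
#' @return `write_measurements`: the path, invisibly; `read_measurements`:
#'   the validated data frame.
#' @export
write_measurements <- function(measurements, path) {
  check_schema(measurements, MEASUREMENT_COLS, "measurement")
  csv_write_precise(measurements[, MEASUREMENT_COLS], path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, MEASUREMENT_COLS, "measurement", validate = list(
    ratio_pct = function(x) is.na(x) | x >= 0,
    location = function(x) x %in% LOCATIONS))
  df
}

#' Write / read a grading table
#'
#' One row per eye x location with the proxy call, individual grader calls
#' (columns `grader1`, `grader2`, ...), the majority call and the
#' adjudication flag.
#'
#' @param gradings Data frame of gradings.
#' @param path CSV file path.
#' @return `write_gradings`: the path, invisibly; `read_gradings`: the
#'   validated data frame.
#' @export
write_gradings <- function(gradings, path) {
  check_schema(gradings, GRADING_COLS, "grading")
  csv_write_precise(gradings, path)
}

#' @rdname write_gradings
#' @export
read_gradings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, GRADING_COLS, "grading", validate = list(
    majority_call = function(x) x %in% c("visible", "not_visible"),
    location = function(x) x %in% LOCATIONS))
  df
}

#' Read a small tabular input (contingency or measurement table) from CSV
#'
#' @param path CSV file path; first column is used as row names when
#'   non-numeric and `rownames = TRUE`.
#' @param rownames Treat the first column as row labels?
#' @return A data frame (or numeric matrix when all cells are numeric).
#' @export
read_table_csv <- function(path, rownames = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (rownames) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    m <- as.matrix(df)
    rownames(m) <- rn
    return(m)
  }
  df
}

#' Write / read an OCT volume as TIFF stack plus JSON sidecar
#'
#' The volume is stored as a multi-page 32-bit float TIFF (one page per
#' B-scan, depth rows x A-scan columns) with grid metadata, the Bruch's
#' reference row and truth annotations in `<prefix>.json`.
#'
#' @param volume An `oct_volume`.
#' @param prefix Path prefix; `<prefix>.tif` and `<prefix>.json` are
#'   written.
#' @return `write_volume`: the prefix, invisibly; `read_volume`: an
#'   `oct_volume` (intensities quantized to float32 by the file format).
#' @export
write_volume <- function(volume, prefix) {
  pages <- lapply(seq_len(volume$grid$n_ascans_y),
                  function(j) volume_bscan(volume, j))
  write_tiff_f32(pages, paste0(prefix, ".tif"))
  ph <- volume$phenotype
  phm <- NULL
  if (!is.null(ph)) {
    phm <- unclass(ph)
    # jsonlite drops names on atomic vectors; keep the location map as an
    # object
    phm$subband_rel_reflectivity <- as.list(ph$subband_rel_reflectivity)
  }
  meta <- list(
    grid = unclass(volume$grid), brm_row = volume$brm_row,
    flattened = volume$flattened, seed = volume$seed, phenotype = phm)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_volume
#' @export
read_volume <- function(prefix) {
  pages <- read_tiff_f32(paste0(prefix, ".tif"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  g <- meta$grid
  grid <- grid_spec(as.numeric(g$axial_pixel_um),
                    as.numeric(g$transverse_pixel_um),
                    g$n_ascans_x, g$n_ascans_y, g$n_depth_px)
  vol <- array(0, dim = c(grid$n_depth_px, grid$n_ascans_x,
                          grid$n_ascans_y))
  for (j in seq_along(pages)) vol[, , j] <- pages[[j]]
  ph <- NULL
  if (!is.null(meta$phenotype)) {
    p <- meta$phenotype
    ph <- eye_phenotype(p$eye_id, p$age_years, p$laterality,
                        stats::setNames(unlist(p$subband_rel_reflectivity),
                                        names(p$subband_rel_reflectivity)),
                        elm_subband_offset_um = p$elm_subband_offset_um,
                        has_dm = p$has_dm,
                        shadow_positions_mm =
                          as.numeric(unlist(p$shadow_positions_mm)))
  }
  v <- list(data = vol, grid = grid, brm_row = meta$brm_row,
            phenotype = ph, fovea_truth = NULL,
            flattened = isTRUE(meta$flattened), seed = meta$seed)
  class(v) <- "oct_volume"
  v
}

#' Write a display image as a plain-text PGM panel
#'
#' Grading panels are written as ASCII PGM (P2), a text format writable
#' without external graphics libraries.
#'
#' @param display A `display_image` (or numeric matrix in \[0, 1\]).
#' @param path Output path (conventionally `.pgm`).
#' @param maxval Gray levels - 1.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(display, path, maxval = 255L) {
  px <- if (inherits(display, "display_image")) display$pixels else display
  q <- round(pmin(pmax(px, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxval)), con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
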