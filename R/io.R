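# File interchange: voltage maps and voxel stacks as multi-page TIFF with a
# JSON sidecar, ECG traces and localization / membrane tables as CSV, and
# ground-truth records as JSON.

#' Write / read a voltage map as multi-page TIFF + JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages, min-max scaled to `[0, 1]`;
#' the sidecar records the scaling together with `frame_interval_ms`,
#' `pixel_size_um` and `polarity`, so reading restores the original values
#' to 32-bit float precision.
#'
#' @param map a [voltage_map()].
#' @param tif_path,json_path output paths (default: `tif_path` with
#'   extension swapped to `.json`).
#' @return `read_voltage_map` returns a [voltage_map()].
#' @export
write_voltage_map <- function(map, tif_path, json_path = sub("\\.tiff?$", ".json", tif_path)) {
  stopifnot(inherits(map, "voltage_map"))
  rng <- range(map$data)
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(map$data)[1L]), function(i)
    (map$data[i, , ] - rng[1L]) / span)
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 32L)
  jsonlite::write_json(list(frame_interval_ms = map$frame_interval_ms,
                            pixel_size_um = map$pixel_size_um,
                            polarity = map$polarity,
                            scale_min = rng[1L], scale_span = span,
                            n_frames = dim(map$data)[1L]),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' @rdname write_voltage_map
#' @export
read_voltage_map <- function(tif_path, json_path = sub("\\.tiff?$", ".json", tif_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  arr <- array(0, c(length(pages), dim(pages[[1L]])))
  for (i in seq_along(pages))
    arr[i, , ] <- pages[[i]] * meta$scale_span + meta$scale_min
  voltage_map(arr, as.numeric(meta$frame_interval_ms),
              as.numeric(meta$pixel_size_um), as.numeric(meta$polarity))
}

#' Write / read an ECG trace as CSV + JSON sidecar
#'
#' Two-column CSV (`time_s`, `mv`); the sidecar carries the sampling rate
#' and annotations.
#'
#' @param trace an [ecg_trace()].
#' @param csv_path,json_path file paths.
#' @return `read_ecg_trace` returns an [ecg_trace()].
#' @export
write_ecg_trace <- function(trace, csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(trace, "ecg_trace"))
  df <- data.frame(time_s = (seq_along(trace$samples) - 1L) / trace$sampling_hz,
                   mv = trace$samples)
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(c(list(sampling_hz = trace$sampling_hz), trace$annotations),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_ecg_trace
#' @export
read_ecg_trace <- function(csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  df <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  ecg_trace(df$mv, as.numeric(meta$sampling_hz),
            meta[setdiff(names(meta), "sampling_hz")])
}

#' Write / read a localization table as CSV
#'
#' Header: `x_nm,y_nm,z_nm,channel,precision_xy_nm,precision_z_nm`.
#'
#' @param table a [localization_table()].
#' @param path CSV path.
#' @return `read_localizations` returns a [localization_table()].
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "localization_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_nm", "y_nm", "z_nm", "channel", "precision_xy_nm", "precision_z_nm")
  if (!all(need %in% names(df)))
    stopf("localization CSV must have columns: %s", paste(need, collapse = ","))
  localization_table(df$x_nm, df$y_nm, df$z_nm, df$channel,
                     df$precision_xy_nm, df$precision_z_nm)
}

#' Write / read membrane trace pairs as CSV
#'
#' Columns: `trace_id,vertex_index,x_nm,y_nm` with `trace_id` "A" or "B".
#'
#' @param pair a [membrane_pair()].
#' @param path CSV path.
#' @param site site label on reading.
#' @return `read_membrane_pair` returns a [membrane_pair()].
#' @export
write_membrane_pair <- function(pair, path) {
  stopifnot(inherits(pair, "membrane_pair"))
  df <- rbind(data.frame(trace_id = "A", vertex_index = seq_len(nrow(pair$trace_a)),
                         x_nm = pair$trace_a[, 1L], y_nm = pair$trace_a[, 2L]),
              data.frame(trace_id = "B", vertex_index = seq_len(nrow(pair$trace_b)),
                         x_nm = pair$trace_b[, 1L], y_nm = pair$trace_b[, 2L]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_membrane_pair
#' @export
read_membrane_pair <- function(path, site = "GJ-adjacent") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  a <- df[df$trace_id == "A", ]; b <- df[df$trace_id == "B", ]
  a <- a[order(a$vertex_index), ]; b <- b[order(b$vertex_index), ]
  membrane_pair(cbind(a$x_nm, a$y_nm), cbind(b$x_nm, b$y_nm), site)
}

#' Write / read a ground-truth record as JSON
#'
#' Numeric values are serialized at full double precision (17 significant
#' digits), so generator truths round-trip without loss.
#'
#' @param truth a `ground_truth` object from a generator.
#' @param path JSON path.
#' @return `read_ground_truth` returns the truth as a list (classes of
#'   nested presets are recorded and restored).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- unclass(truth)
  if (!is.null(payload$preset)) {
    payload$preset_class <- class(payload$preset)[1L]
    payload$preset <- unclass(payload$preset)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$preset_class)) {
    class(x$preset) <- x$preset_class
    x$preset_class <- NULL
  }
  class(x) <- "ground_truth"
  x
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> module %s, seed %s\n", x$module, x$seed))
  invisible(x)
}
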