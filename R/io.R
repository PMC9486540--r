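#' Write / read an imaging field as multi-page TIFF with a JSON sidecar
#'
#' One 16-bit TIFF page per channel plus a `<name>.json` sidecar holding
#' the channel order, marker role, arm, well id and the intensity scale
#' used for 16-bit packing, so the round trip recovers intensities to the
#' packing resolution.
#'
#' @param field An `image_field`.
#' @param path Output path (`.tif`); the sidecar goes to `<path>.json`.
#' @return `write_field_tiff` returns `path` invisibly;
#'   `read_field_tiff` returns an `image_field`.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "image_field"))
  scale <- max(1, max(vapply(field$channels, max, numeric(1))))
  pages <- lapply(field$channels, function(ch) pmin(ch / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  sidecar <- list(
    channels = names(field$channels),
    marker_role = field$marker_role,
    arm = field$arm,
    well_id = field$well_id,
    intensity_scale = scale,
    config_hash = field$config_hash %||% NA_character_
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) p * sidecar$intensity_scale)
  names(channels) <- sidecar$channels
  structure(
    list(channels = channels, marker_role = sidecar$marker_role,
         pixel_size = NA_real_,
         well_id = sidecar$well_id %||% NA_character_,
         arm = sidecar$arm, config_hash = sidecar$config_hash %||% NA_character_),
    class = "image_field"
  )
}

#' Validate a plate map
#'
#' Checks the experiment layout: required columns, arms drawn from the
#' fixed vocabulary, a marker role per well, and at least one NHS-only
#' control well per plate (without which the fold-change normalization is
#' undefined). Violations are reported with the offending rows or plates.
#'
#' @param plate_map Data frame with columns `well_id`, `patient_id`,
#'   `arm`, `plate_id`, `marker_role` (`"MAC"` or `"IgG"`).
#' @return The plate map as a tibble, invisibly, if valid; otherwise an
#'   error.
#' @export
validate_plate_map <- function(plate_map) {
  pm <- as_tibble(plate_map)
  required <- c("well_id", "patient_id", "arm", "plate_id", "marker_role")
  missing_cols <- setdiff(required, names(pm))
  if (length(missing_cols)) {
    abort(paste0("plate map is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!pm$arm %in% ARM_LEVELS)
  if (length(bad)) {
    abort(paste0("plate map row(s) ", paste(head(bad, 5), collapse = ", "),
                 ": unknown arm ", paste(unique(pm$arm[bad]), collapse = ", ")))
  }
  bad <- which(!pm$marker_role %in% c("MAC", "IgG"))
  if (length(bad)) {
    abort(paste0("plate map row(s) ", paste(head(bad, 5), collapse = ", "),
                 ": marker_role must be MAC or IgG"))
  }
  plates <- unique(pm$plate_id)
  has_ctrl <- vapply(plates, function(p) {
    any(pm$arm[pm$plate_id == p] == "NHS_only")
  }, logical(1))
  if (!all(has_ctrl)) {
    abort(paste0("plate(s) without an NHS_only control well: ",
                 paste(plates[!has_ctrl], collapse = ", ")))
  }
  invisible(pm)
}
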