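#' Write protected areas to GeoJSON
#'
#' Serializes a rectangular protected-area set as a GeoJSON FeatureCollection
#' of Polygon features with `id`, `area_km2` and `category` properties.
#' Coordinates are the package's planar nominal-km frame (no CRS member is
#' written).
#'
#' @param pas Tibble from [simulate_protected_areas()] (or with the same
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protected_areas_geojson <- function(pas, path) {
  features <- purrr::pmap(pas, function(pa_id, xmin, xmax, ymin, ymax, area_km2, category, ...) {
    ring <- list(
      c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax), c(xmin, ymin)
    )
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(id = pa_id, area_km2 = area_km2, category = category)
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read protected areas from GeoJSON
#'
#' Reads a FeatureCollection written by [write_protected_areas_geojson()]
#' (or any collection of axis-aligned rectangular Polygons with `id`,
#' `area_km2`, `category` properties) back into the tabular form the overlay
#' functions consume. Non-rectangular rings are rejected.
#'
#' @param path GeoJSON file path.
#' @return A `protected_areas` tibble.
#' @export
read_protected_areas_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) abort("not a GeoJSON FeatureCollection")
  rows <- purrr::map_dfr(fc$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) abort("only Polygon features are supported")
    ring <- f$geometry$coordinates[[1]]
    xs <- purrr::map_dbl(ring, 1)
    ys <- purrr::map_dbl(ring, 2)
    ux <- sort(unique(xs))
    uy <- sort(unique(ys))
    if (length(ux) != 2 || length(uy) != 2) {
      abort(sprintf("feature '%s' is not an axis-aligned rectangle", f$properties$id))
    }
    tibble::tibble(
      pa_id = as.character(f$properties$id),
      xmin = ux[1], xmax = ux[2], ymin = uy[1], ymax = uy[2],
      area_km2 = as.numeric(f$properties$area_km2 %||% ((ux[2] - ux[1]) * (uy[2] - uy[1]))),
      category = as.character(f$properties$category %||% NA_character_)
    )
  })
  class(rows) <- c("protected_areas", class(rows))
  rows
}

#' Write all landscape layers to disk
#'
#' Persists a [simulate_landscape()] object as plain-text files:
#' `occurrences.csv` (species_id, cell_id, presence), `climate.csv` (long
#' format), `soil.csv`, `species.csv` (niche truth table),
#' `regions.csv` (cell_id, province_id, region_id) and
#' `protected_areas.geojson`.
#'
#' @param land A `synthetic_landscape` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(land, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(land$occurrences, file.path(dir, "occurrences.csv"))
  readr::write_csv(land$climate, file.path(dir, "climate.csv"))
  readr::write_csv(land$soil, file.path(dir, "soil.csv"))
  readr::write_csv(land$species, file.path(dir, "species.csv"))
  readr::write_csv(land$regions, file.path(dir, "regions.csv"))
  write_protected_areas_geojson(land$protected_areas, file.path(dir, "protected_areas.geojson"))
  invisible(dir)
}
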