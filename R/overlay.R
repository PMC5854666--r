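#' Cells covered by protected-area footprints
#'
#' Resolves each protected-area rectangle to the set of grid cells it
#' intersects with positive area. Boundary touching (zero-area intersection)
#' does not count, and the half-open cell convention means no cell is
#' assigned twice. A footprint entirely outside the extent yields no rows
#' and a warning.
#'
#' @param pas `protected_areas` tibble (columns `pa_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax`).
#' @param grid A [make_grid()] grid.
#' @return Tibble `pa_id`, `cell_id`, one row per covered cell, plus a
#'   `single_cell` flag column (TRUE when the footprint lies in one cell).
#' @export
covering_cells <- function(pas, grid) {
  m <- grid_meta(grid)
  W <- m$n_cols * m$cell_size
  H <- m$n_rows * m$cell_size
  out <- purrr::pmap_dfr(
    dplyr::select(pas, "pa_id", "xmin", "xmax", "ymin", "ymax"),
    function(pa_id, xmin, xmax, ymin, ymax) {
      c0 <- max(0L, floor((xmin - m$origin[1]) / m$cell_size))
      c1 <- min(m$n_cols - 1L, ceiling((xmax - m$origin[1]) / m$cell_size) - 1L)
      b0 <- max(0L, floor((ymin - m$origin[2]) / m$cell_size))
      b1 <- min(m$n_rows - 1L, ceiling((ymax - m$origin[2]) / m$cell_size) - 1L)
      if (c0 > c1 || b0 > b1 || xmax <= m$origin[1] || xmin >= m$origin[1] + W ||
        ymax <= m$origin[2] || ymin >= m$origin[2] + H) {
        warn(sprintf("protected area %s lies outside the grid extent", pa_id))
        return(NULL)
      }
      # positive-area overlap only: drop cells touched along an edge
      cols <- c0:c1
      cols <- cols[m$origin[1] + cols * m$cell_size < xmax &
        m$origin[1] + (cols + 1) * m$cell_size > xmin]
      bots <- b0:b1
      bots <- bots[m$origin[2] + bots * m$cell_size < ymax &
        m$origin[2] + (bots + 1) * m$cell_size > ymin]
      rows <- m$n_rows - 1L - bots
      grid_ids <- as.vector(outer(rows * m$n_cols, cols, `+`))
      tibble::tibble(pa_id = pa_id, cell_id = as.integer(sort(grid_ids)))
    }
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(
      pa_id = character(), cell_id = integer(), single_cell = logical()
    ))
  }
  out |>
    dplyr::group_by(.data$pa_id) |>
    dplyr::mutate(single_cell = dplyr::n() == 1) |>
    dplyr::ungroup()
}

# Exact area of the union of axis-aligned rectangles, by coordinate
# compression: sweep the unique x-breaks and accumulate, per vertical slab,
# the union length of the active y-intervals.
rect_union_area <- function(rects) {
  if (nrow(rects) == 0) return(0)
  rects <- rects[rects$xmax > rects$xmin & rects$ymax > rects$ymin, , drop = FALSE]
  if (nrow(rects) == 0) return(0)
  xs <- sort(unique(c(rects$xmin, rects$xmax)))
  total <- 0
  for (i in seq_len(length(xs) - 1)) {
    x0 <- xs[i]
    x1 <- xs[i + 1]
    act <- rects[rects$xmin <= x0 & rects$xmax >= x1, , drop = FALSE]
    if (nrow(act) == 0) next
    iv <- act[order(act$ymin), c("ymin", "ymax")]
    len <- 0
    cur_lo <- iv$ymin[1]
    cur_hi <- iv$ymax[1]
    if (nrow(iv) > 1) {
      for (j in 2:nrow(iv)) {
        if (iv$ymin[j] > cur_hi) {
          len <- len + (cur_hi - cur_lo)
          cur_lo <- iv$ymin[j]
          cur_hi <- iv$ymax[j]
        } else {
          cur_hi <- max(cur_hi, iv$ymax[j])
        }
      }
    }
    len <- len + (cur_hi - cur_lo)
    total <- total + len * (x1 - x0)
  }
  total
}

#' Protected land area per grid cell
#'
#' For every cell, the area of the geometric union of all protected-area
#' footprints clipped to that cell — overlapping protected areas are counted
#' once. This is the weighting layer behind "proportion of total protected
#' land area" statistics.
#'
#' @param pas `protected_areas` tibble.
#' @param grid A [make_grid()] grid.
#' @return Tibble `cell_id`, `protected_km2` (one row per grid cell,
#'   zero-filled), with `protected_km2` in `[0, cell_size^2]`.
#' @export
protected_land_per_cell <- function(pas, grid) {
  m <- grid_meta(grid)
  cov <- suppressWarnings(covering_cells(pas, grid))
  by_cell <- split(cov$pa_id, cov$cell_id)
  prot <- purrr::imap_dbl(by_cell, function(ids, cid) {
    cell <- grid[grid$cell_id == as.integer(cid), ]
    r <- pas[pas$pa_id %in% ids, c("xmin", "xmax", "ymin", "ymax")]
    clipped <- tibble::tibble(
      xmin = pmax(r$xmin, cell$xmin), xmax = pmin(r$xmax, cell$xmax),
      ymin = pmax(r$ymin, cell$ymin), ymax = pmin(r$ymax, cell$ymax)
    )
    rect_union_area(clipped)
  })
  tibble::tibble(cell_id = grid$cell_id) |>
    dplyr::left_join(
      tibble::tibble(cell_id = as.integer(names(by_cell)), protected_km2 = unname(prot)),
      by = "cell_id"
    ) |>
    dplyr::mutate(protected_km2 = tidyr::replace_na(.data$protected_km2, 0))
}

#' Per-protected-area species pools and gain/loss counts
#'
#' Pools the binary species maps over each protected area's covering cells
#' (the cell-aligned aggregation of its footprint: a species counts as
#' present in the polygon if it is present in at least one covering cell),
#' then derives per-PA gain `G` (species entering the pool in the future
#' period), loss `L` (species leaving it), and the per-period richnesses.
#' For a single-cell protected area this reduces exactly to that cell's
#' values.
#'
#' @param overlay Tibble from [covering_cells()].
#' @param maps Binary maps (`species_id`, `cell_id`, `period`, `presence`).
#' @return Tibble `pa_id`, `n_cells`, `refSR`, `futureSR`, `G`, `L`.
#' @export
aggregate_cell_values <- function(overlay, maps) {
  pres <- dplyr::filter(maps, .data$presence == 1)
  pools <- overlay |>
    dplyr::inner_join(pres, by = "cell_id", relationship = "many-to-many") |>
    dplyr::distinct(.data$pa_id, .data$species_id, .data$period)
  wide <- pools |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(
      names_from = "period", values_from = "present", values_fill = FALSE
    )
  if (!"reference" %in% names(wide)) wide$reference <- FALSE
  if (!"future" %in% names(wide)) wide$future <- FALSE
  counts <- wide |>
    dplyr::group_by(.data$pa_id) |>
    dplyr::summarise(
      refSR = sum(.data$reference),
      futureSR = sum(.data$future),
      G = sum(.data$future & !.data$reference),
      L = sum(.data$reference & !.data$future),
      .groups = "drop"
    )
  overlay |>
    dplyr::distinct(.data$pa_id) |>
    dplyr::left_join(dplyr::count(overlay, .data$pa_id, name = "n_cells"), by = "pa_id") |>
    dplyr::left_join(counts, by = "pa_id") |>
    dplyr::mutate(dplyr::across(
      c("refSR", "futureSR", "G", "L"),
      ~ tidyr::replace_na(as.integer(.x), 0L)
    ))
}
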