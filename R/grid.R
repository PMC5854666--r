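#' Build a regular landscape grid
#'
#' Creates the square-cell grid that is the spatial frame for every layer in
#' the analysis (climate, suitability, binary presence, protected land).
#' Cells are axis-aligned, non-overlapping squares tiling the extent exactly.
#' Cell ids are 0-based and row-major: cell id = row * n_cols + col, with
#' row 0 the northernmost band (row index increases southward) and col 0 the
#' westernmost column. Cell boundaries are half-open (`[min, max)` on both
#' axes) so a point on a shared edge belongs to exactly one cell.
#'
#' @param n_rows,n_cols Number of rows / columns (positive integers).
#' @param cell_size Side length of each square cell, in nominal km.
#' @param origin Planar coordinates of the south-west corner of the extent.
#' @return A tibble with class `landscape_grid`, one row per cell, columns
#'   `cell_id`, `row`, `col`, `xmin`, `xmax`, `ymin`, `ymax`, `x`, `y`
#'   (cell centres), plus attributes `n_rows`, `n_cols`, `cell_size`,
#'   `origin`.
#' @examples
#' g <- make_grid(10, 12, 20)
#' nrow(g) # 120
#' @export
make_grid <- function(n_rows, n_cols, cell_size = 20, origin = c(0, 0)) {
  stopifnot_scalar_count(n_rows, "n_rows")
  stopifnot_scalar_count(n_cols, "n_cols")
  if (length(cell_size) != 1 || is.na(cell_size) || cell_size <= 0) {
    abort("`cell_size` must be a single positive number")
  }
  cell_id <- seq_len(n_rows * n_cols) - 1L
  row <- cell_id %/% n_cols
  col <- cell_id %% n_cols
  xmin <- origin[1] + col * cell_size
  # row 0 is the northern edge: its ymin sits at the top of the extent
  ymin <- origin[2] + (n_rows - 1L - row) * cell_size
  g <- tibble::tibble(
    cell_id = cell_id, row = row, col = col,
    xmin = xmin, xmax = xmin + cell_size,
    ymin = ymin, ymax = ymin + cell_size,
    x = xmin + cell_size / 2, y = ymin + cell_size / 2
  )
  structure(
    g,
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size = cell_size, origin = origin,
    class = c("landscape_grid", class(g))
  )
}

grid_meta <- function(grid) {
  list(
    n_rows = attr(grid, "n_rows"), n_cols = attr(grid, "n_cols"),
    cell_size = attr(grid, "cell_size"), origin = attr(grid, "origin")
  )
}

#' Locate points on the grid
#'
#' Maps planar coordinates to cell ids under the half-open boundary rule:
#' a point on the shared edge of two cells belongs to the cell for which it
#' is the lower (west / south) boundary, so every in-extent point is assigned
#' to exactly one cell.
#'
#' @param grid A [make_grid()] grid.
#' @param x,y Coordinate vectors of equal length.
#' @return Integer cell ids; `NA` for points outside the extent.
#' @export
point_to_cell <- function(grid, x, y) {
  m <- grid_meta(grid)
  col <- floor((x - m$origin[1]) / m$cell_size)
  row_from_bottom <- floor((y - m$origin[2]) / m$cell_size)
  row <- m$n_rows - 1 - row_from_bottom
  id <- row * m$n_cols + col
  bad <- col < 0 | col >= m$n_cols | row < 0 | row >= m$n_rows
  id[bad] <- NA_integer_
  as.integer(id)
}
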