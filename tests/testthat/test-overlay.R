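test_that("covering cells match the spec'd small cases", {
  g <- make_grid(5, 5, 10) # cell 17 = row 3, col 2 -> x [20,30), y [10,20)
  inside <- rect_pa("a", 22, 28, 12, 18)
  cov <- covering_cells(inside, g)
  expect_equal(cov$cell_id, 17L)
  expect_true(cov$single_cell)
  # rectangle with positive area in cells 3 and 4 (row 0: y in [40, 50))
  span <- rect_pa("b", 35, 45, 41, 49)
  expect_setequal(covering_cells(span, g)$cell_id, c(3L, 4L))
  # boundary touching with zero area does not count: rect ends exactly at x = 40
  touch <- rect_pa("c", 35, 40, 41, 49)
  expect_equal(covering_cells(touch, g)$cell_id, 3L)
})

test_that("covering cells equal the exhaustive oracle on random geometries", {
  g <- make_grid(20, 30, 7) # 600 cells
  withr::with_seed(19, {
    for (i in 1:40) {
      x0 <- runif(1, -10, 30 * 7)
      y0 <- runif(1, -10, 20 * 7)
      pa <- rect_pa(paste0("r", i), x0, x0 + runif(1, 0.5, 80), y0, y0 + runif(1, 0.5, 80))
      got <- suppressWarnings(covering_cells(pa, g))$cell_id
      expect_equal(sort(got), covering_cells_oracle(pa, g), info = paste("case", i))
    }
  })
})

test_that("a footprint outside the extent yields no cells and a warning", {
  g <- make_grid(5, 5, 10)
  out <- rect_pa("far", 100, 120, 100, 120)
  expect_warning(cov <- covering_cells(out, g), "outside")
  expect_equal(nrow(cov), 0)
})

test_that("pooled per-PA values reduce to the cell values for single-cell PAs", {
  maps <- maps_from_list(list(
    reference = list(spA = c(1L, 5L), spB = 5L),
    future = list(spA = 5L, spC = c(1L, 5L))
  ))
  overlay <- tibble::tibble(pa_id = "p1", cell_id = 5L, single_cell = TRUE)
  agg <- aggregate_cell_values(overlay, maps)
  # cell 5: ref {A,B}, fut {A,C}
  expect_equal(agg$refSR, 2L)
  expect_equal(agg$futureSR, 2L)
  expect_equal(agg$G, 1L)
  expect_equal(agg$L, 1L)
})

test_that("two-cell pooling uses union species pools", {
  maps <- maps_from_list(list(
    reference = list(spA = 1L),
    future = list(spA = 1L, spB = 2L)
  ))
  overlay <- tibble::tibble(pa_id = "p1", cell_id = c(1L, 2L), single_cell = FALSE)
  agg <- aggregate_cell_values(overlay, maps)
  expect_equal(agg$refSR, 1L)
  expect_equal(agg$G, 1L)
  expect_equal(agg$L, 0L)
  # identical periods: G = L = 0
  maps2 <- maps_from_list(list(
    reference = list(spA = 1L, spB = 2L),
    future = list(spA = 1L, spB = 2L)
  ))
  agg2 <- aggregate_cell_values(overlay, maps2)
  expect_equal(agg2$G, 0L)
  expect_equal(agg2$L, 0L)
})

test_that("pooled reference richness is at least the per-cell maximum", {
  g <- make_grid(8, 8)
  withr::with_seed(29, {
    maps <- purrr::map_dfr(paste0("sp", 1:12), function(sp) {
      tibble::tibble(
        species_id = sp,
        cell_id = sample(g$cell_id, 20),
        period = sample(c("reference", "future"), 20, replace = TRUE),
        presence = 1L
      )
    })
    overlay <- tibble::tibble(
      pa_id = "p", cell_id = sample(g$cell_id, 6), single_cell = FALSE
    )
  })
  agg <- aggregate_cell_values(overlay, maps)
  percell <- maps |>
    dplyr::filter(presence == 1, period == "reference", cell_id %in% overlay$cell_id) |>
    dplyr::count(cell_id)
  expect_gte(agg$refSR, max(c(0L, percell$n)))
})

test_that("protected land accounting is exact for simple geometries", {
  g <- make_grid(5, 5, 10)
  # half of cell 17 (x [20,30), y [10,20))
  half <- rect_pa("h", 20, 25, 10, 20)
  pl <- protected_land_per_cell(half, g)
  expect_equal(pl$protected_km2[pl$cell_id == 17], 50)
  expect_equal(sum(pl$protected_km2), 50)
  # two fully overlapping identical PAs count once
  two <- dplyr::bind_rows(rect_pa("a", 22, 28, 12, 18), rect_pa("b", 22, 28, 12, 18))
  pl2 <- protected_land_per_cell(two, g)
  expect_equal(pl2$protected_km2[pl2$cell_id == 17], 36)
  # per-cell value never exceeds the cell area
  expect_true(all(pl2$protected_km2 <= 100))
})

test_that("protected land is invariant to PA order and to splitting a PA in two", {
  g <- make_grid(6, 6, 10)
  a <- rect_pa("a", 5, 25, 8, 18)
  b <- rect_pa("b", 18, 40, 12, 30)
  pl_ab <- protected_land_per_cell(dplyr::bind_rows(a, b), g)
  pl_ba <- protected_land_per_cell(dplyr::bind_rows(b, a), g)
  expect_equal(pl_ab, pl_ba)
  # split `a` into two adjoining halves
  a1 <- rect_pa("a1", 5, 15, 8, 18)
  a2 <- rect_pa("a2", 15, 25, 8, 18)
  pl_split <- protected_land_per_cell(dplyr::bind_rows(a1, a2, b), g)
  expect_equal(pl_split$protected_km2, pl_ab$protected_km2)
})

test_that("protected land union matches a Monte-Carlo hit-or-miss estimate", {
  g <- make_grid(4, 4, 10)
  withr::with_seed(37, {
    pas <- purrr::map_dfr(1:8, function(i) {
      x0 <- runif(1, 0, 35)
      y0 <- runif(1, 0, 35)
      rect_pa(paste0("r", i), x0, x0 + runif(1, 2, 15), y0, y0 + runif(1, 2, 15))
    })
    pl <- protected_land_per_cell(pas, g)
    n_pts <- 1e5
    px <- runif(n_pts, 0, 40)
    py <- runif(n_pts, 0, 40)
  })
  inside_any <- rep(FALSE, length(px))
  for (i in seq_len(nrow(pas))) {
    inside_any <- inside_any |
      (px >= pas$xmin[i] & px < pas$xmax[i] & py >= pas$ymin[i] & py < pas$ymax[i])
  }
  cell <- point_to_cell(g, px, py)
  mc <- tapply(inside_any, cell, mean) * 100 # cell area = 100
  for (cid in names(mc)) {
    p_hat <- mc[[cid]] / 100
    se <- sqrt(p_hat * (1 - p_hat) / (length(px) / 16)) * 100
    expect_lt(
      abs(pl$protected_km2[pl$cell_id == as.integer(cid)] - mc[[cid]]),
      max(3 * se, 1e-6)
    )
  }
})
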