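test_that("gain, loss and turnover formulas match hand-computed values", {
  expect_equal(relative_gain(0, 10), 0)
  expect_equal(relative_gain(10, 10), 100)
  expect_equal(relative_gain(53, 10), 530)
  expect_equal(relative_loss(0, 8), 0)
  expect_equal(relative_loss(8, 8), 100)
  expect_equal(relative_loss(11, 20), 55)
  expect_equal(turnover(0, 0, 12), 0)
  expect_equal(turnover(3, 5, 5), 100)
  expect_equal(turnover(4, 2, 10), 100 * 6 / 14)
  # undefined denominators are NA, not errors
  expect_true(is.na(relative_gain(2, 0)))
  expect_true(is.na(turnover(0, 0, 0)))
  # bookkeeping violation
  expect_error(relative_loss(5, 3), "bookkeeping")
  expect_error(turnover(1, 5, 3), "bookkeeping")
})

test_that("turnover stays in [0, 100], is 100 iff L = refSR, and is monotone in L", {
  withr::with_seed(41, {
    for (i in 1:200) {
      refSR <- sample(1:50, 1)
      L <- sample(0:refSR, 1)
      G <- sample(0:50, 1)
      t <- turnover(G, L, refSR)
      expect_gte(t, 0)
      expect_lte(t, 100)
      expect_equal(t == 100, L == refSR)
      if (L < refSR) expect_gt(turnover(G, L + 1, refSR), t)
    }
  })
})

test_that("the richness identity futureSR = refSR + G - L holds per cell and per PA", {
  g <- make_grid(8, 8)
  withr::with_seed(43, {
    maps <- purrr::map_dfr(paste0("sp", 1:15), function(sp) {
      tidyr::expand_grid(cell_id = g$cell_id, period = c("reference", "future")) |>
        dplyr::mutate(species_id = sp, presence = rbinom(dplyr::n(), 1, 0.3))
    })
  })
  ci <- cell_impact(maps, g)
  expect_equal(ci$futureSR, ci$refSR + ci$G - ci$L)
  pas <- simulate_protected_areas(g, n = 20, size_meanlog = 3, seed = 2)
  ov <- covering_cells(pas, g)
  pi <- pa_impact(ov, maps)
  expect_equal(pi$futureSR, pi$refSR + pi$G - pi$L)
  # rL bounded
  expect_true(all(pi$rL[!is.na(pi$rL)] <= 100))
})

test_that("representativity equals pool ratios and collapses for a degenerate hierarchy", {
  g <- make_grid(4, 3)
  regions <- simulate_region_hierarchy(g, 2, 2)
  # region of cells 0..5 (rows 0-1 = P1R1,P1R2); build maps so PA pool == region pool
  maps <- maps_from_list(list(
    reference = list(spA = 0L, spB = 0L, spC = 4L),
    future = list(spA = 0L)
  ))
  # both covering cells in region P1R1 (row 0), so the assignment is untied
  overlay <- tibble::tibble(pa_id = "p1", cell_id = c(0L, 1L), single_cell = FALSE)
  rep_tbl <- representativity(overlay, regions, maps)
  ref_region <- dplyr::filter(rep_tbl, period == "reference", scale == "region")
  expect_equal(ref_region$representativity, 1)
  # ratio case: enlarge the region pool without touching the PA cells
  maps2 <- dplyr::bind_rows(
    maps,
    maps_from_list(list(reference = list(spD = 2L, spE = 2L, spF = 5L)))
  )
  # PA covers {0,4}: pool {A,B,C}; region P1R1 = row 0 (cells 0,1,2): pool {A,B,D,E}
  overlay2 <- tibble::tibble(pa_id = "p2", cell_id = 0L, single_cell = TRUE)
  r2 <- representativity(overlay2, regions, maps2)
  expect_equal(
    dplyr::filter(r2, period == "reference", scale == "region")$representativity,
    2 / 4
  )
  # degenerate hierarchy: all scales coincide
  regions1 <- simulate_region_hierarchy(g, 1, 1)
  r3 <- representativity(overlay, regions1, maps)
  ref3 <- dplyr::filter(r3, period == "reference")
  expect_equal(length(unique(ref3$representativity)), 1)
})

test_that("representativity never increases as the reference pool coarsens", {
  g <- make_grid(12, 6)
  regions <- simulate_region_hierarchy(g, 3, 2)
  withr::with_seed(47, {
    maps <- purrr::map_dfr(paste0("sp", 1:20), function(sp) {
      tidyr::expand_grid(cell_id = g$cell_id, period = c("reference", "future")) |>
        dplyr::mutate(species_id = sp, presence = rbinom(dplyr::n(), 1, 0.2))
    })
    pas <- simulate_protected_areas(g, n = 30, seed = 5)
  })
  ov <- covering_cells(pas, g)
  r <- representativity(ov, regions, maps) |>
    tidyr::pivot_wider(names_from = scale, values_from = representativity)
  ok <- !is.na(r$region) & !is.na(r$province) & !is.na(r$study_area)
  expect_true(all(r$study_area[ok] <= r$province[ok] + 1e-12))
  expect_true(all(r$province[ok] <= r$region[ok] + 1e-12))
})

test_that("protected-range change matches direct substitutions and exclusion rule", {
  pl <- tibble::tibble(cell_id = 0:3, protected_km2 = c(50, 0, 100, 0))
  maps <- maps_from_list(list(
    reference = list(gone = 0L, same = 2L, up = 0L, dry = 1L),
    future = list(same = 2L, up = c(0L, 2L))
  ))
  pr <- protected_range_change(maps, pl)
  expect_equal(pr$dPR[pr$species_id == "gone"], -100)
  expect_equal(pr$dPR[pr$species_id == "same"], 0)
  # refPR 50 -> futurePR 150: +200%
  expect_equal(pr$dPR[pr$species_id == "up"], 200)
  # species whose reference range overlaps no protected land is excluded
  expect_true(pr$excluded[pr$species_id == "dry"])
  expect_match(pr$reason[pr$species_id == "dry"], "overlap")
  expect_true(is.na(pr$dPR[pr$species_id == "dry"]))
  # dPR >= -100 whenever defined
  expect_true(all(pr$dPR[!is.na(pr$dPR)] >= -100))
})

test_that("land-area shares are protected-land-weighted and sum to one", {
  cells <- tibble::tibble(cell_id = 0:2, T = c(5, 95, 40))
  pl <- tibble::tibble(cell_id = 0:2, protected_km2 = c(10, 30, 0))
  d <- land_area_distribution(cells, pl, "T", breaks = seq(0, 100, 10))
  expect_equal(sum(d$share), 1)
  expect_equal(d$share[d$class == "[0,10)"], 0.25)
  expect_equal(d$share[d$class == "[90,100]"], 0.75)
  # all cells in one class
  d2 <- land_area_distribution(
    tibble::tibble(cell_id = 0:1, T = c(1, 2)),
    tibble::tibble(cell_id = 0:1, protected_km2 = c(5, 5)),
    "T", breaks = c(0, 10)
  )
  expect_equal(d2$share, 1)
  expect_error(
    land_area_distribution(cells, pl, "T", breaks = c(0, 50, 30, 100)),
    "increasing"
  )
})

test_that("the paired Wilcoxon comparison follows the classic signed-rank procedure", {
  # all-zero differences: explicit no-change outcome
  r <- compare_periods(c(3, 4, 5), c(3, 4, 5))
  expect_equal(r$outcome, "no change")
  expect_equal(r$median_diff, 0)
  # hand-ranked example: differences (+1, +2, +3, -1) -> V = 1.5 + 3 + 4 = 8.5
  ref <- c(0, 0, 0, 0)
  fut <- c(1, 2, 3, -1)
  r2 <- compare_periods(ref, fut)
  expect_equal(r2$V, 8.5)
  # uniform +1 shift over 20 pairs: V = 210, significant
  r3 <- compare_periods(rep(0, 20), rep(1, 20))
  expect_equal(r3$V, 210)
  expect_lt(r3$p_value, 0.05)
  expect_error(compare_periods(1:3, 1:4), "equal length")
})

test_that("summaries report mean±SD and median±MAD with raw MAD", {
  s <- summarize_values(c(5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$mad, 0)
  s2 <- summarize_values(c(1, 2, 3, 4, 100))
  expect_equal(s2$median, 3)
  expect_equal(s2$mad, 1)
  s3 <- summarize_values(7)
  expect_equal(s3$mean, 7)
  expect_equal(s3$sd, 0)
  expect_error(summarize_values(NA_real_), "no defined values")
})
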