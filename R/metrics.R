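#' Relative species gain, loss, and turnover
#'
#' The core impact statistics, expressed as percentages of the
#' reference-period modelled richness `refSR`:
#' relative gain `rG = 100 * G / refSR`, relative loss
#' `rL = 100 * L / refSR`, and species turnover
#' `T = 100 * (G + L) / (refSR + G)`. Turnover ranges from 0 (composition
#' unchanged between the two periods) to 100 (full turnover: every
#' reference species lost, i.e. `L = refSR`, for any gain). All three are
#' undefined (`NA`) when their denominator is zero; bookkeeping violations
#' (`L > refSR`) are errors.
#'
#' @param G,L,refSR Species counts (vectorized).
#' @return Percentage vector (full floating precision; rounding is a
#'   reporting concern).
#' @examples
#' turnover(0, 0, 12) # 0
#' turnover(3, 5, 5) # 100
#' relative_gain(53, 10) # 530
#' @export
relative_gain <- function(G, refSR) {
  if (any(G < 0 | refSR < 0, na.rm = TRUE)) abort("counts must be non-negative")
  ifelse(refSR > 0, 100 * G / refSR, NA_real_)
}

#' @rdname relative_gain
#' @export
relative_loss <- function(L, refSR) {
  if (any(L < 0 | refSR < 0, na.rm = TRUE)) abort("counts must be non-negative")
  if (any(L > refSR, na.rm = TRUE)) {
    abort("L > refSR: more species lost than were present (upstream bookkeeping bug)")
  }
  ifelse(refSR > 0, 100 * L / refSR, NA_real_)
}

#' @rdname relative_gain
#' @export
turnover <- function(G, L, refSR) {
  if (any(G < 0 | L < 0 | refSR < 0, na.rm = TRUE)) abort("counts must be non-negative")
  if (any(L > refSR, na.rm = TRUE)) {
    abort("L > refSR: more species lost than were present (upstream bookkeeping bug)")
  }
  ifelse(refSR + G > 0, 100 * (G + L) / (refSR + G), NA_real_)
}

#' Per-cell impact table
#'
#' Computes `refSR`, `futureSR`, `G`, `L`, `rG`, `rL`, `T` for every grid
#' cell from the binary species maps.
#'
#' @param maps Binary maps (`species_id`, `cell_id`, `period`, `presence`).
#' @param grid A [make_grid()] grid (supplies the full cell set so empty
#'   cells appear with zero richness).
#' @return Tibble, one row per cell.
#' @export
cell_impact <- function(maps, grid) {
  wide <- maps |>
    dplyr::filter(.data$presence == 1) |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(
      id_cols = c("species_id", "cell_id"),
      names_from = "period", values_from = "present", values_fill = FALSE
    )
  if (!"reference" %in% names(wide)) wide$reference <- FALSE
  if (!"future" %in% names(wide)) wide$future <- FALSE
  counts <- wide |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      refSR = sum(.data$reference), futureSR = sum(.data$future),
      G = sum(.data$future & !.data$reference),
      L = sum(.data$reference & !.data$future),
      .groups = "drop"
    )
  tibble::tibble(cell_id = grid$cell_id) |>
    dplyr::left_join(counts, by = "cell_id") |>
    dplyr::mutate(
      dplyr::across(c("refSR", "futureSR", "G", "L"), ~ tidyr::replace_na(as.integer(.x), 0L)),
      rG = relative_gain(.data$G, .data$refSR),
      rL = relative_loss(.data$L, .data$refSR),
      T = turnover(.data$G, .data$L, .data$refSR)
    )
}

#' Per-protected-area impact table
#'
#' Combines the cell-aligned aggregation of [aggregate_cell_values()] with
#' the relative statistics. Protected areas with `refSR = 0` keep their
#' counts but have `rG`, `rL`, `T` flagged `NA` (excluded from
#' distributions; the count of such exclusions is attached as attribute
#' `n_undefined`).
#'
#' @param overlay Tibble from [covering_cells()].
#' @param maps Binary maps.
#' @return Tibble: `pa_id`, `n_cells`, `refSR`, `futureSR`, `G`, `L`, `rG`,
#'   `rL`, `T`, `dSR` (`futureSR - refSR`).
#' @export
pa_impact <- function(overlay, maps) {
  out <- aggregate_cell_values(overlay, maps) |>
    dplyr::mutate(
      rG = relative_gain(.data$G, .data$refSR),
      rL = relative_loss(.data$L, .data$refSR),
      T = turnover(.data$G, .data$L, .data$refSR),
      dSR = .data$futureSR - .data$refSR
    )
  attr(out, "n_undefined") <- sum(out$refSR == 0)
  out
}

#' Representativity of protected areas at nested scales
#'
#' Representativity of a protected area is the share of a surrounding
#' region's modelled species pool that also occurs in the cells containing
#' the protected area: |PA pool| / |region pool|, equal to 1 when every
#' species predicted in the region is also predicted in the protected
#' area's cells. Computed per period at three nested scales: the natural
#' region, the natural province, and the whole study area. A protected area
#' is assigned to the region holding the majority of its covering cells
#' (its province is that region's province, keeping the scale chain
#' nested); ties are excluded and counted.
#'
#' @param overlay Tibble from [covering_cells()].
#' @param regions Region hierarchy (`cell_id`, `province_id`, `region_id`).
#' @param maps Binary maps.
#' @return Tibble `pa_id`, `period`, `scale`
#'   (`"region"`/`"province"`/`"study_area"`), `representativity`; attribute
#'   `n_tied` counts protected areas excluded by assignment ties.
#' @export
representativity <- function(overlay, regions, maps) {
  pres <- dplyr::filter(maps, .data$presence == 1)
  # majority-rule assignment of each PA to one region
  assign <- overlay |>
    dplyr::left_join(regions, by = "cell_id") |>
    dplyr::count(.data$pa_id, .data$province_id, .data$region_id) |>
    dplyr::group_by(.data$pa_id) |>
    dplyr::filter(.data$n == max(.data$n))
  tied <- assign |>
    dplyr::summarise(tie = dplyr::n() > 1) |>
    dplyr::filter(.data$tie)
  assign <- assign |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$pa_id %in% tied$pa_id) |>
    dplyr::select("pa_id", "province_id", "region_id")

  pa_pool <- overlay |>
    dplyr::inner_join(pres, by = "cell_id", relationship = "many-to-many") |>
    dplyr::distinct(.data$pa_id, .data$period, .data$species_id) |>
    dplyr::count(.data$pa_id, .data$period, name = "pa_richness")

  cellpools <- dplyr::inner_join(pres, regions, by = "cell_id")
  pool_region <- cellpools |>
    dplyr::distinct(.data$region_id, .data$period, .data$species_id) |>
    dplyr::count(.data$region_id, .data$period, name = "region_richness")
  pool_prov <- cellpools |>
    dplyr::distinct(.data$province_id, .data$period, .data$species_id) |>
    dplyr::count(.data$province_id, .data$period, name = "province_richness")
  pool_study <- pres |>
    dplyr::distinct(.data$period, .data$species_id) |>
    dplyr::count(.data$period, name = "study_richness")

  out <- assign |>
    dplyr::inner_join(pa_pool, by = "pa_id") |>
    dplyr::left_join(pool_region, by = c("region_id", "period")) |>
    dplyr::left_join(pool_prov, by = c("province_id", "period")) |>
    dplyr::left_join(pool_study, by = "period") |>
    dplyr::mutate(
      region = ifelse(.data$region_richness > 0, .data$pa_richness / .data$region_richness, NA_real_),
      province = ifelse(.data$province_richness > 0, .data$pa_richness / .data$province_richness, NA_real_),
      study_area = ifelse(.data$study_richness > 0, .data$pa_richness / .data$study_richness, NA_real_)
    ) |>
    tidyr::pivot_longer(
      c("region", "province", "study_area"),
      names_to = "scale", values_to = "representativity"
    ) |>
    dplyr::select("pa_id", "period", "scale", "representativity")
  attr(out, "n_tied") <- nrow(tied)
  out
}

#' Change in each species' protected range
#'
#' A species' protected range (PR) in a period is the total protected land
#' area over the cells where the species is predicted present. The change
#' statistic is `dPR = 100 * (futurePR - refPR) / refPR`; species whose
#' reference distribution overlaps no protected land (`refPR = 0`) are
#' excluded with the reason recorded. `dPR` is -100 exactly when the future
#' protected range vanishes.
#'
#' @param maps Binary maps.
#' @param protected_land Tibble from [protected_land_per_cell()].
#' @return Tibble `species_id`, `refPR`, `futurePR`, `dPR`, `excluded`,
#'   `reason`.
#' @export
protected_range_change <- function(maps, protected_land) {
  pr <- maps |>
    dplyr::filter(.data$presence == 1) |>
    dplyr::inner_join(protected_land, by = "cell_id") |>
    dplyr::group_by(.data$species_id, .data$period) |>
    dplyr::summarise(PR = sum(.data$protected_km2), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "period", values_from = "PR", values_fill = 0)
  all_sp <- dplyr::distinct(maps, .data$species_id)
  pr <- dplyr::left_join(all_sp, pr, by = "species_id")
  if (!"reference" %in% names(pr)) pr$reference <- 0
  if (!"future" %in% names(pr)) pr$future <- 0
  pr |>
    dplyr::mutate(
      refPR = tidyr::replace_na(.data$reference, 0),
      futurePR = tidyr::replace_na(.data$future, 0),
      excluded = .data$refPR == 0,
      reason = ifelse(.data$excluded, "reference range does not overlap protected land", NA_character_),
      dPR = ifelse(.data$excluded, NA_real_, 100 * (.data$futurePR - .data$refPR) / .data$refPR)
    ) |>
    dplyr::select("species_id", "refPR", "futurePR", "dPR", "excluded", "reason")
}

#' Distribution of a per-cell metric over protected land
#'
#' Bins a per-cell metric into classes and reports, per class, the share of
#' total protected land area whose cells fall in the class (the
#' "proportion of total protected land area" reading of an impact
#' histogram). Cells with zero protected land or an undefined metric
#' contribute nothing; shares sum to 1 over the remaining land.
#'
#' @param cell_values Tibble with `cell_id` and the metric column.
#' @param protected_land Tibble from [protected_land_per_cell()].
#' @param metric Name of the metric column.
#' @param breaks Strictly increasing class edges spanning the metric range;
#'   the last class is closed on the right, and an infinite last edge makes
#'   it open-ended (the default pools values >= 100 into a top class).
#' @return Tibble `class` (factor), `protected_km2`, `share`.
#' @export
land_area_distribution <- function(cell_values, protected_land, metric = "T",
                                   breaks = c(seq(0, 100, by = 10), Inf)) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    abort("`breaks` must be strictly increasing (non-overlapping classes)")
  }
  df <- cell_values |>
    dplyr::inner_join(protected_land, by = "cell_id") |>
    dplyr::filter(.data$protected_km2 > 0, !is.na(.data[[metric]]))
  if (any(df[[metric]] < breaks[1] | df[[metric]] > breaks[length(breaks)])) {
    abort("`breaks` do not span the metric's range")
  }
  df$class <- cut(df[[metric]], breaks = breaks, include.lowest = TRUE, right = FALSE)
  out <- df |>
    dplyr::group_by(.data$class, .drop = FALSE) |>
    dplyr::summarise(protected_km2 = sum(.data$protected_km2), .groups = "drop") |>
    dplyr::mutate(share = .data$protected_km2 / sum(.data$protected_km2))
  out
}

#' Paired comparison of a statistic across periods
#'
#' Two-sided Wilcoxon signed-rank test on paired per-protected-area values
#' (reference vs future). Zero differences are dropped before ranking and
#' the reported `V` is the positive-rank sum; when every difference is zero
#' the test is undefined and an explicit "no change" outcome is returned.
#'
#' @param reference,future Paired numeric vectors (equal length >= 2).
#' @return Tibble `V`, `p_value`, `n` (pairs before zero-removal),
#'   `n_nonzero`, `median_diff`, `outcome` (`"tested"`/`"no change"`).
#' @export
compare_periods <- function(reference, future) {
  if (length(reference) != length(future)) abort("paired vectors must have equal length")
  ok <- !is.na(reference) & !is.na(future)
  reference <- reference[ok]
  future <- future[ok]
  if (length(reference) < 2) abort("need at least two pairs")
  d <- future - reference
  if (all(d == 0)) {
    return(tibble::tibble(
      V = NA_real_, p_value = NA_real_, n = length(d),
      n_nonzero = 0L, median_diff = 0, outcome = "no change"
    ))
  }
  wt <- suppressWarnings(wilcox.test(future, reference, paired = TRUE, exact = NULL))
  tibble::tibble(
    V = unname(wt$statistic), p_value = wt$p.value, n = length(d),
    n_nonzero = sum(d != 0), median_diff = median(d), outcome = "tested"
  )
}

#' Robust and classical location/scale summaries
#'
#' Both summaries are always computed: mean ± SD and median ± MAD (raw
#' median absolute deviation, no consistency constant), so the reporting
#' layer can pick the robust pair when extreme values distort the mean.
#'
#' @param x Numeric vector with at least one non-missing value.
#' @return Tibble `n`, `mean`, `sd`, `median`, `mad`.
#' @examples
#' summarize_values(c(1, 2, 3, 4, 100)) # median 3, MAD 1
#' @export
summarize_values <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("no defined values to summarize")
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) > 1) sd(x) else 0,
    median = median(x),
    mad = mad(x, constant = 1)
  )
}
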