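#' Simulate two-period gridded climate
#'
#' Generates per-cell values for a set of climate variables over a reference
#' and a future period. Each variable follows a linear latitudinal gradient
#' (a per-row slope; row index increases southward, so a positive slope means
#' "warmer towards the south") plus iid Gaussian noise. The future layer is
#' the reference layer plus a spatially uniform offset per variable, so
#' `future - reference` equals the configured warming exactly in every cell.
#'
#' @param grid A [make_grid()] grid.
#' @param variables Character vector of variable names (at least one; supply
#'   two or more if the correlation screen is to be exercised downstream).
#' @param intercepts,gradients,noise_sd,warming Named numeric vectors keyed by
#'   variable: value at row 0, per-row slope, noise standard deviation
#'   (>= 0), and future-minus-reference offset. Variables missing from
#'   `warming` default to 0; missing from `noise_sd` default to 0.
#' @param seed Integer seed; the same seed reproduces the layers exactly.
#' @return A long tibble: `cell_id`, `variable`, `period`
#'   (`"reference"`/`"future"`), `value`.
#' @examples
#' g <- make_grid(5, 4)
#' cl <- simulate_climate(g, "tmean",
#'   intercepts = c(tmean = 0), gradients = c(tmean = 1),
#'   noise_sd = c(tmean = 0), warming = c(tmean = 3), seed = 1
#' )
#' @export
simulate_climate <- function(grid, variables,
                             intercepts, gradients,
                             noise_sd = NULL, warming = NULL,
                             seed = 1L) {
  if (length(variables) < 1) abort("need at least one variable")
  for (nm in c("intercepts", "gradients")) {
    v <- get(nm)
    missing <- setdiff(variables, names(v))
    if (length(missing)) {
      abort(sprintf("`%s` missing entries for: %s", nm, paste(missing, collapse = ", ")))
    }
  }
  extra <- setdiff(
    unique(c(names(intercepts), names(gradients), names(noise_sd), names(warming))),
    variables
  )
  if (length(extra)) {
    abort(sprintf("gradient parameters name unknown variables: %s", paste(extra, collapse = ", ")))
  }
  noise_sd <- setNames(
    ifelse(variables %in% names(noise_sd), noise_sd[variables], 0), variables
  )
  warming <- setNames(
    ifelse(variables %in% names(warming), warming[variables], 0), variables
  )
  if (any(noise_sd < 0)) abort("`noise_sd` must be >= 0")

  ref <- with_seed(derive_seed(seed, 101L), {
    purrr::map_dfr(variables, function(v) {
      tibble::tibble(
        cell_id = grid$cell_id,
        variable = v,
        value = intercepts[[v]] + gradients[[v]] * grid$row +
          rnorm(nrow(grid), 0, noise_sd[[v]])
      )
    })
  })
  fut <- ref
  fut$value <- fut$value + unname(warming[fut$variable])
  dplyr::bind_rows(
    dplyr::mutate(ref, period = "reference"),
    dplyr::mutate(fut, period = "future")
  ) |>
    dplyr::select("cell_id", "variable", "period", "value") |>
    dplyr::arrange(
      .data$period == "future", match(.data$variable, variables), .data$cell_id
    )
}

#' Simulate categorical soil layers
#'
#' Per-cell surface-deposit (7 classes) and soil-drainage (3 classes) labels,
#' used as additional predictors for tree-type species. Classes are sampled
#' independently per cell.
#'
#' @param grid A [make_grid()] grid.
#' @param n_deposit,n_drainage Number of classes per layer.
#' @param seed Integer seed.
#' @return Tibble `cell_id`, `deposit`, `drainage` (factors).
#' @export
simulate_soil <- function(grid, n_deposit = 7, n_drainage = 3, seed = 1L) {
  with_seed(derive_seed(seed, 202L), {
    tibble::tibble(
      cell_id = grid$cell_id,
      deposit = factor(
        sample(paste0("D", seq_len(n_deposit)), nrow(grid), replace = TRUE),
        levels = paste0("D", seq_len(n_deposit))
      ),
      drainage = factor(
        sample(paste0("W", seq_len(n_drainage)), nrow(grid), replace = TRUE),
        levels = paste0("W", seq_len(n_drainage))
      )
    )
  })
}

niche_response <- function(x, shape, optimum, breadth) {
  switch(shape,
    gaussian = exp(-0.5 * ((x - optimum) / breadth)^2),
    logistic = plogis((x - optimum) / breadth),
    step = as.numeric(abs(x - optimum) <= breadth),
    abort(sprintf("unknown niche shape '%s'", shape))
  )
}

#' True suitability surface of a virtual species
#'
#' Evaluates a species' known niche response on the climate of one period:
#' a parametric response (Gaussian bell, logistic ramp, or hard step) to the
#' species' niche variable, multiplied for tree-type species by a categorical
#' soil factor (1 on the preferred deposit class, `soil_penalty` elsewhere).
#' Values always lie in [0, 1].
#'
#' @param species One-row tibble as produced by [simulate_species()] (fields
#'   `shape`, `niche_var`, `optimum`, `breadth`, `soil_pref`, `soil_penalty`).
#' @param climate Long climate tibble from [simulate_climate()].
#' @param period `"reference"` or `"future"`.
#' @param soil Soil tibble from [simulate_soil()], or `NULL` for non-trees.
#' @return Tibble `cell_id`, `suitability`.
#' @export
true_suitability <- function(species, climate, period = "reference", soil = NULL) {
  stopifnot(nrow(species) == 1)
  x <- climate |>
    dplyr::filter(.data$period == !!period, .data$variable == species$niche_var) |>
    dplyr::arrange(.data$cell_id)
  if (nrow(x) == 0) {
    abort(sprintf("climate has no layer for variable '%s', period '%s'", species$niche_var, period))
  }
  suit <- niche_response(x$value, species$shape, species$optimum, species$breadth)
  if (!is.na(species$soil_pref)) {
    if (is.null(soil)) abort("species has a soil preference but no `soil` layer given")
    s <- soil[match(x$cell_id, soil$cell_id), ]
    suit <- suit * ifelse(as.character(s$deposit) == species$soil_pref, 1, species$soil_penalty)
  }
  tibble::tibble(cell_id = x$cell_id, suitability = suit)
}

#' Simulate virtual species and sample their occurrences
#'
#' Draws a community of virtual species with known climatic niches and
#' samples reference-period presence/absence per cell as independent
#' Bernoulli trials with probability `suitability * sampling_rate`. The
#' taxon composition mirrors a northern species pool (birds, amphibians,
#' trees, other vascular plants); tree species additionally prefer one
#' surface-deposit class. Niche optima are drawn uniformly over the observed
#' reference range of the niche variable, optionally extended beyond its warm
#' (southern) end so that some species are "immigrants" whose suitable
#' climate only enters the study area under warming.
#'
#' @param grid A [make_grid()] grid.
#' @param climate Long climate tibble; the niche variable must be present.
#' @param n_per_taxon Named integer vector over
#'   `c("bird","amphibian","tree","other_plant")`.
#' @param niche_var Climate variable the niches respond to.
#' @param shape Niche response shape for all species (`"gaussian"` default).
#' @param breadth_range Range the niche breadths are drawn from (same units
#'   as `niche_var`).
#' @param extend_warm Fraction of the reference span of `niche_var` by which
#'   the optimum range is extended beyond the warm edge (immigrant species).
#' @param optimum_power Skew of the optimum distribution: optima are drawn as
#'   `lo + (hi - lo) * U^(1/optimum_power)`. The default 2 gives a linearly
#'   increasing density toward the warm edge, so synthetic species richness
#'   decreases with latitude as in a northern species pool; 1 gives uniform
#'   optima.
#' @param soil Soil tibble (required if any tree species are requested).
#' @param soil_penalty Suitability multiplier off the preferred deposit class.
#' @param sampling_rate Detection probability in [0, 1].
#' @param seed Integer seed.
#' @return List with `species` (one row per species: `species_id`, `taxon`,
#'   `shape`, `niche_var`, `optimum`, `breadth`, `soil_pref`, `soil_penalty`,
#'   `sampling_rate`), `occurrences` (`species_id`, `cell_id`, `presence`),
#'   and `suitability` (ground truth per `species_id`, `cell_id`, `period`).
#' @export
simulate_species <- function(grid, climate,
                             n_per_taxon = c(bird = 20, amphibian = 8, tree = 12, other_plant = 20),
                             niche_var = "tmean", shape = "gaussian",
                             breadth_range = c(1.5, 3.5), extend_warm = 0.25,
                             optimum_power = 2,
                             soil = NULL, soil_penalty = 0.4,
                             sampling_rate = 1, seed = 1L) {
  check_fraction(sampling_rate, "sampling_rate")
  taxa <- rep(names(n_per_taxon), times = n_per_taxon)
  n_sp <- length(taxa)
  if (n_sp < 1) abort("no species requested")
  if (any(taxa == "tree") && is.null(soil)) {
    abort("tree species requested but no `soil` layer supplied")
  }
  ref_vals <- climate$value[climate$period == "reference" & climate$variable == niche_var]
  if (!length(ref_vals)) abort(sprintf("climate lacks reference layer for '%s'", niche_var))
  rng <- range(ref_vals)
  span <- diff(rng)

  species <- with_seed(derive_seed(seed, 303L), {
    tibble::tibble(
      species_id = sprintf("sp%03d", seq_len(n_sp)),
      taxon = taxa,
      shape = shape,
      niche_var = niche_var,
      optimum = rng[1] + (rng[2] + extend_warm * span - rng[1]) *
        runif(n_sp)^(1 / optimum_power),
      breadth = runif(n_sp, breadth_range[1], breadth_range[2]),
      soil_pref = ifelse(
        taxa == "tree",
        sample(levels(soil$deposit) %||% "D1", n_sp, replace = TRUE),
        NA_character_
      ),
      soil_penalty = soil_penalty,
      sampling_rate = sampling_rate
    )
  })

  suit <- purrr::map_dfr(seq_len(n_sp), function(i) {
    sp <- species[i, ]
    dplyr::bind_rows(
      dplyr::mutate(true_suitability(sp, climate, "reference", soil),
        species_id = sp$species_id, period = "reference"
      ),
      dplyr::mutate(true_suitability(sp, climate, "future", soil),
        species_id = sp$species_id, period = "future"
      )
    )
  }) |>
    dplyr::select("species_id", "cell_id", "period", "suitability")

  occurrences <- with_seed(derive_seed(seed, 404L), {
    ref <- dplyr::filter(suit, .data$period == "reference")
    ref |>
      dplyr::group_by(.data$species_id) |>
      dplyr::mutate(presence = rbinom(dplyr::n(), 1, .data$suitability * sampling_rate)) |>
      dplyr::ungroup() |>
      dplyr::select("species_id", "cell_id", "presence")
  })

  list(species = species, occurrences = occurrences, suitability = suit)
}

#' Simulate a protected-area network
#'
#' Places axis-aligned rectangular protected areas uniformly inside the grid
#' extent with a right-skewed (log-normal) size distribution. The default
#' parameters put roughly 97% of areas below the 50 km^2 size cap, emulating
#' a network dominated by small reserves with a tail of large parks. Areas
#' may overlap one another; geometric areas are recorded exactly.
#'
#' @param grid A [make_grid()] grid.
#' @param n Number of protected areas (>= 1).
#' @param size_meanlog,size_sdlog Log-normal parameters of the area (km^2)
#'   distribution.
#' @param size_cap Nominal small-area cap (km^2) used for reporting; must not
#'   exceed the grid extent area.
#' @param aspect_range Range of width/height aspect ratios.
#' @param categories,category_prob Management-category labels and their
#'   sampling weights.
#' @param seed Integer seed.
#' @return Tibble with class `protected_areas`: `pa_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax`, `area_km2`, `category`.
#' @export
simulate_protected_areas <- function(grid, n = 150,
                                     size_meanlog = 1.66, size_sdlog = 1.2,
                                     size_cap = 50,
                                     aspect_range = c(0.4, 2.5),
                                     categories = c("II", "III", "IV", "VI"),
                                     category_prob = c(0.15, 0.1, 0.45, 0.3),
                                     seed = 1L) {
  stopifnot_scalar_count(n, "n")
  m <- grid_meta(grid)
  W <- m$n_cols * m$cell_size
  H <- m$n_rows * m$cell_size
  if (size_cap > W * H) abort("`size_cap` exceeds the grid extent area")
  with_seed(derive_seed(seed, 505L), {
    area <- pmin(rlnorm(n, size_meanlog, size_sdlog), 0.2 * W * H)
    aspect <- runif(n, aspect_range[1], aspect_range[2])
    w <- pmin(sqrt(area * aspect), 0.9 * W)
    h <- pmin(area / w, 0.9 * H)
    w <- area / h # restore exact area after clamping
    x0 <- m$origin[1] + runif(n, 0, W - w)
    y0 <- m$origin[2] + runif(n, 0, H - h)
    pa <- tibble::tibble(
      pa_id = sprintf("pa%04d", seq_len(n)),
      xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h,
      area_km2 = w * h,
      category = sample(categories, n, replace = TRUE, prob = category_prob)
    )
    class(pa) <- c("protected_areas", class(pa))
    pa
  })
}

#' Simulate a nested region hierarchy
#'
#' Partitions the grid into contiguous latitudinal bands: `n_provinces`
#' provinces, each split into `n_regions_per_province` regions. Every cell
#' belongs to exactly one region and one province, and each region's cells
#' are a subset of exactly one province's cells, giving the three nested
#' scales used by representativity (study area, province, region).
#'
#' @param grid A [make_grid()] grid.
#' @param n_provinces,n_regions_per_province Band counts; the total number of
#'   bands must not exceed the number of grid rows.
#' @return Tibble `cell_id`, `province_id`, `region_id`.
#' @export
simulate_region_hierarchy <- function(grid, n_provinces = 3, n_regions_per_province = 2) {
  stopifnot_scalar_count(n_provinces, "n_provinces")
  stopifnot_scalar_count(n_regions_per_province, "n_regions_per_province")
  m <- grid_meta(grid)
  if (n_provinces > m$n_rows) abort("more provinces than grid rows")
  if (n_provinces * n_regions_per_province > m$n_rows) {
    abort("more regions than grid rows")
  }
  prov_of_row <- dplyr::ntile(seq_len(m$n_rows), n_provinces)
  reg_within <- unlist(lapply(split(seq_len(m$n_rows), prov_of_row), function(rows) {
    dplyr::ntile(seq_along(rows), n_regions_per_province)
  }), use.names = FALSE)
  tibble::tibble(
    cell_id = grid$cell_id,
    province_id = paste0("P", prov_of_row[grid$row + 1L]),
    region_id = paste0("P", prov_of_row[grid$row + 1L], "R", reg_within[grid$row + 1L])
  )
}

#' Simulate the complete synthetic study system
#'
#' Convenience wrapper producing every layer the pipeline consumes: grid,
#' two-period climate (four variables by default, with a strong latitudinal
#' temperature gradient and a uniform-warming future), soil classes, virtual
#' species with sampled occurrences, protected areas, and the nested region
#' hierarchy. All randomness flows from `seed` through independent streams.
#'
#' @param config A configuration list as returned by [default_config()]
#'   (only the `landscape` block is used).
#' @param seed Master integer seed; overrides `config$seed` when given.
#' @return A list with class `synthetic_landscape`: `grid`, `climate`,
#'   `soil`, `species`, `occurrences`, `suitability`, `protected_areas`,
#'   `regions`, `seed`.
#' @examples
#' land <- simulate_landscape(seed = 42)
#' dplyr::count(land$species, taxon)
#' @export
simulate_landscape <- function(config = default_config(), seed = NULL) {
  lc <- config$landscape
  seed <- as.integer(seed %||% config$seed %||% 1L)
  grid <- make_grid(lc$n_rows, lc$n_cols, lc$cell_size)
  climate <- simulate_climate(
    grid,
    variables = names(lc$climate$intercepts),
    intercepts = unlist(lc$climate$intercepts),
    gradients = unlist(lc$climate$gradients),
    noise_sd = unlist(lc$climate$noise_sd),
    warming = unlist(lc$climate$warming),
    seed = seed
  )
  soil <- simulate_soil(grid, seed = seed)
  sp <- simulate_species(
    grid, climate,
    n_per_taxon = unlist(lc$species$n_per_taxon),
    niche_var = lc$species$niche_var,
    shape = lc$species$shape,
    breadth_range = unlist(lc$species$breadth_range),
    extend_warm = lc$species$extend_warm,
    optimum_power = lc$species$optimum_power %||% 2,
    soil = soil,
    soil_penalty = lc$species$soil_penalty,
    sampling_rate = lc$species$sampling_rate,
    seed = seed
  )
  pas <- simulate_protected_areas(
    grid,
    n = lc$protected_areas$n,
    size_meanlog = lc$protected_areas$size_meanlog,
    size_sdlog = lc$protected_areas$size_sdlog,
    size_cap = lc$protected_areas$size_cap,
    seed = seed
  )
  regions <- simulate_region_hierarchy(
    grid, lc$regions$n_provinces, lc$regions$n_regions_per_province
  )
  structure(
    list(
      grid = grid, climate = climate, soil = soil,
      species = sp$species, occurrences = sp$occurrences,
      suitability = sp$suitability,
      protected_areas = pas, regions = regions, seed = seed
    ),
    class = "synthetic_landscape"
  )
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  m <- grid_meta(x$grid)
  cat(sprintf(
    "<synthetic_landscape> %d x %d grid (%g km cells), %d species, %d protected areas, %d regions\n",
    m$n_rows, m$n_cols, m$cell_size, nrow(x$species), nrow(x$protected_areas),
    dplyr::n_distinct(x$regions$region_id)
  ))
  invisible(x)
}
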