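#' Default pipeline configuration
#'
#' The demo-scale study system: a 30 x 20 grid of 20 km cells, four climate
#' variables with a strong north-south temperature gradient and a uniform
#' +3 degree warming, 60 virtual species (20 birds, 8 amphibians, 12 trees,
#' 20 other vascular plants), 150 protected areas, and a 3-province /
#' 6-region nested hierarchy. The ENM block carries the documented ensemble
#' defaults ([enm_options()]); the metrics block the class edges of the
#' land-area distributions (width-10 bins with an open top class pooling
#' relative gains >= 100).
#'
#' @return A nested configuration list (round-trips through YAML unchanged).
#' @export
default_config <- function() {
  list(
    version = 1L,
    seed = 1L,
    landscape = list(
      n_rows = 30L, n_cols = 20L, cell_size = 20,
      climate = list(
        intercepts = list(tmean = -2, precip = 1100, tmin = -10, gdd = 800),
        gradients = list(tmean = 0.6, precip = -2, tmin = 0.7, gdd = 40),
        noise_sd = list(tmean = 0.8, precip = 120, tmin = 1.0, gdd = 150),
        warming = list(tmean = 3, precip = 0, tmin = 3.4, gdd = 180)
      ),
      species = list(
        n_per_taxon = list(bird = 20L, amphibian = 8L, tree = 12L, other_plant = 20L),
        niche_var = "tmean", shape = "gaussian",
        breadth_range = list(1.5, 3.5), extend_warm = 0.25, optimum_power = 2,
        soil_penalty = 0.4, sampling_rate = 1
      ),
      protected_areas = list(
        n = 150L, size_meanlog = 1.66, size_sdlog = 1.2, size_cap = 50
      ),
      regions = list(n_provinces = 3L, n_regions_per_province = 2L)
    ),
    predictors = list(threshold = 0.6, candidates = NULL),
    enm = list(
      n_rep = 10L, buffer_cells = 2, split = 0.7, auc_floor = 0.7,
      families = c("glm_quad", "cart", "bagged", "knn"),
      min_presences = 15L, lambda = 0.01, ntree = 100L, k = 7L
    ),
    metrics = list(
      gain_breaks = c(seq(0, 100, by = 10), Inf),
      loss_breaks = seq(0, 100, by = 10),
      turnover_breaks = seq(0, 100, by = 10)
    )
  )
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; violations are returned, not thrown, so a
#' caller can report all of them at once.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  lc <- config$landscape
  if (is.null(lc)) {
    add("missing `landscape` block")
    return(v)
  }
  if (is.null(lc$n_rows) || lc$n_rows < 1) add("landscape$n_rows: must be >= 1")
  if (is.null(lc$n_cols) || lc$n_cols < 1) add("landscape$n_cols: must be >= 1")
  if (!is.null(lc$cell_size) && lc$cell_size <= 0) add("landscape$cell_size: must be > 0")
  n_sp <- sum(unlist(lc$species$n_per_taxon))
  if (is.na(n_sp) || n_sp < 1) add("landscape$species$n_per_taxon: no species configured")
  sr <- lc$species$sampling_rate
  if (!is.null(sr) && (sr < 0 || sr > 1)) add("landscape$species$sampling_rate: must be in [0, 1]")
  if (length(lc$climate$intercepts) < 2) {
    add("landscape$climate: need >= 2 variables so the correlation screen is exercisable")
  }
  if (!is.null(lc$regions)) {
    if (lc$regions$n_provinces * lc$regions$n_regions_per_province > lc$n_rows) {
      add("landscape$regions: more region bands than grid rows")
    }
  }
  thr <- config$predictors$threshold
  if (!is.null(thr) && (thr <= 0 || thr > 1)) add("predictors$threshold: must be in (0, 1]")
  enm <- config$enm
  if (!is.null(enm)) {
    if (enm$auc_floor < 0 || enm$auc_floor > 1) add("enm$auc_floor: must be in [0, 1]")
    if (enm$split <= 0 || enm$split >= 1) add("enm$split: must be in (0, 1)")
    if (enm$buffer_cells < 0) add("enm$buffer_cells: must be >= 0")
    if (enm$n_rep < 1) add("enm$n_rep: must be >= 1")
    if (!is.null(lc$n_cols) && enm$buffer_cells > max(lc$n_rows, lc$n_cols)) {
      add("enm$buffer_cells: buffer exceeds the grid in cell units")
    }
  }
  for (b in c("gain_breaks", "loss_breaks", "turnover_breaks")) {
    br <- config$metrics[[b]]
    if (!is.null(br) && is.unsorted(br, strictly = TRUE)) {
      add(sprintf("metrics$%s: class edges must be strictly increasing", b))
    }
  }
  v
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end: synthetic-landscape generation,
#' predictor screening, per-species ensemble modelling and projection,
#' protected-area overlay, and the conservation metrics (per-cell and
#' per-PA impact, representativity at three scales, protected-range change,
#' land-area distributions, and paired Wilcoxon comparisons of richness and
#' representativity across periods). One master seed determines every
#' random stream; the same config and seed reproduce every output exactly.
#'
#' @param config Configuration list; validated before anything runs.
#' @param seed Master seed override.
#' @param outdir Optional directory; when given, every stage output is
#'   written as CSV/GeoJSON plus a `run_report.yaml`.
#' @param quiet Suppress per-stage progress messages.
#' @return List with `landscape`, `predictor_sets`, `model` (fits, maps,
#'   report), `overlay`, `protected_land`, `cells` (per-cell impact),
#'   `impact` (per-PA), `representativity`, `protection`, `distributions`,
#'   `tests`, `summaries`, `config`, `seed`.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL, outdir = NULL,
                         quiet = FALSE) {
  violations <- validate_config(config)
  if (length(violations)) {
    abort(paste(c("invalid configuration:", violations), collapse = "\n  - "))
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  say <- function(...) if (!quiet) inform(sprintf(...))

  say("stage 1/5: simulating landscape (seed %d)", seed)
  land <- simulate_landscape(config, seed = seed)

  say("stage 2/5: screening predictors")
  psets <- build_predictor_sets(
    land$climate,
    candidates = config$predictors$candidates,
    threshold = config$predictors$threshold %||% 0.6
  )

  say("stage 3/5: ensemble niche modelling (%d species)", nrow(land$species))
  opts <- do.call(enm_options, config$enm[names(config$enm) %in% names(formals(enm_options))])
  model <- withCallingHandlers(
    model_all_species(land, psets, opts, seed = seed),
    warning = function(w) {
      say("  note: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (nrow(model$maps) == 0) {
    abort("stage enm_ensemble: no species could be modelled")
  }

  say("stage 4/5: protected-area overlay")
  overlay <- covering_cells(land$protected_areas, land$grid)
  prot_land <- protected_land_per_cell(land$protected_areas, land$grid)

  say("stage 5/5: conservation metrics")
  cells <- cell_impact(model$maps, land$grid)
  impact <- pa_impact(overlay, model$maps)
  repr <- representativity(overlay, land$regions, model$maps)
  protection <- protected_range_change(model$maps, prot_land)
  distributions <- list(
    rG = land_area_distribution(cells, prot_land, "rG", config$metrics$gain_breaks),
    rL = land_area_distribution(cells, prot_land, "rL", config$metrics$loss_breaks),
    T = land_area_distribution(cells, prot_land, "T", config$metrics$turnover_breaks)
  )
  repr_prov <- repr |>
    dplyr::filter(.data$scale == "province") |>
    tidyr::pivot_wider(names_from = "period", values_from = "representativity")
  tests <- dplyr::bind_rows(
    dplyr::mutate(compare_periods(impact$refSR, impact$futureSR), statistic = "richness"),
    dplyr::mutate(compare_periods(repr_prov$reference, repr_prov$future),
      statistic = "representativity_province"
    )
  ) |>
    dplyr::relocate("statistic")
  summaries <- dplyr::bind_rows(
    dplyr::mutate(summarize_values(impact$rG), statistic = "rG"),
    dplyr::mutate(summarize_values(impact$rL), statistic = "rL"),
    dplyr::mutate(summarize_values(impact$T), statistic = "T"),
    dplyr::mutate(summarize_values(protection$dPR), statistic = "dPR")
  ) |>
    dplyr::relocate("statistic")

  res <- list(
    landscape = land, predictor_sets = psets, model = model,
    overlay = overlay, protected_land = prot_land, cells = cells,
    impact = impact, representativity = repr, protection = protection,
    distributions = distributions, tests = tests, summaries = summaries,
    config = config, seed = seed
  )
  class(res) <- "refugia_run"
  if (!is.null(outdir)) write_run(res, outdir)
  res
}

#' @export
print.refugia_run <- function(x, ...) {
  cat(sprintf(
    "<refugia_run> seed %d: %d species (%d modelled), %d protected areas\n",
    x$seed, nrow(x$landscape$species),
    sum(x$model$report$status == "ok"), nrow(x$landscape$protected_areas)
  ))
  print(x$summaries)
  invisible(x)
}

#' Write all pipeline outputs to disk
#'
#' @param run A `refugia_run` object.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_landscape(run$landscape, file.path(outdir, "landscape"))
  readr::write_csv(run$predictor_sets, file.path(outdir, "predictor_sets.csv"))
  readr::write_csv(run$model$maps, file.path(outdir, "suitability_maps.csv"))
  readr::write_csv(run$model$report, file.path(outdir, "model_report.csv"))
  readr::write_csv(run$overlay, file.path(outdir, "overlay_index.csv"))
  readr::write_csv(run$protected_land, file.path(outdir, "protected_land.csv"))
  readr::write_csv(run$cells, file.path(outdir, "cell_impact.csv"))
  readr::write_csv(run$impact, file.path(outdir, "pa_impact.csv"))
  readr::write_csv(run$representativity, file.path(outdir, "representativity.csv"))
  readr::write_csv(run$protection, file.path(outdir, "protection_change.csv"))
  for (nm in names(run$distributions)) {
    readr::write_csv(
      run$distributions[[nm]],
      file.path(outdir, sprintf("land_distribution_%s.csv", nm))
    )
  }
  readr::write_csv(run$tests, file.path(outdir, "period_tests.csv"))
  readr::write_csv(run$summaries, file.path(outdir, "summaries.csv"))
  report <- list(
    seed = run$seed,
    package_version = as.character(utils::packageVersion("refugia")),
    n_species = nrow(run$landscape$species),
    species_modelled = sum(run$model$report$status == "ok"),
    species_skipped = sum(run$model$report$status == "skipped_few_presences"),
    species_unmodellable = sum(run$model$report$status == "unmodellable"),
    pas_undefined_metrics = attr(run$impact, "n_undefined"),
    pas_region_tie_excluded = attr(run$representativity, "n_tied"),
    species_excluded_protection = sum(run$protection$excluded),
    config = run$config
  )
  yaml::write_yaml(report, file.path(outdir, "run_report.yaml"))
  invisible(outdir)
}
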