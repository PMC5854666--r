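# Shared fixture builders; everything is generated in code at test time.

# Small noise-free climate: one monotone temperature-like gradient plus an
# uncorrelated second variable.
tiny_climate <- function(grid, warming = 3, noise = 0, seed = 1) {
  simulate_climate(
    grid,
    variables = c("tmean", "precip"),
    intercepts = c(tmean = 0, precip = 1000),
    gradients = c(tmean = 1, precip = 0),
    noise_sd = c(tmean = noise, precip = 50),
    warming = c(tmean = warming, precip = 0),
    seed = seed
  )
}

# Binary presence maps built from an explicit list:
#   list(reference = list(spA = cells, ...), future = list(...))
maps_from_list <- function(spec_list) {
  purrr::imap_dfr(spec_list, function(bysp, per) {
    purrr::imap_dfr(bysp, function(cells, sp) {
      tibble::tibble(
        species_id = sp, cell_id = as.integer(cells),
        period = per, presence = 1L
      )
    })
  })
}

# One axis-aligned rectangle as a protected_areas tibble.
rect_pa <- function(id, xmin, xmax, ymin, ymax, category = "IV") {
  tibble::tibble(
    pa_id = id, xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
    area_km2 = (xmax - xmin) * (ymax - ymin), category = category
  )
}

# Brute-force oracle: cells whose open square intersects the rectangle with
# positive area.
covering_cells_oracle <- function(pa, grid) {
  hit <- pmin(grid$xmax, pa$xmax) > pmax(grid$xmin, pa$xmin) &
    pmin(grid$ymax, pa$ymax) > pmax(grid$ymin, pa$ymin)
  sort(grid$cell_id[hit])
}

# Brute-force AUC by pair enumeration (ties count one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}
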