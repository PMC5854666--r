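test_that("pseudo-absence repetitions have exact 0.5 prevalence and respect the buffer", {
  g <- make_grid(20, 15)
  withr::with_seed(3, pres <- sample(g$cell_id, 30))
  ts <- select_pseudo_absences(pres, g, buffer_cells = 2, n_rep = 5, seed = 13)
  for (r in 1:5) {
    tr <- dplyr::filter(ts, rep == r)
    expect_equal(sum(tr$presence == 1), 30)
    expect_equal(sum(tr$presence == 0), 30)
    expect_equal(mean(tr$presence), 0.5)
    pa <- tr$cell_id[tr$presence == 0]
    expect_equal(anyDuplicated(pa), 0L)
    # exhaustive distance check: centre-to-centre > 2 cell widths
    for (cell in pa) {
      d <- sqrt((g$x[match(cell, g$cell_id)] - g$x[match(pres, g$cell_id)])^2 +
        (g$y[match(cell, g$cell_id)] - g$y[match(pres, g$cell_id)])^2)
      expect_gt(min(d), 2 * 20)
    }
  }
  # repetitions differ
  expect_false(identical(
    dplyr::filter(ts, rep == 1)$cell_id, dplyr::filter(ts, rep == 2)$cell_id
  ))
  # determinism
  expect_identical(ts, select_pseudo_absences(pres, g, 2, 5, seed = 13))
})

test_that("buffer radius 0 makes every non-presence cell eligible", {
  g <- make_grid(6, 6)
  pres <- c(0L, 7L, 14L)
  ts <- select_pseudo_absences(pres, g, buffer_cells = 0, n_rep = 50, seed = 1)
  drawn <- unique(ts$cell_id[ts$presence == 0])
  expect_true(all(!drawn %in% pres))
  # with many repetitions nearly all eligible cells are eventually drawn
  expect_gt(length(drawn), 30)
})

test_that("infeasible buffers raise an error naming the species", {
  g <- make_grid(5, 5)
  expect_error(
    select_pseudo_absences(0:15, g, buffer_cells = 3, n_rep = 1, species_id = "spX"),
    "spX.*smaller buffer"
  )
})

test_that("AUC matches hand-enumerated examples and handles ties", {
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(evaluate_auc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(evaluate_auc(c(0.7, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(evaluate_auc(c(0.1, 0.2), c(1, 1)), "single class")
})

test_that("AUC equals the brute-force pair enumeration (and pROC) on random holdouts", {
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- sample(10:200, 1)
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), 2) # rounding forces ties
      a <- evaluate_auc(scores, labels)
      expect_equal(a, auc_oracle(scores, labels))
      expect_equal(
        a,
        as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE, direction = "<")))
      )
    }
  })
})

separable_training <- function(n = 80) {
  # step niche on one predictor: labels perfectly separable
  tibble::tibble(
    tmean = c(runif(n / 2, 0, 4), runif(n / 2, 8, 12)),
    precip = rnorm(n, 1000, 50),
    .presence = factor(rep(c(0, 1), each = n / 2), levels = c(0, 1))
  )
}

test_that("every committee member separates a step-niche species perfectly", {
  withr::with_seed(5, data <- separable_training())
  fits <- fit_members(data, enm_options(), seed = 2)
  fams <- enm_families()
  for (nm in names(fits)) {
    sc <- fams[[nm]]$predict(fits[[nm]], data[c("tmean", "precip")])
    expect_equal(evaluate_auc(sc, data$.presence), 1.0, info = nm)
  }
})

test_that("shuffled labels give chance-level member AUC", {
  withr::with_seed(6, {
    n <- 800
    data <- tibble::tibble(
      tmean = runif(n, 0, 10), precip = rnorm(n, 1000, 50),
      .presence = factor(rbinom(n, 1, 0.5), levels = c(0, 1))
    )
  })
  train <- data[1:400, ]
  holdout <- data[401:800, ]
  fits <- fit_members(train, enm_options(), seed = 3)
  fams <- enm_families()
  for (nm in c("glm_quad", "knn")) {
    sc <- fams[[nm]]$predict(fits[[nm]], holdout[c("tmean", "precip")])
    expect_lt(abs(evaluate_auc(sc, holdout$.presence) - 0.5), 0.12)
  }
})

test_that("single-class training sets are rejected", {
  data <- tibble::tibble(
    tmean = runif(20), .presence = factor(rep(1, 20), levels = c(0, 1))
  )
  expect_error(fit_members(data, enm_options()), "single class")
})

test_that("consensus weighting follows AUC with floor exclusion", {
  fams <- list(
    k1 = list(predict = function(fit, newdata) rep(0.2, nrow(newdata))),
    k2 = list(predict = function(fit, newdata) rep(0.6, nrow(newdata)))
  )
  nd <- tibble::tibble(x = 1:5)
  # equal AUCs: plain mean
  members <- list(
    list(family = "k1", auc = 0.8, fit = NULL),
    list(family = "k2", auc = 0.8, fit = NULL)
  )
  expect_equal(consensus_project(members, nd, fams, 0.7), rep(0.4, 5))
  # identical outputs: consensus equals them regardless of weights
  fams_same <- list(
    k1 = list(predict = function(fit, newdata) rep(0.33, nrow(newdata))),
    k2 = list(predict = function(fit, newdata) rep(0.33, nrow(newdata)))
  )
  members2 <- list(
    list(family = "k1", auc = 0.95, fit = NULL),
    list(family = "k2", auc = 0.72, fit = NULL)
  )
  expect_equal(consensus_project(members2, nd, fams_same, 0.7), rep(0.33, 5))
  # one member below the floor: the survivor's output
  members3 <- list(
    list(family = "k1", auc = 0.55, fit = NULL),
    list(family = "k2", auc = 0.9, fit = NULL)
  )
  expect_equal(consensus_project(members3, nd, fams, 0.7), rep(0.6, 5))
  # no member above the floor
  members4 <- list(list(family = "k1", auc = 0.6, fit = NULL))
  expect_null(consensus_project(members4, nd, fams, 0.7))
  # invariance to member ordering
  expect_equal(
    consensus_project(rev(members), nd, fams, 0.7),
    consensus_project(members, nd, fams, 0.7)
  )
})

test_that("max-TSS threshold uses the smallest maximizer and reproduces separable labels", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  thr <- tss_threshold(scores, labels)
  expect_equal(thr$threshold, 0.8)
  expect_equal(thr$tss, 1)
  expect_equal(as.integer(scores >= thr$threshold), labels)
  # degenerate: all scores identical
  thr2 <- tss_threshold(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(thr2$threshold, 0.5)
  expect_equal(thr2$tss, 0)
  expect_error(tss_threshold(c(0.3, 0.4), c(1, 1)), "both classes")
})

test_that("a single-family ensemble recovers a logistic niche monotonically", {
  g <- make_grid(25, 20) # 500 cells
  cl <- tiny_climate(g, noise = 0)
  sim <- simulate_species(g, cl,
    n_per_taxon = c(bird = 1), shape = "logistic",
    extend_warm = 0, sampling_rate = 1, seed = 17
  )
  occ <- sim$occurrences
  fit <- suppressWarnings(model_species(
    occ, "bird", cl, "tmean", g,
    opts = enm_options(families = "glm_quad", n_rep = 3), seed = 9
  ))
  expect_equal(fit$status, "ok")
  truth <- dplyr::filter(sim$suitability, period == "reference")
  j <- dplyr::inner_join(
    dplyr::filter(fit$maps, period == "reference"), truth,
    by = "cell_id"
  )
  expect_gt(cor(j$suitability.x, j$suitability.y, method = "spearman"), 0.9)
})

test_that("model_species output is deterministic and its maps well-formed", {
  g <- make_grid(15, 10)
  cl <- tiny_climate(g, noise = 0.3)
  sim <- simulate_species(g, cl, n_per_taxon = c(bird = 1), extend_warm = 0, seed = 23)
  occ <- sim$occurrences
  opts <- enm_options(n_rep = 2)
  f1 <- suppressWarnings(model_species(occ, "bird", cl, c("tmean", "precip"), g, opts = opts, seed = 4))
  f2 <- suppressWarnings(model_species(occ, "bird", cl, c("tmean", "precip"), g, opts = opts, seed = 4))
  expect_equal(f1$members, f2$members)
  expect_equal(f1$maps, f2$maps)
  expect_equal(f1$status, "ok")
  expect_true(all(f1$maps$suitability >= 0 & f1$maps$suitability <= 1))
  expect_setequal(unique(f1$maps$period), c("reference", "future"))
  expect_equal(nrow(f1$maps), 2 * nrow(g))
  expect_true(all(f1$maps$presence %in% 0:1))
  # binary = suitability >= threshold everywhere
  expect_equal(f1$maps$presence, as.integer(f1$maps$suitability >= f1$threshold))
})

test_that("tidy() and glance() expose the member table and fit summary", {
  g <- make_grid(15, 10)
  cl <- tiny_climate(g, noise = 0.3)
  sim <- simulate_species(g, cl, n_per_taxon = c(bird = 1), extend_warm = 0, seed = 23)
  fit <- suppressWarnings(model_species(
    sim$occurrences, "bird", cl, c("tmean", "precip"), g,
    opts = enm_options(n_rep = 2), seed = 4
  ))
  td <- generics::tidy(fit)
  gl <- generics::glance(fit)
  expect_true(all(c("species_id", "rep", "family", "auc", "kept", "weight") %in% names(td)))
  expect_equal(nrow(gl), 1)
  expect_equal(gl$species_id, fit$species_id)
  if (fit$status == "ok") {
    expect_equal(sum(td$weight), 1, tolerance = 1e-12)
    expect_equal(gl$n_kept, sum(td$kept))
  }
})
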