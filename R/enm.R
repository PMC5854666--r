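#' Options for ensemble niche modelling
#'
#' Collects the tunable parameters of the ensemble: number of pseudo-absence
#' repetitions (ten by default, matching the study design), pseudo-absence
#' exclusion buffer in cell widths, calibration/evaluation split fraction,
#' AUC floor for consensus membership, the model-family committee, and the
#' minimum number of presences below which a species is skipped.
#'
#' @param n_rep Pseudo-absence repetitions (for tree-type species with real
#'   absences these become repeated stratified splits instead).
#' @param buffer_cells Buffer radius around presences, in cell widths;
#'   pseudo-absences are drawn strictly outside it.
#' @param split Calibration fraction of each repetition (stratified by class).
#' @param auc_floor Members with evaluation AUC below this are excluded from
#'   the consensus (exclusion is recorded).
#' @param families Committee members, a subset of `names(enm_families())`.
#' @param min_presences Species with fewer sampled presences are skipped.
#' @param lambda Ridge penalty of the regularized logistic member.
#' @param ntree Trees in the bagged-trees member.
#' @param k Neighbours in the kNN member.
#' @return A named list of options.
#' @export
enm_options <- function(n_rep = 10, buffer_cells = 2, split = 0.7,
                        auc_floor = 0.7,
                        families = c("glm_quad", "cart", "bagged", "knn"),
                        min_presences = 15, lambda = 0.01, ntree = 100, k = 7) {
  list(
    n_rep = n_rep, buffer_cells = buffer_cells, split = split,
    auc_floor = auc_floor, families = families,
    min_presences = min_presences, lambda = lambda, ntree = ntree, k = k
  )
}

#' Select pseudo-absences outside a presence buffer
#'
#' For a species with presence-only data, draws repetitions of pseudo-absence
#' cells uniformly without replacement from the cells lying strictly farther
#' (centre to centre) than `buffer_cells * cell_size` from every presence
#' cell. Each repetition draws exactly as many pseudo-absences as there are
#' presences, so the training prevalence is exactly 0.5.
#'
#' @param presence_cells Integer cell ids with recorded presence.
#' @param grid A [make_grid()] grid.
#' @param buffer_cells Buffer radius in cell widths (>= 0).
#' @param n_rep Number of repetitions.
#' @param seed Integer seed.
#' @param species_id Label used in error messages.
#' @return Tibble `rep`, `cell_id`, `presence` (1 for the presence rows,
#'   repeated in every repetition; 0 for the drawn pseudo-absences).
#' @export
select_pseudo_absences <- function(presence_cells, grid, buffer_cells = 2,
                                   n_rep = 10, seed = 1L, species_id = "?") {
  if (buffer_cells < 0) abort("`buffer_cells` must be >= 0")
  n_pres <- length(presence_cells)
  if (n_pres < 1) abort("no presence cells")
  m <- grid_meta(grid)
  idx <- match(presence_cells, grid$cell_id)
  px <- grid$x[idx]
  py <- grid$y[idx]
  radius <- buffer_cells * m$cell_size
  # minimum centre-to-centre distance from each cell to any presence
  d2min <- rep(Inf, nrow(grid))
  for (i in seq_len(n_pres)) {
    d2 <- (grid$x - px[i])^2 + (grid$y - py[i])^2
    d2min <- pmin(d2min, d2)
  }
  eligible <- grid$cell_id[d2min > radius^2 & !(grid$cell_id %in% presence_cells)]
  if (length(eligible) < n_pres) {
    abort(sprintf(
      "species %s: only %d cells outside the %g-cell buffer for %d presences; use a smaller buffer",
      species_id, length(eligible), buffer_cells, n_pres
    ))
  }
  purrr::map_dfr(seq_len(n_rep), function(r) {
    pa <- with_seed(derive_seed(seed, 606L, r), sample(eligible, n_pres))
    tibble::tibble(
      rep = r,
      cell_id = c(presence_cells, pa),
      presence = rep(c(1L, 0L), each = n_pres)
    )
  })
}

# ---- model-family committee -------------------------------------------------

# Numeric design matrix: each numeric predictor contributes a linear and a
# squared column (so linear members can express unimodal responses); factor
# predictors are one-hot coded over their full level sets.
build_design <- function(df, quad = TRUE) {
  cols <- list()
  for (v in names(df)) {
    x <- df[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
      if (quad) cols[[paste0(v, "_sq")]] <- x^2
    } else {
      f <- if (is.factor(x)) x else factor(x)
      mm <- stats::model.matrix(~ f - 1)
      colnames(mm) <- paste0(v, levels(f))
      for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  do.call(cbind, cols)
}

#' The built-in model-family registry
#'
#' Four families spanning linear, tree, ensemble-of-trees and instance-based
#' learners: ridge-regularized logistic regression with quadratic terms
#' (`glm_quad`), a recursive-partitioning tree (`cart`), bagged trees
#' (`bagged`, a random forest with `mtry` equal to the predictor count), and
#' k-nearest neighbours (`knn`). Each family is a list with `fit(data, opts,
#' seed)` and `predict(fit, newdata)` returning per-row suitabilities in
#' [0, 1]; `data` carries the class in column `.presence` (factor "0"/"1").
#' Users can extend the committee by passing a modified registry to
#' [model_species()].
#'
#' @return Named list of family definitions.
#' @export
enm_families <- function() {
  list(
    glm_quad = list(
      fit = function(data, opts, seed) {
        x <- build_design(data[setdiff(names(data), ".presence")], quad = TRUE)
        fit <- glmnet::glmnet(x, data$.presence,
          family = "binomial", alpha = 0,
          lambda = opts$lambda, standardize = TRUE
        )
        list(fit = fit, lambda = opts$lambda)
      },
      predict = function(object, newdata) {
        x <- build_design(newdata, quad = TRUE)
        as.numeric(predict(object$fit, newx = x, s = object$lambda, type = "response"))
      }
    ),
    cart = list(
      fit = function(data, opts, seed) {
        with_seed(seed, rpart::rpart(
          .presence ~ ., data = data, method = "class",
          control = rpart::rpart.control(minbucket = 5, cp = 0.005, xval = 0)
        ))
      },
      predict = function(object, newdata) {
        predict(object, newdata = newdata, type = "prob")[, "1"]
      }
    ),
    bagged = list(
      fit = function(data, opts, seed) {
        pred <- data[setdiff(names(data), ".presence")]
        with_seed(seed, randomForest::randomForest(
          x = as.data.frame(pred), y = data$.presence,
          ntree = opts$ntree, mtry = ncol(pred)
        ))
      },
      predict = function(object, newdata) {
        predict(object, newdata = as.data.frame(newdata), type = "prob")[, "1"]
      }
    ),
    knn = list(
      fit = function(data, opts, seed) {
        x <- build_design(data[setdiff(names(data), ".presence")], quad = FALSE)
        ctr <- colMeans(x)
        scl <- apply(x, 2, sd)
        scl[scl == 0] <- 1
        list(
          x = scale(x, ctr, scl), y = data$.presence,
          ctr = ctr, scl = scl, k = opts$k, seed = seed
        )
      },
      predict = function(object, newdata) {
        xt <- scale(build_design(newdata, quad = FALSE), object$ctr, object$scl)
        cl <- with_seed(object$seed, class::knn(
          object$x, xt, object$y,
          k = object$k, prob = TRUE, use.all = TRUE
        ))
        p_win <- attr(cl, "prob")
        ifelse(cl == "1", p_win, 1 - p_win)
      }
    )
  )
}

#' Fit the committee on one training set
#'
#' @param data Tibble with factor column `.presence` ("0"/"1") and predictor
#'   columns.
#' @param opts [enm_options()] list.
#' @param families Family registry (default [enm_families()]); `opts$families`
#'   selects the committee from it.
#' @param seed Integer seed (fitting is deterministic given it).
#' @return Named list of fitted member objects.
#' @export
fit_members <- function(data, opts = enm_options(), families = enm_families(), seed = 1L) {
  fam <- opts$families
  if (length(fam) < 1) abort("need at least one model family")
  missing <- setdiff(fam, names(families))
  if (length(missing)) abort(sprintf("unknown families: %s", paste(missing, collapse = ", ")))
  if (dplyr::n_distinct(data$.presence) < 2) {
    abort("degenerate training set: single class")
  }
  out <- purrr::imap(families[fam], function(f, nm) {
    f$fit(data, opts, derive_seed(seed, match(nm, names(families))))
  })
  out
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' presence is scored above a randomly chosen absence, ties counting one
#' half.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) class labels, 1 = presence.
#' @return AUC in [0, 1].
#' @examples
#' evaluate_auc(c(0.7, 0.4, 0.6, 0.2), c(1, 1, 0, 0)) # 0.75
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.integer(as.character(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC undefined: hold-out contains a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC-weighted consensus projection
#'
#' Combines member probabilities into a consensus suitability: a weighted
#' mean over the members whose evaluation AUC reaches the floor, with
#' weights proportional to AUC (normalized to sum to one). Members below the
#' floor are excluded.
#'
#' @param members List of member records, each a list with elements `fit`
#'   (fitted object), `family` (registry name) and `auc`.
#' @param newdata Predictor tibble to project onto.
#' @param families Family registry used to fit the members.
#' @param auc_floor Minimum AUC for consensus membership.
#' @return Numeric consensus suitability per row of `newdata`, or `NULL` if
#'   no member reaches the floor.
#' @export
consensus_project <- function(members, newdata, families = enm_families(),
                              auc_floor = 0.7) {
  aucs <- purrr::map_dbl(members, "auc")
  keep <- which(aucs >= auc_floor)
  if (length(keep) == 0) return(NULL)
  w <- aucs[keep] / sum(aucs[keep])
  preds <- purrr::map(members[keep], function(mb) {
    families[[mb$family]]$predict(mb$fit, newdata)
  })
  Reduce(`+`, purrr::map2(preds, w, `*`))
}

#' Maximum-TSS binarization threshold
#'
#' Chooses the threshold maximizing the true skill statistic
#' (sensitivity + specificity - 1) over the unique calibration scores, with
#' the smallest maximizing threshold as tie-break. Presence is predicted
#' where score >= threshold.
#'
#' @param scores Calibration scores.
#' @param labels 0/1 labels (both classes required).
#' @return List with `threshold` and `tss`.
#' @export
tss_threshold <- function(scores, labels) {
  labels <- as.integer(as.character(labels))
  if (dplyr::n_distinct(labels) < 2) abort("binarization needs both classes")
  cand <- sort(unique(scores))
  tss <- purrr::map_dbl(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  })
  best <- max(tss)
  list(threshold = cand[which(tss == best)[1]], tss = best)
}

# ---- per-species driver -----------------------------------------------------

# Wide predictor table for one period: cell_id + the set's climate columns
# (+ soil columns for trees).
predictor_table <- function(climate, period, vars, soil = NULL, soil_vars = character(0)) {
  wide <- climate |>
    dplyr::filter(.data$period == !!period, .data$variable %in% vars) |>
    tidyr::pivot_wider(id_cols = "cell_id", names_from = "variable", values_from = "value") |>
    dplyr::arrange(.data$cell_id)
  if (length(soil_vars)) {
    wide <- dplyr::left_join(
      wide, dplyr::select(soil, "cell_id", dplyr::all_of(soil_vars)),
      by = "cell_id"
    )
  }
  wide
}

stratified_split <- function(labels, frac, seed) {
  with_seed(seed, {
    cal <- logical(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_cal <- max(1L, round(frac * length(idx)))
      cal[sample(idx, n_cal)] <- TRUE
    }
    cal
  })
}

#' Fit, evaluate and project the ensemble for one species
#'
#' End-to-end per-species workflow: build training sets (pseudo-absence
#' repetitions, or repeated splits of the real-absence table for trees),
#' fit the committee per repetition on a stratified calibration split,
#' evaluate each member by AUC on the held-out rows, combine members above
#' the AUC floor into an AUC-weighted consensus, project the consensus onto
#' the reference and future climates, and binarize both projections with a
#' single maximum-TSS threshold estimated on the pooled training cells.
#'
#' @param occ Occurrence tibble for one species (`cell_id`, `presence`; for
#'   tree-type species zeros are treated as real absences).
#' @param taxon Taxon group (`"tree"` switches to real absences).
#' @param climate Long climate tibble covering both periods.
#' @param predictor_vars Climate variable names to use as predictors.
#' @param grid A [make_grid()] grid.
#' @param soil Soil tibble (trees only).
#' @param soil_vars Soil covariate names (trees only).
#' @param opts [enm_options()].
#' @param families Family registry.
#' @param seed Integer seed.
#' @param species_id Label for reporting.
#' @return An object of class `enm_fit`: list with `species_id`, `taxon`,
#'   `status` (`"ok"`, `"skipped_few_presences"`, or `"unmodellable"`),
#'   `members` (tibble: `rep`, `family`, `auc`, `kept`, `weight`),
#'   `threshold`, `tss`, `n_presences`, and `maps` (tibble `cell_id`,
#'   `period`, `suitability`, `presence`) when status is `"ok"`.
#' @export
model_species <- function(occ, taxon, climate, predictor_vars, grid,
                          soil = NULL, soil_vars = character(0),
                          opts = enm_options(), families = enm_families(),
                          seed = 1L, species_id = occ$species_id[1] %||% "?") {
  pres_cells <- occ$cell_id[occ$presence == 1]
  res <- list(
    species_id = species_id, taxon = taxon, status = "ok",
    n_presences = length(pres_cells), members = NULL,
    threshold = NA_real_, tss = NA_real_, maps = NULL
  )
  class(res) <- "enm_fit"
  if (length(pres_cells) < opts$min_presences) {
    warn(sprintf(
      "species %s skipped: %d presences < %d required",
      species_id, length(pres_cells), opts$min_presences
    ))
    res$status <- "skipped_few_presences"
    return(res)
  }

  if (identical(taxon, "tree")) {
    base <- tibble::tibble(rep = 1L, cell_id = occ$cell_id, presence = occ$presence)
    train_sets <- purrr::map_dfr(seq_len(opts$n_rep), function(r) {
      dplyr::mutate(base, rep = r)
    })
  } else {
    train_sets <- tryCatch(
      select_pseudo_absences(
        pres_cells, grid,
        buffer_cells = opts$buffer_cells,
        n_rep = opts$n_rep, seed = derive_seed(seed, 11L),
        species_id = species_id
      ),
      error = function(e) e
    )
    if (inherits(train_sets, "error")) {
      # widespread species can exhaust the eligible pool; skip, don't abort
      warn(sprintf("species %s skipped: %s", species_id, conditionMessage(train_sets)))
      res$status <- "skipped_pseudo_absence_infeasible"
      return(res)
    }
  }

  ref_pred <- predictor_table(climate, "reference", predictor_vars, soil, soil_vars)
  fut_pred <- predictor_table(climate, "future", predictor_vars, soil, soil_vars)
  pred_cols <- setdiff(names(ref_pred), "cell_id")

  members <- list()
  for (r in seq_len(opts$n_rep)) {
    tr <- dplyr::filter(train_sets, .data$rep == r)
    data <- ref_pred[match(tr$cell_id, ref_pred$cell_id), pred_cols, drop = FALSE]
    data$.presence <- factor(tr$presence, levels = c(0, 1))
    cal <- stratified_split(tr$presence, opts$split, derive_seed(seed, 22L, r))
    cal_data <- data[cal, , drop = FALSE]
    eval_data <- data[!cal, , drop = FALSE]
    if (dplyr::n_distinct(eval_data$.presence) < 2 ||
      dplyr::n_distinct(cal_data$.presence) < 2) {
      warn(sprintf("species %s rep %d: degenerate split, repetition dropped", species_id, r))
      next
    }
    fits <- fit_members(cal_data, opts, families, seed = derive_seed(seed, 33L, r))
    for (nm in names(fits)) {
      sc <- families[[nm]]$predict(fits[[nm]], eval_data[pred_cols])
      members[[length(members) + 1]] <- list(
        rep = r, family = nm, fit = fits[[nm]],
        auc = evaluate_auc(sc, eval_data$.presence)
      )
    }
  }

  member_tbl <- tibble::tibble(
    rep = purrr::map_int(members, ~ as.integer(.x$rep)),
    family = purrr::map_chr(members, "family"),
    auc = purrr::map_dbl(members, "auc")
  ) |>
    dplyr::mutate(
      kept = .data$auc >= opts$auc_floor,
      weight = ifelse(.data$kept, .data$auc / sum(.data$auc[.data$kept]), 0)
    )
  res$members <- member_tbl
  if (!any(member_tbl$kept)) {
    warn(sprintf("species %s unmodellable: no member reached AUC floor %g", species_id, opts$auc_floor))
    res$status <- "unmodellable"
    return(res)
  }

  cons_ref <- consensus_project(members, ref_pred[pred_cols], families, opts$auc_floor)
  cons_fut <- consensus_project(members, fut_pred[pred_cols], families, opts$auc_floor)

  # single threshold from the pooled training cells, applied to both periods
  calib <- dplyr::distinct(train_sets, .data$cell_id, .data$presence)
  thr <- tss_threshold(cons_ref[match(calib$cell_id, ref_pred$cell_id)], calib$presence)
  res$threshold <- thr$threshold
  res$tss <- thr$tss
  res$maps <- dplyr::bind_rows(
    tibble::tibble(
      cell_id = ref_pred$cell_id, period = "reference",
      suitability = cons_ref, presence = as.integer(cons_ref >= thr$threshold)
    ),
    tibble::tibble(
      cell_id = fut_pred$cell_id, period = "future",
      suitability = cons_fut, presence = as.integer(cons_fut >= thr$threshold)
    )
  )
  res
}

#' @export
print.enm_fit <- function(x, ...) {
  cat(sprintf(
    "<enm_fit> %s (%s): status %s, %d presences",
    x$species_id, x$taxon, x$status, x$n_presences
  ))
  if (!is.null(x$members) && nrow(x$members)) {
    cat(sprintf(
      ", %d/%d members kept (mean AUC %.3f), threshold %.3f",
      sum(x$members$kept), nrow(x$members), mean(x$members$auc), x$threshold
    ))
  }
  cat("\n")
  invisible(x)
}

#' Model every species of a landscape
#'
#' Runs [model_species()] over all species of a synthetic (or ingested)
#' landscape using per-taxon predictor sets, and collects binary/continuous
#' maps and a model report.
#'
#' @param land A `synthetic_landscape` (or a list with the same elements).
#' @param predictor_sets Tibble from [build_predictor_sets()].
#' @param opts [enm_options()].
#' @param families Family registry.
#' @param seed Integer seed (defaults to the landscape's).
#' @return List with `fits` (named list of `enm_fit`), `maps` (tibble
#'   `species_id`, `cell_id`, `period`, `suitability`, `presence` over
#'   successfully modelled species) and `report` (one [glance()] row per
#'   species).
#' @export
model_all_species <- function(land, predictor_sets = build_predictor_sets(land$climate),
                              opts = enm_options(), families = enm_families(),
                              seed = NULL) {
  seed <- as.integer(seed %||% land$seed %||% 1L)
  fits <- purrr::imap(split(land$occurrences, land$occurrences$species_id)[land$species$species_id], function(occ, sid) {
    sp <- land$species[land$species$species_id == sid, ]
    pset <- dplyr::filter(predictor_sets, .data$taxon == sp$taxon)
    model_species(
      occ,
      taxon = sp$taxon, climate = land$climate,
      predictor_vars = pset$variable[pset$kind == "climate"],
      grid = land$grid, soil = land$soil,
      soil_vars = pset$variable[pset$kind == "soil"],
      opts = opts, families = families,
      seed = derive_seed(seed, 77L, match(sid, land$species$species_id)),
      species_id = sid
    )
  })
  maps <- purrr::map_dfr(fits, function(f) {
    if (f$status != "ok") return(NULL)
    dplyr::mutate(f$maps, species_id = f$species_id, .before = 1)
  })
  report <- purrr::map_dfr(fits, glance)
  list(fits = fits, maps = maps, report = report)
}
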