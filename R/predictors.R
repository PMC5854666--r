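#' Pairwise Pearson correlations between climate variables
#'
#' Computes the correlation matrix over cells for one period of a long-format
#' climate table. Constant variables make Pearson r undefined and are
#' reported as an error naming the offending variable.
#'
#' @param climate Long tibble (`cell_id`, `variable`, `period`, `value`).
#' @param period Period to use (default `"reference"`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(climate, period = "reference") {
  wide <- climate |>
    dplyr::filter(.data$period == !!period) |>
    tidyr::pivot_wider(
      id_cols = "cell_id", names_from = "variable", values_from = "value"
    ) |>
    dplyr::arrange(.data$cell_id) |>
    dplyr::select(-"cell_id")
  if (ncol(wide) < 2) abort("need at least two variables")
  if (nrow(wide) < 3) abort("need at least three cells")
  sds <- purrr::map_dbl(wide, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "constant variable(s): %s — Pearson correlation undefined",
      paste(names(wide)[sds == 0], collapse = ", ")
    ))
  }
  cor(as.matrix(wide))
}

#' Greedy collinearity screen on a correlation matrix
#'
#' Scans candidates in priority order and retains a variable iff its absolute
#' correlation with every already-retained variable is strictly below the
#' threshold. The retained set therefore satisfies |r| < threshold for all
#' pairs; retention order is the priority order. Greedy screening is
#' deterministic but not guaranteed maximum-cardinality.
#'
#' @param cmat Correlation matrix (symmetric, named dims).
#' @param threshold Screening threshold in (0, 1]; pairs at exactly the
#'   threshold are rejected (strict inequality).
#' @param priority Candidate labels in decreasing priority; defaults to the
#'   matrix column order. Must cover all candidates.
#' @return Character vector of retained variable labels, in retention order.
#' @examples
#' m <- diag(3)
#' dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
#' m["a", "b"] <- m["b", "a"] <- 0.9
#' correlation_filter(m, 0.6) # a and c survive, b is dropped
#' @export
correlation_filter <- function(cmat, threshold = 0.6, priority = colnames(cmat)) {
  if (length(threshold) != 1 || is.na(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must be in (0, 1]")
  }
  if (!setequal(priority, colnames(cmat)) || length(priority) != ncol(cmat)) {
    abort("`priority` must be a permutation of the candidate labels")
  }
  retained <- character(0)
  for (v in priority) {
    if (all(abs(cmat[v, retained]) < threshold)) {
      retained <- c(retained, v)
    }
  }
  retained
}

#' Assemble per-taxon predictor sets
#'
#' Runs the correlation screen once per taxon over that taxon's candidate
#' climate variables and appends the categorical soil covariates for
#' tree-type species (soil layers are categorical and bypass the Pearson
#' screen). Defaults give the first three candidates to birds and
#' amphibians and four to trees and other plants, mirroring a three-to-four
#' variable design.
#'
#' @param climate Long climate tibble (reference period is screened).
#' @param candidates Named list: taxon -> character vector of candidate
#'   variables, in priority order. Missing taxa fall back to `default_vars`.
#' @param taxa Taxa to build sets for.
#' @param default_vars Fallback candidate order (defaults to all variables in
#'   the climate table).
#' @param threshold Screening threshold (see [correlation_filter()]).
#' @param soil_vars Categorical covariate names appended for trees.
#' @return Tibble `taxon`, `variable`, `kind` (`"climate"`/`"soil"`),
#'   `rank` (retention order).
#' @export
build_predictor_sets <- function(climate,
                                 candidates = NULL,
                                 taxa = c("bird", "amphibian", "tree", "other_plant"),
                                 default_vars = NULL,
                                 threshold = 0.6,
                                 soil_vars = c("deposit", "drainage")) {
  all_vars <- unique(climate$variable)
  default_vars <- default_vars %||% all_vars
  n_default <- c(bird = 3, amphibian = 3, tree = 4, other_plant = 4)
  cmat <- pairwise_correlation(climate)
  purrr::map_dfr(taxa, function(tx) {
    cand <- candidates[[tx]] %||%
      head(default_vars, n_default[[tx]] %||% length(default_vars))
    cand <- intersect(cand, all_vars)
    if (length(cand) < 1) abort(sprintf("no candidate variables for taxon '%s'", tx))
    kept <- if (length(cand) == 1) cand else {
      correlation_filter(cmat[cand, cand, drop = FALSE], threshold, priority = cand)
    }
    out <- tibble::tibble(
      taxon = tx, variable = kept, kind = "climate", rank = seq_along(kept)
    )
    if (tx == "tree" && length(soil_vars)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        taxon = tx, variable = soil_vars, kind = "soil",
        rank = length(kept) + seq_along(soil_vars)
      ))
    }
    out
  })
}
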