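#' Tidy an ensemble fit
#'
#' One row per fitted committee member: repetition, family, evaluation AUC,
#' whether the member reached the consensus floor, and its normalized
#' consensus weight.
#'
#' @param x An `enm_fit` from [model_species()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy enm_fit
#' @export
tidy.enm_fit <- function(x, ...) {
  if (is.null(x$members) || nrow(x$members) == 0) {
    return(tibble::tibble(
      species_id = character(), rep = integer(), family = character(),
      auc = double(), kept = logical(), weight = double()
    ))
  }
  dplyr::mutate(x$members, species_id = x$species_id, .before = 1)
}

#' One-row summary of an ensemble fit
#'
#' @param x An `enm_fit` from [model_species()].
#' @param ... Unused.
#' @return A tibble with `species_id`, `taxon`, `status`, `n_presences`,
#'   `n_members`, `n_kept`, `mean_auc`, `max_auc`, `threshold`, `tss`.
#' @method glance enm_fit
#' @export
glance.enm_fit <- function(x, ...) {
  mb <- x$members
  tibble::tibble(
    species_id = x$species_id,
    taxon = x$taxon,
    status = x$status,
    n_presences = x$n_presences,
    n_members = if (is.null(mb)) 0L else nrow(mb),
    n_kept = if (is.null(mb)) 0L else sum(mb$kept),
    mean_auc = if (is.null(mb) || !nrow(mb)) NA_real_ else mean(mb$auc),
    max_auc = if (is.null(mb) || !nrow(mb)) NA_real_ else max(mb$auc),
    threshold = x$threshold,
    tss = x$tss
  )
}
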