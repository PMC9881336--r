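#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted gait mixed model
#'
#' @param x A `gait_lmm` object.
#' @param ... Unused.
#' @return Tibble with one row per fixed effect: `metric`, `term`,
#'   `estimate`, `std_error`, `df`, `p_value`.
#' @method tidy gait_lmm
#' @export
tidy.gait_lmm <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(metric = x$metric), x$coefficients)
}

#' One-row summary of a fitted gait mixed model
#'
#' @param x A `gait_lmm` object.
#' @param ... Unused.
#' @return Tibble with `metric`, `estimator`, `sigma_b`, `sigma_e`,
#'   `n_obs`, `n_participants`, `converged`, `singular`.
#' @method glance gait_lmm
#' @export
glance.gait_lmm <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, estimator = x$estimator,
    sigma_b = x$sigma_b, sigma_e = x$sigma_e,
    n_obs = x$n_obs, n_participants = x$n_participants,
    converged = x$converged, singular = x$singular
  )
}

#' Tidy a clustering result
#'
#' @param x A `gait_clusters` object.
#' @param ... Unused.
#' @return Tibble with one row per participant: `participant_id`,
#'   `cluster`, `pc1`, `pc2`.
#' @method tidy gait_clusters
#' @export
tidy.gait_clusters <- function(x, ...) {
  tibble::tibble(
    participant_id = names(x$labels),
    cluster = unname(x$labels),
    pc1 = x$pca_scores[, 1],
    pc2 = x$pca_scores[, 2]
  )
}

#' One-row summary of a clustering result
#'
#' @param x A `gait_clusters` object.
#' @param ... Unused.
#' @return Tibble with `condition`, `k`, `n`, `wss_total`, `bss`, `tss`,
#'   `mean_silhouette` (of the chosen k, when selection was run).
#' @method glance gait_clusters
#' @export
glance.gait_clusters <- function(x, ...) {
  tibble::tibble(
    condition = x$condition, k = x$chosen_k, n = length(x$labels),
    wss_total = x$wss_total, bss = x$bss, tss = x$tss,
    mean_silhouette = if (!is.null(x$silhouette_by_k)) {
      unname(x$silhouette_by_k[as.character(x$chosen_k)])
    } else NA_real_
  )
}

#' Combine fits from [fit_all_metrics()] into one tidy table
#'
#' @param fits Named list of `gait_lmm` objects.
#' @return Tibble with one row per metric and term.
#' @export
tidy_metric_fits <- function(fits) {
  purrr::map_dfr(fits, tidy)
}
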