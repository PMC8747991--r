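#' Majority (plurality) rating for one drug pair
#'
#' The reference rating against which each resource's rating is
#' judged: the strict plurality among the non-`unrated` standardized
#' ratings cast for the pair. No majority exists — and `NA` is
#' returned — when fewer than `min_raters` resources rate the pair
#' (sparse coverage falls outside the consistency assessment) or when
#' the top count is tied (a tie defines no reference standard).
#'
#' @param matrix Standardized evidence-matrix tibble.
#' @param pair_id Pair to tally.
#' @param component `"severity"` or `"course_of_action"`.
#' @param min_raters Minimum number of cast ratings (default 3,
#'   excluding pairs covered by two or fewer resources).
#' @param mode `"plurality"` (default) or `"absolute"`: absolute
#'   requires the top category to exceed half the cast ratings.
#' @return A single category label, or `NA_character_`.
#' @export
majority_rating <- function(matrix, pair_id, component =
                              c("severity", "course_of_action"),
                            min_raters = 3,
                            mode = c("plurality", "absolute")) {
  component <- match.arg(component)
  mode <- match.arg(mode)
  col <- if (component == "severity") "severity_std" else "action_std"
  ratings <- matrix[[col]][matrix$pair_id == pair_id]
  ratings <- ratings[ratings != "unrated"]
  majority_of(ratings, min_raters, mode)
}

#' @keywords internal
majority_of <- function(ratings, min_raters, mode = "plurality") {
  if (length(ratings) < min_raters) return(NA_character_)
  tab <- sort(table(ratings), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
  if (mode == "absolute" && tab[1] * 2 <= length(ratings)) {
    return(NA_character_)
  }
  names(tab)[1]
}

#' Majority-vote consistency scores per resource
#'
#' For each resource, the fraction of its ratings that match the
#' majority rating across resources for the same pair. A pair is
#' eligible for a resource when the resource cast a non-`unrated`
#' rating and a majority exists (see [majority_rating()]). For
#' severity, a `minor` rating still participates in the vote tally but
#' is always scored inconsistent for the resource that cast it, even
#' when minor wins the plurality: minor-severity pairs fall outside
#' the moderate-to-contraindicated frame, so a minor call can never be
#' confirmed consistent (switch off with `minor_inconsistent =
#' FALSE`).
#'
#' @param matrix Standardized evidence-matrix tibble.
#' @param component `"severity"` or `"course_of_action"`.
#' @param min_raters Minimum cast ratings for a majority (default 3).
#' @param mode Majority mode, see [majority_rating()].
#' @param minor_inconsistent Score `minor` severity ratings as always
#'   inconsistent (default `TRUE`)?
#' @param decimals Decimals kept by the truncated `percent` column.
#' @return Tibble: `resource_id`, `component`, `n_consistent`,
#'   `n_eligible`, `percent` (NA when no eligible pair).
#' @export
consistency_scores <- function(matrix, component =
                                 c("severity", "course_of_action"),
                               min_raters = 3,
                               mode = c("plurality", "absolute"),
                               minor_inconsistent = TRUE,
                               decimals = 1) {
  component <- match.arg(component)
  mode <- match.arg(mode)
  col <- if (component == "severity") "severity_std" else "action_std"
  if (!col %in% names(matrix)) {
    rlang::abort("matrix must be standardized first (see apply_standardization)",
                 class = "ddi_schema_error")
  }
  rated <- matrix |>
    dplyr::filter(.data[[col]] != "unrated") |>
    dplyr::select("pair_id", "resource_id", rating = dplyr::all_of(col))
  majorities <- rated |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(majority = majority_of(.data$rating, min_raters, mode),
                     .groups = "drop")
  scored <- rated |>
    dplyr::left_join(majorities, by = "pair_id") |>
    dplyr::filter(!is.na(.data$majority)) |>
    dplyr::mutate(
      consistent = .data$rating == .data$majority &
        !(component == "severity" & minor_inconsistent &
            .data$rating == "minor")
    )
  all_res <- levels(order_resources(matrix$resource_id))
  tibble::tibble(resource_id = all_res) |>
    dplyr::left_join(
      scored |>
        dplyr::group_by(.data$resource_id) |>
        dplyr::summarise(
          n_consistent = sum(.data$consistent),
          n_eligible = dplyr::n(), .groups = "drop"
        ),
      by = "resource_id"
    ) |>
    dplyr::mutate(
      component = component,
      n_consistent = dplyr::coalesce(.data$n_consistent, 0L),
      n_eligible = dplyr::coalesce(.data$n_eligible, 0L),
      percent = ifelse(.data$n_eligible > 0,
                       truncate_percent(.data$n_consistent,
                                        pmax(.data$n_eligible, 1), decimals),
                       NA_real_)
    ) |>
    dplyr::select("resource_id", "component", "n_consistent",
                  "n_eligible", "percent")
}
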