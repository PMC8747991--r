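#' Run the full concordance pipeline
#'
#' Validates an evidence matrix, harmonizes its severity and
#' course-of-action labels, and computes every concordance endpoint:
#' per-resource scope, per-component and overall completeness,
#' pairwise McNemar (scope) and Wilcoxon signed-rank (completeness)
#' comparisons, completeness tiers, majority-vote consistency for
#' severity and course of action, and per-component Fleiss kappa.
#'
#' @param matrix Evidence-matrix tibble (raw labels), e.g. from
#'   [read_matrix_csv()] or [generate_matrix()].
#' @param map Harmonization map (default [default_severity_map()]).
#' @param min_raters Minimum cast ratings for a consistency majority.
#' @param alpha Significance level for tier separation.
#' @param kappa_mode `"variable_raters"` or `"complete_case"`.
#' @param percent_decimals Decimals kept by truncated percentages in
#'   the scope table (completeness/consistency tables use 1).
#' @param holm Add Holm-adjusted p-values to the pairwise table?
#' @return A list of class `ddi_report` with tibbles `scope`,
#'   `completeness`, `consistency`, `kappa`, `pairwise`, `tiers`, and
#'   a `params` list.
#' @export
run_pipeline <- function(matrix, map = default_severity_map(),
                         min_raters = 3, alpha = 0.05,
                         kappa_mode = "variable_raters",
                         percent_decimals = 2, holm = FALSE) {
  assert_valid_matrix(dplyr::select(matrix, -dplyr::any_of(
    c("severity_std", "action_std"))))
  std <- apply_standardization(matrix, map)
  scope <- scope_scores(std, decimals = percent_decimals)
  completeness <- completeness_summary(std)
  pairwise <- pairwise_tests(std, holm = holm)
  tiers <- assign_tiers(completeness, pairwise, alpha = alpha)
  consistency <- dplyr::bind_rows(
    consistency_scores(std, "severity", min_raters = min_raters),
    consistency_scores(std, "course_of_action", min_raters = min_raters)
  )
  kappa <- kappa_components(std, mode = kappa_mode)
  structure(
    list(
      scope = scope,
      completeness = dplyr::select(completeness, -"scores"),
      consistency = consistency,
      kappa = kappa,
      pairwise = pairwise,
      tiers = tiers,
      params = list(min_raters = min_raters, alpha = alpha,
                    kappa_mode = kappa_mode,
                    percent_decimals = percent_decimals, holm = holm)
    ),
    class = "ddi_report"
  )
}

#' @export
print.ddi_report <- function(x, ...) {
  cat("DDI concordance report\n\nScope:\n")
  print(x$scope)
  cat("\nCompleteness (median [Q1, Q3]):\n")
  print(dplyr::select(x$completeness, "resource_id", "n_present",
                      "median", "q1", "q3"))
  cat("\nConsistency:\n")
  print(x$consistency)
  cat("\nInter-resource agreement (Fleiss kappa):\n")
  print(tibble::as_tibble(x$kappa))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits each table of a [run_pipeline()] report as TSV and JSON,
#' plus a `run_info.json` with the parameters. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param report A `ddi_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ddi_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("scope", "completeness", "consistency", "kappa",
              "pairwise", "tiers")
  for (tb in tables) {
    tab <- tibble::as_tibble(report[[tb]])
    readr::write_tsv(tab, file.path(dir, paste0(tb, ".tsv")),
                     progress = FALSE)
    jsonlite::write_json(tab, file.path(dir, paste0(tb, ".json")),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  jsonlite::write_json(report$params, file.path(dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Plot per-resource scope scores
#'
#' @param scope Output of [scope_scores()].
#' @return A ggplot.
#' @export
plot_scope <- function(scope) {
  ggplot2::ggplot(scope, ggplot2::aes(
    x = stats::reorder(.data$resource_id, -.data$percent),
    y = .data$percent
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Scope (% of pairs with an entry)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot per-component completeness percentages
#'
#' @param completeness Output of [completeness_summary()].
#' @return A ggplot (resources x components tile map).
#' @export
plot_completeness <- function(completeness) {
  long <- completeness |>
    dplyr::select("resource_id", dplyr::ends_with("_pct")) |>
    tidyr::pivot_longer(-"resource_id", names_to = "component",
                        values_to = "percent") |>
    dplyr::mutate(component = sub("_pct$", "", .data$component))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$component, y = .data$resource_id, fill = .data$percent
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$percent), "-",
                     formatC(.data$percent, format = "f", digits = 1))
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "% documented") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot consistency scores
#'
#' @param consistency Stacked output of [consistency_scores()].
#' @return A ggplot (grouped bars by component).
#' @export
plot_consistency <- function(consistency) {
  ggplot2::ggplot(consistency, ggplot2::aes(
    x = .data$resource_id, y = .data$percent, fill = .data$component
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Consistency with majority (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest-style plot of per-component kappa estimates
#'
#' @param object A `ddi_kappa_tbl` from [kappa_components()].
#' @param ... Unused.
#' @return A ggplot with point estimates, confidence intervals, and
#'   Landis-Koch band cut-offs.
#' @export
autoplot.ddi_kappa_tbl <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$kappa))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$kappa, y = stats::reorder(.data$component, .data$kappa)
  )) +
    ggplot2::geom_vline(xintercept = c(0.2, 0.4, 0.6, 0.8),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$ci_low, xmax = .data$ci_high
    ), height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$band), size = 2.5) +
    ggplot2::labs(x = "Fleiss' kappa", y = NULL, colour = "Agreement") +
    ggplot2::theme_minimal()
}

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL
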