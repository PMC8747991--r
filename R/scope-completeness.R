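#' Truncate a ratio to a printed percentage
#'
#' Report tables print percentages truncated — not rounded — to a
#' fixed number of decimals (115/181 prints as 63.53, not 63.54; the
#' same convention at one decimal turns 85/181 = 46.96 into 46.9).
#' `format_percent()` gives the printed string; `truncate_percent()`
#' the numeric value.
#'
#' @param numerator,denominator Counts; `denominator > 0`.
#' @param decimals Decimal places kept (default 2).
#' @return `format_percent()`: character; `truncate_percent()`: numeric.
#' @export
#' @examples
#' format_percent(115, 181, 2)
#' format_percent(36, 70, 2)
format_percent <- function(numerator, denominator, decimals = 2) {
  val <- truncate_percent(numerator, denominator, decimals)
  formatC(val, format = "f", digits = decimals)
}

#' @rdname format_percent
#' @export
truncate_percent <- function(numerator, denominator, decimals = 2) {
  if (any(denominator <= 0)) {
    rlang::abort("denominator must be positive", class = "ddi_schema_error")
  }
  scale <- 10^decimals
  # 1e-9 guards against floor() eating an exact ratio to float error
  floor(100 * numerator / denominator * scale + 1e-9) / scale
}

#' Per-resource scope scores
#'
#' Scope is the presence of an interaction entry in a resource,
#' reported as the percentage of evaluated drug pairs that have an
#' entry. The denominator is always the full pair sample.
#'
#' @param matrix Evidence-matrix tibble.
#' @param decimals Decimals kept by the truncated `percent` column.
#' @return Tibble: `resource_id`, `n_present`, `n_total`, `percent`,
#'   one row per resource in canonical-first order.
#' @export
scope_scores <- function(matrix, decimals = 2) {
  assert_valid_matrix(matrix)
  if (nrow(matrix) == 0) {
    rlang::abort("empty evidence matrix", class = "ddi_schema_error")
  }
  n_total <- dplyr::n_distinct(matrix$pair_id)
  matrix |>
    dplyr::group_by(resource_id = order_resources(.data$resource_id)) |>
    dplyr::summarise(n_present = sum(.data$present), .groups = "drop") |>
    dplyr::arrange(.data$resource_id) |>
    dplyr::mutate(
      resource_id = as.character(.data$resource_id),
      n_total = n_total,
      percent = truncate_percent(.data$n_present, n_total, decimals)
    )
}

# Canonical six first (fixed report order), then others alphabetically.
#' @keywords internal
order_resources <- function(ids) {
  lev <- c(intersect(ddi_resources(), unique(ids)),
           sort(setdiff(unique(ids), ddi_resources())))
  factor(ids, levels = lev)
}

# Tukey inclusive (median-of-halves) quartiles; the median is shared
# by both halves when n is odd.
#' @keywords internal
quartiles_tukey <- function(x) {
  x <- sort(x)
  n <- length(x)
  lower <- x[seq_len(ceiling(n / 2))]
  upper <- x[seq.int(floor(n / 2) + 1, n)]
  c(q1 = stats::median(lower), median = stats::median(x),
    q3 = stats::median(upper))
}

#' Per-resource completeness summary
#'
#' Completeness asks whether an entry clearly documents each of five
#' components: mechanism, clinical effects, severity, level of
#' documentation, and course of action. Component percentages use the
#' resource's entry count (`n_present`) as denominator; the overall
#' score per entry is the number of documented components (0-5),
#' summarized by its median and Tukey inclusive quartiles.
#'
#' @param matrix Evidence-matrix tibble.
#' @param decimals Decimals kept by the truncated percentages.
#' @return Tibble with one row per resource: `resource_id`,
#'   `n_present`, per-component `<component>_n` and `<component>_pct`,
#'   `median`, `q1`, `q3`, and a `scores` list-column holding the
#'   multiset of 0-5 entry scores. Resources without any entry get
#'   `NA` percentages and quartiles and raise a warning.
#' @export
completeness_summary <- function(matrix, decimals = 1) {
  assert_valid_matrix(matrix)
  flags <- component_cols()
  short <- sub("^has_", "", flags)
  present <- dplyr::filter(matrix, .data$present)
  all_res <- levels(order_resources(matrix$resource_id))
  empty <- setdiff(all_res, unique(present$resource_id))
  if (length(empty) > 0) {
    rlang::warn(paste0(
      "resource(s) without any entry; completeness undefined: ",
      paste(empty, collapse = ", ")
    ), class = "ddi_empty_resource_warning")
  }
  rows <- purrr::map(all_res, function(res) {
    sub <- dplyr::filter(present, .data$resource_id == res)
    n <- nrow(sub)
    counts <- if (n > 0) unname(colSums(as.matrix(sub[flags]))) else
      rep(NA_real_, 5)
    pcts <- if (n > 0) truncate_percent(counts, n, decimals) else
      rep(NA_real_, 5)
    scores <- if (n > 0) as.integer(rowSums(as.matrix(sub[flags]))) else
      integer()
    qs <- if (n > 0) quartiles_tukey(scores) else
      c(q1 = NA_real_, median = NA_real_, q3 = NA_real_)
    out <- tibble::tibble(resource_id = res, n_present = n)
    for (k in seq_along(short)) {
      out[[paste0(short[k], "_n")]] <- as.integer(counts[k])
      out[[paste0(short[k], "_pct")]] <- pcts[k]
    }
    out$median <- qs[["median"]]
    out$q1 <- qs[["q1"]]
    out$q3 <- qs[["q3"]]
    out$scores <- list(scores)
    out
  })
  dplyr::bind_rows(rows)
}

#' Compare two resources' scope with McNemar's test
#'
#' Presence/absence of an entry is paired over the same drug pairs;
#' the discordant counts (pairs covered by one resource only) drive
#' [mcnemar_test()]. Symmetric in its two resource arguments.
#'
#' @param matrix Evidence-matrix tibble.
#' @param resource_a,resource_b Resource ids present in the matrix.
#' @param method Passed to [mcnemar_test()].
#' @return One-row tibble: `resource_a`, `resource_b`, `test_name`,
#'   `method`, `statistic`, `p_value`, `n_effective`, `degenerate`.
#' @export
compare_scope <- function(matrix, resource_a, resource_b,
                          method = c("auto", "exact", "asymptotic")) {
  wide <- presence_wide(matrix, resource_a, resource_b)
  b <- sum(wide$a & !wide$b)
  c_ <- sum(!wide$a & wide$b)
  res <- mcnemar_test(b, c_, method = method)
  tibble::tibble(resource_a = resource_a, resource_b = resource_b, res)
}

#' @keywords internal
presence_wide <- function(matrix, resource_a, resource_b) {
  for (r in c(resource_a, resource_b)) {
    if (!r %in% matrix$resource_id) {
      rlang::abort(paste0("resource '", r, "' not in matrix"),
                   class = "ddi_schema_error")
    }
  }
  matrix |>
    dplyr::filter(.data$resource_id %in% c(resource_a, resource_b)) |>
    dplyr::select("pair_id", "resource_id", "present") |>
    tidyr::pivot_wider(names_from = "resource_id",
                       values_from = "present") |>
    dplyr::rename(a = dplyr::all_of(resource_a),
                  b = dplyr::all_of(resource_b))
}

#' Compare two resources' overall completeness with a signed-rank test
#'
#' Overall 0-5 completeness scores are paired over the drug pairs
#' covered by both resources (absent entries have no score, so no
#' imputation is attempted); the paired differences go to
#' [wilcoxon_signed_rank()].
#'
#' @inheritParams compare_scope
#' @param method Passed to [wilcoxon_signed_rank()].
#' @return One-row tibble as in [compare_scope()] with
#'   `test_name = "wilcoxon"`; `n_effective` counts non-zero paired
#'   differences.
#' @export
compare_completeness <- function(matrix, resource_a, resource_b,
                                 method = c("auto", "exact", "normal")) {
  flags <- component_cols()
  both <- matrix |>
    dplyr::filter(.data$resource_id %in% c(resource_a, resource_b),
                  .data$present) |>
    dplyr::mutate(score = rowSums(dplyr::across(dplyr::all_of(flags)))) |>
    dplyr::select("pair_id", "resource_id", "score") |>
    tidyr::pivot_wider(names_from = "resource_id", values_from = "score") |>
    dplyr::filter(!is.na(.data[[resource_a]]), !is.na(.data[[resource_b]]))
  if (nrow(both) == 0) {
    rlang::abort(
      paste0("no drug pair is covered by both '", resource_a, "' and '",
             resource_b, "'"),
      class = "ddi_degenerate_error"
    )
  }
  d <- both[[resource_a]] - both[[resource_b]]
  res <- wilcoxon_signed_rank(d, method = method)
  tibble::tibble(resource_a = resource_a, resource_b = resource_b, res)
}

#' All pairwise scope and completeness comparisons
#'
#' Runs [compare_scope()] and [compare_completeness()] over every
#' unordered pair of resources. No multiplicity correction is applied
#' by default (each comparison is reported at its nominal level); set
#' `holm = TRUE` to add a Holm-adjusted p-value column.
#'
#' @param matrix Evidence-matrix tibble.
#' @param holm Add `p_adjusted` (Holm, within each test family)?
#' @return Tibble of stacked pairwise results.
#' @export
pairwise_tests <- function(matrix, holm = FALSE) {
  res <- levels(order_resources(matrix$resource_id))
  combos <- utils::combn(res, 2, simplify = FALSE)
  scope <- purrr::map(combos, ~ compare_scope(matrix, .x[1], .x[2]))
  compl <- purrr::map(combos, function(ab) {
    tryCatch(compare_completeness(matrix, ab[1], ab[2]),
             ddi_degenerate_error = function(e) NULL)
  })
  out <- dplyr::bind_rows(dplyr::bind_rows(scope), dplyr::bind_rows(compl))
  if (holm) {
    out <- out |>
      dplyr::group_by(.data$test_name) |>
      dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup()
  }
  out
}

#' Group resources into completeness tiers
#'
#' Resources are ordered by median overall completeness (then Q1, Q3,
#' then name) and grouped greedily: a resource joins the current tier
#' iff its pairwise signed-rank p-value against every member already
#' in the tier is at least `alpha`; otherwise it starts a new tier.
#' This is a reporting convention for ranking resources, not a formal
#' multiple-comparison inference.
#'
#' @param completeness Output of [completeness_summary()].
#' @param pairwise Output of [pairwise_tests()] (the `wilcoxon` rows
#'   are used).
#' @param alpha Significance level separating tiers (default 0.05).
#' @return Tibble: `resource_id`, `tier` (1 = most complete),
#'   `median`, `q1`, `q3`.
#' @export
assign_tiers <- function(completeness, pairwise, alpha = 0.05) {
  wil <- dplyr::filter(pairwise, .data$test_name == "wilcoxon")
  p_lookup <- function(a, b) {
    hit <- wil$p_value[(wil$resource_a == a & wil$resource_b == b) |
                         (wil$resource_a == b & wil$resource_b == a)]
    if (length(hit) == 0) {
      rlang::abort(paste0("no pairwise completeness test for (", a, ", ",
                          b, ")"), class = "ddi_schema_error")
    }
    hit[1]
  }
  ranked <- completeness |>
    dplyr::arrange(dplyr::desc(.data$median), dplyr::desc(.data$q1),
                   dplyr::desc(.data$q3), .data$resource_id)
  tier <- integer(nrow(ranked))
  current <- character()
  t <- 0L
  for (i in seq_len(nrow(ranked))) {
    res <- ranked$resource_id[i]
    joins <- length(current) > 0 &&
      all(purrr::map_dbl(current, ~ p_lookup(res, .x)) >= alpha)
    if (!joins) {
      t <- t + 1L
      current <- character()
    }
    current <- c(current, res)
    tier[i] <- t
  }
  tibble::tibble(
    resource_id = ranked$resource_id, tier = tier,
    median = ranked$median, q1 = ranked$q1, q3 = ranked$q3
  )
}
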