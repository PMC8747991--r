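#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for categorical ratings by two or more
#' raters. The input is a subjects-by-categories count table `n_ij`
#' (how many raters assigned subject i to category j). Per-subject
#' agreement is
#' `P_i = [sum_j n_ij (n_ij - 1)] / [n_i (n_i - 1)]` with
#' `n_i = sum_j n_ij`; overall agreement is the mean of the `P_i`;
#' chance agreement is `Pe = sum_j p_j^2` with `p_j` the pooled
#' category proportions; and `kappa = (P - Pe) / (1 - Pe)`.
#'
#' Two rater-count modes are provided because compendia cover
#' different drug pairs: `variable_raters` keeps every subject rated
#' by at least two raters and uses the per-subject `n_i`
#' generalization above; `complete_case` keeps only subjects rated by
#' the full rater panel (all `n_i` equal).
#'
#' The standard error is the Fleiss (1971) fixed-marginal null
#' variance (with the mean rater count substituted for `n` when rater
#' counts vary); the z test is of H0: kappa = 0 and the confidence
#' interval is `kappa +/- z * SE`.
#'
#' @param table Numeric matrix or data frame, subjects x categories,
#'   of assignment counts.
#' @param mode `"variable_raters"` (default) or `"complete_case"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `ddi_kappa`: a list with `kappa`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `band`, `n_subjects`,
#'   `n_excluded`, `mode`, `conf_level`.
#' @export
#' @examples
#' tab <- rbind(c(2, 0), c(0, 2), c(2, 0), c(1, 1))
#' fleiss_kappa(tab)
fleiss_kappa <- function(table, mode = c("variable_raters", "complete_case"),
                         conf_level = 0.95) {
  mode <- match.arg(mode)
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != floor(m))) {
    rlang::abort("ratings table must hold non-negative integer counts",
                 class = "ddi_schema_error")
  }
  ni <- rowSums(m)
  if (mode == "complete_case") {
    keep <- ni == max(ni) & ni >= 2
  } else {
    keep <- ni >= 2
  }
  n_excluded <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  ni <- ni[keep]
  if (nrow(m) < 2) {
    rlang::abort("need at least 2 subjects with >= 2 ratings",
                 class = "ddi_degenerate_error")
  }

  p_i <- (rowSums(m^2) - ni) / (ni * (ni - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(m) / sum(ni)
  pe <- sum(p_j^2)
  if (1 - pe < .Machine$double.eps^0.5) {
    rlang::abort("all ratings fall in a single category; kappa undefined",
                 class = "ddi_degenerate_error")
  }
  kappa <- (p_bar - pe) / (1 - pe)

  n_subj <- nrow(m)
  n_bar <- mean(ni)
  se <- sqrt(2 / (n_subj * n_bar * (n_bar - 1))) *
    sqrt(pe - (2 * n_bar - 3) * pe^2 + 2 * (n_bar - 2) * sum(p_j^3)) /
    (1 - pe)
  z <- kappa / se
  p_value <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)

  structure(
    list(
      kappa = kappa, se = se,
      ci_low = kappa - zq * se, ci_high = kappa + zq * se,
      p_value = p_value, band = interpret_kappa(kappa),
      n_subjects = n_subj, n_excluded = n_excluded,
      mode = mode, conf_level = conf_level
    ),
    class = "ddi_kappa"
  )
}

#' @export
print.ddi_kappa <- function(x, ...) {
  cat(sprintf(
    "Fleiss' kappa: %.3f (%s agreement)\n%g%% CI [%.3f, %.3f], p = %.3g\n%d subjects (%d excluded), mode = %s\n",
    x$kappa, x$band, 100 * x$conf_level, x$ci_low, x$ci_high, x$p_value,
    x$n_subjects, x$n_excluded, x$mode
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fleiss_kappa
#' @param x A `ddi_kappa` object.
#' @param ... Unused.
#' @export
tidy.ddi_kappa <- function(x, ...) {
  tibble::tibble(
    estimate = x$kappa, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p_value, band = x$band
  )
}

#' @rdname fleiss_kappa
#' @export
glance.ddi_kappa <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_excluded = x$n_excluded,
    mode = x$mode, conf_level = x$conf_level
  )
}

#' Landis-Koch interpretation of a kappa value
#'
#' Verbal agreement bands: `<= 0.20` poor, `(0.20, 0.40]` fair,
#' `(0.40, 0.60]` moderate, `(0.60, 0.80]` substantial,
#' `(0.80, 1.00]` almost perfect.
#'
#' @param k Numeric vector of kappa values in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
#' @examples
#' interpret_kappa(c(0.483, 0.124, 0.20))
interpret_kappa <- function(k) {
  stopifnot(all(k >= -1 - 1e-9 & k <= 1 + 1e-9))
  as.character(cut(
    k,
    breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
    labels = c("poor", "fair", "moderate", "substantial", "almost perfect")
  ))
}

#' McNemar's test from discordant-pair counts
#'
#' Paired test of marginal homogeneity for two binary classifications,
#' driven entirely by the discordant counts: `b` pairs classified
#' positive by the first rater only and `c` by the second only. The
#' exact method doubles the binomial(b + c, 1/2) tail at `min(b, c)`
#' (capped at 1); the asymptotic method is the continuity-corrected
#' chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df. `auto` uses the
#' exact test when `b + c < 25`.
#'
#' @param b,c Non-negative discordant counts.
#' @param method `"auto"`, `"exact"`, or `"asymptotic"`.
#' @return One-row tibble: `test_name`, `method`, `statistic`,
#'   `p_value`, `n_effective` (= b + c), `degenerate`.
#' @export
#' @examples
#' mcnemar_test(10, 0)
mcnemar_test <- function(b, c, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  stopifnot(length(b) == 1, length(c) == 1, b >= 0, c >= 0,
            b == floor(b), c == floor(c))
  n <- b + c
  if (n == 0) {
    return(tibble::tibble(
      test_name = "mcnemar", method = method, statistic = NA_real_,
      p_value = 1, n_effective = 0L, degenerate = TRUE
    ))
  }
  if (method == "auto") method <- if (n < 25) "exact" else "asymptotic"
  if (method == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    statistic <- min(b, c)
  } else {
    statistic <- (abs(b - c) - 1)^2 / n
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(
    test_name = "mcnemar", method = method, statistic = statistic,
    p_value = p, n_effective = as.integer(n), degenerate = FALSE
  )
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; tied absolute differences share
#' average ranks; the statistic is `W+`, the sum of ranks of positive
#' differences. The exact method enumerates all `2^n` sign
#' assignments of the observed rank vector (valid under ties) and sums
#' the probability of outcomes at least as far from the null mean
#' `sum(ranks) / 2` as observed; it is used by `auto` when the number
#' of non-zero differences is at most 15. Otherwise a normal
#' approximation with tie-corrected variance `sum(ranks^2) / 4` and a
#' 0.5 continuity correction is used.
#'
#' @param differences Numeric vector of paired score differences.
#' @param method `"auto"`, `"exact"`, or `"normal"`.
#' @return One-row tibble: `test_name`, `method`, `statistic` (W+),
#'   `p_value`, `n_effective`, `degenerate`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))
wilcoxon_signed_rank <- function(differences,
                                 method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(differences) > 0, is.numeric(differences))
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(
      test_name = "wilcoxon", method = method, statistic = 0,
      p_value = 1, n_effective = 0L, degenerate = TRUE
    ))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (method == "auto") method <- if (n <= 15) "exact" else "normal"
  if (method == "exact") {
    sums <- signed_rank_sums(r)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  tibble::tibble(
    test_name = "wilcoxon", method = method, statistic = w,
    p_value = p, n_effective = as.integer(n), degenerate = FALSE
  )
}

# All 2^n subset sums of the rank vector (distribution of W+ under
# random signs). Doubling construction; n <= 20 or so is fine.
#' @keywords internal
signed_rank_sums <- function(r) {
  sums <- 0
  for (x in r) sums <- c(sums, sums + x)
  sums
}

#' Build a subjects-by-categories ratings table from an evidence matrix
#'
#' Converts the standardized evidence matrix into the count-table input
#' of [fleiss_kappa()] for one rated aspect of the interaction
#' monographs. For `severity` / `course_of_action` the categories are
#' the standardized labels cast by resources with a non-`unrated`
#' rating. For the five documentation components the "rating" is
#' whether a resource with an entry documents the component (two
#' categories: yes/no). For `overall_completeness` the rating is the
#' 0-5 completeness score of each entry.
#'
#' @param matrix Standardized evidence-matrix tibble.
#' @param component One of `"severity"`, `"course_of_action"`,
#'   `"mechanism"`, `"clinical_effects"`, `"documentation_level"`,
#'   `"overall_completeness"`.
#' @return Integer matrix (pairs x categories) of assignment counts;
#'   rows are drug pairs, only ratings actually cast are counted.
#' @export
ratings_table <- function(matrix,
                          component = c("severity", "course_of_action",
                                        "mechanism", "clinical_effects",
                                        "documentation_level",
                                        "overall_completeness")) {
  component <- match.arg(component)
  if (component %in% c("severity", "course_of_action")) {
    col <- if (component == "severity") "severity_std" else "action_std"
    if (!col %in% names(matrix)) {
      rlang::abort("matrix must be standardized first (see apply_standardization)",
                   class = "ddi_schema_error")
    }
    levels <- setdiff(
      if (component == "severity") severity_levels() else action_levels(),
      "unrated"
    )
    rated <- dplyr::filter(matrix, .data[[col]] != "unrated")
    rating <- factor(rated[[col]], levels = levels)
  } else if (component == "overall_completeness") {
    rated <- dplyr::filter(matrix, .data$present)
    score <- rowSums(as.matrix(rated[component_cols()]))
    rating <- factor(score, levels = 0:5)
  } else {
    flag <- paste0("has_", component)
    rated <- dplyr::filter(matrix, .data$present)
    rating <- factor(ifelse(rated[[flag]], "documented", "undocumented"),
                     levels = c("documented", "undocumented"))
  }
  tab <- table(factor(rated$pair_id), rating)
  m <- matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Inter-resource agreement across all monograph components
#'
#' Runs [fleiss_kappa()] on each rated aspect of the interaction
#' monographs — mechanism, clinical effects, severity, level of
#' documentation, course of action (documentation yes/no or
#' standardized categories, as appropriate) and the overall 0-5
#' completeness score — and reports the kappa, its confidence
#' interval, p-value, and Landis-Koch band per component.
#'
#' @param matrix Standardized evidence-matrix tibble.
#' @param mode Rater-count mode passed to [fleiss_kappa()].
#' @param conf_level Confidence level.
#' @return Tibble of class `ddi_kappa_tbl` with one row per component:
#'   `component`, `kappa`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `band`, `n_subjects`.
#' @export
kappa_components <- function(matrix, mode = "variable_raters",
                             conf_level = 0.95) {
  comps <- c("mechanism", "clinical_effects", "severity",
             "documentation_level", "course_of_action",
             "overall_completeness")
  rows <- purrr::map(comps, function(cmp) {
    res <- tryCatch(
      fleiss_kappa(ratings_table(matrix, cmp), mode = mode,
                   conf_level = conf_level),
      ddi_degenerate_error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble::tibble(
        component = cmp, kappa = NA_real_, se = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        band = NA_character_, n_subjects = NA_integer_
      ))
    }
    tibble::tibble(
      component = cmp, kappa = res$kappa, se = res$se,
      ci_low = res$ci_low, ci_high = res$ci_high, p_value = res$p_value,
      band = res$band, n_subjects = res$n_subjects
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ddi_kappa_tbl", class(out))
  out
}
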