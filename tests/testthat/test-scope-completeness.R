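test_that("scope percentages match a loop-and-count oracle", {
  withr::local_seed(101)
  pres <- matrix(runif(60) < 0.5, 20, 3,
                 dimnames = list(NULL, c("r1", "r2", "r3")))
  m <- presence_matrix(pres)
  got <- scope_scores(m)
  for (res in colnames(pres)) {
    n_manual <- 0
    for (i in seq_len(nrow(pres))) n_manual <- n_manual + pres[i, res]
    row <- got[got$resource_id == res, ]
    expect_identical(row$n_present, as.integer(n_manual))
    expect_identical(row$n_total, 20L)
    expect_equal(row$percent, unname(floor(10000 * n_manual / 20 + 1e-9) / 100))
  }
})

test_that("scope is 100 for all-present matrices and permutation invariant", {
  m <- build_matrix(tidyr::expand_grid(
    pair_id = sprintf("P%02d", 1:12), resource_id = c("a", "b")
  ))
  expect_true(all(scope_scores(m)$percent == 100))

  m2 <- generate_matrix(synthetic_config(n_pairs = 30, seed = 4))
  shuffled <- m2[sample.int(nrow(m2)), ]
  expect_equal(scope_scores(m2), scope_scores(shuffled))
})

test_that("empty matrix errors", {
  m <- generate_matrix(synthetic_config(n_pairs = 5, seed = 1))
  expect_error(scope_scores(m[0, ]), class = "ddi_schema_error")
})

test_that("component percentages use entries as denominator", {
  m <- marginal_completeness_matrix(85, c(83, 81, 85, 85, 85),
                                    resource = "res_a")
  got <- completeness_summary(m, decimals = 1)
  expect_identical(got$n_present, 85L)
  expect_identical(got$clinical_effects_n, 81L)
  expect_equal(got$clinical_effects_pct, 95.2)
  expect_equal(got$mechanism_pct, 97.6)
  expect_equal(got$severity_pct, 100)
})

test_that("overall scores sum the five flags; median/IQR match an oracle", {
  entries <- tibble::tibble(
    pair_id = sprintf("P%02d", 1:10), resource_id = "r",
    has_mechanism = rep(c(TRUE, FALSE), 5),
    has_clinical_effects = c(rep(TRUE, 7), rep(FALSE, 3)),
    has_documentation_level = rep(FALSE, 10)
  )
  m <- build_matrix(entries, "r")
  got <- completeness_summary(m)
  scores <- got$scores[[1]]
  expect_true(all(scores >= 0 & scores <= 5))
  expect_identical(
    sort(scores),
    sort(as.integer(rowSums(as.matrix(
      m[m$present, grep("^has_", names(m))]))))
  )
  q <- oracle_quartiles(scores)
  expect_equal(got$median, q[["median"]])
  expect_equal(got$q1, q[["q1"]])
  expect_equal(got$q3, q[["q3"]])

  # removing one flag from one entry drops its score by exactly 1
  m2 <- m
  i <- which(m2$present & m2$has_severity)[1]
  m2$has_severity[i] <- FALSE
  m2$severity_std[i] <- "unrated"
  m2$severity_raw[i] <- ""
  s2 <- completeness_summary(m2)$scores[[1]]
  expect_identical(sum(scores) - sum(s2), 1L)
})

test_that("an entry documenting everything scores 5", {
  m <- build_matrix(tibble::tibble(pair_id = "P1", resource_id = "r"))
  expect_identical(completeness_summary(m)$scores[[1]], 5L)
})

test_that("a resource without entries is flagged, not silently NaN", {
  m <- build_matrix(tibble::tibble(
    pair_id = c("P1", "P2"), resource_id = "r1",
    present = c(TRUE, TRUE)
  ), resources = c("r1", "r2"))
  expect_warning(got <- completeness_summary(m),
                 class = "ddi_empty_resource_warning")
  r2 <- got[got$resource_id == "r2", ]
  expect_true(is.na(r2$mechanism_pct))
  expect_true(is.na(r2$median))
})

test_that("compare_scope runs McNemar on discordant coverage", {
  pres <- cbind(a = rep(TRUE, 12), b = rep(TRUE, 12))
  m <- presence_matrix(pres)
  same <- compare_scope(m, "a", "b")
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  # 10 pairs covered by a only
  pres2 <- cbind(a = rep(TRUE, 12), b = c(rep(FALSE, 10), TRUE, TRUE))
  m2 <- presence_matrix(pres2)
  r <- compare_scope(m2, "a", "b")
  expect_equal(r$p_value, 2 * 0.5^10)
  # symmetry
  expect_equal(compare_scope(m2, "b", "a")$p_value, r$p_value)
})

test_that("compare_scope holds its level under equal coverage", {
  n_reject <- 0
  reps <- 200
  for (s in seq_len(reps)) {
    withr::local_seed(1000 + s)
    pres <- matrix(runif(1000) < 0.5, 500, 2,
                   dimnames = list(NULL, c("a", "b")))
    m <- presence_matrix(pres)
    n_reject <- n_reject + (compare_scope(m, "a", "b")$p_value < 0.05)
  }
  expect_gte((reps - n_reject) / reps, 0.9)
})

test_that("compare_completeness pairs over shared coverage only", {
  # scores a = (5,5,5,4), b = (3,3,3,4) on the same four pairs
  mk <- function(res, scores) {
    purrr::map_dfr(seq_along(scores), function(i) {
      s <- scores[i]
      tibble::tibble(
        pair_id = sprintf("P%d", i), resource_id = res,
        has_mechanism = s >= 1, has_clinical_effects = s >= 2,
        has_severity = s >= 3, has_documentation_level = s >= 4,
        has_course_of_action = s >= 5
      )
    })
  }
  m <- build_matrix(dplyr::bind_rows(mk("a", c(5, 5, 5, 4)),
                                     mk("b", c(3, 3, 3, 4))),
                    c("a", "b"))
  r <- compare_completeness(m, "a", "b")
  expect_identical(r$n_effective, 3L)
  expect_equal(r$p_value, 0.25)

  ident <- build_matrix(dplyr::bind_rows(mk("a", c(4, 4, 4, 4)),
                                         mk("b", c(4, 4, 4, 4))),
                        c("a", "b"))
  r2 <- compare_completeness(ident, "a", "b")
  expect_equal(r2$p_value, 1)
  expect_identical(r2$n_effective, 0L)

  # no shared coverage
  nshare <- build_matrix(tibble::tibble(
    pair_id = c("P1", "P2"), resource_id = c("a", "b")
  ), c("a", "b"))
  expect_error(compare_completeness(nshare, "a", "b"),
               class = "ddi_degenerate_error")
})

test_that("compare_completeness detects a documentation gap at n = 181", {
  hits <- 0
  reps <- 200
  cfg_hi <- synthetic_config(n_pairs = 181, resources = c("a", "b"),
                             coverage = 1,
                             doc_probs = rbind(rep(0.95, 5), rep(0.7, 5)))
  for (s in seq_len(reps)) {
    m <- generate_matrix(cfg_hi, seed = s)
    hits <- hits + (compare_completeness(m, "a", "b")$p_value < 0.05)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("tier grouping follows the greedy significance rule", {
  # engineered medians 5,5,4,4,3,3 with agreement inside levels
  mk <- function(res, score, n = 20) {
    tibble::tibble(
      pair_id = sprintf("P%03d", seq_len(n)), resource_id = res,
      has_mechanism = score >= 1, has_clinical_effects = score >= 2,
      has_severity = score >= 3, has_documentation_level = score >= 4,
      has_course_of_action = score >= 5
    )
  }
  m <- build_matrix(dplyr::bind_rows(
    mk("r1", 5), mk("r2", 5), mk("r3", 4), mk("r4", 4),
    mk("r5", 3), mk("r6", 3)
  ), paste0("r", 1:6))
  compl <- completeness_summary(m)
  pw <- pairwise_tests(m)
  tiers <- assign_tiers(compl, pw)
  expect_identical(max(tiers$tier), 3L)
  expect_identical(
    unname(split(tiers$resource_id, tiers$tier)),
    list(c("r1", "r2"), c("r3", "r4"), c("r5", "r6"))
  )
})

test_that("percentage truncation matches the printed convention", {
  expect_identical(format_percent(115, 181, 2), "63.53")
  expect_identical(format_percent(95, 181, 2), "52.48")
  expect_identical(format_percent(36, 70, 2), "51.42")
  expect_identical(format_percent(181, 181, 0), "100")
  expect_equal(truncate_percent(85, 181, 1), 46.9)
  expect_error(format_percent(1, 0), class = "ddi_schema_error")
})
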