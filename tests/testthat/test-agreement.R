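test_that("unanimous ratings give kappa 1", {
  tab <- rbind(c(6, 0), c(0, 6), c(6, 0), c(0, 6), c(6, 0))
  k <- fleiss_kappa(tab)
  expect_equal(k$kappa, 1)
  expect_identical(k$band, "almost perfect")
})

test_that("kappa matches a hand computation on the 4-subject table", {
  tab <- rbind(c(2, 0), c(0, 2), c(2, 0), c(1, 1))
  k <- fleiss_kappa(tab)
  # P = (1 + 1 + 1 + 0)/4, Pe = (5/8)^2 + (3/8)^2, kappa = 7/15
  expect_equal(k$kappa, 7 / 15, tolerance = 1e-12)
  expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)
  expect_equal(k$ci_high - k$kappa, 1.96 * k$se, tolerance = 1e-3)
})

test_that("kappa equals the from-definition oracle on all small tables", {
  # every 2-rater, 4-subject table over 2 and over 3 categories
  for (n_cat in 2:3) {
    per_subject <- as.matrix(expand.grid(rep(list(0:2), n_cat)))
    per_subject <- per_subject[rowSums(per_subject) == 2, , drop = FALSE]
    idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(per_subject))), 4)))
    for (r in seq_len(nrow(idx))) {
      tab <- per_subject[idx[r, ], , drop = FALSE]
      p_j <- colSums(tab) / sum(tab)
      if (sum(p_j^2) >= 1 - 1e-12) next  # degenerate: single category
      expect_equal(fleiss_kappa(tab)$kappa, oracle_fleiss(tab),
                   tolerance = 1e-12)
    }
  }
})

test_that("independent uniform ratings give kappa near zero", {
  withr::local_seed(2024)
  n <- 2000
  tab <- t(stats::rmultinom(n, 6, rep(1 / 3, 3)))
  k <- fleiss_kappa(tab)
  expect_lt(abs(k$kappa), 0.05)
  expect_identical(k$band, "poor")
})

test_that("kappa is invariant to subject and category permutation", {
  withr::local_seed(8)
  tab <- t(stats::rmultinom(30, 5, c(0.2, 0.5, 0.3)))
  k0 <- fleiss_kappa(tab)$kappa
  expect_equal(fleiss_kappa(tab[sample.int(30), ])$kappa, k0)
  expect_equal(fleiss_kappa(tab[, c(3, 1, 2)])$kappa, k0)
})

test_that("rater-count modes and exclusions behave", {
  tab <- rbind(c(3, 3), c(6, 0), c(1, 0), c(0, 6))  # subject 3 has 1 rating
  k <- fleiss_kappa(tab, mode = "variable_raters")
  expect_identical(k$n_excluded, 1L)
  expect_identical(k$n_subjects, 3L)
  tab2 <- rbind(c(3, 3), c(6, 0), c(2, 2), c(0, 6))
  kc <- fleiss_kappa(tab2, mode = "complete_case")
  expect_identical(kc$n_subjects, 3L)  # the 4-rating subject dropped
  # all ratings one category is degenerate
  expect_error(fleiss_kappa(rbind(c(6, 0), c(6, 0))),
               class = "ddi_degenerate_error")
})

test_that("tidy and glance expose the kappa fit", {
  k <- fleiss_kappa(rbind(c(2, 0), c(0, 2), c(2, 0), c(1, 1)))
  td <- generics::tidy(k)
  expect_named(td, c("estimate", "std.error", "conf.low", "conf.high",
                     "p.value", "band"))
  expect_equal(td$estimate, k$kappa)
  gl <- generics::glance(k)
  expect_identical(gl$n_subjects, 4L)
})

test_that("Landis-Koch bands use the conventional cut points", {
  expect_identical(
    interpret_kappa(c(0.483, 0.124, 0.276, 0.187, 0.462, 0.270)),
    c("moderate", "poor", "fair", "poor", "moderate", "fair")
  )
  expect_identical(interpret_kappa(0.20), "poor")
  expect_identical(interpret_kappa(0.40), "fair")
  expect_identical(interpret_kappa(0.60), "moderate")
  expect_identical(interpret_kappa(0.80), "substantial")
  expect_identical(interpret_kappa(1), "almost perfect")
  expect_identical(interpret_kappa(-0.3), "poor")
})

test_that("exact McNemar doubles the binomial tail", {
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(10, 0)$p_value, 2 * 0.5^10)
  deg <- mcnemar_test(0, 0)
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  # symmetry across methods
  for (meth in c("exact", "asymptotic")) {
    expect_equal(mcnemar_test(7, 3, meth)$p_value,
                 mcnemar_test(3, 7, meth)$p_value)
  }
})

test_that("asymptotic McNemar applies the continuity correction", {
  r <- mcnemar_test(40, 20, "asymptotic")
  expect_equal(r$statistic, 19^2 / 60)
  expect_equal(r$p_value, stats::pchisq(19^2 / 60, 1, lower.tail = FALSE))
  # cross-check against the stats implementation on the full 2x2 table
  tab <- matrix(c(30, 40, 20, 10), 2)
  expect_equal(r$p_value, stats::mcnemar.test(tab)$p.value)
})

test_that("exact McNemar equals the enumeration oracle for b + c <= 20", {
  for (n in 0:20) {
    for (b in 0:n) {
      expect_equal(mcnemar_test(b, n - b, "exact")$p_value,
                   oracle_mcnemar_p(b, n - b))
    }
  }
})

test_that("signed-rank handles zeros, ties, and small-sample exactness", {
  deg <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_equal(deg$p_value, 1)
  expect_identical(deg$n_effective, 0L)
  expect_true(deg$degenerate)

  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$p_value, 0.25)
  expect_equal(r$statistic, 6)

  # agreement with stats::wilcox.test when there are no ties
  d <- c(3, -1, 4, -7, 2, 9, -5)
  expect_equal(wilcoxon_signed_rank(d, "exact")$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value)
})

test_that("exact signed-rank equals full sign enumeration for n <= 12", {
  withr::local_seed(31)
  for (n in c(2, 3, 5, 8, 10, 12)) {
    for (rep_i in 1:3) {
      d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # plenty of ties
      expect_equal(wilcoxon_signed_rank(d, "exact")$p_value,
                   oracle_wilcoxon_p(d))
    }
  }
})

test_that("signed-rank p is invariant under negating all differences", {
  withr::local_seed(13)
  for (rep_i in 1:10) {
    d <- sample(c(-3:-1, 1:3), 9, replace = TRUE)
    for (meth in c("exact", "normal")) {
      expect_equal(wilcoxon_signed_rank(d, meth)$p_value,
                   wilcoxon_signed_rank(-d, meth)$p_value)
    }
  }
})

test_that("ratings tables are assembled per component", {
  m <- ratings_matrix(list(r1 = c("moderate", "minor"),
                           r2 = c("moderate", "moderate"),
                           r3 = c("major_contraindicated", "moderate")))
  tab <- ratings_table(m, "severity")
  expect_identical(dim(tab), c(2L, 3L))
  expect_identical(rowSums(tab), c(P001 = 3, P002 = 3))
  expect_identical(tab["P001", "moderate"], 2L)
  expect_identical(tab["P002", "minor"], 1L)

  # documentation components count documented vs undocumented
  i <- which(m$resource_id == "r2" & m$pair_id == "P001")
  m$has_clinical_effects[i] <- FALSE
  tab2 <- ratings_table(m, "clinical_effects")
  expect_identical(tab2["P001", "undocumented"], 1L)
})
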