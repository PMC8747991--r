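# Fixture builders shared across the suite. All matrices are built in
# code; nothing is read from disk.

# Build a complete evidence matrix from a compact entry description.
# `entries`: tibble/data.frame with pair_id, resource_id and any of
# present, the five has_* flags, severity_std, action_std. Missing
# (pair, resource) combinations become absent entries; flags default
# to the entry's presence; std ratings default to moderate/monitor
# for present+flagged entries. Raw labels mirror the std categories
# and resources get a generic vocabulary, so the fixture is already
# standardized and internally coherent.
build_matrix <- function(entries, resources = unique(entries$resource_id)) {
  entries <- tibble::as_tibble(entries)
  pairs <- unique(entries$pair_id)
  full <- tidyr::expand_grid(pair_id = pairs, resource_id = resources) |>
    dplyr::left_join(entries, by = c("pair_id", "resource_id"))
  n <- nrow(full)
  fill <- function(col, default) {
    if (col %in% names(full)) dplyr::coalesce(full[[col]], default) else
      rep(default, n)
  }
  present <- fill("present", FALSE)
  # described entries are present unless told otherwise
  described <- !is.na(full$pair_id) &
    paste(full$pair_id, full$resource_id) %in%
      paste(entries$pair_id, entries$resource_id)
  if (!"present" %in% names(entries)) present <- described
  flags <- c("has_mechanism", "has_clinical_effects", "has_severity",
             "has_documentation_level", "has_course_of_action")
  out <- tibble::tibble(
    pair_id = full$pair_id,
    psychotropic = paste0("psy_", full$pair_id),
    covid_drug = paste0("cov_", full$pair_id),
    psychotropic_class = "SSRI",
    resource_id = full$resource_id,
    present = present
  )
  for (f in flags) out[[f]] <- fill(f, TRUE) & present
  sev <- fill("severity_std", "moderate")
  act <- fill("action_std", "monitor")
  out$severity_std <- ifelse(out$present & out$has_severity, sev, "unrated")
  out$action_std <- ifelse(out$present & out$has_course_of_action, act,
                           "unrated")
  out$severity_raw <- ifelse(out$severity_std == "unrated", "",
                             out$severity_std)
  out$action_raw <- ifelse(out$action_std == "unrated", "", out$action_std)
  dplyr::relocate(out, severity_raw, action_raw, .before = severity_std)
}

# Matrix where every resource rates every pair, with per-resource
# severity vectors given as a named list resource -> categories.
ratings_matrix <- function(severities, actions = NULL) {
  resources <- names(severities)
  n <- length(severities[[1]])
  entries <- purrr::map_dfr(resources, function(res) {
    tibble::tibble(
      pair_id = sprintf("P%03d", seq_len(n)),
      resource_id = res,
      severity_std = severities[[res]],
      action_std = if (is.null(actions)) "monitor" else actions[[res]]
    )
  })
  build_matrix(entries, resources)
}

# A presence-only matrix: `presence` is a logical matrix
# (pairs x resources) with resource ids as column names.
presence_matrix <- function(presence) {
  resources <- colnames(presence)
  entries <- purrr::map_dfr(resources, function(res) {
    tibble::tibble(
      pair_id = sprintf("P%03d", seq_len(nrow(presence))),
      resource_id = res,
      present = presence[, res]
    )
  })
  build_matrix(entries, resources)
}

# Completeness fixture: one resource with n entries and given
# per-component documented counts, deficits assigned to entries
# according to `spread` ("distinct" puts each missing component on a
# different entry where possible; "random" scatters them).
marginal_completeness_matrix <- function(n, counts, resource = "res_a",
                                         spread = c("distinct", "random")) {
  spread <- match.arg(spread)
  flags <- c("has_mechanism", "has_clinical_effects", "has_severity",
             "has_documentation_level", "has_course_of_action")
  stopifnot(length(counts) == 5, all(counts <= n))
  m <- matrix(TRUE, n, 5, dimnames = list(NULL, flags))
  deficits <- n - counts
  if (spread == "distinct") {
    cursor <- 0
    for (k in seq_len(5)) {
      if (deficits[k] == 0) next
      idx <- ((cursor + seq_len(deficits[k]) - 1) %% n) + 1
      m[idx, k] <- FALSE
      cursor <- cursor + deficits[k]
    }
  } else {
    for (k in seq_len(5)) {
      if (deficits[k] > 0) m[sample.int(n, deficits[k]), k] <- FALSE
    }
  }
  entries <- tibble::as_tibble(m) |>
    dplyr::mutate(pair_id = sprintf("P%03d", seq_len(n)),
                  resource_id = resource, present = TRUE)
  build_matrix(entries, resource)
}

# Tukey inclusive quartile oracle, written independently of the
# package: explicit sort-and-index median of each half.
oracle_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  med_at <- function(v) {
    k <- length(v)
    if (k %% 2 == 1) v[(k + 1) / 2] else (v[k / 2] + v[k / 2 + 1]) / 2
  }
  lower <- x[1:ceiling(n / 2)]
  upper <- x[(n - ceiling(n / 2) + 1):n]
  c(q1 = med_at(lower), median = med_at(x), q3 = med_at(upper))
}

# From-definition Fleiss kappa oracle: reconstructs individual rater
# pairs per subject and counts agreeing pairs directly.
oracle_fleiss <- function(tab) {
  tab <- as.matrix(tab)
  ni <- rowSums(tab)
  agree <- function(row) {
    pairs_total <- sum(row) * (sum(row) - 1) / 2
    pairs_agree <- sum(row * (row - 1) / 2)
    pairs_agree / pairs_total
  }
  p_bar <- mean(apply(tab, 1, agree))
  p_j <- colSums(tab) / sum(ni)
  pe <- sum(p_j^2)
  (p_bar - pe) / (1 - pe)
}

# Exact two-sided signed-rank p-value by explicit enumeration of all
# sign vectors (not the package's subset-sum construction).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact McNemar oracle: binomial tail via explicit choose() sums.
oracle_mcnemar_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  tail <- sum(choose(n, 0:k)) / 2^n
  min(1, 2 * tail)
}

# Brute-force consistency oracle: per-pair vote tally with explicit
# loops, strict plurality, min_raters cut, minor always inconsistent.
oracle_consistency <- function(matrix, component, min_raters = 3) {
  col <- if (component == "severity") "severity_std" else "action_std"
  resources <- unique(matrix$resource_id)
  out <- list()
  for (res in resources) {
    n_elig <- 0
    n_cons <- 0
    for (p in unique(matrix$pair_id)) {
      sub <- matrix[matrix$pair_id == p, ]
      ratings <- sub[[col]][sub[[col]] != "unrated"]
      if (length(ratings) < min_raters) next
      tab <- table(ratings)
      top <- names(tab)[tab == max(tab)]
      if (length(top) != 1) next
      mine <- sub[[col]][sub$resource_id == res]
      if (length(mine) != 1 || mine == "unrated") next
      n_elig <- n_elig + 1
      ok <- mine == top && !(component == "severity" && mine == "minor")
      n_cons <- n_cons + ok
    }
    out[[res]] <- tibble::tibble(resource_id = res,
                                 n_consistent = n_cons,
                                 n_eligible = n_elig)
  }
  dplyr::bind_rows(out)
}
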