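#' Canonical resource identifiers
#'
#' The six drug-information resources compared by the pipeline, in the
#' fixed order used by all reports: three subscription point-of-care
#' databases (PEPID, Micromedex, UpToDate) followed by three free online
#' interaction checkers (Drugs.com, Medscape, WebMD). Resource
#' identifiers elsewhere in the package are free strings; this vector
#' only fixes naming and ordering for the canonical six.
#'
#' @return Character vector of six resource ids.
#' @export
#' @examples
#' ddi_resources()
ddi_resources <- function() {
  c("pepid", "micromedex", "uptodate", "drugscom", "medscape", "webmd")
}

#' Standardized severity categories
#'
#' The harmonized severity scale: `minor`, `moderate`,
#' `major_contraindicated`, plus `unrated` for entries that are absent
#' or do not document severity. Sub-moderate ratings are kept as a
#' distinct `minor` category because a minor rating can never be scored
#' consistent with a majority (minor-severity pairs fall outside the
#' moderate-to-contraindicated study frame).
#'
#' @return Character vector of category labels, `unrated` last.
#' @export
severity_levels <- function() {
  c("minor", "moderate", "major_contraindicated", "unrated")
}

#' Standardized course-of-action categories
#'
#' Management recommendations harmonized to four categories: no action
#' required, monitoring, dosage modification, and avoidance of the
#' combination; `unrated` marks absent/undocumented entries.
#'
#' @return Character vector of category labels, `unrated` last.
#' @export
action_levels <- function() {
  c("no_action", "monitor", "modify_dosage", "avoid", "unrated")
}

#' @keywords internal
component_cols <- function() {
  c("has_mechanism", "has_clinical_effects", "has_severity",
    "has_documentation_level", "has_course_of_action")
}

#' @keywords internal
matrix_cols <- function() {
  c("pair_id", "psychotropic", "covid_drug", "psychotropic_class",
    "resource_id", "present", component_cols(), "severity_raw", "action_raw")
}

#' Default psychotropic drug list
#'
#' The 37 psychotropic drugs in the default evaluation universe, with
#' their therapeutic class: SSRIs, SNRIs, TCAs, MAOIs, other
#' antidepressants, antipsychotics, mood stabilizers, and anxiolytics.
#'
#' @return A tibble with columns `drug` and `class`.
#' @export
psychotropic_drugs <- function() {
  tibble::tribble(
    ~drug, ~class,
    "fluvoxamine", "SSRI",
    "fluoxetine", "SSRI",
    "sertraline", "SSRI",
    "citalopram", "SSRI",
    "escitalopram", "SSRI",
    "paroxetine", "SSRI",
    "duloxetine", "SNRI",
    "venlafaxine", "SNRI",
    "amitriptyline", "TCA",
    "nortriptyline", "TCA",
    "imipramine", "TCA",
    "clomipramine", "TCA",
    "doxepin", "TCA",
    "isocarboxazid", "MAOI",
    "phenelzine", "MAOI",
    "tranylcypromine", "MAOI",
    "bupropion", "other-antidepressant",
    "mirtazapine", "other-antidepressant",
    "trazodone", "other-antidepressant",
    "vilazodone", "other-antidepressant",
    "vortioxetine", "other-antidepressant",
    "chlorpromazine", "antipsychotic",
    "haloperidol", "antipsychotic",
    "trifluoperazine", "antipsychotic",
    "quetiapine", "antipsychotic",
    "risperidone", "antipsychotic",
    "olanzapine", "antipsychotic",
    "aripiprazole", "antipsychotic",
    "ziprasidone", "antipsychotic",
    "clozapine", "antipsychotic",
    "carbamazepine", "mood-stabilizer",
    "valproic acid", "mood-stabilizer",
    "lamotrigine", "mood-stabilizer",
    "lithium", "mood-stabilizer",
    "diazepam", "anxiolytic",
    "midazolam", "anxiolytic",
    "alprazolam", "anxiolytic"
  )
}

#' Default COVID-19 medication list
#'
#' The nine repurposed or investigational COVID-19 medications in the
#' default evaluation universe.
#'
#' @return Character vector of drug names.
#' @export
covid_drugs <- function() {
  c("hydroxychloroquine", "lopinavir", "ritonavir", "azithromycin",
    "dexamethasone", "ivermectin", "remdesivir", "interferon",
    "tocilizumab")
}

#' Cross-product universe of candidate drug pairs
#'
#' Every (psychotropic, COVID-19 drug) combination that a synthetic
#' evidence matrix may sample from. Pairs among psychotropics or among
#' COVID-19 drugs are never formed.
#'
#' @param psychotropics Tibble with columns `drug`, `class`
#'   (default [psychotropic_drugs()]).
#' @param covid Character vector of COVID-19 medication names
#'   (default [covid_drugs()]).
#' @return A tibble with columns `psychotropic`, `psychotropic_class`,
#'   `covid_drug`; one row per combination.
#' @export
drug_pair_universe <- function(psychotropics = psychotropic_drugs(),
                               covid = covid_drugs()) {
  stopifnot(all(c("drug", "class") %in% names(psychotropics)))
  tidyr::expand_grid(
    psychotropic = psychotropics$drug,
    covid_drug = covid
  ) |>
    dplyr::left_join(
      dplyr::rename(psychotropics,
                    psychotropic = "drug", psychotropic_class = "class"),
      by = "psychotropic"
    ) |>
    dplyr::select("psychotropic", "psychotropic_class", "covid_drug")
}

#' Validate an evidence matrix
#'
#' Checks the structural invariants of a pair-by-resource evidence
#' matrix and reports every violation found. The checks are:
#' required columns exist; one entry per (pair, resource); absent
#' entries carry no component flags and no standardized ratings;
#' undocumented severity / course-of-action components carry `unrated`
#' standardized values; and (optionally) drug names come from a
#' configured universe. Purely a reporting operation: the input is
#' never modified and repeated calls give identical output.
#'
#' @param matrix Evidence-matrix tibble (see [read_matrix_csv()] for
#'   the column contract). Standardized columns `severity_std` /
#'   `action_std` are checked only if present.
#' @param universe Optional tibble from [drug_pair_universe()]; when
#'   supplied, pair drug names must appear in it.
#' @return A tibble of violations with columns `pair_id`,
#'   `resource_id`, `rule`; zero rows when the matrix is valid.
#' @export
validate_matrix <- function(matrix, universe = NULL) {
  v <- list()
  bad_cols <- setdiff(matrix_cols(), names(matrix))
  if (length(bad_cols) > 0) {
    return(tibble::tibble(
      pair_id = NA_character_, resource_id = NA_character_,
      rule = paste0("missing column(s): ", paste(bad_cols, collapse = ", "))
    ))
  }

  dup <- matrix |>
    dplyr::count(.data$pair_id, .data$resource_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    v$dup <- tibble::tibble(
      pair_id = dup$pair_id, resource_id = dup$resource_id,
      rule = "duplicated (pair_id, resource_id) entry"
    )
  }

  any_flag <- rowSums(as.matrix(matrix[component_cols()])) > 0
  absent_flag <- matrix[!matrix$present & any_flag, ]
  if (nrow(absent_flag) > 0) {
    v$absent_flag <- tibble::tibble(
      pair_id = absent_flag$pair_id, resource_id = absent_flag$resource_id,
      rule = "present = FALSE but a component flag is TRUE"
    )
  }

  if ("severity_std" %in% names(matrix)) {
    bad_sev <- matrix |>
      dplyr::filter((!.data$present | !.data$has_severity) &
                      .data$severity_std != "unrated")
    if (nrow(bad_sev) > 0) {
      v$sev <- tibble::tibble(
        pair_id = bad_sev$pair_id, resource_id = bad_sev$resource_id,
        rule = "severity_std must be 'unrated' when absent/undocumented"
      )
    }
    bad_lvl <- matrix |>
      dplyr::filter(!.data$severity_std %in% severity_levels())
    if (nrow(bad_lvl) > 0) {
      v$sev_lvl <- tibble::tibble(
        pair_id = bad_lvl$pair_id, resource_id = bad_lvl$resource_id,
        rule = "severity_std outside the standardized categories"
      )
    }
  }
  if ("action_std" %in% names(matrix)) {
    bad_act <- matrix |>
      dplyr::filter((!.data$present | !.data$has_course_of_action) &
                      .data$action_std != "unrated")
    if (nrow(bad_act) > 0) {
      v$act <- tibble::tibble(
        pair_id = bad_act$pair_id, resource_id = bad_act$resource_id,
        rule = "action_std must be 'unrated' when absent/undocumented"
      )
    }
    bad_lvl <- matrix |>
      dplyr::filter(!.data$action_std %in% action_levels())
    if (nrow(bad_lvl) > 0) {
      v$act_lvl <- tibble::tibble(
        pair_id = bad_lvl$pair_id, resource_id = bad_lvl$resource_id,
        rule = "action_std outside the standardized categories"
      )
    }
  }

  pair_meta <- matrix |>
    dplyr::distinct(.data$pair_id, .data$psychotropic, .data$covid_drug)
  multi <- pair_meta |>
    dplyr::count(.data$pair_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    v$pair <- tibble::tibble(
      pair_id = multi$pair_id, resource_id = NA_character_,
      rule = "pair_id mapped to more than one drug pair"
    )
  }

  if (!is.null(universe)) {
    unknown <- pair_meta |>
      dplyr::anti_join(universe, by = c("psychotropic", "covid_drug"))
    if (nrow(unknown) > 0) {
      v$universe <- tibble::tibble(
        pair_id = unknown$pair_id, resource_id = NA_character_,
        rule = "drug pair not in the configured universe"
      )
    }
  }

  if (length(v) == 0) {
    tibble::tibble(pair_id = character(), resource_id = character(),
                   rule = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' @keywords internal
assert_valid_matrix <- function(matrix, universe = NULL) {
  viol <- validate_matrix(matrix, universe)
  if (nrow(viol) > 0) {
    rlang::abort(
      c("invalid evidence matrix",
        stats::setNames(utils::head(viol$rule, 5), rep("x", min(5, nrow(viol))))),
      class = "ddi_schema_error", violations = viol
    )
  }
  invisible(matrix)
}

#' Materialize missing (pair, resource) rows as scope misses
#'
#' A (pair, resource) combination with no row in the input is treated
#' as "the resource has no entry for this pair" rather than as missing
#' data: it is filled in with `present = FALSE`, all component flags
#' `FALSE`, and empty raw labels.
#'
#' @param matrix Evidence-matrix tibble (possibly sparse).
#' @param resources Resource ids the matrix should cover; defaults to
#'   those observed in the data.
#' @return A tibble with exactly one row per (pair, resource).
#' @export
complete_matrix <- function(matrix, resources = unique(matrix$resource_id)) {
  pair_meta <- matrix |>
    dplyr::distinct(.data$pair_id, .data$psychotropic, .data$covid_drug,
                    .data$psychotropic_class)
  full <- tidyr::expand_grid(
    pair_id = pair_meta$pair_id,
    resource_id = resources
  ) |>
    dplyr::left_join(pair_meta, by = "pair_id") |>
    dplyr::left_join(
      dplyr::select(matrix, -"psychotropic", -"covid_drug",
                    -"psychotropic_class"),
      by = c("pair_id", "resource_id")
    ) |>
    dplyr::mutate(
      present = dplyr::coalesce(.data$present, FALSE),
      dplyr::across(dplyr::all_of(component_cols()),
                    ~ dplyr::coalesce(.x, FALSE)),
      severity_raw = dplyr::coalesce(.data$severity_raw, ""),
      action_raw = dplyr::coalesce(.data$action_raw, "")
    )
  if ("severity_std" %in% names(full)) {
    full <- dplyr::mutate(
      full,
      severity_std = dplyr::coalesce(.data$severity_std, "unrated"),
      action_std = dplyr::coalesce(.data$action_std, "unrated")
    )
  }
  dplyr::select(full, dplyr::all_of(matrix_cols()), dplyr::everything())
}

#' Read an evidence matrix from CSV
#'
#' Reads the pair-by-resource evidence matrix interchange format:
#' UTF-8 CSV with header, columns `pair_id, psychotropic, covid_drug,
#' psychotropic_class, resource_id, present, has_mechanism,
#' has_clinical_effects, has_severity, has_documentation_level,
#' has_course_of_action, severity_raw, action_raw`; booleans encoded
#' 0/1. Standardized columns (`severity_std`, `action_std`) are read
#' back if present, so a written matrix round-trips field-for-field.
#' Rows absent for a (pair, resource) combination are materialized as
#' `present = FALSE` via [complete_matrix()].
#'
#' @param path CSV file path.
#' @param resources Resource ids to complete against; defaults to those
#'   observed in the file.
#' @return Evidence-matrix tibble.
#' @export
read_matrix_csv <- function(path, resources = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  bad <- setdiff(matrix_cols(), names(raw))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("evidence-matrix CSV is missing column(s): ",
             paste(bad, collapse = ", ")),
      class = "ddi_schema_error"
    )
  }
  bool_cols <- c("present", component_cols())
  out <- raw |>
    dplyr::mutate(
      dplyr::across(dplyr::all_of(bool_cols), ~ .x %in% c("1", "TRUE", "true")),
      severity_raw = dplyr::coalesce(.data$severity_raw, ""),
      action_raw = dplyr::coalesce(.data$action_raw, "")
    )
  if (is.null(resources)) resources <- unique(out$resource_id)
  complete_matrix(out, resources)
}

#' Write an evidence matrix to CSV
#'
#' Inverse of [read_matrix_csv()]; booleans are written as 0/1 and
#' standardized columns are preserved when present.
#'
#' @param matrix Evidence-matrix tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(matrix, path) {
  bool_cols <- c("present", component_cols())
  out <- dplyr::mutate(
    matrix,
    dplyr::across(dplyr::all_of(bool_cols), as.integer)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
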