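#' @keywords internal
normalize_label <- function(x) {
  x <- stringr::str_replace_all(x, "’", "'")
  stringr::str_to_lower(stringr::str_squish(x))
}

#' Read a severity/action harmonization map
#'
#' Loads a YAML map with two top-level keys: `severity`, a per-resource
#' table of raw severity labels to standardized categories, and
#' `action`, a shared table of raw course-of-action labels to action
#' categories. Every raw label maps to exactly one category; lookups
#' are case-insensitive after whitespace trimming.
#'
#' @param path YAML file path.
#' @return A list with elements `severity` (named list of named
#'   character vectors, keyed by resource id) and `action` (named
#'   character vector), keys normalized to lower case.
#' @seealso [default_severity_map()]
#' @export
read_severity_map <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!all(c("severity", "action") %in% names(raw))) {
    rlang::abort("map file must have top-level keys 'severity' and 'action'",
                 class = "ddi_schema_error")
  }
  sev <- purrr::map(raw$severity, function(tbl) {
    out <- unlist(tbl)
    names(out) <- normalize_label(names(out))
    bad <- setdiff(out, setdiff(severity_levels(), "unrated"))
    if (length(bad) > 0) {
      rlang::abort(paste0("unknown severity category in map: ",
                          paste(bad, collapse = ", ")),
                   class = "ddi_schema_error")
    }
    out
  })
  act <- unlist(raw$action)
  names(act) <- normalize_label(names(act))
  bad <- setdiff(act, setdiff(action_levels(), "unrated"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown action category in map: ",
                        paste(bad, collapse = ", ")),
                 class = "ddi_schema_error")
  }
  list(severity = sev, action = act)
}

#' Default harmonization map for the six canonical resources
#'
#' The map shipped with the package: PEPID numeric levels (3 moderate;
#' 4-5 major/contraindicated; 1-2 minor), Micromedex and Drugs.com
#' verbal scales, UpToDate risk ratings (C monitor therapy = moderate;
#' D/X = major/contraindicated; A/B = minor), and the "monitor
#' closely"/"serious"/"don't use together" labels used by Medscape and
#' WebMD, together with the shared course-of-action vocabulary.
#'
#' @return A map list as documented in [read_severity_map()].
#' @export
default_severity_map <- function() {
  read_severity_map(system.file("extdata", "severity_map.yaml",
                                package = "ddiconcord", mustWork = TRUE))
}

#' Standardize a raw severity label
#'
#' Maps one resource's native severity label onto the standardized
#' scale. Matching is exact after trimming and case-folding; there is
#' no fuzzy matching, so an unknown label is a loud error rather than a
#' silent coercion. Empty labels return `unrated`.
#'
#' @param raw Character vector of raw labels (`""`/`NA` allowed).
#' @param resource_id Resource whose vocabulary `raw` belongs to.
#' @param map Harmonization map (default [default_severity_map()]).
#' @return Character vector of standardized severity categories.
#' @export
#' @examples
#' standardize_severity("C", "uptodate")
#' standardize_severity("5", "pepid")
standardize_severity <- function(raw, resource_id,
                                 map = default_severity_map()) {
  if (!resource_id %in% names(map$severity)) {
    rlang::abort(paste0("no severity map for resource '", resource_id, "'"),
                 class = "ddi_standardization_error")
  }
  tbl <- map$severity[[resource_id]]
  key <- normalize_label(raw)
  out <- unname(tbl[key])
  out[is.na(raw) | key == ""] <- "unrated"
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    rlang::abort(
      paste0("unknown severity label(s) for resource '", resource_id,
             "': ", paste(bad, collapse = ", ")),
      class = "ddi_standardization_error",
      labels = bad, resource_id = resource_id
    )
  }
  out
}

#' Standardize a raw course-of-action label
#'
#' Maps a management-recommendation label onto `no_action`, `monitor`,
#' `modify_dosage`, or `avoid` (shared vocabulary across resources).
#' Empty labels return `unrated`; unknown labels error.
#'
#' @param raw Character vector of raw labels.
#' @param map Harmonization map (default [default_severity_map()]).
#' @return Character vector of standardized action categories.
#' @export
#' @examples
#' standardize_action("Avoid combination")
#' standardize_action("Monitor closely")
standardize_action <- function(raw, map = default_severity_map()) {
  key <- normalize_label(raw)
  out <- unname(map$action[key])
  out[is.na(raw) | key == ""] <- "unrated"
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    rlang::abort(
      paste0("unknown course-of-action label(s): ",
             paste(bad, collapse = ", ")),
      class = "ddi_standardization_error", labels = bad
    )
  }
  out
}

#' Apply harmonization to a whole evidence matrix
#'
#' Adds (or recomputes) `severity_std` and `action_std` columns from
#' the raw labels: entries that are present and document the component
#' get the mapped category; everything else is `unrated`. All other
#' fields are unchanged, and the operation is idempotent because the
#' standardized columns are always derived from the raw ones.
#'
#' @param matrix Evidence-matrix tibble.
#' @param map Harmonization map (default [default_severity_map()]).
#' @return The matrix with `severity_std` and `action_std` populated.
#' @export
apply_standardization <- function(matrix, map = default_severity_map()) {
  assert_valid_matrix(dplyr::select(matrix, -dplyr::any_of(
    c("severity_std", "action_std"))))
  by_res <- split(seq_len(nrow(matrix)), matrix$resource_id)
  severity_std <- character(nrow(matrix))
  for (res in names(by_res)) {
    i <- by_res[[res]]
    rate <- matrix$present[i] & matrix$has_severity[i]
    severity_std[i] <- "unrated"
    if (any(rate)) {
      mapped <- tryCatch(
        standardize_severity(matrix$severity_raw[i][rate], res, map),
        ddi_standardization_error = function(e) {
          bad_pairs <- matrix$pair_id[i][rate][
            normalize_label(matrix$severity_raw[i][rate]) %in%
              normalize_label(e$labels)]
          rlang::abort(
            paste0(rlang::cnd_message(e), " (pair(s): ",
                   paste(unique(bad_pairs), collapse = ", "), ")"),
            class = "ddi_standardization_error", parent = e
          )
        }
      )
      severity_std[i][rate] <- mapped
    }
  }
  rate <- matrix$present & matrix$has_course_of_action
  action_std <- rep("unrated", nrow(matrix))
  if (any(rate)) {
    action_std[rate] <- tryCatch(
      standardize_action(matrix$action_raw[rate], map),
      ddi_standardization_error = function(e) {
        hit <- normalize_label(matrix$action_raw[rate]) %in%
          normalize_label(e$labels)
        rlang::abort(
          paste0(rlang::cnd_message(e), " (pair(s): ",
                 paste(unique(matrix$pair_id[rate][hit]), collapse = ", "),
                 ")"),
          class = "ddi_standardization_error", parent = e
        )
      }
    )
  }
  dplyr::mutate(matrix, severity_std = severity_std, action_std = action_std)
}
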