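#' Configuration for the synthetic evidence-matrix generator
#'
#' Describes the generative model the analysis assumes: a sample of
#' drug pairs drawn from the psychotropic x COVID-19 cross-product;
#' per-resource entry coverage `Bernoulli(coverage[r])`; per-component
#' documentation flags `Bernoulli(doc_probs[r, k])` conditional on an
#' entry; a latent true severity per pair; and a per-resource
#' confusion process — with probability `agreement` the resource
#' reports the latent severity, otherwise a uniform draw over the
#' three informative categories, so `agreement = 0` is independent
#' uniform rating and `agreement = 1` is unanimity. The course of
#' action is the deterministic image of the latent severity
#' (minor -> no action, moderate -> monitor, major/contraindicated ->
#' avoid) perturbed by the same agreement parameter (uniform over the
#' four actions on a miss).
#'
#' @param n_pairs Number of drug pairs to sample (default 181).
#' @param resources Resource ids (default the canonical six).
#' @param coverage Named (or unnamed, recycled) numeric vector of
#'   entry probabilities per resource, each in `[0, 1]`.
#' @param doc_probs Matrix (resources x 5 components) or single value
#'   of documentation probabilities given an entry; columns ordered
#'   mechanism, clinical effects, severity, level of documentation,
#'   course of action.
#' @param severity_dist Probabilities of latent `minor`, `moderate`,
#'   `major_contraindicated` (default c(0.05, 0.55, 0.40)).
#' @param agreement Probability a resource reports the latent category
#'   (default 0.8).
#' @param seed Integer root seed; every draw in [generate_matrix()]
#'   derives from it.
#' @param psychotropics,covid Drug universe overrides (see
#'   [drug_pair_universe()]).
#' @return A list of class `ddi_synth_config`.
#' @export
synthetic_config <- function(n_pairs = 181,
                             resources = ddi_resources(),
                             coverage = 0.6,
                             doc_probs = 0.8,
                             severity_dist = c(minor = 0.05,
                                               moderate = 0.55,
                                               major_contraindicated = 0.40),
                             agreement = 0.8,
                             seed = 1L,
                             psychotropics = psychotropic_drugs(),
                             covid = covid_drugs()) {
  n_res <- length(resources)
  if (length(coverage) == 1) coverage <- rep(coverage, n_res)
  if (is.null(names(coverage))) names(coverage) <- resources
  coverage <- coverage[resources]
  if (length(doc_probs) == 1) {
    doc_probs <- matrix(doc_probs, n_res, 5)
  }
  doc_probs <- as.matrix(doc_probs)
  rownames(doc_probs) <- resources
  colnames(doc_probs) <- component_cols()
  stopifnot(
    n_pairs >= 1,
    all(coverage >= 0 & coverage <= 1),
    all(doc_probs >= 0 & doc_probs <= 1),
    length(severity_dist) == 3,
    all(severity_dist >= 0), sum(severity_dist) > 0,
    agreement >= 0, agreement <= 1
  )
  structure(
    list(
      n_pairs = as.integer(n_pairs), resources = resources,
      coverage = coverage, doc_probs = doc_probs,
      severity_dist = severity_dist / sum(severity_dist),
      agreement = agreement, seed = as.integer(seed),
      psychotropics = psychotropics, covid = covid
    ),
    class = "ddi_synth_config"
  )
}

#' Generator configuration matching the published survey marginals
#'
#' A [synthetic_config()] whose coverage probabilities equal the
#' per-resource scope proportions reported for the six compendia over
#' the 181-pair psychotropic x COVID-19 sample (e.g. 143/181 for
#' PEPID), and whose documentation probabilities equal the reported
#' per-component completeness proportions (e.g. Drugs.com mechanism
#' 115/115, clinical effects 23/115). Joint dependence between
#' resources' coverage is not identifiable from marginals and is
#' modeled as independence.
#'
#' @param ... Overrides passed on to [synthetic_config()] (e.g.
#'   `agreement`, `seed`, `n_pairs`).
#' @return A `ddi_synth_config`.
#' @export
reference_marginal_config <- function(...) {
  counts <- reference_marginal_counts()
  coverage <- stats::setNames(counts$n_present / counts$n_total,
                              counts$resource_id)
  doc <- as.matrix(counts[, paste0(sub("^has_", "", component_cols()), "_n")])
  doc_probs <- doc / counts$n_present
  rownames(doc_probs) <- counts$resource_id
  synthetic_config(coverage = coverage, doc_probs = doc_probs, ...)
}

#' Published per-resource marginal counts
#'
#' The scope and per-component completeness counts reported for the
#' six compendia over the 181-pair sample; used both to parameterize
#' [reference_marginal_config()] and as fixed inputs for arithmetic
#' checks.
#'
#' @return Tibble: `resource_id`, `n_total`, `n_present`, and the five
#'   `<component>_n` columns.
#' @export
reference_marginal_counts <- function() {
  tibble::tribble(
    ~resource_id, ~n_present, ~mechanism_n, ~clinical_effects_n,
    ~severity_n, ~documentation_level_n, ~course_of_action_n,
    "pepid", 143L, 143L, 114L, 143L, 139L, 143L,
    "micromedex", 85L, 83L, 81L, 85L, 85L, 85L,
    "uptodate", 71L, 68L, 26L, 71L, 71L, 66L,
    "drugscom", 115L, 115L, 23L, 115L, 45L, 115L,
    "medscape", 95L, 71L, 36L, 94L, 16L, 94L,
    "webmd", 81L, 52L, 21L, 81L, 16L, 81L
  ) |>
    dplyr::mutate(n_total = 181L, .after = "resource_id")
}

# Representative raw label each resource uses for a standardized
# severity category (inverse of the default map).
#' @keywords internal
severity_raw_labels <- function() {
  list(
    pepid = c(minor = "2", moderate = "3", major_contraindicated = "5"),
    micromedex = c(minor = "Minor", moderate = "Moderate",
                   major_contraindicated = "Major"),
    uptodate = c(minor = "B", moderate = "C", major_contraindicated = "X"),
    drugscom = c(minor = "Minor", moderate = "Moderate",
                 major_contraindicated = "Major"),
    medscape = c(minor = "Minor", moderate = "Monitor closely",
                 major_contraindicated = "Serious"),
    webmd = c(minor = "Minor", moderate = "Monitor closely",
              major_contraindicated = "Serious")
  )
}

#' @keywords internal
action_raw_labels <- function() {
  c(no_action = "No action required", monitor = "Monitor closely",
    modify_dosage = "Consider therapy modification",
    avoid = "Avoid combination")
}

#' Generate a synthetic evidence matrix
#'
#' Draws an evidence matrix from the model described in
#' [synthetic_config()]. Pairs are sampled without replacement from
#' the configured drug universe; raw severity labels are emitted in
#' each resource's native vocabulary (so the matrix exercises the
#' standardization stage), falling back to the standardized category
#' name for resources without a configured vocabulary. Fully
#' reproducible: the same config and seed give identical matrices,
#' and the caller's RNG state is untouched.
#'
#' @param config A `ddi_synth_config`.
#' @param seed Root seed override (default `config$seed`).
#' @param standardize Also populate `severity_std` / `action_std` via
#'   [apply_standardization()]? Default `FALSE` (raw interchange form).
#' @return Evidence-matrix tibble (`n_pairs * length(resources)` rows).
#' @export
generate_matrix <- function(config = synthetic_config(),
                            seed = config$seed, standardize = FALSE) {
  stopifnot(inherits(config, "ddi_synth_config"))
  universe <- drug_pair_universe(config$psychotropics, config$covid)
  if (config$n_pairs > nrow(universe)) {
    rlang::abort(paste0(
      "n_pairs (", config$n_pairs, ") exceeds the drug-universe ",
      "cross-product (", nrow(universe), ")"
    ), class = "ddi_schema_error")
  }
  sev_cats <- setdiff(severity_levels(), "unrated")
  act_cats <- setdiff(action_levels(), "unrated")
  sev_to_act <- c(minor = "no_action", moderate = "monitor",
                  major_contraindicated = "avoid")
  sev_labels <- severity_raw_labels()
  act_labels <- action_raw_labels()

  withr::with_seed(seed, {
    pairs <- universe[sample.int(nrow(universe), config$n_pairs), ]
    pairs$pair_id <- sprintf("P%04d", seq_len(config$n_pairs))
    latent_sev <- sample(sev_cats, config$n_pairs, replace = TRUE,
                         prob = config$severity_dist)
    latent_act <- unname(sev_to_act[latent_sev])

    rows <- purrr::map(config$resources, function(res) {
      n <- config$n_pairs
      present <- stats::runif(n) < config$coverage[[res]]
      flags <- matrix(FALSE, n, 5,
                      dimnames = list(NULL, component_cols()))
      for (k in seq_len(5)) {
        flags[, k] <- present & (stats::runif(n) < config$doc_probs[res, k])
      }
      hit <- stats::runif(n) < config$agreement
      sev <- ifelse(hit, latent_sev,
                    sample(sev_cats, n, replace = TRUE))
      hit_a <- stats::runif(n) < config$agreement
      act <- ifelse(hit_a, latent_act,
                    sample(act_cats, n, replace = TRUE))
      res_sev_labels <- sev_labels[[res]]
      if (is.null(res_sev_labels)) {
        res_sev_labels <- stats::setNames(sev_cats, sev_cats)
      }
      rate_sev <- present & flags[, "has_severity"]
      rate_act <- present & flags[, "has_course_of_action"]
      tibble::tibble(
        pair_id = pairs$pair_id,
        psychotropic = pairs$psychotropic,
        covid_drug = pairs$covid_drug,
        psychotropic_class = pairs$psychotropic_class,
        resource_id = res,
        present = present,
        has_mechanism = flags[, "has_mechanism"],
        has_clinical_effects = flags[, "has_clinical_effects"],
        has_severity = flags[, "has_severity"],
        has_documentation_level = flags[, "has_documentation_level"],
        has_course_of_action = flags[, "has_course_of_action"],
        severity_raw = ifelse(rate_sev, unname(res_sev_labels[sev]), ""),
        action_raw = ifelse(rate_act, unname(act_labels[act]), "")
      )
    })
    out <- dplyr::bind_rows(rows)
    if (standardize) out <- apply_standardization(out, synthetic_map(config))
    out
  })
}

# Default map extended so that generic-universe matrices (resources or
# categories without a native vocabulary) standardize cleanly.
#' @keywords internal
synthetic_map <- function(config) {
  map <- default_severity_map()
  sev_cats <- setdiff(severity_levels(), "unrated")
  for (res in config$resources) {
    if (is.null(map$severity[[res]])) {
      map$severity[[res]] <- stats::setNames(sev_cats,
                                             normalize_label(sev_cats))
    }
  }
  map
}

#' Write the generator sidecar
#'
#' Records the generator configuration and seed next to a written
#' matrix so a run can be reproduced exactly.
#'
#' @param config A `ddi_synth_config`.
#' @param path Output JSON path.
#' @param seed Seed actually used.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(config, path, seed = config$seed) {
  out <- list(
    n_pairs = config$n_pairs, resources = config$resources,
    coverage = as.list(config$coverage),
    doc_probs = apply(config$doc_probs, 1, as.list, simplify = FALSE),
    severity_dist = as.list(config$severity_dist),
    agreement = config$agreement, seed = seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
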