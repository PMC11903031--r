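#' Analysis configuration for the end-to-end pipeline
#'
#' Bundles every setting of [run_pipeline()] so a run is reproducible from
#' its config alone. All randomness flows from the single `seed`, fanned
#' out internally with fixed per-stage offsets.
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohorts, or
#'   `NULL` when data are supplied to [run_pipeline()] directly.
#' @param n_train Cross-sectional training cohort size.
#' @param n_controls,n_patients Longitudinal cohort sizes.
#' @param idps Phenotype columns to analyse (default: the cohort's).
#' @param split_prop Fraction of controls used for site adaptation; the
#'   rest form the calibration set C.
#' @param theta Two-sided flag rate for individual z-diff scores.
#' @param fdr_level Benjamini-Hochberg FDR level for the group tests.
#' @param euler_threshold Rescaled-Euler QC cutoff (used when the data
#'   carry an `euler` column).
#' @param new_site Label of the longitudinal site when it is not among the
#'   training sites (default: reuse training sites, no adaptation needed).
#' @param seed Master seed.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = cohort_spec(),
                            n_train = 1000L,
                            n_controls = 80L,
                            n_patients = 60L,
                            idps = NULL,
                            split_prop = 0.5,
                            theta = 0.05,
                            fdr_level = 0.05,
                            euler_threshold = 10,
                            new_site = "siteNEW",
                            seed = 1L) {
  if (split_prop <= 0 || split_prop >= 1) abort("`split_prop` must be in (0, 1).")
  if (fdr_level <= 0 || fdr_level >= 1) abort("`fdr_level` must be in (0, 1).")
  if (theta <= 0 || theta >= 1) abort("`theta` must be in (0, 1).")
  structure(
    list(cohort = cohort, n_train = n_train, n_controls = n_controls,
         n_patients = n_patients, idps = idps, split_prop = split_prop,
         theta = theta, fdr_level = fdr_level,
         euler_threshold = euler_threshold, new_site = new_site,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Quality-control filter on the rescaled Euler number
#'
#' Removes every subject whose rescaled Euler number (a surface
#' reconstruction quality index supplied by the user, one value per visit
#' row) exceeds the threshold at *any* visit — both visits of a flagged
#' subject are dropped. Rows without an `euler` column pass through
#' untouched.
#'
#' @param visits Long-format visits tibble, optionally with an `euler`
#'   column.
#' @param threshold Exclusion cutoff (default 10); `Inf` disables the
#'   filter.
#' @param euler_col Name of the quality column.
#' @return List with `data` (filtered tibble) and `exclusions` (tibble of
#'   removed subjects with the offending visit and value).
#' @export
qc_euler_filter <- function(visits, threshold = 10, euler_col = "euler") {
  if (is.null(visits[[euler_col]])) {
    return(list(data = visits, exclusions = tibble::tibble(
      subject_id = character(), visit = integer(), value = numeric()
    )))
  }
  bad <- visits[visits[[euler_col]] > threshold, , drop = FALSE]
  exclusions <- tibble::tibble(
    subject_id = bad$subject_id, visit = bad$visit,
    value = bad[[euler_col]]
  )
  list(
    data = dplyr::filter(visits, !(.data$subject_id %in% exclusions$subject_id)),
    exclusions = exclusions
  )
}

#' Cross-sectional group comparison of deviation scores
#'
#' Two-sided Mann-Whitney U test of patients against held-out controls per
#' phenotype and visit, on the cross-sectional z-scores, with
#' Benjamini-Hochberg FDR correction across all tests. The sign of the
#' median difference (patients minus controls) gives the direction of the
#' effect.
#'
#' @param zscores Tibble with columns `idp`, `visit`, `group` (values
#'   `"patient"` / `"control"`) and `z`.
#' @param level FDR level.
#' @return Tibble with `idp`, `visit`, `direction`, `p`, `q`,
#'   `significant`.
#' @export
cross_sectional_group_test <- function(zscores, level = 0.05) {
  out <- zscores |>
    dplyr::group_by(.data$idp, .data$visit) |>
    dplyr::summarise(
      direction = sign(median(.data$z[.data$group == "patient"]) -
                         median(.data$z[.data$group == "control"])),
      p = suppressWarnings(wilcox.test(
        .data$z[.data$group == "patient"],
        .data$z[.data$group == "control"]
      )$p.value),
      .groups = "drop"
    )
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= level
  out
}

#' Run the full longitudinal normative-modelling pipeline
#'
#' End-to-end orchestration on synthetic (or supplied) data:
#' \enumerate{
#'   \item generate / load the cross-sectional training cohort and the
#'     two-visit longitudinal cohort at a new site;
#'   \item QC-filter on the rescaled Euler number (when present);
#'   \item fit one normative model per phenotype on the training cohort;
#'   \item split the longitudinal controls into an adaptation set and the
#'     calibration set C (disjoint by construction) and adapt each model
#'     to the new site;
#'   \item estimate the longitudinal noise scale on C;
#'   \item compute cross-sectional z-scores and the patients-vs-controls
#'     Mann-Whitney group test per visit;
#'   \item compute z-diff scores for all evaluation subjects (patients and
#'     non-C controls) and the per-phenotype Wilcoxon group test.
#' }
#' A run is fully determined by its config; rerunning with the same config
#' reproduces every output exactly.
#'
#' @param config An [analysis_config()].
#' @param train Optional cross-sectional training tibble (else generated).
#' @param longitudinal Optional long-format two-visit tibble with a
#'   `group` column (else generated).
#' @return A list of class `zdiff_run`: `models`, `noise`, `zscores`,
#'   `cross_sectional_test`, `zdiff`, `zdiff_test`, `sets` (subject ids of
#'   the adaptation / calibration / evaluation sets), `qc_exclusions`,
#'   `config`.
#' @export
run_pipeline <- function(config, train = NULL, longitudinal = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  spec <- config$cohort
  if (is.null(train)) {
    tspec <- spec
    tspec$n_subjects <- config$n_train
    tspec$seed <- config$seed
    train <- gen_cross_sectional(tspec)
  }
  if (is.null(longitudinal)) {
    lspec <- spec
    lspec$seed <- config$seed + 1L
    lspec$sites <- config$new_site
    lspec$site_offsets <- stats::setNames(0.2, config$new_site)
    longitudinal <- gen_longitudinal(lspec, config$n_controls,
                                     config$n_patients)$visits
  }
  idps <- config$idps %||% spec$idp

  qc <- qc_euler_filter(longitudinal, config$euler_threshold)
  longitudinal <- qc$data

  controls <- dplyr::filter(longitudinal, .data$group == "control")
  patients <- dplyr::filter(longitudinal, .data$group == "patient")
  split <- split_controls(controls, prop = config$split_prop,
                          seed = config$seed + 2L)
  sets <- list(
    adaptation = unique(split$adapt$subject_id),
    calibration = unique(split$calibration$subject_id),
    evaluation = unique(patients$subject_id)
  )
  if (length(intersect(sets$calibration, sets$evaluation)) ||
      length(intersect(sets$adaptation, sets$calibration))) {
    abort("Adaptation, calibration and evaluation sets must be disjoint.")
  }

  eval_visits <- dplyr::bind_rows(patients)
  basis <- basis_spec_from_data(train, age_headroom = c(1, 3))
  models <- list(); noise <- list()
  zsc <- list(); zdf <- list()
  for (idp in idps) {
    m <- fit_normative(train, idp = idp, basis = basis,
                       seed = config$seed + 3L)
    new_sites <- setdiff(unique(longitudinal$site), m$basis$site_labels)
    for (s in new_sites) {
      m <- adapt_to_site(m, dplyr::filter(split$adapt, .data$site == s),
                         site = s, idp = idp)
    }
    cal_pairs <- make_visit_pairs(split$calibration, idp)
    ns <- estimate_noise(cal_pairs, m)
    ev_pairs <- make_visit_pairs(eval_visits, idp)
    if (length(intersect(ev_pairs$subject_id, sets$calibration))) {
      abort("Calibration subjects C must not appear in the evaluation set.")
    }
    zd <- zdiff_score(ev_pairs, m, ns)
    zd$flag <- flag_score(zd$zdiff, config$theta)
    zs <- zscore(dplyr::bind_rows(split$calibration, patients), m, idp = idp)
    zs$idp <- idp
    models[[idp]] <- m
    noise[[idp]] <- ns
    zsc[[idp]] <- dplyr::select(zs, "subject_id", "visit", "group", "idp", "z")
    zdf[[idp]] <- zd
  }
  zscores <- dplyr::bind_rows(zsc)
  zdiff <- dplyr::bind_rows(zdf)
  structure(
    list(
      models = models,
      noise = noise,
      zscores = zscores,
      cross_sectional_test = cross_sectional_group_test(zscores,
                                                        config$fdr_level),
      zdiff = zdiff,
      zdiff_test = group_wilcoxon(zdiff, level = config$fdr_level),
      sets = sets,
      qc_exclusions = qc$exclusions,
      config = config
    ),
    class = "zdiff_run"
  )
}

#' @export
print.zdiff_run <- function(x, ...) {
  cat("<zdiff_run>", length(x$models), "phenotype(s) |",
      length(x$sets$adaptation), "adaptation /",
      length(x$sets$calibration), "calibration /",
      length(x$sets$evaluation), "evaluation subjects\n")
  cat("  flagged:", sum(x$zdiff$flag), "of", nrow(x$zdiff),
      "z-diff scores at theta =", x$config$theta, "\n")
  cat("  group-significant phenotypes:",
      sum(x$zdiff_test$significant), "of", nrow(x$zdiff_test), "\n")
  invisible(x)
}

#' @export
glance.zdiff_run <- function(x, ...) {
  tibble::tibble(
    n_idps = length(x$models),
    n_adaptation = length(x$sets$adaptation),
    n_calibration = length(x$sets$calibration),
    n_evaluation = length(x$sets$evaluation),
    n_flagged = sum(x$zdiff$flag),
    n_significant_idps = sum(x$zdiff_test$significant)
  )
}
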