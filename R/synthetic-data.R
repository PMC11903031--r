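#' Specification of a synthetic cohort
#'
#' Defines the generative truth for synthetic cross-sectional and two-visit
#' longitudinal cohorts. In warped space the healthy mean surface is linear,
#' `w0 + w_age * age + w_sex * sex + site_offset[site]`, and the residual of
#' a subject is either the subject-stable-factor process
#' \eqn{\varepsilon^{(i)} = \eta + \xi^{(i)}} with
#' \eqn{\eta \sim N(0, \sigma_\eta^2)}, \eqn{\xi^{(i)} \sim N(0,
#' \sigma_\xi^2)} iid across visits (so \eqn{\sigma^2 = \sigma_\eta^2 +
#' \sigma_\xi^2} and between-visit correlation \eqn{\rho =
#' \sigma_\eta^2/\sigma^2}), or, if `general_rho` is set, a stationary
#' Gaussian pair with that autocorrelation. Patients receive an additive
#' disruption \eqn{\Delta} at the second visit.
#'
#' Defaults follow the study conditions of the detection simulation:
#' total residual variance 1 split 0.7/0.3 between stable factor and visit
#' noise, a 1.1-year between-visit interval, adult age range, two sites,
#' balanced sexes.
#'
#' @param n_subjects Cross-sectional cohort size.
#' @param age_range Length-2 numeric, years; ages drawn uniformly.
#' @param sites Character vector of site labels.
#' @param site_offsets Additive site effects (warped units), one per site.
#' @param sex_balance Probability of the `sex = 1` code.
#' @param true_weights Named numeric `c(w0, w_age, w_sex)` of the mean
#'   surface in warped units.
#' @param sigma_eta2 Variance of the subject-stable factor, >= 0.
#' @param sigma_xi2 Variance of the iid visit noise, >= 0 (not both 0).
#' @param general_rho Optional autocorrelation in (-1, 1) overriding the
#'   eta+xi split (total variance stays `sigma_eta2 + sigma_xi2`).
#' @param warp A [warp_spec()]; targets are returned in raw space through
#'   its inverse.
#' @param delta Disruption added to patients' second visits (a single
#'   number: point mass).
#' @param interval_years Between-visit interval.
#' @param idp Name of the generated phenotype column.
#' @param seed Seed; identical specs generate identical tables.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 500L,
                        age_range = c(18, 60),
                        sites = c("siteA", "siteB"),
                        site_offsets = c(-0.15, 0.15),
                        sex_balance = 0.5,
                        true_weights = c(w0 = 2.5, w_age = -0.01, w_sex = 0.05),
                        sigma_eta2 = 0.7,
                        sigma_xi2 = 0.3,
                        general_rho = NULL,
                        warp = warp_spec("identity"),
                        delta = 0,
                        interval_years = 1.1,
                        idp = "thickness",
                        seed = 1L) {
  if (sigma_eta2 < 0 || sigma_xi2 < 0 || (sigma_eta2 == 0 && sigma_xi2 == 0)) {
    abort("sigma_eta2 and sigma_xi2 must be >= 0 and not both 0.")
  }
  if (!is.null(general_rho) && abs(general_rho) >= 1) {
    abort("`general_rho` must lie in (-1, 1).")
  }
  if (length(site_offsets) != length(sites)) {
    abort("One site offset per site is required.")
  }
  structure(
    list(n_subjects = n_subjects, age_range = age_range, sites = sites,
         site_offsets = stats::setNames(site_offsets, sites),
         sex_balance = sex_balance, true_weights = true_weights,
         sigma_eta2 = sigma_eta2, sigma_xi2 = sigma_xi2,
         general_rho = general_rho, warp = warp, delta = delta,
         interval_years = interval_years, idp = idp, seed = seed),
    class = "cohort_spec"
  )
}

sim_covariates <- function(spec, n) {
  tibble::tibble(
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    sex = as.numeric(runif(n) < spec$sex_balance),
    site = sample(spec$sites, n, replace = TRUE)
  )
}

true_surface <- function(spec, cov) {
  w <- spec$true_weights
  unname(w[1] + w[2] * cov$age + w[3] * cov$sex +
           spec$site_offsets[cov$site])
}

#' Generate a synthetic cross-sectional training cohort
#'
#' One visit per subject: warped targets are the true mean surface plus
#' \eqn{N(0, \sigma^2)} noise with \eqn{\sigma^2 = \sigma_\eta^2 +
#' \sigma_\xi^2}, returned in raw space through the inverse warp.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `subject_id`, `visit`, `age`, `sex`, `site` and the
#'   phenotype column.
#' @export
gen_cross_sectional <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    cov <- sim_covariates(spec, n)
    s2 <- spec$sigma_eta2 + spec$sigma_xi2
    wy <- true_surface(spec, cov) + rnorm(n, sd = sqrt(s2))
    out <- tibble::tibble(
      subject_id = sprintf("xs%05d", seq_len(n)), visit = 1L,
      age = cov$age, sex = cov$sex, site = cov$site
    )
    out[[spec$idp]] <- unwarp(wy, spec$warp)
    out
  })
}

#' Generate a synthetic two-visit longitudinal cohort with ground truth
#'
#' Controls follow the healthy residual process of the spec; patients
#' additionally receive the disruption \eqn{\Delta} at visit 2. Visit-2 age
#' is visit-1 age plus the interval. The ground truth (per-subject
#' residual components and disruption) is returned beside the data so tests
#' never re-derive it.
#'
#' @param spec A [cohort_spec()].
#' @param n_controls,n_patients Numbers of subjects per group.
#' @return List of two tibbles: `visits` (long format, with a `group`
#'   column) and `truth` (`subject_id`, `group`, `eta`, `xi1`, `xi2`,
#'   `eps1`, `eps2`, `delta`; the eta/xi columns are `NA` under a
#'   `general_rho` process).
#' @export
gen_longitudinal <- function(spec, n_controls, n_patients = 0L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed + 1L, {
    n <- n_controls + n_patients
    cov <- sim_covariates(spec, n)
    group <- rep(c("control", "patient"), c(n_controls, n_patients))
    s2 <- spec$sigma_eta2 + spec$sigma_xi2
    if (is.null(spec$general_rho)) {
      eta <- rnorm(n, sd = sqrt(spec$sigma_eta2))
      xi1 <- rnorm(n, sd = sqrt(spec$sigma_xi2))
      xi2 <- rnorm(n, sd = sqrt(spec$sigma_xi2))
      eps1 <- eta + xi1
      eps2 <- eta + xi2
    } else {
      rho <- spec$general_rho
      z1 <- rnorm(n); z2 <- rnorm(n)
      eps1 <- sqrt(s2) * z1
      eps2 <- sqrt(s2) * (rho * z1 + sqrt(1 - rho^2) * z2)
      eta <- rep(NA_real_, n); xi1 <- rep(NA_real_, n); xi2 <- rep(NA_real_, n)
    }
    delta <- ifelse(group == "patient", spec$delta, 0)
    id <- sprintf("lg%05d", seq_len(n))
    mk_visit <- function(visit, age, eps, dd) {
      out <- tibble::tibble(
        subject_id = id, visit = visit, age = age,
        sex = cov$sex, site = cov$site, group = group
      )
      out[[spec$idp]] <- unwarp(true_surface(spec, out) + eps + dd, spec$warp)
      out
    }
    visits <- dplyr::bind_rows(
      mk_visit(1L, cov$age, eps1, 0),
      mk_visit(2L, cov$age + spec$interval_years, eps2, delta)
    )
    truth <- tibble::tibble(subject_id = id, group = group,
                            eta = eta, xi1 = xi1, xi2 = xi2,
                            eps1 = eps1, eps2 = eps2, delta = delta)
    list(visits = visits, truth = truth)
  })
}
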