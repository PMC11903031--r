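#' Detection-power simulation grid
#'
#' Settings for the simulation comparing the z-diff score against naive
#' z-score subtraction: for each combination of disruption size
#' \eqn{\Delta} and residual autocorrelation \eqn{\rho}, simulated patients
#' receive correlated residual pairs and a visit-2 shift \eqn{\Delta}, and
#' the fraction flagged at nominal rate \eqn{\theta} is recorded.
#'
#' @param delta_values Disruption sizes, spanning \eqn{[-4, 4]} by default.
#' @param rho_values Autocorrelations, strictly inside \eqn{(-1, 1)}.
#' @param theta Nominal two-sided flag rate (default 0.05).
#' @param sigma2 Total residual variance (default 1).
#' @param n_per_cell Simulated subjects per \eqn{(\Delta, \rho)} cell.
#' @param interval_years Between-visit interval for the sampled covariates.
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return An object of class `sim_grid`.
#' @export
sim_grid <- function(delta_values = -4:4,
                     rho_values = c(-0.9, -0.5, 0, 0.5, 0.9),
                     theta = 0.05,
                     sigma2 = 1,
                     n_per_cell = 10000L,
                     interval_years = 1.1,
                     seed = 1L) {
  if (theta <= 0 || theta >= 1) abort("`theta` must be in (0, 1).")
  if (any(abs(rho_values) >= 1)) abort("All `rho_values` must lie in (-1, 1).")
  if (n_per_cell < 1) abort("`n_per_cell` must be >= 1.")
  if (sigma2 <= 0) abort("`sigma2` must be > 0.")
  structure(
    list(delta_values = delta_values, rho_values = rho_values,
         theta = theta, sigma2 = sigma2, n_per_cell = as.integer(n_per_cell),
         interval_years = interval_years, seed = as.integer(seed)),
    class = "sim_grid"
  )
}

#' Fit a small normative model for use as simulation truth
#'
#' The simulation scores subjects through the package's own machinery, so
#' it needs a fitted model supplying \eqn{\bar w} and \eqn{A}. This helper
#' fits one on a synthetic cross-sectional cohort whose total residual
#' variance equals the grid's `sigma2`, with the noise variance fixed at
#' that value (the remaining parameters are the cross-sectional
#' estimates). With `n_train` in the thousands the model-uncertainty term
#' is small, matching the pre-trained large-cohort setting.
#'
#' @param sigma2 Residual variance of the training cohort.
#' @param n_train Training cohort size.
#' @param seed Seed for the training draw.
#' @return A `normative_model` with an identity warp.
#' @export
make_sim_model <- function(sigma2 = 1, n_train = 2000L, seed = 1L) {
  spec <- cohort_spec(n_subjects = n_train,
                      sigma_eta2 = 0.7 * sigma2, sigma_xi2 = 0.3 * sigma2,
                      seed = seed)
  train <- gen_cross_sectional(spec)
  basis <- basis_spec(boundary_knots = spec$age_range + c(0, 2),
                      degree = 1L, site_labels = spec$sites)
  fit_normative(train, idp = spec$idp, basis = basis,
                sigma2 = sigma2, omega2 = 10)
}

#' Simulate one (delta, rho) cell
#'
#' Draws `n_per_cell` subjects with ages uniform over the model's age range
#' and balanced sexes, residual pairs \eqn{(\varepsilon^{(1)},
#' \varepsilon^{(2)})} bivariate normal with variance `sigma2` and
#' correlation `rho`, and visit-2 disruption `delta`. Each subject is
#' scored with [zdiff_score()] using the true noise scale
#' \eqn{2\sigma^2(1-\rho)} and with [naive_zdiff()]; the fractions flagged
#' at `theta` are returned.
#'
#' @param delta Disruption added at visit 2.
#' @param rho Residual autocorrelation, in (-1, 1).
#' @param grid A [sim_grid()].
#' @param model A `normative_model` (see [make_sim_model()]); its `sigma2`
#'   should equal the grid's.
#' @param seed Seed for this cell's draws.
#' @return Tibble with rows for methods `zdiff` and `naive`: `delta`,
#'   `rho`, `method`, `rate`, `se`, `n`.
#' @export
simulate_cell <- function(delta, rho, grid, model, seed = grid$seed) {
  if (abs(rho) >= 1) abort("`rho` must lie in (-1, 1).")
  basis <- model$basis
  n <- grid$n_per_cell
  s2 <- grid$sigma2
  with_seed(seed, {
    cov <- tibble::tibble(
      age = runif(n, basis$boundary_knots[1],
                  basis$boundary_knots[2] - grid$interval_years),
      sex = rep_len(c(0, 1), n),
      site = basis$site_labels[1]
    )
    z1 <- rnorm(n); z2 <- rnorm(n)
    eps1 <- sqrt(s2) * z1
    eps2 <- sqrt(s2) * (rho * z1 + sqrt(1 - rho^2) * z2)
    X1 <- expand_basis(cov, basis)
    cov2 <- dplyr::mutate(cov, age = .data$age + grid$interval_years)
    X2 <- expand_basis(cov2, basis)
    pairs <- tibble::tibble(
      subject_id = sprintf("sim%05d", seq_len(n)),
      sex = cov$sex, site = cov$site,
      age1 = cov$age, age2 = cov2$age, interval = grid$interval_years,
      y1 = unwarp(drop(X1 %*% model$w_bar) + eps1, model$warp),
      y2 = unwarp(drop(X2 %*% model$w_bar) + eps2 + delta, model$warp),
      idp = model$idp
    )
    zd <- zdiff_score(pairs, model, noise = 2 * s2 * (1 - rho))$zdiff
    nv <- naive_zdiff(pairs, model)$naive
    rate_z <- mean(flag_score(zd, grid$theta))
    rate_n <- mean(flag_score(nv, grid$theta))
    tibble::tibble(
      delta = delta, rho = rho,
      method = c("zdiff", "naive"),
      rate = c(rate_z, rate_n),
      se = sqrt(c(rate_z, rate_n) * (1 - c(rate_z, rate_n)) / n),
      n = n
    )
  })
}

#' Run the full detection-rate grid
#'
#' Simulates every \eqn{(\Delta, \rho)} cell of the grid for both methods.
#' Deterministic given the grid seed (per-cell seeds are derived from it,
#' so cells are independent and order-insensitive).
#'
#' @param grid A [sim_grid()].
#' @param model A `normative_model`; by default a small simulation-truth
#'   model fitted with [make_sim_model()] at the grid's `sigma2`.
#' @return A tibble of class `sim_result` with columns `delta`, `rho`,
#'   `method`, `rate`, `se`, `n`.
#' @export
run_grid <- function(grid, model = NULL) {
  stopifnot(inherits(grid, "sim_grid"))
  if (is.null(model)) model <- make_sim_model(grid$sigma2, seed = grid$seed)
  cells <- tidyr::expand_grid(delta = grid$delta_values, rho = grid$rho_values)
  out <- purrr::pmap(
    list(cells$delta, cells$rho, seq_len(nrow(cells))),
    function(d, r, i) simulate_cell(d, r, grid, model,
                                    seed = grid$seed + 1000L * i)
  )
  res <- dplyr::bind_rows(out)
  attr(res, "theta") <- grid$theta
  attr(res, "sigma2") <- grid$sigma2
  class(res) <- c("sim_result", class(res))
  res
}

#' Closed-form detection rate
#'
#' Analytic counterpart of the simulation, assuming a negligible
#' model-uncertainty term. The z-diff statistic is \eqn{N(\mu, 1)} with
#' \eqn{\mu = \Delta/\sqrt{2\sigma^2(1-\rho)}}, so the detection rate is
#' \eqn{\Phi(q_{\theta/2} - \mu) + 1 - \Phi(q_{1-\theta/2} - \mu)}. The
#' naive difference of z-scores is \eqn{N(\Delta/\sigma,\; 2(1-\rho))}
#' thresholded at the same standard-normal quantiles — hence its null rate
#' \eqn{2\Phi(q_{\theta/2}/\sqrt{2(1-\rho)})} drifts with \eqn{\rho}.
#'
#' @param delta Disruption size (vectorised).
#' @param rho Autocorrelation (vectorised).
#' @param theta Nominal two-sided rate.
#' @param sigma2 Total residual variance.
#' @param method `"zdiff"` or `"naive"`.
#' @return Numeric detection rate(s) in \[0, 1\].
#' @export
analytic_detection_rate <- function(delta, rho, theta = 0.05, sigma2 = 1,
                                    method = c("zdiff", "naive")) {
  method <- match.arg(method)
  lo <- qnorm(theta / 2)
  hi <- qnorm(1 - theta / 2)
  if (method == "zdiff") {
    mu <- delta / sqrt(2 * sigma2 * (1 - rho))
    pnorm(lo - mu) + 1 - pnorm(hi - mu)
  } else {
    m <- delta / sqrt(sigma2)
    s <- sqrt(2 * (1 - rho))
    pnorm(lo, mean = m, sd = s) + 1 - pnorm(hi, mean = m, sd = s)
  }
}

#' @export
glance.sim_result <- function(x, ...) {
  theta <- attr(x, "theta")
  null_rates <- dplyr::filter(x, .data$delta == 0)
  tibble::tibble(
    theta = theta,
    n_cells = nrow(x) / 2,
    fpr_zdiff = mean(null_rates$rate[null_rates$method == "zdiff"]),
    fpr_naive = mean(null_rates$rate[null_rates$method == "naive"])
  )
}

#' Plot a detection-rate grid
#'
#' Detection rate against disruption size, one panel per autocorrelation,
#' simulated points with analytic curves underneath.
#'
#' @param object A `sim_result` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_result <- function(object, ...) {
  theta <- attr(object, "theta") %||% 0.05
  sigma2 <- attr(object, "sigma2") %||% 1
  curves <- tidyr::expand_grid(
    delta = seq(min(object$delta), max(object$delta), length.out = 81),
    rho = unique(object$rho),
    method = c("zdiff", "naive")
  )
  curves$rate <- purrr::pmap_dbl(
    list(curves$delta, curves$rho, curves$method),
    function(d, r, m) analytic_detection_rate(d, r, theta, sigma2, m)
  )
  ggplot2::ggplot(object, ggplot2::aes(.data$delta, .data$rate,
                                       colour = .data$method)) +
    ggplot2::geom_line(data = curves, alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = theta, linetype = "dotted") +
    ggplot2::facet_wrap(~rho, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(Delta), y = "detection rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
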