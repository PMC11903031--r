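#' Fit the Bayesian linear regression posterior in warped space
#'
#' Given a design matrix \eqn{\Phi} and warped targets \eqn{\varphi(y)},
#' with Gaussian noise variance \eqn{\sigma^2} and an isotropic
#' \eqn{N(0, \omega^2 I)} prior on the weights, computes the posterior
#' \eqn{w \mid y \sim N(\bar w, A^{-1})} in closed form:
#' \deqn{A = \sigma^{-2}\Phi^\top\Phi + \omega^{-2} I, \qquad
#'       \bar w = \sigma^{-2} A^{-1} \Phi^\top \varphi(y).}
#' `A` is factorised by Cholesky; its inverse is never formed explicitly.
#' An empty design returns the prior (`w_bar = 0`, `A` = \eqn{\omega^{-2}I}).
#'
#' @param design N x K numeric matrix (no non-finite entries).
#' @param warped_targets Length-N numeric vector, already in warped space.
#' @param sigma2 Warped-space noise variance, > 0.
#' @param omega2 Prior weight variance, > 0.
#' @param warp A [warp_spec()] stored with the model (default identity).
#' @param basis Optional [basis_spec()] stored with the model; required by
#'   the data-frame scoring interface ([zscore()], [predictive()]).
#' @param idp Name of the phenotype this model describes.
#' @return An object of class `normative_model` with elements `w_bar`,
#'   `chol_A` (upper-triangular factor, `A = t(R) %*% R`), `sigma2`,
#'   `omega2`, `warp`, `basis`, `n_train`, `idp`, `adaptations`.
#' @export
fit_posterior <- function(design, warped_targets, sigma2, omega2,
                          warp = warp_spec("identity"), basis = NULL,
                          idp = "idp") {
  design <- as.matrix(design)
  K <- ncol(design)
  n <- nrow(design)
  if (length(warped_targets) != n) abort("Design/target length mismatch.")
  if (n > 0 && (any(!is.finite(design)) || any(!is.finite(warped_targets)))) {
    abort("Non-finite entries in design or targets.")
  }
  if (sigma2 <= 0 || omega2 <= 0) abort("Variances must be > 0.")
  if (K > n) inform(paste0("K = ", K, " > N = ", n,
                           "; the prior regularises the fit."))
  A <- crossprod(design) / sigma2 + diag(1 / omega2, K)
  R <- chol(A)
  b <- if (n > 0) crossprod(design, warped_targets) / sigma2 else rep(0, K)
  w_bar <- backsolve(R, backsolve(R, b, transpose = TRUE))
  structure(
    list(w_bar = drop(w_bar), chol_A = R, sigma2 = sigma2, omega2 = omega2,
         warp = warp, basis = basis, n_train = n, idp = idp,
         adaptations = list()),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model>", x$idp, "| K =", length(x$w_bar),
      "| n_train =", x$n_train, "\n")
  cat("  sigma2 =", signif(x$sigma2, 5), " omega2 =", signif(x$omega2, 5),
      " warp:", x$warp$family, "\n")
  if (length(x$adaptations)) {
    cat("  adapted sites:", paste(names(x$adaptations), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.normative_model <- function(x, ...) {
  nm <- names(x$w_bar)
  if (is.null(nm)) nm <- paste0("w", seq_along(x$w_bar))
  tibble::tibble(term = nm, estimate = unname(x$w_bar))
}

#' @export
glance.normative_model <- function(x, ...) {
  tibble::tibble(
    idp = x$idp, k = length(x$w_bar), n_train = x$n_train,
    sigma2 = x$sigma2, omega2 = x$omega2, warp_family = x$warp$family,
    n_adapted_sites = length(x$adaptations)
  )
}

# diag(X %*% A^{-1} %*% t(X)) via the stored Cholesky factor
quad_Ainv <- function(model, X) {
  if (nrow(X) == 0L) return(numeric())
  Z <- backsolve(model$chol_A, t(X), transpose = TRUE)
  colSums(Z^2)
}

# design rows for scoring: training sites use their dummy, adapted sites use
# the site-agnostic map (dummies zeroed); anything else is an error
model_design <- function(data, model) {
  basis <- model$basis
  if (is.null(basis)) abort("Model carries no basis_spec; cannot score data frames.")
  site <- as.character(data$site)
  if (is.null(data$site)) abort("Missing `site` column.")
  known <- site %in% basis$site_labels
  adapted <- site %in% names(model$adaptations)
  if (any(!known & !adapted)) {
    bad <- unique(site[!known & !adapted])
    abort(paste0("Site(s) ", paste(bad, collapse = ", "),
                 " are neither in the training sites nor adapted. ",
                 "Run `adapt_to_site()` first."))
  }
  X <- matrix(0, nrow(data), basis_dim(basis))
  if (any(known & !adapted)) {
    X[known & !adapted, ] <- expand_basis(data[known & !adapted, , drop = FALSE], basis)
  }
  if (any(!known & adapted)) {
    X[!known & adapted, ] <- expand_basis(data[!known & adapted, , drop = FALSE],
                                          basis, average_site = TRUE)
  }
  list(X = X, adapted = !known & adapted, site = site)
}

#' Posterior predictive distribution at new covariates
#'
#' For each row, returns the predictive mean \eqn{\bar w^\top \phi(x)} and
#' variance \eqn{\phi(x)^\top A^{-1}\phi(x) + \sigma^2} of the warped
#' phenotype. The variance always exceeds \eqn{\sigma^2}.
#'
#' @param data Data frame with the model's covariate columns and `site`.
#' @param model A `normative_model`.
#' @return The input as a tibble with columns `.pred_mean` and `.pred_var`
#'   (warped units) appended.
#' @export
predictive <- function(data, model) {
  d <- model_design(data, model)
  mu <- drop(d$X %*% model$w_bar)
  v <- quad_Ainv(model, d$X) + model$sigma2
  dplyr::mutate(tibble::as_tibble(data), .pred_mean = mu, .pred_var = v)
}

#' Cross-sectional deviation z-score
#'
#' Position of each observation within the modelled healthy population:
#' \deqn{z = \frac{\varphi(y) - \bar w^\top\phi(x)}
#'   {\sqrt{\phi(x)^\top A^{-1}\phi(x) + \sigma^2}}.}
#' At a site the model was adapted to with [adapt_to_site()], the score is
#' additionally recentred and rescaled by that site's stored offset and
#' scale.
#'
#' @inheritParams predictive
#' @param idp Column holding the raw phenotype; defaults to the model's.
#' @return The input as a tibble with a `z` column appended.
#' @export
zscore <- function(data, model, idp = model$idp) {
  y <- data[[idp]]
  if (is.null(y)) abort(paste0("Missing phenotype column `", idp, "`."))
  d <- model_design(data, model)
  mu <- drop(d$X %*% model$w_bar)
  v <- quad_Ainv(model, d$X) + model$sigma2
  z <- (warp(y, model$warp) - mu) / sqrt(v)
  if (any(d$adapted)) {
    for (s in unique(d$site[d$adapted])) {
      i <- d$adapted & d$site == s
      ad <- model$adaptations[[s]]
      z[i] <- (z[i] - ad$offset) / ad$scale
    }
  }
  dplyr::mutate(tibble::as_tibble(data), z = z)
}

#' Warped marginal log-likelihood (model evidence)
#'
#' Log density of the warped targets under the evidence
#' \eqn{N(0,\; \sigma^2 I + \omega^2 \Phi\Phi^\top)} plus the Jacobian term
#' \eqn{\sum_n \log\varphi'(y_n)} — the objective maximised to estimate the
#' hyper-parameters. Evaluated via the matrix-determinant lemma in K x K
#' space, so cost is linear in N.
#'
#' @param raw_targets Length-N numeric vector in raw phenotype units.
#' @param design N x K matrix.
#' @param sigma2,omega2 Variances, > 0.
#' @param warp A [warp_spec()].
#' @return Scalar log-likelihood.
#' @export
warped_marginal_loglik <- function(raw_targets, design, sigma2, omega2,
                                   warp = warp_spec("identity")) {
  if (sigma2 <= 0 || omega2 <= 0) abort("Variances must be > 0.")
  design <- as.matrix(design)
  n <- nrow(design)
  z <- warp(raw_targets, warp)
  M <- diag(ncol(design)) + (omega2 / sigma2) * crossprod(design)
  Rm <- chol(M)
  logdet <- n * log(sigma2) + 2 * sum(log(diag(Rm)))
  pz <- crossprod(design, z)
  sol <- backsolve(Rm, backsolve(Rm, pz, transpose = TRUE))
  quad <- (sum(z^2) - (omega2 / sigma2) * sum(pz * sol)) / sigma2
  -0.5 * (n * log(2 * pi) + logdet + quad) + sum(warp_logderiv(raw_targets, warp))
}

#' Estimate hyper-parameters by maximising the warped evidence
#'
#' Quasi-Newton (BFGS) search over \eqn{(\log\sigma^2, \log\omega^2)} and,
#' for the sinh-arcsinh family, the unconstrained \eqn{(a, \log b)}, with
#' seeded multi-start (default 5 restarts) around a moment-based
#' initialisation. The returned optimum never falls below any restart's
#' initial objective value.
#'
#' @param raw_targets Length-N numeric vector, raw units.
#' @param design N x K matrix.
#' @param warp_family `"identity"` or `"sinh_arcsinh"`.
#' @param restarts Number of restarts.
#' @param seed Seed for the restart jitter.
#' @return List with `sigma2`, `omega2`, `warp` (a [warp_spec()] carrying
#'   the fitted gamma), and `loglik` at the optimum.
#' @export
optimize_hyperparams <- function(raw_targets, design,
                                 warp_family = c("identity", "sinh_arcsinh"),
                                 restarts = 5L, seed = 1L) {
  warp_family <- match.arg(warp_family)
  design <- as.matrix(design)
  n <- nrow(design)
  if (n < ncol(design)) inform("N < K; evidence optimisation may be poorly identified.")
  loc <- mean(raw_targets)
  scale <- sd(raw_targets)
  if (!is.finite(scale) || scale < 1e-12) scale <- 1
  mk_warp <- function(par) {
    if (warp_family == "identity") warp_spec("identity")
    else warp_spec("sinh_arcsinh", gamma = c(par[3], exp(par[4])),
                   loc = loc, scale = scale)
  }
  lb <- log(1e-8)
  negll <- function(par) {
    par[1:2] <- pmax(par[1:2], lb)
    w <- tryCatch(mk_warp(par), error = function(e) NULL)
    if (is.null(w)) return(1e10)
    v <- tryCatch(
      -warped_marginal_loglik(raw_targets, design, exp(par[1]), exp(par[2]), w),
      error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  v0 <- var(raw_targets)
  if (!is.finite(v0) || v0 < 1e-8) v0 <- 1e-8
  base <- c(log(v0), log(max(v0, 1)))
  if (warp_family == "sinh_arcsinh") base <- c(base, 0, 0)
  inits <- with_seed(seed, {
    lapply(seq_len(max(1L, restarts)), function(i) {
      if (i == 1L) base else base + rnorm(length(base), sd = 1)
    })
  })
  fits <- lapply(inits, function(p0) {
    tryCatch(
      optim(p0, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits)) abort("Hyper-parameter optimisation failed in all restarts.")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  par <- best$par
  par[1:2] <- pmax(par[1:2], lb)
  list(sigma2 = exp(par[1]), omega2 = exp(par[2]), warp = mk_warp(par),
       loglik = -best$value)
}

#' Fit a normative model to a cross-sectional cohort
#'
#' High-level fit for one phenotype: builds (or accepts) a [basis_spec()],
#' estimates \eqn{\sigma^2, \omega^2} (and warp shape) by evidence
#' maximisation unless supplied, then computes the closed-form posterior.
#'
#' @param data Cross-sectional tibble with covariates, `site`, and the
#'   phenotype column.
#' @param idp Name of the phenotype column.
#' @param basis Optional [basis_spec()]; by default built from the data
#'   with [basis_spec_from_data()].
#' @param warp_family Likelihood warp family.
#' @param sigma2,omega2 Optional fixed variances; both must be given to
#'   skip evidence optimisation.
#' @param restarts,seed Passed to [optimize_hyperparams()].
#' @return A `normative_model`.
#' @export
fit_normative <- function(data, idp, basis = NULL,
                          warp_family = c("identity", "sinh_arcsinh"),
                          sigma2 = NULL, omega2 = NULL,
                          restarts = 5L, seed = 1L) {
  warp_family <- match.arg(warp_family)
  y <- data[[idp]]
  if (is.null(y)) abort(paste0("Missing phenotype column `", idp, "`."))
  if (is.null(basis)) basis <- basis_spec_from_data(data)
  X <- expand_basis(data, basis)
  if (is.null(sigma2) || is.null(omega2)) {
    hp <- optimize_hyperparams(y, X, warp_family, restarts = restarts, seed = seed)
    sigma2 <- hp$sigma2; omega2 <- hp$omega2; wsp <- hp$warp
  } else {
    wsp <- warp_spec("identity")
  }
  m <- fit_posterior(X, warp(y, wsp), sigma2, omega2,
                     warp = wsp, basis = basis, idp = idp)
  names(m$w_bar) <- colnames(X)
  m
}

#' Plot normative centile curves over age
#'
#' Predictive centiles of the raw phenotype as a function of age at a
#' reference site and linear-covariate setting.
#'
#' @param object A `normative_model` (with a basis).
#' @param site Site label to plot at (default: first training site).
#' @param centiles Probabilities of the curves to draw.
#' @param sex Value of the sex code used for the curves.
#' @param n Grid resolution over the age range.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normative_model <- function(object, site = NULL,
                                     centiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                     sex = 0, n = 101, ...) {
  basis <- object$basis
  if (is.null(basis)) abort("Model carries no basis_spec.")
  if (is.null(site)) site <- basis$site_labels[1]
  grid <- tibble::tibble(
    age = seq(basis$boundary_knots[1], basis$boundary_knots[2], length.out = n),
    sex = sex, site = site
  )
  pred <- predictive(grid, object)
  curves <- purrr::map_dfr(centiles, function(p) {
    dplyr::mutate(pred,
                  centile = p,
                  value = unwarp(.data$.pred_mean + qnorm(p) * sqrt(.data$.pred_var),
                                 object$warp))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$age, .data$value,
                                       group = .data$centile)) +
    ggplot2::geom_line(ggplot2::aes(linetype = factor(.data$centile))) +
    ggplot2::labs(x = "age (years)", y = object$idp,
                  linetype = "centile",
                  title = paste("Normative centiles at site", site)) +
    ggplot2::theme_minimal()
}
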