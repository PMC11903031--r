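#' Covariate basis specification
#'
#' Describes the deterministic feature map applied to each subject's
#' covariates before regression: a B-spline expansion of one continuous
#' covariate (age, in years), raw linear covariates (e.g. a 0/1 sex code),
#' a one-hot block of site dummies, and an optional intercept. The resulting
#' feature vector has a fixed length
#' `K = (degree + 1 + #interior knots) + #linear + #sites + intercept`.
#'
#' Site dummies are full one-hot (not reference-coded); the ridge-type
#' prior on the regression weights absorbs the redundancy with the
#' intercept. Ages outside the boundary knots are clamped to the boundary
#' with a warning, so a pre-trained model can score slightly out-of-range
#' subjects without extrapolating the spline.
#'
#' @param boundary_knots Length-2 numeric, the spline support (years).
#' @param interior_knots Non-decreasing numeric vector of interior knots
#'   (years), strictly inside the boundary.
#' @param degree B-spline degree (3 = cubic).
#' @param spline_covariate Name of the column expanded by the spline.
#' @param linear_covariates Character vector of columns entered linearly.
#' @param site_labels Ordered character vector of known scanner sites.
#' @param intercept Include an intercept column?
#' @param sex_levels Named numeric vector documenting the sex coding stored
#'   with the model (so scoring cannot silently flip it).
#'
#' @return An object of class `basis_spec`.
#' @seealso [expand_basis()], [basis_spec_from_data()]
#' @export
basis_spec <- function(boundary_knots,
                       interior_knots = numeric(),
                       degree = 3L,
                       spline_covariate = "age",
                       linear_covariates = "sex",
                       site_labels = "site1",
                       intercept = TRUE,
                       sex_levels = c(female = 0, male = 1)) {
  boundary_knots <- as.numeric(boundary_knots)
  interior_knots <- as.numeric(interior_knots)
  if (length(boundary_knots) != 2L || boundary_knots[1] >= boundary_knots[2]) {
    abort("`boundary_knots` must be an increasing pair.")
  }
  if (is.unsorted(interior_knots)) {
    abort("`interior_knots` must be non-decreasing.")
  }
  if (length(interior_knots) &&
      (min(interior_knots) <= boundary_knots[1] ||
       max(interior_knots) >= boundary_knots[2])) {
    abort("Boundary knots must bracket all interior knots.")
  }
  if (degree < 0) abort("`degree` must be >= 0.")
  spec <- structure(
    list(
      spline_covariate = spline_covariate,
      spline_degree = as.integer(degree),
      interior_knots = interior_knots,
      boundary_knots = boundary_knots,
      linear_covariates = as.character(linear_covariates),
      site_labels = as.character(site_labels),
      include_intercept = isTRUE(intercept),
      sex_levels = sex_levels
    ),
    class = "basis_spec"
  )
  spec
}

#' Build a basis specification from training data
#'
#' Places `n_interior` interior knots at equally spaced quantiles of the
#' training ages, with boundary knots at the training age range, and takes
#' the site labels from the data.
#'
#' @param data Data frame with the covariate columns.
#' @param n_interior Number of interior knots (default 5).
#' @param age_headroom Years added beyond the training age range when
#'   placing the boundary knots (length 1: above only; length 2: below and
#'   above), so that scored subjects slightly outside the training range —
#'   notably follow-up visits — do not hit the boundary clamp.
#' @inheritParams basis_spec
#' @return A `basis_spec`.
#' @export
basis_spec_from_data <- function(data, n_interior = 5L, degree = 3L,
                                 spline_covariate = "age",
                                 linear_covariates = "sex",
                                 intercept = TRUE,
                                 age_headroom = 0) {
  ages <- data[[spline_covariate]]
  if (is.null(ages)) abort(paste0("Missing covariate `", spline_covariate, "`."))
  probs <- seq(0, 1, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  pad <- if (length(age_headroom) == 1L) c(0, age_headroom) else age_headroom
  basis_spec(
    boundary_knots = range(ages) + c(-pad[1], pad[2]),
    interior_knots = unname(quantile(ages, probs)),
    degree = degree,
    spline_covariate = spline_covariate,
    linear_covariates = linear_covariates,
    site_labels = sort(unique(as.character(data$site))),
    intercept = intercept
  )
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("<basis_spec> K =", basis_dim(x), "\n")
  cat("  spline:", x$spline_covariate, "degree", x$spline_degree,
      "| interior knots:", if (length(x$interior_knots)) paste(signif(x$interior_knots, 4), collapse = ", ") else "none",
      "| boundary:", paste(signif(x$boundary_knots, 4), collapse = "-"), "\n")
  cat("  linear:", paste(x$linear_covariates, collapse = ", "),
      "| sites:", paste(x$site_labels, collapse = ", "),
      "| intercept:", x$include_intercept, "\n")
  invisible(x)
}

#' Output dimension K of a basis specification
#' @param spec A `basis_spec`.
#' @return Integer K.
#' @export
basis_dim <- function(spec) {
  (spec$spline_degree + 1L + length(spec$interior_knots)) +
    length(spec$linear_covariates) +
    length(spec$site_labels) +
    as.integer(spec$include_intercept)
}

# full knot vector for splines::splineDesign
full_knots <- function(spec) {
  c(rep(spec$boundary_knots[1], spec$spline_degree + 1L),
    spec$interior_knots,
    rep(spec$boundary_knots[2], spec$spline_degree + 1L))
}

#' Expand covariate rows into the model feature space
#'
#' Evaluates the deterministic feature map for every row of `data`:
#' B-spline block (standard B-spline recursion via [splines::splineDesign()]),
#' linear covariates, one-hot site dummies, intercept. Deterministic;
#' the spline block of every row sums to exactly 1 (partition of unity).
#'
#' @param data Data frame supplying every covariate named in `spec`
#'   (and a `site` column unless `average_site = TRUE`).
#' @param spec A [basis_spec()].
#' @param average_site If `TRUE`, the site-dummy block is set to `1/S` in
#'   each of the `S` site columns for all rows — the site-agnostic
#'   "average training site" reference used when scoring an unseen scanner.
#'   (A zeroed dummy block would leave the training span, since the spline
#'   block, intercept and dummies are collinear, and would pick up
#'   prior-level uncertainty; the average-site row stays in-span and is
#'   unbiased up to the mean training-site effect.)
#' @return Numeric matrix with `nrow(data)` rows and `basis_dim(spec)`
#'   columns.
#' @export
expand_basis <- function(data, spec, average_site = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  n <- nrow(data)
  x <- data[[spec$spline_covariate]]
  if (is.null(x)) abort(paste0("Missing covariate `", spec$spline_covariate, "`."))
  if (any(!is.finite(x))) abort("Non-finite values in the spline covariate.")
  bk <- spec$boundary_knots
  if (any(x < bk[1] | x > bk[2])) {
    warn(paste0("Ages outside the boundary knots [", bk[1], ", ", bk[2],
                "] were clamped to the boundary."))
    x <- pmin(pmax(x, bk[1]), bk[2])
  }
  spl <- splines::splineDesign(full_knots(spec), x,
                               ord = spec$spline_degree + 1L,
                               outer.ok = FALSE)
  colnames(spl) <- paste0("spline", seq_len(ncol(spl)))

  lin <- NULL
  if (length(spec$linear_covariates)) {
    lin <- vapply(spec$linear_covariates, function(v) {
      col <- data[[v]]
      if (is.null(col)) abort(paste0("Missing covariate `", v, "`."))
      as.numeric(col)
    }, numeric(n))
    lin <- matrix(lin, nrow = n,
                  dimnames = list(NULL, spec$linear_covariates))
    if (any(!is.finite(lin))) abort("Non-finite values in linear covariates.")
  }

  ns <- length(spec$site_labels)
  sites <- matrix(if (average_site) 1 / ns else 0, n, ns,
                  dimnames = list(NULL, paste0("site_", spec$site_labels)))
  if (!average_site && ns > 0) {
    lab <- as.character(data$site)
    if (is.null(data$site)) abort("Missing `site` column.")
    idx <- match(lab, spec$site_labels)
    if (anyNA(idx)) {
      bad <- unique(lab[is.na(idx)])
      abort(paste0("Unknown site label(s): ", paste(bad, collapse = ", "),
                   ". Known sites: ", paste(spec$site_labels, collapse = ", "),
                   ". Use `adapt_to_site()` for a new scanner."))
    }
    sites[cbind(seq_len(n), idx)] <- 1
  }

  out <- cbind(spl, lin, sites)
  if (spec$include_intercept) {
    out <- cbind(out, `(intercept)` = rep(1, n))
  }
  out
}

#' Likelihood warp specification
#'
#' A monotone transform applied to the raw phenotype so its residuals are
#' Gaussian in the warped space. Two families are supported:
#' `identity` (no transform) and `sinh_arcsinh`,
#' \eqn{\varphi(y) = \sinh(b\,\mathrm{asinh}(\tilde y) - a)} with
#' \eqn{\tilde y = (y - \mathrm{loc})/\mathrm{scale}}, shape parameters
#' \eqn{\gamma = (a, b)} controlling skew and tail weight, `b > 0`.
#' Strict monotonicity is checked numerically on a grid at construction.
#'
#' @param family `"identity"` or `"sinh_arcsinh"`.
#' @param gamma Numeric shape vector: empty for identity, `c(a, b)` for
#'   sinh-arcsinh.
#' @param loc,scale Affine input standardisation, in raw phenotype units.
#' @return An object of class `warp_spec`.
#' @export
warp_spec <- function(family = c("identity", "sinh_arcsinh"),
                      gamma = numeric(), loc = 0, scale = 1) {
  family <- match.arg(family)
  if (family == "sinh_arcsinh") {
    if (length(gamma) != 2L) abort("sinh_arcsinh needs gamma = c(a, b).")
    if (!all(is.finite(gamma))) abort("Non-finite warp parameters.")
    if (gamma[2] <= 0) abort("Warp tail parameter b must be > 0.")
  }
  if (scale <= 0) abort("`scale` must be > 0.")
  spec <- structure(
    list(family = family, gamma = as.numeric(gamma),
         loc = as.numeric(loc), scale = as.numeric(scale)),
    class = "warp_spec"
  )
  grid <- spec$loc + spec$scale * seq(-5, 5, length.out = 201)
  if (any(diff(warp(grid, spec)) <= 0)) {
    abort("Warp is not strictly increasing on the support.")
  }
  spec
}

#' @export
print.warp_spec <- function(x, ...) {
  cat("<warp_spec>", x$family)
  if (x$family == "sinh_arcsinh") {
    cat(" a =", x$gamma[1], "b =", x$gamma[2])
  }
  cat(" | loc =", x$loc, "scale =", x$scale, "\n")
  invisible(x)
}

#' Apply / invert the likelihood warp
#'
#' `warp()` maps raw phenotype values into the warped (Gaussian) space,
#' `unwarp()` is its exact inverse, and `warp_logderiv()` returns
#' \eqn{\log \varphi'(y)}, the Jacobian term of the warped marginal
#' likelihood.
#'
#' @param y,z Numeric vectors (raw / warped values).
#' @param spec A [warp_spec()].
#' @return Numeric vector.
#' @export
warp <- function(y, spec) {
  if (any(!is.finite(y))) abort("Non-finite input to warp().")
  if (spec$family == "identity") return(y)
  yt <- (y - spec$loc) / spec$scale
  sinh(spec$gamma[2] * asinh(yt) - spec$gamma[1])
}

#' @rdname warp
#' @export
unwarp <- function(z, spec) {
  if (any(!is.finite(z))) abort("Non-finite input to unwarp().")
  if (spec$family == "identity") return(z)
  spec$loc + spec$scale * sinh((asinh(z) + spec$gamma[1]) / spec$gamma[2])
}

#' @rdname warp
#' @export
warp_logderiv <- function(y, spec) {
  if (any(!is.finite(y))) abort("Non-finite input to warp_logderiv().")
  if (spec$family == "identity") return(rep(0, length(y)))
  yt <- (y - spec$loc) / spec$scale
  log(spec$gamma[2]) + log(cosh(spec$gamma[2] * asinh(yt) - spec$gamma[1])) -
    0.5 * log1p(yt^2) - log(spec$scale)
}
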