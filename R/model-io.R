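MODEL_SCHEMA_VERSION <- 1L

basis_to_list <- function(b) {
  list(
    spline_covariate = b$spline_covariate,
    spline_degree = b$spline_degree,
    interior_knots = b$interior_knots,
    boundary_knots = b$boundary_knots,
    linear_covariates = b$linear_covariates,
    site_labels = b$site_labels,
    include_intercept = b$include_intercept,
    sex_levels = as.list(b$sex_levels)
  )
}

basis_from_list <- function(l) {
  basis_spec(
    boundary_knots = unlist(l$boundary_knots),
    interior_knots = unlist(l$interior_knots),
    degree = l$spline_degree,
    spline_covariate = l$spline_covariate,
    linear_covariates = unlist(l$linear_covariates),
    site_labels = unlist(l$site_labels),
    intercept = l$include_intercept,
    sex_levels = unlist(l$sex_levels)
  )
}

warp_to_list <- function(w) {
  list(family = w$family, gamma = w$gamma, loc = w$loc, scale = w$scale)
}

warp_from_list <- function(l) {
  warp_spec(l$family, gamma = unlist(l$gamma), loc = l$loc, scale = l$scale)
}

model_to_list <- function(m) {
  list(
    idp = m$idp,
    w_bar = unname(m$w_bar),
    w_names = names(m$w_bar),
    chol_A = m$chol_A,
    sigma2 = m$sigma2,
    omega2 = m$omega2,
    gamma = m$warp$gamma,
    n_train = m$n_train,
    warp = warp_to_list(m$warp),
    basis = basis_to_list(m$basis),
    adaptations = m$adaptations
  )
}

model_from_list <- function(l) {
  m <- structure(
    list(
      w_bar = unlist(l$w_bar),
      # jsonlite stores matrices row-major (array of rows)
      chol_A = matrix(unlist(l$chol_A), nrow = length(unlist(l$w_bar)),
                      byrow = TRUE),
      sigma2 = l$sigma2, omega2 = l$omega2,
      warp = warp_from_list(l$warp),
      basis = if (!is.null(l$basis)) basis_from_list(l$basis) else NULL,
      n_train = l$n_train, idp = l$idp,
      adaptations = lapply(l$adaptations, function(a) {
        list(offset = a$offset, scale = a$scale, n_controls = a$n_controls)
      })
    ),
    class = "normative_model"
  )
  if (!is.null(l$w_names)) names(m$w_bar) <- unlist(l$w_names)
  m
}

#' Serialise normative models to / from JSON
#'
#' One JSON document holds a collection of per-phenotype models sharing the
#' documented schema: `{schema_version, models: {<idp>: {w_bar, chol_A,
#' sigma2, omega2, gamma, n_train, warp, basis, adaptations}}}`. Floats are
#' written at full precision. A single model is written as a collection of
#' one.
#'
#' @param models A `normative_model` or a named list of them.
#' @param path File path for the JSON document.
#' @return `read_normative_models()` returns a named list of
#'   `normative_model` objects; `write_normative_models()` returns `path`
#'   invisibly.
#' @export
write_normative_models <- function(models, path) {
  if (inherits(models, "normative_model")) {
    models <- stats::setNames(list(models), models$idp)
  }
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    models = lapply(models, model_to_list)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_normative_models
#' @export
read_normative_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version > MODEL_SCHEMA_VERSION) {
    abort("Unsupported model file schema.")
  }
  lapply(doc$models, model_from_list)
}
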