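#' Adapt a pre-trained model to a new scanner site
#'
#' A normative model can only score subjects from sites present in its
#' training data. For a new scanner, a local sample of healthy controls is
#' used to estimate the site effect: standardised residuals
#' \eqn{r_n = (\varphi(y_n) - \bar w^\top\phi_0(x_n)) /
#' \sqrt{\phi_0^\top A^{-1}\phi_0 + \sigma^2}} are computed with the
#' site-agnostic feature map \eqn{\phi_0} (site block set to the average
#' training site; see [expand_basis()]), and the
#' site's offset (`mean(r)`) and scale (`sd(r)`) are stored. Subsequent
#' [zscore()] calls at this site return `(r - offset)/scale`, so the local
#' controls are standard by construction. The pre-trained weights stay
#' frozen; models for other sites are untouched.
#'
#' @param model A `normative_model`.
#' @param controls Tibble of healthy-control rows, all from the one new
#'   site, with covariates and the model's phenotype column.
#' @param site Site label to adapt; default: the single label in
#'   `controls$site`.
#' @param idp Phenotype column name; defaults to the model's.
#' @return The model with the new site registered in `$adaptations`.
#' @export
adapt_to_site <- function(model, controls, site = NULL, idp = model$idp) {
  if (is.null(site)) {
    site <- unique(as.character(controls$site))
    if (length(site) != 1L) abort("`controls` must come from a single site.")
  } else {
    controls <- controls[as.character(controls$site) == site, , drop = FALSE]
  }
  n <- nrow(controls)
  if (n < 2L) abort("Site adaptation needs at least 2 controls.")
  if (n < 10L) warn(paste0("Only ", n, " controls for site adaptation; ",
                           ">= 10 recommended."))
  y <- controls[[idp]]
  if (is.null(y)) abort(paste0("Missing phenotype column `", idp, "`."))
  X <- expand_basis(controls, model$basis, average_site = TRUE)
  v <- quad_Ainv(model, X) + model$sigma2
  r <- (warp(y, model$warp) - drop(X %*% model$w_bar)) / sqrt(v)
  s <- sd(r)
  if (!is.finite(s) || s < 1e-12) abort("Zero residual variance among controls.")
  model$adaptations[[site]] <- list(offset = mean(r), scale = s, n_controls = n)
  model
}

#' Split longitudinal controls into adaptation and calibration sets
#'
#' Healthy controls at a new site serve two distinct purposes that must not
#' share subjects: site adaptation, and estimation of the longitudinal
#' noise scale (the calibration set C, which is excluded from evaluation).
#' Subjects are split once, stratified by sex and first-visit age tertile.
#'
#' @param controls Long-format visits tibble (one or two rows per subject).
#' @param prop Fraction of subjects assigned to the adaptation set.
#' @param seed Seed for the stratified draw.
#' @return List with tibbles `adapt` and `calibration` (all visits of each
#'   subject kept together).
#' @export
split_controls <- function(controls, prop = 0.5, seed = 1L) {
  if (prop <= 0 || prop >= 1) abort("`prop` must be in (0, 1).")
  first <- controls |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice_min(.data$visit, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  cuts <- quantile(first$age, c(1 / 3, 2 / 3))
  first$stratum <- paste(first$sex, findInterval(first$age, cuts))
  adapt_ids <- with_seed(seed, {
    unlist(lapply(split(first$subject_id, first$stratum), function(ids) {
      k <- round(length(ids) * prop)
      if (k == 0 && length(ids) > 1) k <- 1
      sample(as.character(ids), k)
    }), use.names = FALSE)
  })
  list(
    adapt = dplyr::filter(controls, .data$subject_id %in% adapt_ids),
    calibration = dplyr::filter(controls, !(.data$subject_id %in% adapt_ids))
  )
}
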