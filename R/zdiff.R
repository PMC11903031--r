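#' Pair up two visits per subject
#'
#' Converts a long-format visits table (one row per subject and visit) into
#' one row per subject holding both visits of one phenotype. Subjects with
#' more than two visits are rejected with guidance to score consecutive
#' pairs; visits of one subject must share a site, and the between-visit
#' interval must be positive.
#'
#' @param visits Tibble with `subject_id`, `visit`, `age`, `sex`, `site`
#'   and the phenotype column.
#' @param idp Phenotype column name.
#' @return Tibble with columns `subject_id`, `sex`, `site`, `age1`, `age2`,
#'   `interval`, `y1`, `y2`, `idp`.
#' @export
make_visit_pairs <- function(visits, idp) {
  if (is.null(visits[[idp]])) abort(paste0("Missing phenotype column `", idp, "`."))
  counts <- table(visits$subject_id)
  if (any(counts > 2)) {
    abort(paste0("Subject(s) with > 2 visits: ",
                 paste(names(counts)[counts > 2], collapse = ", "),
                 ". Score consecutive visit pairs separately."))
  }
  if (any(counts < 2)) {
    warn(paste0(sum(counts < 2), " subject(s) with a single visit dropped."))
  }
  v <- visits[order(visits$subject_id, visits$visit), , drop = FALSE]
  v <- v[v$subject_id %in% names(counts)[counts == 2], , drop = FALSE]
  i1 <- seq(1, nrow(v), by = 2)
  i2 <- i1 + 1
  if (any(as.character(v$site[i1]) != as.character(v$site[i2]))) {
    abort("Cross-site visit pairs are not supported.")
  }
  pairs <- tibble::tibble(
    subject_id = v$subject_id[i1],
    sex = v$sex[i1],
    site = as.character(v$site[i1]),
    age1 = v$age[i1], age2 = v$age[i2],
    interval = v$age[i2] - v$age[i1],
    y1 = v[[idp]][i1], y2 = v[[idp]][i2],
    idp = idp
  )
  if (any(pairs$interval <= 0)) abort("Between-visit interval must be > 0.")
  pairs
}

# warped differences and model-uncertainty quadratic term for visit pairs
pair_terms <- function(pairs, model) {
  d1 <- tibble::tibble(age = pairs$age1, sex = pairs$sex, site = pairs$site)
  d2 <- tibble::tibble(age = pairs$age2, sex = pairs$sex, site = pairs$site)
  X1 <- model_design(d1, model)$X
  X2 <- model_design(d2, model)$X
  dX <- X2 - X1
  list(
    dwy = warp(pairs$y2, model$warp) - warp(pairs$y1, model$warp),
    dmu = drop(dX %*% model$w_bar),
    quad = quad_Ainv(model, dX)
  )
}

#' Estimate the longitudinal noise scale from calibration controls
#'
#' The z-diff denominator needs the variance of the healthy between-visit
#' residual change, \eqn{2\sigma_\xi^2} under the subject-stable-factor
#' model (generally \eqn{2\sigma^2(1-\rho)}). It is estimated on a
#' dedicated subsample C of healthy-control pairs, excluded from any later
#' evaluation, as the sample mean of
#' \deqn{(\varphi(y^{(2)}_k)-\varphi(y^{(1)}_k) -
#'   \bar w^\top[\phi(x^{(2)}_k)-\phi(x^{(1)}_k)])^2 -
#'   [\phi(x^{(2)}_k)-\phi(x^{(1)}_k)]^\top A^{-1}
#'   [\phi(x^{(2)}_k)-\phi(x^{(1)}_k)].}
#' Finite-sample noise can push the raw estimate negative, in which case it
#' is clamped to a small positive floor (`1e-8 * 2 * sigma2`) with a loud
#' warning; the raw value is always kept. A raw value exceeding the
#' cross-sectional \eqn{2\sigma^2} implies negative residual
#' autocorrelation and is flagged as a centile-tracking violation.
#'
#' @param calibration_pairs Visit pairs of the calibration controls C
#'   (from [make_visit_pairs()]), scored with the same adapted model used
#'   later for patients.
#' @param model A (site-adapted) `normative_model`.
#' @return An object of class `noise_estimate`: `idp`, `two_sigma_xi2`,
#'   `raw_value`, `n_calibration`, `implied_rho`, `tracking_violation`.
#' @export
estimate_noise <- function(calibration_pairs, model) {
  n <- nrow(calibration_pairs)
  if (n < 2L) abort("Noise calibration needs at least 2 control pairs.")
  t <- pair_terms(calibration_pairs, model)
  raw <- mean((t$dwy - t$dmu)^2 - t$quad)
  floor <- 1e-8 * 2 * model$sigma2
  val <- max(raw, floor)
  if (raw < floor) {
    warn(paste0("Raw longitudinal noise estimate ", signif(raw, 4),
                " clamped to ", signif(floor, 4),
                "; the calibration sample is too small or degenerate."))
  }
  structure(
    list(
      idp = model$idp,
      two_sigma_xi2 = val,
      raw_value = raw,
      n_calibration = n,
      implied_rho = 1 - val / (2 * model$sigma2),
      tracking_violation = raw > 2 * model$sigma2
    ),
    class = "noise_estimate"
  )
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat("<noise_estimate>", x$idp, "| 2*sigma_xi^2 =", signif(x$two_sigma_xi2, 5),
      "(raw", paste0(signif(x$raw_value, 5), ")"),
      "| |C| =", x$n_calibration, "\n")
  cat("  implied rho =", signif(x$implied_rho, 4),
      if (x$tracking_violation) "| WARNING: centile-tracking assumption violated"
      else "", "\n")
  invisible(x)
}

#' @export
tidy.noise_estimate <- function(x, ...) {
  tibble::tibble(
    idp = x$idp, two_sigma_xi2 = x$two_sigma_xi2, raw_value = x$raw_value,
    n_calibration = x$n_calibration, implied_rho = x$implied_rho,
    tracking_violation = x$tracking_violation
  )
}

#' Score between-visit change (z-diff)
#'
#' The calibrated change score
#' \deqn{\mathrm{z\mbox{-}diff} =
#'   \frac{[\varphi(y^{(2)})-\varphi(y^{(1)})] -
#'         \bar w^\top[\phi(x^{(2)})-\phi(x^{(1)})]}
#'        {\sqrt{[\phi(x^{(2)})-\phi(x^{(1)})]^\top A^{-1}
#'               [\phi(x^{(2)})-\phi(x^{(1)})] + 2\hat\sigma_\xi^2}}}
#' is standard normal for healthy controls, so exceedances flag unusual
#' change. The model-uncertainty quadratic is always included: it is
#' negligible in adult cohorts with stable covariates but not in
#' developmental or ageing groups.
#'
#' @param pairs Visit pairs from [make_visit_pairs()] (calibration subjects
#'   must not be among them).
#' @param model A (site-adapted) `normative_model`.
#' @param noise A [estimate_noise()] result, or a number to use directly as
#'   the noise scale \eqn{2\sigma_\xi^2}.
#' @return Tibble with `subject_id`, `idp`, `zdiff`.
#' @export
zdiff_score <- function(pairs, model, noise) {
  s2 <- if (inherits(noise, "noise_estimate")) noise$two_sigma_xi2 else as.numeric(noise)
  if (!is.finite(s2) || s2 <= 0) abort("Noise scale must be a positive number.")
  t <- pair_terms(pairs, model)
  tibble::tibble(
    subject_id = pairs$subject_id,
    idp = model$idp,
    zdiff = (t$dwy - t$dmu) / sqrt(t$quad + s2)
  )
}

#' Naive z-score subtraction (comparison baseline only)
#'
#' The difference of the two cross-sectional z-scores, \eqn{z^{(2)} -
#' z^{(1)}}. This is *not* a calibrated change score: it scales each visit
#' by its own uncertainty and wrongly includes the subject-stable residual
#' variance, so its null variance is \eqn{2(1-\rho)} rather than 1 —
#' over-flagging when residual autocorrelation is below 0.5. Provided only
#' as the baseline against which z-diff is compared.
#'
#' @inheritParams zdiff_score
#' @return Tibble with `subject_id`, `idp`, `naive`.
#' @export
naive_zdiff <- function(pairs, model) {
  v1 <- tibble::tibble(subject_id = pairs$subject_id, age = pairs$age1,
                       sex = pairs$sex, site = pairs$site, y = pairs$y1)
  v2 <- tibble::tibble(subject_id = pairs$subject_id, age = pairs$age2,
                       sex = pairs$sex, site = pairs$site, y = pairs$y2)
  z1 <- zscore(v1, model, idp = "y")$z
  z2 <- zscore(v2, model, idp = "y")$z
  tibble::tibble(subject_id = pairs$subject_id, idp = model$idp,
                 naive = z2 - z1)
}

#' Two-sided flagging of a score at nominal rate theta
#'
#' Flags scores outside the \eqn{\theta/2} and \eqn{1-\theta/2} quantiles
#' of the standard normal distribution.
#'
#' @param z Numeric scores.
#' @param theta Nominal false-positive rate in (0, 1]; `theta = 1` flags
#'   everything.
#' @return Logical vector.
#' @export
flag_score <- function(z, theta = 0.05) {
  if (theta <= 0 || theta > 1) abort("`theta` must be in (0, 1].")
  if (theta >= 1) return(rep(TRUE, length(z)))
  z < qnorm(theta / 2) | z > qnorm(1 - theta / 2)
}

#' Region-wise group test of z-diff scores
#'
#' One-sample Wilcoxon signed-rank test of the scores against zero, per
#' phenotype, with Benjamini-Hochberg FDR correction across phenotypes.
#'
#' @param scores Tibble with columns `idp` and the score column.
#' @param score_col Name of the score column (default `"zdiff"`).
#' @param level FDR level for the significance mask.
#' @return Tibble with `idp`, `n`, `median`, `p`, `q`, `significant`.
#' @export
group_wilcoxon <- function(scores, score_col = "zdiff", level = 0.05) {
  out <- scores |>
    dplyr::group_by(.data$idp) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data[[score_col]]),
      p = {
        x <- .data[[score_col]]
        if (all(x == 0)) 1
        else suppressWarnings(wilcox.test(x, mu = 0)$p.value)
      },
      .groups = "drop"
    )
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= level
  out
}
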