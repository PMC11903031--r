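# Shared fixtures, all built in code at test time.

# minimal linear-truth basis over a fixed adult age range
toy_basis <- function(sites = c("siteA", "siteB")) {
  # upper boundary leaves headroom for visit-2 ages (visit 1 + interval)
  basis_spec(boundary_knots = c(18, 62), degree = 1L, site_labels = sites)
}

# small fitted model with known hyper-parameters on synthetic training data
toy_model <- function(n_train = 1000L, sigma2 = 1, seed = 42L,
                      sites = c("siteA", "siteB")) {
  spec <- cohort_spec(n_subjects = n_train,
                      sigma_eta2 = 0.7 * sigma2, sigma_xi2 = 0.3 * sigma2,
                      sites = sites,
                      site_offsets = c(-0.15, 0.15)[seq_along(sites)],
                      seed = seed)
  train <- gen_cross_sectional(spec)
  fit_normative(train, idp = spec$idp, basis = toy_basis(sites),
                sigma2 = sigma2, omega2 = 10)
}

# independent de Boor recursion (textbook Cox-de Boor), used as the spline
# oracle; deliberately naive and separate from splines::splineDesign
deboor_basis <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  B <- function(i, d, x) {
    if (d == 0) {
      # right-closed at the final interval so the last basis reaches 1
      upper <- if (knots[i + 1] == max(knots)) x <= knots[i + 1] else x < knots[i + 1]
      return(as.numeric(x >= knots[i] & upper))
    }
    t1 <- 0
    if (knots[i + d] > knots[i]) {
      t1 <- (x - knots[i]) / (knots[i + d] - knots[i]) * B(i, d - 1, x)
    }
    t2 <- 0
    if (knots[i + d + 1] > knots[i + 1]) {
      t2 <- (knots[i + d + 1] - x) / (knots[i + d + 1] - knots[i + 1]) *
        B(i + 1, d - 1, x)
    }
    t1 + t2
  }
  vapply(seq_len(n_basis), function(i) B(i, degree, x), numeric(length(x)))
}
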