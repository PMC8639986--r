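#' Dimeric fraction of a membrane receptor under monomer-dimer equilibrium
#'
#' Computes the fraction of receptor protomers that are part of a dimer at a
#' total surface density `total_density` given a two-dimensional dissociation
#' constant `k_diss`, under mass action for the monomer-dimer equilibrium
#' (monomer M, dimer D, with `[T] = [M] + 2[D]` counted in protomers and
#' `K_diss = [M]^2 / [D]`):
#'
#' \deqn{f_D = \frac{[T] - \frac{K_{diss}}{4}\left(\sqrt{1 + 8[T]/K_{diss}} - 1\right)}{[T]}}
#'
#' Internally the algebraically equivalent, cancellation-free form
#' \eqn{f_D = 8x / (1 + \sqrt{1 + 8x})^2} with \eqn{x = [T]/K_{diss}} is used,
#' which is accurate to machine precision for density ratios spanning many
#' orders of magnitude.
#'
#' Densities are in arbitrary but mutually consistent surface-density units;
#' the package never converts to molecules per unit area.
#'
#' @param total_density Total receptor surface density `[T]` (> 0). Vectorized.
#' @param k_diss Two-dimensional dissociation constant, same units as
#'   `total_density` (> 0). Vectorized (recycled against `total_density`).
#' @return Numeric vector of dimeric fractions, each in (0, 1).
#' @examples
#' dimeric_fraction(200, 200) # exactly 0.5 at [T] = K_diss
#' dimeric_fraction(c(1, 100, 1e6), k_diss = 100)
#' @seealso [predict_fret()], [fit_dimerization()]
#' @export
dimeric_fraction <- function(total_density, k_diss) {
  if (!is.numeric(total_density) || !is.numeric(k_diss)) {
    abort("`total_density` and `k_diss` must be numeric.")
  }
  if (any(!is.finite(total_density)) || any(total_density <= 0)) {
    abort("`total_density` must be finite and > 0.")
  }
  if (any(!is.finite(k_diss)) || any(k_diss <= 0)) {
    abort("`k_diss` must be finite and > 0.")
  }
  x <- total_density / k_diss
  s <- sqrt(1 + 8 * x)
  8 * x / (1 + s)^2
}

#' Predicted FRET efficiency for a membrane region
#'
#' Forward model for dimerization FRET: the measured efficiency in a membrane
#' region is the dimeric fraction times the acceptor fraction times the
#' intrinsic FRET of the donor-acceptor dimer,
#' \eqn{FRET = f_D([T]; K_{diss}) \, x_A \, \tilde{E}}.
#'
#' @param total_density Total receptor surface density (> 0).
#' @param acceptor_fraction Acceptor fraction \eqn{x_A} in \[0, 1\].
#' @param k_diss Dissociation constant (> 0).
#' @param e_tilde Intrinsic FRET efficiency of a donor-acceptor dimer, in
#'   (0, 1]. A structural constant independent of dimerization propensity.
#' @return Numeric vector of FRET efficiencies in \[0, 1\].
#' @examples
#' predict_fret(200, acceptor_fraction = 0.6, k_diss = 200, e_tilde = 0.5)
#' @export
predict_fret <- function(total_density, acceptor_fraction, k_diss, e_tilde) {
  if (any(acceptor_fraction < 0 | acceptor_fraction > 1)) {
    abort("`acceptor_fraction` must lie in [0, 1].")
  }
  check_number(e_tilde, "e_tilde", lower = 0, upper = 1, strict_lower = TRUE)
  dimeric_fraction(total_density, k_diss) * acceptor_fraction * e_tilde
}

fret_rss <- function(log_k, y, total_density, w) {
  # profile RSS over K with the conditionally optimal e_tilde substituted
  f <- dimeric_fraction(total_density, exp(log_k))
  e_hat <- sum(w * y * f) / sum(w * f^2)
  e_hat <- min(max(e_hat, 1e-8), 1)
  list(rss = sum(w * (y - f * e_hat)^2), e_tilde = e_hat)
}

#' Fit the monomer-dimer equilibrium to FRET dimerization data
#'
#' Estimates the two-dimensional dissociation constant `k_diss` and the
#' intrinsic FRET `e_tilde` by nonlinear least squares on
#' \eqn{FRET_i / x_{A,i} = f_D([T]_i; K_{diss}) \tilde{E}}, i.e. the measured
#' efficiency divided by the acceptor fraction against total density. Each
#' point is weighted equally unless `weights` (inverse-variance) are supplied.
#'
#' The objective is profiled over `k_diss` on a log-spaced multi-start grid
#' (the conditionally optimal `e_tilde` is available in closed form), then
#' polished with a quasi-Newton step on (log `k_diss`, logit `e_tilde`) so the
#' positivity and efficiency bounds hold without a constrained solver.
#' Asymptotic standard errors come from the Jacobian curvature at the optimum.
#' If the profile of the objective in `k_diss` is flat within tolerance (for
#' example for data that are fully dimeric at all observed densities) the
#' smallest `k_diss` in the flat region is reported and the
#' `non_identifiable` flag is set.
#'
#' @param samples Data frame with columns `total_density`, `acceptor_fraction`
#'   and `fret` (one row per membrane region), e.g. from
#'   [sim_fret_samples()] or [read_fret_samples()].
#' @param init Optional length-2 numeric `c(k_diss, e_tilde)` starting value;
#'   when absent a multi-start over a log-spaced `k_diss` grid
#'   (1e-2 to 1e4 times the median density) is used.
#' @param weights Optional non-negative per-sample weights (e.g. inverse
#'   variances). Default: equal weights.
#' @param grid_points Number of multi-start grid points (default 61).
#' @return An object of class `dimer_fit` with elements `k_diss`, `e_tilde`,
#'   `se` (named), `ci` (2x2 matrix of 95% asymptotic intervals), `rss`,
#'   `n_samples`, `converged`, `non_identifiable`, `profile` (tibble of the
#'   `k_diss` profile RSS) and `data`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' d <- sim_fret_samples(n_regions = 150, k_diss = 200, e_tilde = 0.55,
#'                       noise_sd = 0.02, seed = 7)
#' fit <- fit_dimerization(d)
#' tidy(fit)
#' @export
fit_dimerization <- function(samples, init = NULL, weights = NULL,
                             grid_points = 61) {
  check_columns(samples, c("total_density", "acceptor_fraction", "fret"),
                "samples")
  keep <- samples$acceptor_fraction > 0
  if (!any(keep)) {
    abort("All samples have acceptor_fraction = 0; the model is unfittable.")
  }
  samples <- samples[keep, , drop = FALSE]
  n <- nrow(samples)
  if (n < 2) abort("Need at least 2 samples with acceptor_fraction > 0.")
  tt <- samples$total_density
  y <- samples$fret / samples$acceptor_fraction
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == length(keep))
    weights[keep]
  }

  spread_flag <- FALSE
  if (diff(range(tt)) < 0.05 * median(tt)) {
    warn("Density range is very narrow; the fit may be ill-conditioned.")
    spread_flag <- TRUE
  }

  k_grid <- exp(seq(log(1e-2 * median(tt)), log(1e4 * median(tt)),
                    length.out = grid_points))
  prof <- vapply(log(k_grid), function(lk) fret_rss(lk, y, tt, w)$rss, 0.0)

  if (!is.null(init)) {
    start <- c(log(init[[1]]), stats::qlogis(min(max(init[[2]], 1e-6), 1 - 1e-6)))
  } else {
    lk0 <- log(k_grid[which.min(prof)])
    e0 <- fret_rss(lk0, y, tt, w)$e_tilde
    start <- c(lk0, stats::qlogis(min(max(e0, 1e-6), 1 - 1e-6)))
  }

  obj <- function(p) {
    f <- dimeric_fraction(tt, exp(p[1]))
    sum(w * (y - f * stats::plogis(p[2]))^2)
  }
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 500))
  opt2 <- tryCatch(
    optim(opt$par, obj, method = "BFGS",
          control = list(reltol = 1e-12, maxit = 500)),
    error = function(e) opt
  )
  if (opt2$value <= opt$value) opt <- opt2

  # 1-D polish on the k_diss profile (e_tilde has a closed form given K)
  pol <- optimize(function(lk) fret_rss(lk, y, tt, w)$rss,
                  interval = opt$par[1] + c(-1, 1), tol = 1e-12)
  if (pol$objective < opt$value) {
    opt$value <- pol$objective
    opt$par <- c(pol$minimum,
                 stats::qlogis(min(max(fret_rss(pol$minimum, y, tt,
                                                w)$e_tilde, 1e-8), 1 - 1e-8)))
  }

  k_hat <- exp(opt$par[1])
  e_hat <- stats::plogis(opt$par[2])
  rss <- opt$value

  # flat-profile detection: smallest K whose profile RSS is within tolerance
  tol <- max(rss * 1e-4, 1e-12 * sum(w * y^2), .Machine$double.eps)
  flat <- k_grid[prof <= min(min(prof), rss) + tol]
  non_ident <- length(flat) > 1 &&
    (log10(max(flat)) - log10(min(flat))) > 2
  if (non_ident) k_hat <- min(flat)
  # a K estimate that escaped below the multi-start grid means the data are
  # consistent with the fully-dimeric limit: K is not identified
  if (k_hat < min(k_grid)) non_ident <- TRUE

  # asymptotic SEs from the Jacobian of the mean function at the optimum
  f_hat <- dimeric_fraction(tt, k_hat)
  dk <- k_hat * 1e-6
  df_dk <- (dimeric_fraction(tt, k_hat + dk) -
              dimeric_fraction(tt, k_hat - dk)) / (2 * dk)
  jac <- cbind(k_diss = e_hat * df_dk, e_tilde = f_hat) * sqrt(w)
  sigma2 <- rss / max(n - 2, 1)
  vcv <- tryCatch(solve(crossprod(jac)) * sigma2, error = function(e) NULL)
  if (is.null(vcv) || any(!is.finite(diag(vcv))) || any(diag(vcv) < 0)) {
    se <- c(k_diss = NA_real_, e_tilde = NA_real_)
  } else {
    se <- sqrt(diag(vcv))
  }
  tcrit <- qt(0.975, max(n - 2, 1))
  ci <- rbind(
    k_diss = c(k_hat - tcrit * se[["k_diss"]], k_hat + tcrit * se[["k_diss"]]),
    e_tilde = c(e_hat - tcrit * se[["e_tilde"]], e_hat + tcrit * se[["e_tilde"]])
  )
  colnames(ci) <- c("conf.low", "conf.high")

  structure(
    list(
      k_diss = k_hat, e_tilde = e_hat, se = se, ci = ci, rss = rss,
      sigma = sqrt(sigma2), n_samples = n,
      converged = opt$convergence == 0,
      non_identifiable = non_ident,
      narrow_density_range = spread_flag,
      profile = tibble::tibble(k_diss = k_grid, rss = prof),
      data = tibble::as_tibble(samples)
    ),
    class = "dimer_fit"
  )
}

#' @export
print.dimer_fit <- function(x, ...) {
  cat("Monomer-dimer equilibrium FRET fit\n")
  cat(sprintf("  k_diss : %.4g (SE %.3g)\n", x$k_diss, x$se[["k_diss"]]))
  cat(sprintf("  e_tilde: %.4g (SE %.3g)\n", x$e_tilde, x$se[["e_tilde"]]))
  cat(sprintf("  n = %d, RSS = %.4g, converged: %s%s\n", x$n_samples, x$rss,
              x$converged,
              if (x$non_identifiable) ", NON-IDENTIFIABLE k_diss" else ""))
  invisible(x)
}

#' @method tidy dimer_fit
#' @export
tidy.dimer_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_diss", "e_tilde"),
    estimate = c(x$k_diss, x$e_tilde),
    std.error = unname(x$se),
    conf.low = x$ci[, "conf.low"],
    conf.high = x$ci[, "conf.high"]
  )
}

#' @method glance dimer_fit
#' @export
glance.dimer_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, sigma = x$sigma, nobs = x$n_samples,
    converged = x$converged, non_identifiable = x$non_identifiable
  )
}

#' Case-resampling bootstrap confidence intervals for the dimerization fit
#'
#' Refits the monomer-dimer model to `n_boot` case resamples of the data and
#' reports percentile confidence intervals for `k_diss` and `e_tilde`.
#' Deterministic given `seed`.
#'
#' @inheritParams fit_dimerization
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer RNG seed.
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`, `n_boot`.
#' @examples
#' d <- sim_fret_samples(n_regions = 80, noise_sd = 0.02, seed = 3)
#' bootstrap_fit(d, n_boot = 100, seed = 1)
#' @export
bootstrap_fit <- function(samples, n_boot = 1000, seed = 1, level = 0.95) {
  check_count(n_boot, "n_boot", min = 100L)
  check_columns(samples, c("total_density", "acceptor_fraction", "fret"),
                "samples")
  if (nrow(samples) < 3) {
    abort("Need more samples than model parameters to bootstrap.")
  }
  fit0 <- fit_dimerization(samples)
  init <- c(fit0$k_diss, fit0$e_tilde)
  draws <- with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(samples), replace = TRUE)
      fb <- tryCatch(
        suppressWarnings(fit_dimerization(samples[idx, , drop = FALSE],
                                          init = init)),
        error = function(e) NULL
      )
      if (is.null(fb)) c(NA_real_, NA_real_) else c(fb$k_diss, fb$e_tilde)
    })
  })
  mat <- do.call(rbind, draws)
  a <- (1 - level) / 2
  qs <- apply(mat, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  tibble::tibble(
    term = c("k_diss", "e_tilde"),
    estimate = init,
    conf.low = qs[1, ],
    conf.high = qs[2, ],
    n_boot = n_boot
  )
}

#' Read FRET dimerization samples from CSV
#'
#' Expects columns `region_id`, `donor_density`, `acceptor_density`, `fret`.
#' Total density is the sum of donor and acceptor densities; the acceptor
#' fraction is `acceptor / (donor + acceptor)`.
#'
#' @param path CSV file path.
#' @return Tibble with `region_id`, `total_density`, `acceptor_fraction`,
#'   `fret` (plus the original density columns).
#' @export
read_fret_samples <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  check_columns(df, c("region_id", "donor_density", "acceptor_density", "fret"),
                "FRET csv")
  dplyr::mutate(
    df,
    total_density = .data$donor_density + .data$acceptor_density,
    acceptor_fraction = .data$acceptor_density / .data$total_density
  )
}
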