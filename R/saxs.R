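#' Read a SAXS scattering curve from text
#'
#' Parses a 2- or 3-column whitespace- or comma-separated text file
#' (`q`, `I`, optional `sigma`), tolerating comment and header lines (any
#' line that does not start with a number). Momentum transfer must be
#' strictly increasing. Negative-intensity points are flagged and retained
#' unless `trim_negative = TRUE`.
#'
#' @param path File path.
#' @param trim_negative Drop negative-intensity points (default FALSE).
#' @return Tibble with columns `q` (1/Angstrom), `intensity`, `sigma`
#'   (`NA` when absent) and `flag_negative`.
#' @export
read_scattering <- function(path, trim_negative = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  is_data <- grepl("^[-+]?[0-9.]", lines) & !grepl("^[-+]?\\.?$", lines)
  fields <- strsplit(gsub(",", " ", lines[is_data]), "\\s+")
  nums <- purrr::map(fields, ~ suppressWarnings(as.numeric(.x)))
  nums <- nums[purrr::map_lgl(nums, ~ length(.x) >= 2 && !any(is.na(.x[1:2])))]
  if (length(nums) == 0) abort("No numeric data rows found.")
  q <- purrr::map_dbl(nums, 1)
  i <- purrr::map_dbl(nums, 2)
  s <- purrr::map_dbl(nums, ~ if (length(.x) >= 3) .x[3] else NA_real_)
  if (any(q <= 0)) abort("q values must be > 0.")
  if (is.unsorted(q, strictly = TRUE)) abort("q must be strictly increasing.")
  out <- tibble::tibble(q = q, intensity = i, sigma = s,
                        flag_negative = i < 0)
  if (trim_negative) out <- out[!out$flag_negative, , drop = FALSE]
  out
}

#' Write a scattering curve as 3-column text
#'
#' @param curve Tibble with `q`, `intensity` and optionally `sigma`.
#' @param path Output path.
#' @param comment Header comment written on the first line.
#' @export
write_scattering <- function(curve, path, comment = "q intensity sigma") {
  check_columns(curve, c("q", "intensity"), "curve")
  sig <- if ("sigma" %in% names(curve)) curve$sigma else rep(NA_real_, nrow(curve))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  writeLines(sprintf("%.10g %.10g %.10g", curve$q, curve$intensity,
                     ifelse(is.na(sig), 0, sig)), con)
  invisible(path)
}

#' Guinier analysis of a scattering curve
#'
#' Fits `ln I` against `q^2` on the largest low-q window whose upper limit
#' satisfies `q_max * Rg <= qmax_rg_cutoff` (expanding from the
#' `min_points` lowest-q points, refitting as the window grows). Returns the
#' radius of gyration `Rg = sqrt(-3 * slope)` and forward scattering
#' `I0 = exp(intercept)`. A positive slope in the low-q region (no Guinier
#' regime) raises an error, as expected for aggregated or strongly
#' interacting samples.
#'
#' @param curve Tibble with `q` and `intensity` (positive intensities are
#'   required inside the fit window).
#' @param qmax_rg_cutoff Dimensionless Guinier validity cutoff
#'   (default 1.3, the standard globular-particle choice).
#' @param min_points Minimum points in the fit window (default 5).
#' @return Object of class `guinier_fit`: `rg`, `i0`, `q_range_used`,
#'   `n_points`, `r_squared`, `qmax_rg`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' q <- seq(0.004, 0.2, by = 0.002)
#' curve <- tibble::tibble(q = q, intensity = 7 * exp(-q^2 * 25^2 / 3))
#' guinier_fit(curve)$rg
#' @export
guinier_fit <- function(curve, qmax_rg_cutoff = 1.3, min_points = 5) {
  check_columns(curve, c("q", "intensity"), "curve")
  check_number(qmax_rg_cutoff, "qmax_rg_cutoff", lower = 0, strict_lower = TRUE)
  ok <- curve$intensity > 0
  q <- curve$q[ok]
  i <- curve$intensity[ok]
  if (length(q) < min_points) abort("Need at least `min_points` positive-intensity points.")
  fit_window <- function(n) {
    fit <- lm(log(i[1:n]) ~ I(q[1:n]^2))
    slope <- coef(fit)[[2]]
    list(fit = fit, slope = slope,
         rg = if (slope < 0) sqrt(-3 * slope) else NA_real_)
  }
  best <- NULL
  ever_negative <- FALSE
  for (n in min_points:length(q)) {
    w <- fit_window(n)
    if (is.na(w$rg)) {
      # positive slope: spurious in tiny noisy windows, so keep expanding
      # unless a valid window was already found past its cutoff
      if (!is.null(best)) break
      next
    }
    ever_negative <- TRUE
    if (q[n] * w$rg > qmax_rg_cutoff) {
      if (!is.null(best)) break
      next
    }
    best <- c(w, list(n = n))
  }
  if (is.null(best)) {
    if (!ever_negative) {
      abort("Positive Guinier slope: non-globular or aggregated input.")
    }
    # a negative-slope window exists but none satisfies the cutoff
    w <- fit_window(min_points)
    if (is.na(w$rg)) {
      abort("Positive Guinier slope: non-globular or aggregated input.")
    }
    best <- c(w, list(n = min_points))
    warn("q_max * Rg exceeds the cutoff even for the smallest window.")
  }
  n <- best$n
  # summary.lm warns on numerically perfect fits; r.squared is still valid
  r2 <- suppressWarnings(summary(best$fit)$r.squared)
  structure(
    list(
      rg = best$rg, i0 = exp(coef(best$fit)[[1]]),
      q_range_used = c(q[1], q[n]), n_points = n,
      r_squared = r2, qmax_rg = q[n] * best$rg,
      window = tibble::tibble(q = q[1:n], intensity = i[1:n],
                              fitted = exp(stats::fitted(best$fit)))
    ),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: Rg = %.3f A, I0 = %.4g (%d pts, q %.4g-%.4g, qmax*Rg = %.2f, R^2 = %.4f)\n",
    x$rg, x$i0, x$n_points, x$q_range_used[1], x$q_range_used[2], x$qmax_rg,
    x$r_squared))
  invisible(x)
}

#' @method tidy guinier_fit
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(term = c("rg", "i0"), estimate = c(x$rg, x$i0))
}

#' @method glance guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, i0 = x$i0, n_points = x$n_points,
                 q_min = x$q_range_used[1], q_max = x$q_range_used[2],
                 qmax_rg = x$qmax_rg, r_squared = x$r_squared)
}

#' Debye scattering intensity from a point model
#'
#' Computes \eqn{I(q) = \sum_i \sum_j w_i w_j \, \mathrm{sinc}(q r_{ij})}
#' (with sinc(0) = 1) either by the direct double sum over all point pairs or
#' via a pair-distance histogram (much faster for large models, accurate to
#' the bin width).
#'
#' @param atoms Tibble with columns `x`, `y`, `z` and optionally `weight`
#'   (default 1), coordinates in Angstrom.
#' @param q Numeric vector of momentum-transfer values (1/Angstrom).
#' @param method `"direct"` or `"histogram"`.
#' @param bin_width Histogram bin width in Angstrom (histogram method).
#' @return Tibble with `q` and `intensity`; `I(0)` equals `(sum w)^2`.
#' @examples
#' two <- tibble::tibble(x = c(0, 10), y = 0, z = 0, weight = 1)
#' debye_intensity(two, q = c(0.1, 0.3)) # 2 + 2*sin(qd)/(qd)
#' @export
debye_intensity <- function(atoms, q, method = c("histogram", "direct"),
                            bin_width = 0.1) {
  method <- match.arg(method)
  check_columns(atoms, c("x", "y", "z"), "atoms")
  if (length(q) == 0) abort("`q` grid is empty.")
  w <- if ("weight" %in% names(atoms)) atoms$weight else rep(1, nrow(atoms))
  n <- nrow(atoms)
  if (n == 1) {
    return(tibble::tibble(q = q, intensity = rep(w^2, length(q))))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.vector(stats::dist(xyz))
  wp <- outer_pair_weights(w)
  self <- sum(w^2)
  inten <- if (method == "direct") {
    vapply(q, function(qq) self + 2 * sum(wp * ssinc(qq * d)), 0.0)
  } else {
    h <- pair_histogram(d, wp, bin_width)
    vapply(q, function(qq) self + 2 * sum(h$weight * ssinc(qq * h$r)), 0.0)
  }
  tibble::tibble(q = q, intensity = inten)
}

# products w_i * w_j over unordered pairs, ordered as stats::dist
outer_pair_weights <- function(w) {
  n <- length(w)
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) out[[i]] <- w[i] * w[(i + 1):n]
  unlist(out)
}

pair_histogram <- function(d, wp, bin_width) {
  idx <- floor(d / bin_width)
  agg <- rowsum(wp, idx)
  # weighted mean distance per bin (first moment exact; bias O(bin_width^2))
  rbar <- rowsum(wp * d, idx) / agg
  list(r = as.vector(rbar), weight = as.vector(agg))
}

new_pair_distribution <- function(r, p, d_max, rg) {
  structure(list(r = r, p = p, d_max = d_max, rg = rg),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("pair_distribution: D_max = %.2f A, Rg = %.3f A (%d r points)\n",
              x$d_max, x$rg, length(x$r)))
  invisible(x)
}

#' @export
as.data.frame.pair_distribution <- function(x, ...) {
  data.frame(r = x$r, p = x$p)
}

pr_moment_rg <- function(r, p) {
  dr <- diff(r)
  # trapezoid moments
  m0 <- sum((p[-1] + p[-length(p)]) / 2 * dr)
  m2 <- sum((r[-1]^2 * p[-1] + r[-length(r)]^2 * p[-length(p)]) / 2 * dr)
  sqrt(m2 / m0 / 2)
}

#' Pair-distance distribution from a point model
#'
#' Histograms the weighted pairwise distances of a point model into bins of
#' `bin_width`, normalizes to unit area, and reports the maximum pairwise
#' distance `D_max` and the second-moment radius of gyration
#' \eqn{R_g^2 = \int r^2 P(r) dr / 2}.
#'
#' @inheritParams debye_intensity
#' @param bin_width Histogram bin width in Angstrom (default 1).
#' @return Object of class `pair_distribution` with `r` (grid from 0 to
#'   `D_max`), `p` (P(r), unit area, `p[1] = 0`), `d_max`, `rg`.
#' @examples
#' sph <- sim_toy_structure("solid_sphere_beads", radius = 30,
#'                          n_points = 1000, seed = 1)
#' pr_from_structure(sph)
#' @export
pr_from_structure <- function(atoms, bin_width = 1) {
  check_columns(atoms, c("x", "y", "z"), "atoms")
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  if (nrow(atoms) < 2) {
    return(new_pair_distribution(r = 0, p = 0, d_max = 0, rg = 0))
  }
  w <- if ("weight" %in% names(atoms)) atoms$weight else rep(1, nrow(atoms))
  d <- as.vector(stats::dist(as.matrix(atoms[, c("x", "y", "z")])))
  wp <- outer_pair_weights(w)
  d_max <- max(d)
  edges <- seq(0, d_max + bin_width, by = bin_width)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  counts <- rep(0, length(mids))
  idx <- pmin(floor(d / bin_width) + 1, length(mids))
  agg <- rowsum(wp, idx)
  counts[as.integer(rownames(agg))] <- as.vector(agg)
  r <- c(0, mids)
  p <- c(0, counts)
  area <- sum((p[-1] + p[-length(p)]) / 2 * diff(r))
  p <- p / area
  new_pair_distribution(r = r, p = p, d_max = d_max,
                        rg = pr_moment_rg(r, p))
}

#' Mass-weighted radius of gyration from coordinates
#'
#' Second moment of the (weighted) point model about its centroid.
#'
#' @inheritParams debye_intensity
#' @return Rg in Angstrom.
#' @export
rg_coords <- function(atoms) {
  check_columns(atoms, c("x", "y", "z"), "atoms")
  w <- if ("weight" %in% names(atoms)) atoms$weight else rep(1, nrow(atoms))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colSums(xyz * w) / sum(w)
  sq <- sweep(xyz, 2, ctr)
  sqrt(sum(w * rowSums(sq^2)) / sum(w))
}

#' Regularized indirect Fourier transform of a scattering curve
#'
#' Inverts \eqn{I(q) = 4\pi \int_0^{D_{max}} P(r)\,\mathrm{sinc}(qr)\,dr}
#' on a fixed r-grid for each candidate `D_max`: the discretized linear
#' system with a second-derivative smoothness penalty and the boundary
#' conditions `P(0) = P(D_max) = 0` is solved under the non-negativity
#' constraint by non-negative least squares. The winning `D_max` is chosen
#' by a perceptual-criterion score combining fit quality (weighted chi
#' square), parsimony in `D_max`, and a stability term penalizing
#' oscillatory solutions; the reported `D_max` is the end of the recovered
#' support (trimmed of trailing near-zero mass) at the r-grid resolution.
#'
#' @param curve Tibble with `q`, `intensity` and optionally `sigma`
#'   (missing or zero sigmas default to 1% of the intensity scale).
#' @param d_max_candidates Positive candidate maximum dimensions (Angstrom).
#' @param alpha Smoothness weight; `NULL` (default) selects it by an
#'   L-curve corner heuristic over a log-spaced grid.
#' @param n_r Number of r-grid points per candidate (default 101).
#' @param chi_tol Candidates whose chi square exceeds `chi_tol` times the
#'   best candidate's are rejected before parsimony selection (default 2).
#' @return A `pair_distribution` with attribute `"candidates"` (tibble of
#'   candidate `d_max`, `chisq`, `score`, `selected`) and attribute
#'   `"alpha"`.
#' @examples
#' sph <- sim_toy_structure("solid_sphere_beads", radius = 20,
#'                          n_points = 600, seed = 1)
#' cur <- debye_intensity(sph, q = seq(0.01, 0.45, length.out = 70))
#' ift <- ift_pr(cur, d_max_candidates = seq(25, 60, by = 5))
#' ift$d_max # ~ 40
#' @export
ift_pr <- function(curve, d_max_candidates, alpha = NULL, n_r = 101,
                   chi_tol = 2) {
  check_columns(curve, c("q", "intensity"), "curve")
  if (nrow(curve) < 50) abort("Need at least 50 scattering points for the IFT.")
  if (any(d_max_candidates <= 0)) abort("`d_max_candidates` must be > 0.")
  q <- curve$q
  y <- curve$intensity
  sig <- if ("sigma" %in% names(curve)) curve$sigma else rep(NA_real_, length(q))
  sig[is.na(sig) | sig <= 0] <- 0.01 * max(abs(y))
  wts <- 1 / sig

  solve_candidate <- function(d_max, a) {
    r <- seq(0, d_max, length.out = n_r)
    dr <- r[2] - r[1]
    # trapezoid quadrature; boundary nodes are pinned to zero and dropped
    quad <- rep(dr, n_r); quad[c(1, n_r)] <- dr / 2
    kern <- 4 * pi * outer(q, r, function(qq, rr) ssinc(qq * rr))
    amat <- sweep(kern, 2, quad, `*`)[, 2:(n_r - 1), drop = FALSE]
    amat_w <- amat * wts
    y_w <- y * wts
    m <- n_r - 2
    d2 <- matrix(0, m, m)
    for (j in seq_len(m)) {
      d2[j, j] <- -2
      if (j > 1) d2[j, j - 1] <- 1
      if (j < m) d2[j, j + 1] <- 1
    }
    # scale-free penalty: second difference per unit dr^2, normalized to the
    # magnitude of the data rows so alpha is comparable across candidates
    pen <- d2 / dr^2 * sqrt(sum(amat_w^2) / (m * length(q)))
    sol <- pracma::lsqnonneg(rbind(amat_w, sqrt(a) * pen),
                             c(y_w, rep(0, m)))$x
    p <- c(0, sol, 0)
    resid <- y_w - as.vector(amat_w %*% sol)
    chisq <- sum(resid^2) / length(q)
    rough <- sum((d2 %*% sol / dr^2)^2) / max(sum(sol^2), .Machine$double.eps)
    dpos <- diff(p)
    signs <- sign(dpos[abs(dpos) > 1e-6 * max(abs(p))])
    osc <- max(0, sum(diff(signs) != 0) - 1)
    list(r = r, p = p, chisq = chisq, rough = rough, osc = osc)
  }

  pick_alpha <- function(d_max) {
    if (!is.null(alpha)) return(alpha)
    grid <- 10^seq(-6, 2, length.out = 9)
    pts <- purrr::map(grid, function(a) {
      s <- solve_candidate(d_max, a)
      c(log(max(s$chisq, 1e-300)), log(max(s$rough, 1e-300)))
    })
    pm <- do.call(rbind, pts)
    # discrete L-curve corner: maximal curvature of (log rho, log eta)
    if (nrow(pm) < 3) return(grid[1])
    curv <- rep(-Inf, nrow(pm))
    for (k in 2:(nrow(pm) - 1)) {
      v1 <- pm[k, ] - pm[k - 1, ]
      v2 <- pm[k + 1, ] - pm[k, ]
      cross <- v1[1] * v2[2] - v1[2] * v2[1]
      denom <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
      if (denom > 0) curv[k] <- cross / denom
    }
    grid[which.max(curv)]
  }

  a_used <- pick_alpha(stats::median(d_max_candidates))
  sols <- purrr::map(d_max_candidates, solve_candidate, a = a_used)
  chis <- purrr::map_dbl(sols, "chisq")
  best_chi <- min(chis)
  feasible <- chis <= chi_tol * max(best_chi, 1e-300)
  if (!any(feasible)) {
    abort(paste0("No candidate D_max fits the curve; chi-square values: ",
                 paste(signif(chis, 3), collapse = ", ")))
  }
  score <- chis / max(best_chi, 1e-300) +
    0.05 * purrr::map_dbl(sols, "osc") +
    0.02 * rank(d_max_candidates)
  score[!feasible] <- Inf
  sel <- which.min(score)
  s <- sols[[sel]]
  # trim trailing near-zero support; report D_max at grid resolution
  keep <- which(s$p > 1e-3 * max(s$p))
  d_eff <- if (length(keep) > 0) s$r[min(max(keep) + 1, length(s$r))] else
    s$r[length(s$r)]
  r <- s$r[s$r <= d_eff]
  p <- s$p[seq_along(r)]
  p[length(p)] <- 0
  area <- sum((p[-1] + p[-length(p)]) / 2 * diff(r))
  p <- p / area
  out <- new_pair_distribution(r = r, p = p, d_max = d_eff,
                               rg = pr_moment_rg(r, p))
  attr(out, "candidates") <- tibble::tibble(
    d_max = d_max_candidates, chisq = chis, score = score,
    selected = seq_along(sols) == sel
  )
  attr(out, "alpha") <- a_used
  out
}

#' Compare two pair-distance distributions
#'
#' Interpolates both distributions onto a common r-grid (zero-padding to the
#' larger `D_max`) and reports the differences in maximum dimension and
#' radius of gyration, the difference in tail mass beyond a reference
#' quantile of the *average* distribution (so swapping the arguments negates
#' all deltas), and the L1 distance between the normalized curves.
#'
#' @param pr_a,pr_b `pair_distribution` objects.
#' @param tail_quantile Quantile of the averaged distribution defining the
#'   long-distance tail (default 0.9).
#' @return One-row tibble: `delta_d_max`, `delta_rg`, `tail_r`,
#'   `delta_tail_mass`, `l1_distance`.
#' @export
compare_pr <- function(pr_a, pr_b, tail_quantile = 0.9) {
  for (obj in list(pr_a, pr_b)) {
    if (!inherits(obj, "pair_distribution")) {
      abort("Inputs must be pair_distribution objects.")
    }
  }
  r_max <- max(pr_a$d_max, pr_b$d_max)
  r <- seq(0, r_max, length.out = 201)
  interp <- function(pd) {
    p <- stats::approx(pd$r, pd$p, xout = r, yleft = 0, yright = 0,
                       rule = 2)$y
    p[r > pd$d_max] <- 0
    area <- sum((p[-1] + p[-length(p)]) / 2 * diff(r))
    if (area > 0) p / area else p
  }
  pa <- interp(pr_a)
  pb <- interp(pr_b)
  avg <- (pa + pb) / 2
  cum <- cumsum((avg[-1] + avg[-length(avg)]) / 2 * diff(r))
  cum <- c(0, cum) / max(cum[length(cum)], .Machine$double.eps)
  tail_r <- r[min(which(cum >= tail_quantile))]
  tail_mass <- function(p) {
    sel <- r >= tail_r
    rr <- r[sel]
    pp <- p[sel]
    sum((pp[-1] + pp[-length(pp)]) / 2 * diff(rr))
  }
  tibble::tibble(
    delta_d_max = pr_a$d_max - pr_b$d_max,
    delta_rg = pr_a$rg - pr_b$rg,
    tail_r = tail_r,
    delta_tail_mass = tail_mass(pa) - tail_mass(pb),
    l1_distance = sum((abs(pa - pb)[-1] + abs(pa - pb)[-length(pa)]) / 2 *
                        diff(r))
  )
}

#' Read a point model from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` returning coordinates as a tidy atom
#' table with unit weights (shape-only scattering; per-atom form factors are
#' out of scope).
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier(s) to keep.
#' @param calpha_only Keep only C-alpha atoms (default FALSE).
#' @return Tibble with `x`, `y`, `z`, `weight`, `chain`, `elety`.
#' @export
read_atoms <- function(path, chain = NULL, calpha_only = FALSE) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Package `bio3d` is required to read PDB files.")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (calpha_only) at <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0) abort("No atoms left after selection.")
  tibble::tibble(x = at$x, y = at$y, z = at$z, weight = 1,
                 chain = at$chain, elety = at$elety)
}

#' Write a point model as a minimal PDB file
#'
#' Emits plain ATOM records (pseudo-atoms, Angstrom) so toy structures can be
#' exchanged with standard SAXS tooling.
#'
#' @inheritParams debye_intensity
#' @param path Output path.
#' @export
write_atoms <- function(atoms, path) {
  check_columns(atoms, c("x", "y", "z"), "atoms")
  n <- nrow(atoms)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000, seq_len(n) %% 10000,
    atoms$x, atoms$y, atoms$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
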