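#' Simulate FRET dimerization samples with known ground truth
#'
#' Draws membrane regions with total densities and acceptor fractions uniform
#' over the given ranges, computes the noiseless efficiency from the
#' monomer-dimer forward model `f_D([T]; k_diss) * x_A * e_tilde`, adds
#' additive Gaussian measurement noise on the efficiency and clips to
#' \[0, 1\]. Deterministic given `seed`.
#'
#' Default sample size and noise emulate a typical single-construct imaging
#' session: a few hundred membrane regions and an efficiency scatter of a few
#' percent around the binding curve.
#'
#' @param n_regions Number of membrane regions.
#' @param k_diss Generating dissociation constant (> 0), arbitrary surface
#'   density units shared with `density_range`.
#' @param e_tilde Generating intrinsic FRET in (0, 1].
#' @param density_range Length-2 range (min > 0) of total densities.
#' @param acceptor_fraction_range Length-2 range within \[0, 1\].
#' @param noise_sd Gaussian SD of the additive efficiency noise (>= 0).
#' @param seed Integer RNG seed.
#' @return Tibble with columns `region_id`, `total_density`,
#'   `acceptor_fraction`, `fret_true` (noiseless) and `fret` (noisy,
#'   clipped). Generating parameters are stored in attribute `"truth"`.
#' @examples
#' sim_fret_samples(n_regions = 5, seed = 1)
#' @export
sim_fret_samples <- function(n_regions = 300, k_diss = 200, e_tilde = 0.55,
                             density_range = c(10, 4000),
                             acceptor_fraction_range = c(0.3, 0.8),
                             noise_sd = 0.03, seed = 1) {
  check_count(n_regions, "n_regions")
  check_number(k_diss, "k_diss", lower = 0, strict_lower = TRUE)
  check_number(e_tilde, "e_tilde", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (length(density_range) != 2 || density_range[1] <= 0 ||
      diff(density_range) < 0) {
    abort("`density_range` must be (min, max) with min > 0.")
  }
  if (length(acceptor_fraction_range) != 2 ||
      acceptor_fraction_range[1] < 0 || acceptor_fraction_range[2] > 1 ||
      diff(acceptor_fraction_range) < 0) {
    abort("`acceptor_fraction_range` must be (min, max) within [0, 1].")
  }
  with_seed(seed, {
    tt <- exp(runif(n_regions, log(density_range[1]), log(density_range[2])))
    xa <- runif(n_regions, acceptor_fraction_range[1],
                acceptor_fraction_range[2])
    fret_true <- predict_fret(tt, xa, k_diss, e_tilde)
    fret <- pmin(pmax(fret_true + rnorm(n_regions, 0, noise_sd), 0), 1)
    out <- tibble::tibble(
      region_id = sprintf("r%04d", seq_len(n_regions)),
      total_density = tt, acceptor_fraction = xa,
      fret_true = fret_true, fret = fret
    )
    attr(out, "truth") <- list(k_diss = k_diss, e_tilde = e_tilde,
                               noise_sd = noise_sd)
    out
  })
}

#' Simulate a photon-count membrane image over mixed oligomer populations
#'
#' Per pixel, each oligomeric species of size `s` contributes
#' `N_s ~ Poisson(mu_s)` independent units; the detected photon count is then
#' `Poisson(q * sum_s N_s * s)` for a photon-counting detector (for the
#' analog detector, Gaussian read noise of variance `detector_var` is added
#' to the shot-noise-limited signal). The large-image apparent brightness is
#' `q * sum(mu * s^2) / sum(mu * s)` (law of total variance).
#'
#' @param shape Length-2 integer image shape (rows, cols).
#' @param species Data frame with columns `size` (oligomer size, integer
#'   >= 1) and `mean_per_pixel` (mean oligomers per pixel, >= 0).
#' @param photons_per_fluorophore Expected photons per labelled protomer per
#'   exposure (q > 0).
#' @param detector `"photon_counting"` (default) or `"analog"`.
#' @param detector_sd Read-noise SD for the analog detector (ignored for
#'   photon counting).
#' @param mask Optional logical matrix marking the cell footprint; default
#'   all `TRUE`.
#' @param seed Integer RNG seed.
#' @return Object of class `photon_image`: list with integer (or numeric,
#'   analog) matrix `counts`, logical matrix `mask`, `detector`,
#'   `detector_var`, and the generating `truth` (expected mean, variance and
#'   apparent brightness).
#' @examples
#' img <- sim_membrane_image(shape = c(60, 60),
#'                           species = data.frame(size = 1, mean_per_pixel = 5),
#'                           photons_per_fluorophore = 3, seed = 1)
#' mean(img$counts) # close to 15
#' @export
sim_membrane_image <- function(shape = c(150, 150),
                               species = data.frame(size = 1,
                                                    mean_per_pixel = 5),
                               photons_per_fluorophore = 3,
                               detector = c("photon_counting", "analog"),
                               detector_sd = 0, mask = NULL, seed = 1) {
  detector <- match.arg(detector)
  check_number(photons_per_fluorophore, "photons_per_fluorophore",
               lower = 0, strict_lower = TRUE)
  check_columns(species, c("size", "mean_per_pixel"), "species")
  if (any(species$size < 1 | species$size != round(species$size))) {
    abort("`species$size` must be integers >= 1.")
  }
  if (any(species$mean_per_pixel < 0)) {
    abort("`species$mean_per_pixel` must be >= 0.")
  }
  if (length(shape) != 2 || any(shape < 1)) {
    abort("`shape` must be two positive integers.")
  }
  q <- photons_per_fluorophore
  n_pix <- prod(shape)
  counts <- with_seed(seed, {
    fluor <- rep(0, n_pix)
    for (i in seq_len(nrow(species))) {
      fluor <- fluor +
        rpois(n_pix, species$mean_per_pixel[i]) * species$size[i]
    }
    if (detector == "photon_counting") {
      rpois(n_pix, q * fluor)
    } else {
      rpois(n_pix, q * fluor) + rnorm(n_pix, 0, detector_sd)
    }
  })
  mu_s <- species$mean_per_pixel
  s <- species$size
  mean_true <- q * sum(mu_s * s)
  var_true <- mean_true + q^2 * sum(mu_s * s^2) +
    if (detector == "analog") detector_sd^2 else 0
  eps_true <- if (mean_true > 0) q * sum(mu_s * s^2) / sum(mu_s * s) else NA_real_
  if (is.null(mask)) mask <- matrix(TRUE, shape[1], shape[2])
  structure(
    list(
      counts = matrix(counts, shape[1], shape[2]),
      mask = mask,
      detector = detector,
      detector_var = if (detector == "analog") detector_sd^2 else 0,
      truth = list(mean = mean_true, variance = var_true,
                   brightness = eps_true, q = q)
    ),
    class = "photon_image"
  )
}

#' @export
print.photon_image <- function(x, ...) {
  cat(sprintf("photon_image: %d x %d (%s detector), %d masked pixels\n",
              nrow(x$counts), ncol(x$counts), x$detector, sum(x$mask)))
  invisible(x)
}

#' Generate toy point-model structures for scattering fixtures
#'
#' Point models with unit weights on which scattering quantities have simple
#' closed forms: a solid sphere of radius R has `Rg = R * sqrt(3/5)` and
#' `D_max = 2R` in the infinite-bead limit; a dumbbell of two spheres with
#' centres `d` apart has `D_max = d + 2R`.
#'
#' @param kind One of `"solid_sphere_beads"`, `"sphere_shell"`,
#'   `"dumbbell"`, `"two_domain_linker"`.
#' @param radius Sphere radius in Angstrom (for the dumbbell, both lobes).
#' @param n_points Number of points.
#' @param centers_distance Centre-centre distance for `"dumbbell"` /
#'   `"two_domain_linker"`.
#' @param radius2 Second-domain radius for `"two_domain_linker"`.
#' @param linker_fraction Fraction of points laid along the linker axis for
#'   `"two_domain_linker"`.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `x`, `y`, `z`, `weight` (class keeps plain
#'   tibble semantics; coordinates in Angstrom).
#' @examples
#' sph <- sim_toy_structure("solid_sphere_beads", radius = 30,
#'                          n_points = 2000, seed = 1)
#' rg_coords(sph) # ~ 30 * sqrt(3/5) = 23.24
#' @export
sim_toy_structure <- function(kind = c("solid_sphere_beads", "sphere_shell",
                                       "dumbbell", "two_domain_linker"),
                              radius = 30, n_points = 2000,
                              centers_distance = 80, radius2 = radius,
                              linker_fraction = 0.1, seed = 1) {
  kind <- match.arg(kind)
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_count(n_points, "n_points")
  if (kind %in% c("dumbbell", "two_domain_linker")) {
    check_number(centers_distance, "centers_distance", lower = 0,
                 strict_lower = TRUE)
    check_number(radius2, "radius2", lower = 0, strict_lower = TRUE)
  }
  ball <- function(n, r) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    u * (r * runif(n)^(1 / 3))
  }
  shell <- function(n, r) {
    u <- matrix(rnorm(3 * n), ncol = 3)
    r * u / sqrt(rowSums(u^2))
  }
  xyz <- with_seed(seed, switch(
    kind,
    solid_sphere_beads = ball(n_points, radius),
    sphere_shell = shell(n_points, radius),
    dumbbell = {
      n1 <- floor(n_points / 2)
      rbind(
        sweep(ball(n1, radius), 2, c(-centers_distance / 2, 0, 0)),
        sweep(ball(n_points - n1, radius), 2, c(centers_distance / 2, 0, 0))
      )
    },
    two_domain_linker = {
      n_link <- max(2, round(linker_fraction * n_points))
      n1 <- floor((n_points - n_link) / 2)
      n2 <- n_points - n_link - n1
      rbind(
        sweep(ball(n1, radius), 2, c(-centers_distance / 2, 0, 0)),
        sweep(ball(n2, radius2), 2, c(centers_distance / 2, 0, 0)),
        cbind(seq(-centers_distance / 2, centers_distance / 2,
                  length.out = n_link), 0, 0)
      )
    }
  ))
  tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 weight = rep(1, nrow(xyz)))
}

# average amino-acid residue masses (Da), for undeuterated peptide centroids
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

peptide_mass <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  bad <- setdiff(aa, names(AA_MASS))
  if (length(bad) > 0) {
    abort(sprintf("Unknown residue(s): %s.", paste(unique(bad), collapse = ", ")))
  }
  sum(AA_MASS[aa]) + 18.0153
}

#' Simulate a deuterium-uptake peptide table with exponential exchange
#'
#' Exchange at each backbone amide follows first-order kinetics with the
#' supplied per-residue rate constants; the measured centroid mass of a
#' peptide at time `t` is the undeuterated centroid plus
#' `(1 - back_exchange) * sum(1 - exp(-k * t))` over its exchange-competent
#' amides, plus Gaussian replicate noise. Exchange-competent amides are all
#' residues except prolines and the first two residues of the peptide (the
#' N-terminal residue has no retained amide and the second back-exchanges
#' fast).
#'
#' @param sequence Amino-acid string of the construct (one-letter codes).
#' @param residue_offset Residue number of the first sequence position
#'   (construct numbering, 1-based).
#' @param rates Per-residue exchange rate constants (1/min), length
#'   `nchar(sequence)`, >= 0.
#' @param peptides Data frame with columns `start`, `end` (construct
#'   numbering, inclusive) and optionally `peptide_id`.
#' @param time_points Exchange times in minutes (default the standard
#'   five-point grid `c(0, 0.5, 1, 2, 5)`).
#' @param back_exchange Global back-exchange fraction lost, in \[0, 1).
#' @param replicate_sd Gaussian replicate noise on centroid mass (Da).
#' @param n_replicates Replicates per time point (default 3).
#' @param seed Integer RNG seed.
#' @return Tibble in "state table" layout: `peptide_id`, `sequence`, `start`,
#'   `end`, `undeuterated_centroid`, `time`, `replicate`, `centroid_mass`,
#'   plus `uptake_true` (noiseless deuterium uptake, Da). Attribute
#'   `"truth"` stores the generator settings.
#' @examples
#' peps <- data.frame(start = c(1, 6), end = c(10, 14))
#' sim_hdx_peptides("GSSGKLMNPQRSTV", rates = rep(1, 14), peptides = peps,
#'                  seed = 1)
#' @export
sim_hdx_peptides <- function(sequence, residue_offset = 1, rates, peptides,
                             time_points = c(0, 0.5, 1, 2, 5),
                             back_exchange = 0.25, replicate_sd = 0.05,
                             n_replicates = 3, seed = 1) {
  n_res <- nchar(sequence)
  if (length(rates) != n_res) {
    abort("`rates` must have one rate per sequence residue.")
  }
  if (any(rates < 0)) abort("`rates` must be >= 0.")
  check_number(back_exchange, "back_exchange", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(replicate_sd, "replicate_sd", lower = 0)
  check_columns(peptides, c("start", "end"), "peptides")
  if (!"peptide_id" %in% names(peptides)) {
    peptides$peptide_id <- sprintf("p%03d", seq_len(nrow(peptides)))
  }
  aa <- strsplit(sequence, "")[[1]]
  last_res <- residue_offset + n_res - 1
  if (any(peptides$start < residue_offset | peptides$end > last_res |
          peptides$end < peptides$start)) {
    abort("Peptide span outside the sequence.")
  }
  with_seed(seed, {
    rows <- purrr::pmap(peptides, function(start, end, peptide_id, ...) {
      idx <- (start:end) - residue_offset + 1
      pep_seq <- paste(aa[idx], collapse = "")
      # competent: drop the peptide's first two residues and all prolines
      comp <- idx[-c(1, 2)]
      comp <- comp[aa[comp] != "P"]
      undeut <- peptide_mass(pep_seq)
      grid <- tidyr::expand_grid(time = time_points,
                                 replicate = seq_len(n_replicates))
      uptake_true <- vapply(grid$time, function(t) {
        (1 - back_exchange) * sum(1 - exp(-rates[comp] * t))
      }, 0.0)
      tibble::tibble(
        peptide_id = peptide_id, sequence = pep_seq,
        start = start, end = end,
        undeuterated_centroid = undeut,
        time = grid$time, replicate = grid$replicate,
        uptake_true = uptake_true,
        centroid_mass = undeut + uptake_true +
          rnorm(nrow(grid), 0, replicate_sd)
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- list(back_exchange = back_exchange,
                               replicate_sd = replicate_sd, rates = rates)
    out
  })
}

#' Simulate a long-tailed kinase-screen signal table
#'
#' Builds `n_kinases` kinase records whose descending signal curve follows a
#' power law in rank, with the exponent solved (by root finding) so that the
#' top `n_top` kinases account for exactly `top_share` of the total signal.
#' Log-normal jitter is applied within the top and tail groups and each group
#' is rescaled to preserve the exact share; jitter is automatically damped if
#' it would let a tail kinase overtake the top group. Deterministic given
#' `seed`.
#'
#' @param n_kinases Number of kinases (e.g. 298 for a serine/threonine
#'   kinome-scale screen).
#' @param n_top Size of the top group (1 <= n_top < n_kinases).
#' @param top_share Fraction of total signal carried by the top group, in
#'   (n_top/n_kinases, 1).
#' @param total_signal Total signal over the table (CPM units by default).
#' @param assay `"radio_33P"` (CPM) or `"adp_glo"` (RLU).
#' @param jitter_sd Log-normal jitter SD (log scale).
#' @param seed Integer RNG seed.
#' @return Tibble with `kinase`, `family`, `substrate_peptide`, `signal`,
#'   `assay`, sorted in the generation order (not ranked).
#' @examples
#' tab <- sim_kinase_table(n_kinases = 298, n_top = 45, top_share = 0.70,
#'                         seed = 1)
#' sum(sort(tab$signal, decreasing = TRUE)[1:45]) / sum(tab$signal)
#' @export
sim_kinase_table <- function(n_kinases = 298, n_top = 45, top_share = 0.70,
                             total_signal = 5e6,
                             assay = c("radio_33P", "adp_glo"),
                             jitter_sd = 0.15, seed = 1) {
  assay <- match.arg(assay)
  check_count(n_kinases, "n_kinases", min = 2L)
  check_count(n_top, "n_top", min = 1L)
  if (n_top >= n_kinases) abort("`n_top` must be < `n_kinases`.")
  check_number(top_share, "top_share", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (top_share <= n_top / n_kinases) {
    abort(sprintf(
      "Infeasible share: top_share must exceed n_top/n_kinases = %.3f for a descending curve.",
      n_top / n_kinases
    ))
  }
  ranks <- seq_len(n_kinases)
  share_at <- function(g) sum(ranks[1:n_top]^-g) / sum(ranks^-g)
  gamma <- uniroot(function(g) share_at(g) - top_share,
                   lower = 1e-6, upper = 50)$root
  base <- ranks^-gamma
  with_seed(seed, {
    repeat_sd <- jitter_sd
    repeat {
      sig <- base * exp(rnorm(n_kinases, 0, repeat_sd))
      top <- sort(sig[1:n_top], decreasing = TRUE)
      rest <- sort(sig[(n_top + 1):n_kinases], decreasing = TRUE)
      top <- top / sum(top) * top_share * total_signal
      rest <- rest / sum(rest) * (1 - top_share) * total_signal
      if (min(top) > max(rest) || repeat_sd < 1e-8) break
      repeat_sd <- repeat_sd / 2
    }
    fam <- paste0("FAM", sprintf("%02d", ((ranks - 1) %% 25) + 1))
    tibble::tibble(
      kinase = sprintf("KIN%03d", ranks),
      family = fam,
      substrate_peptide = "linker_pS897",
      signal = c(top, rest),
      assay = assay
    )
  })
}
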