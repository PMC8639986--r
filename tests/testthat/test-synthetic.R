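test_that("generators are deterministic given a seed", {
  expect_identical(sim_fret_samples(n_regions = 20, seed = 3),
                   sim_fret_samples(n_regions = 20, seed = 3))
  expect_identical(sim_membrane_image(shape = c(30, 30), seed = 5)$counts,
                   sim_membrane_image(shape = c(30, 30), seed = 5)$counts)
  expect_identical(sim_kinase_table(n_kinases = 50, n_top = 10,
                                    top_share = 0.6, seed = 2),
                   sim_kinase_table(n_kinases = 50, n_top = 10,
                                    top_share = 0.6, seed = 2))
  peps <- data.frame(start = 1, end = 8)
  expect_identical(
    sim_hdx_peptides("GAKLEVSA", rates = rep(1, 8), peptides = peps, seed = 7),
    sim_hdx_peptides("GAKLEVSA", rates = rep(1, 8), peptides = peps, seed = 7)
  )
})

test_that("noise-free FRET samples satisfy the forward model exactly", {
  d <- sim_fret_samples(n_regions = 100, k_diss = 150, e_tilde = 0.6,
                        noise_sd = 0, seed = 2)
  expect_identical(d$fret, d$fret_true)
  pred <- predict_fret(d$total_density, d$acceptor_fraction, 150, 0.6)
  expect_equal(d$fret, pred, tolerance = 1e-14)
  # single region pinned at [T] = K_diss with x_A = 1 gives half e_tilde
  d1 <- sim_fret_samples(n_regions = 1, k_diss = 300, e_tilde = 0.8,
                         density_range = c(300, 300),
                         acceptor_fraction_range = c(1, 1),
                         noise_sd = 0, seed = 1)
  expect_equal(d1$fret, 0.4)
  expect_error(sim_fret_samples(e_tilde = 1.4), "e_tilde")
  expect_error(sim_fret_samples(density_range = c(-5, 10)), "density_range")
})

test_that("membrane images match the Poisson mixture moments", {
  # >= 1e6 pixels; empirical mean/variance vs <I> = q*sum(mu*s) and
  # sigma^2 = <I> + q^2*sum(mu*s^2), within 3 Monte-Carlo standard errors
  species <- data.frame(size = c(1, 2), mean_per_pixel = c(3, 2))
  q <- 2
  img <- sim_membrane_image(shape = c(1000, 1000), species = species,
                            photons_per_fluorophore = q, seed = 10)
  x <- as.vector(img$counts)
  n <- length(x)
  mean_true <- q * sum(species$mean_per_pixel * species$size)
  var_true <- mean_true + q^2 * sum(species$mean_per_pixel * species$size^2)
  se_mean <- sd(x) / sqrt(n)
  m <- mean(x)
  se_var <- sqrt((mean((x - m)^4) - var(x)^2) / n)
  expect_lt(abs(m - mean_true), 3 * se_mean)
  expect_lt(abs(var(x) - var_true), 3 * se_var)
  expect_equal(img$truth$brightness, eps_oracle(species$mean_per_pixel,
                                                species$size, q))
})

test_that("membrane image with no molecules is all zeros, not an error", {
  img <- sim_membrane_image(shape = c(20, 20),
                            species = data.frame(size = 1, mean_per_pixel = 0),
                            photons_per_fluorophore = 3, seed = 1)
  expect_true(all(img$counts == 0))
  expect_true(is.na(img$truth$brightness))
})

test_that("toy structures obey their closed-form geometry", {
  sph <- sim_toy_structure("solid_sphere_beads", radius = 30,
                           n_points = 5000, seed = 1)
  expect_lt(abs(rg_coords(sph) / (30 * sqrt(3 / 5)) - 1), 0.01)
  one <- tibble::tibble(x = 1, y = 2, z = 3, weight = 1)
  expect_equal(rg_coords(one), 0)
  pr1 <- pr_from_structure(one)
  expect_equal(pr1$d_max, 0)
  db <- sim_toy_structure("dumbbell", radius = 15, centers_distance = 80,
                          n_points = 4000, seed = 2)
  prd <- pr_from_structure(db)
  expect_lt(abs(prd$d_max - 110), 2) # within a bin or two of 80 + 2*15
  expect_error(sim_toy_structure("dumbbell", radius = -3), "radius")
})

test_that("HDX generator follows the exponential-exchange closed forms", {
  peps <- data.frame(start = c(1, 4), end = c(10, 12))
  seqs <- "GAKLEVSAPTQR"
  # zero rates: flat zero uptake at all times
  d0 <- sim_hdx_peptides(seqs, rates = rep(0, 12), peptides = peps,
                         replicate_sd = 0, seed = 1)
  expect_true(all(d0$uptake_true == 0))
  expect_true(all(abs(d0$centroid_mass - d0$undeuterated_centroid) < 1e-12))
  # saturating rates with back exchange: plateau at (1-be) * max amides
  dfast <- sim_hdx_peptides(seqs, rates = rep(1e6, 12), peptides = peps,
                            back_exchange = 0.25, replicate_sd = 0, seed = 1)
  plateau <- dfast[dfast$time == 5, ]
  expect_equal(plateau$uptake_true,
               0.75 * max_exchangeable(plateau$sequence), tolerance = 1e-9)
  # t = 0 is exactly undeuterated
  expect_true(all(dfast$uptake_true[dfast$time == 0] == 0))
  # noiseless uptake is non-decreasing in time for every peptide
  d <- sim_hdx_peptides(seqs, rates = runif(12, 0, 3), peptides = peps,
                        replicate_sd = 0, seed = 3)
  by_pep <- split(d[d$replicate == 1, ], d$peptide_id[d$replicate == 1])
  for (p in by_pep) {
    expect_true(all(diff(p$uptake_true[order(p$time)]) >= 0))
  }
  expect_error(
    sim_hdx_peptides(seqs, rates = rep(1, 12),
                     peptides = data.frame(start = 1, end = 20), seed = 1),
    "span"
  )
})

test_that("kinase tables carry the requested top-group share exactly", {
  tab <- sim_kinase_table(n_kinases = 298, n_top = 45, top_share = 0.70,
                          seed = 1)
  expect_identical(nrow(tab), 298L)
  expect_equal(share_brute(tab$signal, 45), 0.70, tolerance = 1e-12)
  expect_equal(top_k_share(tab, 45), 0.70, tolerance = 1e-12)
  # holds for other seeds and shapes (construction, not luck)
  for (s in 2:6) {
    t2 <- sim_kinase_table(n_kinases = 120, n_top = 20, top_share = 0.55,
                           seed = s)
    expect_equal(share_brute(t2$signal, 20), 0.55, tolerance = 1e-12)
  }
  expect_error(sim_kinase_table(n_top = 0), "n_top")
  expect_error(sim_kinase_table(n_kinases = 100, n_top = 50,
                                top_share = 0.3), "Infeasible")
})
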