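test_that("scattering text files round-trip with comments and flags", {
  q <- seq(0.01, 0.3, length.out = 40)
  cur <- tibble::tibble(q = q, intensity = exp(-q^2 * 100),
                        sigma = 0.01 * exp(-q^2 * 100))
  path <- withr::local_tempfile(fileext = ".dat")
  write_scattering(cur, path)
  back <- read_scattering(path)
  expect_equal(back$q, cur$q, tolerance = 1e-9)
  expect_equal(back$intensity, cur$intensity, tolerance = 1e-9)
  # headers/comments tolerated, negatives flagged but retained
  writeLines(c("# a comment", "q I err", "0.01 1.0 0.1",
               "0.02 0.5 0.1", "0.03 -0.01 0.1"), path)
  cur2 <- read_scattering(path)
  expect_identical(nrow(cur2), 3L)
  expect_identical(cur2$flag_negative, c(FALSE, FALSE, TRUE))
  expect_identical(nrow(read_scattering(path, trim_negative = TRUE)), 2L)
  writeLines(c("0.03 1", "0.01 2"), path)
  expect_error(read_scattering(path), "increasing")
})

test_that("Guinier fit inverts an exact Gaussian curve to machine precision", {
  q <- seq(0.002, 0.2, by = 0.002)
  cur <- tibble::tibble(q = q, intensity = 7 * exp(-q^2 * 25^2 / 3))
  g <- guinier_fit(cur)
  expect_lt(abs(g$rg - 25), 1e-9)
  expect_lt(abs(g$i0 - 7), 1e-9)
  expect_lte(g$qmax_rg, 1.3)
  # positive slope has no Guinier region
  bad <- tibble::tibble(q = q, intensity = exp(q^2 * 50))
  expect_error(guinier_fit(bad), "aggregated")
})

test_that("Guinier Rg is robust to multiplicative noise", {
  q <- seq(0.004, 0.12, by = 0.002)
  base <- 3 * exp(-q^2 * 22^2 / 3)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    cur <- tibble::tibble(q = q, intensity = base * (1 + rnorm(length(q), 0, 0.01)))
    guinier_fit(cur)$rg / 22 - 1
  }, 0.0)
  expect_lt(abs(median(errs)), 0.02)
})

test_that("Debye intensities match closed forms and the histogram shortcut", {
  one <- tibble::tibble(x = 0, y = 0, z = 0, weight = 2)
  expect_equal(debye_intensity(one, c(0.1, 1))$intensity, c(4, 4))
  two <- tibble::tibble(x = c(0, 10), y = 0, z = 0, weight = 1)
  q <- c(0.05, 0.2, 0.7)
  expect_equal(debye_intensity(two, q, method = "direct")$intensity,
               2 + 2 * sin(q * 10) / (q * 10), tolerance = 1e-12)
  expect_equal(debye_intensity(two, q, method = "direct")$intensity[1],
               debye_intensity(two, q, method = "histogram",
                               bin_width = 0.001)$intensity[1],
               tolerance = 1e-6)
  # histogram acceleration vs direct double sum on a random cloud
  set.seed(7)
  cloud <- tibble::tibble(x = runif(500, 0, 40), y = runif(500, 0, 40),
                          z = runif(500, 0, 40), weight = 1)
  qs <- seq(0.01, 0.5, length.out = 25)
  i_dir <- debye_intensity(cloud, qs, method = "direct")$intensity
  i_his <- debye_intensity(cloud, qs, method = "histogram",
                           bin_width = 0.1)$intensity
  expect_lt(max(abs(i_his / i_dir - 1)), 1e-3)
  expect_error(debye_intensity(two, numeric(0)), "empty")
})

test_that("P(r) from structure reports geometry and normalization", {
  two <- tibble::tibble(x = c(0, 50), y = 0, z = 0, weight = 1)
  pr <- pr_from_structure(two)
  expect_equal(pr$d_max, 50)
  expect_identical(pr$p[1], 0)
  occupied <- pr$r[pr$p > 0]
  expect_true(all(abs(occupied - 50) <= 1))
  # unit area for every output
  area <- sum((pr$p[-1] + pr$p[-length(pr$p)]) / 2 * diff(pr$r))
  expect_equal(area, 1, tolerance = 1e-12)
  # moment Rg agrees with the direct coordinate Rg on a globular model
  sph <- sim_toy_structure("solid_sphere_beads", radius = 30,
                           n_points = 3000, seed = 5)
  prs <- pr_from_structure(sph)
  expect_lt(abs(prs$rg / rg_coords(sph) - 1), 0.01)
})

test_that("pair-distribution comparisons are antisymmetric", {
  sph <- sim_toy_structure("solid_sphere_beads", radius = 20,
                           n_points = 1500, seed = 1)
  db <- sim_toy_structure("dumbbell", radius = 15, centers_distance = 80,
                          n_points = 1500, seed = 2)
  pa <- pr_from_structure(sph)
  pb <- pr_from_structure(db)
  self <- compare_pr(pa, pa)
  expect_equal(self$delta_d_max, 0)
  expect_equal(self$delta_rg, 0)
  expect_equal(self$delta_tail_mass, 0)
  expect_equal(self$l1_distance, 0)
  ab <- compare_pr(pb, pa) # elongated minus compact
  ba <- compare_pr(pa, pb)
  expect_gt(ab$delta_d_max, 0)
  expect_gt(ab$delta_tail_mass, 0)
  expect_equal(ab$delta_d_max, -ba$delta_d_max)
  expect_equal(ab$delta_rg, -ba$delta_rg)
  expect_equal(ab$delta_tail_mass, -ba$delta_tail_mass, tolerance = 1e-12)
})

test_that("undersized D_max candidates are rejected by the fit", {
  sph <- sim_toy_structure("solid_sphere_beads", radius = 25,
                           n_points = 1000, seed = 3)
  cur <- debye_intensity(sph, seq(0.01, 0.4, length.out = 70))
  ift <- ift_pr(cur, d_max_candidates = c(20, 30, 50, 60))
  cand <- attr(ift, "candidates")
  # truncated supports cannot fit the curve: chi-square blows up
  expect_gt(cand$chisq[cand$d_max == 20] / min(cand$chisq), 100)
  expect_false(cand$selected[cand$d_max == 20])
  expect_lt(abs(ift$d_max / 50 - 1), 0.1)
})

test_that("PDB atom tables round-trip through the minimal writer", {
  sph <- sim_toy_structure("solid_sphere_beads", radius = 10,
                           n_points = 50, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_atoms(sph, path)
  back <- read_atoms(path)
  expect_identical(nrow(back), 50L)
  expect_equal(back$x, round(sph$x, 3), tolerance = 1e-9)
  expect_equal(rg_coords(back), rg_coords(sph), tolerance = 1e-3)
  ca <- read_atoms(path, calpha_only = TRUE)
  expect_identical(nrow(ca), 50L)
})
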