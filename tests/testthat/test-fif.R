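test_that("segmentation tiles the mask into full 15x15 blocks", {
  img <- matrix(5L, 45, 45)
  seg <- segment_cell(img)
  expect_identical(nrow(seg), 9L)
  expect_true(all(seg$n_pixels == 225))
  # constant image: mean c, zero variance
  expect_true(all(seg$mean_intensity == 5))
  expect_true(all(seg$variance == 0))
  # checkerboard of 0/2: mean ~1, unbiased variance ~225/224 (a 15x15 block
  # holds 225 pixels, so the split is 113/112 rather than exactly even)
  cb <- matrix(0L, 30, 30)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 2L
  segcb <- segment_cell(cb)
  expect_equal(segcb$mean_intensity, rep(1, nrow(segcb)), tolerance = 0.005)
  expect_equal(segcb$variance, rep(225 / 224, nrow(segcb)), tolerance = 1e-4)
  # exact check against direct variance of the block's own pixels
  blk <- cb[1:15, 1:15]
  expect_equal(segcb$variance[1], var(as.vector(blk)), tolerance = 1e-15)
  # partial blocks at the mask edge are dropped
  mask <- matrix(TRUE, 40, 40) # 40 = 2*15 + 10
  seg2 <- segment_cell(matrix(1L, 40, 40), mask)
  expect_identical(nrow(seg2), 4L)
  expect_warning(segment_cell(matrix(1L, 10, 10)), "smaller than one segment")
})

test_that("brightness follows the photon-counting and analog estimators", {
  st <- tibble::tibble(mean_intensity = c(10, 0, 8), variance = c(30, 0, 8))
  b <- segment_brightness(st)
  expect_equal(b$brightness[1], 2) # 30/10 - 1
  expect_true(is.na(b$brightness[2]) && !b$valid[2])
  expect_equal(b$brightness[3], 0) # shot-noise-limited: sigma^2 = <I>
  ba <- segment_brightness(st, detector = "analog", detector_var = 10)
  expect_equal(ba$brightness[1], 2) # (30 - 10)/10
  # pure Poisson background has brightness ~ 0
  set.seed(21)
  pois <- matrix(rpois(150 * 150, 15), 150, 150)
  eps <- segment_brightness(segment_cell(pois))$brightness
  expect_lt(abs(median(eps)), 0.05)
})

test_that("segment brightness converges to the mixture oracle", {
  # three mixtures checked against eps_app = q * sum(mu s^2) / sum(mu s)
  cases <- list(
    list(species = data.frame(size = 1, mean_per_pixel = 5), q = 3),
    list(species = data.frame(size = 2, mean_per_pixel = 2.5), q = 3),
    list(species = data.frame(size = c(1, 2), mean_per_pixel = c(2, 2)), q = 2)
  )
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    img <- sim_membrane_image(shape = c(150, 150), species = cs$species,
                              photons_per_fluorophore = cs$q, seed = 30 + i)
    eps <- segment_brightness(segment_cell(img))$brightness
    oracle <- eps_oracle(cs$species$mean_per_pixel, cs$species$size, cs$q)
    expect_lt(abs(median(eps) / oracle - 1), 0.1)
  }
})

make_cells <- function(seeds, species, q = 3) {
  dplyr::bind_rows(lapply(seq_along(seeds), function(i) {
    img <- sim_membrane_image(shape = c(90, 90), species = species,
                              photons_per_fluorophore = q, seed = seeds[i])
    segment_brightness(segment_cell(img, cell_id = i))
  }))
}

test_that("brightness distributions are normalized and averaged per cell", {
  segs <- make_cells(1:4, data.frame(size = 1, mean_per_pixel = 5))
  bd <- brightness_distribution(segs)
  expect_identical(bd$n_cells, 4L)
  expect_equal(unname(rowSums(bd$per_cell)), rep(1, 4), tolerance = 1e-12)
  expect_equal(bd$curve$mean, unname(colMeans(bd$per_cell)))
  # single cell: SE curve all zeros
  bd1 <- brightness_distribution(segs[segs$cell_id == 1, ])
  expect_true(all(bd1$curve$se == 0))
  # two identical cells: mean equals either, SE = 0
  s2 <- dplyr::bind_rows(segs[segs$cell_id == 1, ],
                         dplyr::mutate(segs[segs$cell_id == 1, ],
                                       cell_id = 99))
  bd2 <- brightness_distribution(s2)
  expect_equal(bd2$curve$mean, unname(bd2$per_cell[1, ]))
  expect_true(all(bd2$curve$se < 1e-15))
})

test_that("dimer populations sit right of monomer populations", {
  # stochastic right shift of the median in >= 95/100 seeds
  wins <- 0L
  for (s in 1:100) {
    mono <- sim_membrane_image(shape = c(90, 90),
                               species = data.frame(size = 1,
                                                    mean_per_pixel = 5),
                               photons_per_fluorophore = 3, seed = s)
    dim2 <- sim_membrane_image(shape = c(90, 90),
                               species = data.frame(size = 2,
                                                    mean_per_pixel = 2.5),
                               photons_per_fluorophore = 3, seed = s + 500)
    em <- median(segment_brightness(segment_cell(mono))$brightness)
    ed <- median(segment_brightness(segment_cell(dim2))$brightness)
    if (ed > em) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("distribution placement against monomer/dimer controls works", {
  mono_segs <- make_cells(1:3, data.frame(size = 1, mean_per_pixel = 5))
  dim_segs <- make_cells(11:13, data.frame(size = 2, mean_per_pixel = 2.5))
  mix_segs <- make_cells(21:23, data.frame(size = c(1, 2),
                                           mean_per_pixel = c(2.5, 1.25)))
  tetra_segs <- make_cells(31:33, data.frame(size = 4,
                                             mean_per_pixel = 1.25))
  bins <- exp(seq(log(0.5), log(30), length.out = 30))
  mono <- brightness_distribution(mono_segs, bins = bins)
  dimr <- brightness_distribution(dim_segs, bins = bins)
  mix <- brightness_distribution(mix_segs, bins = bins)
  tetra <- brightness_distribution(tetra_segs, bins = bins)
  self <- compare_to_references(mono, mono, dimr)
  expect_equal(self$ratio_vs_monomer, 1)
  expect_identical(self$classification, "at monomer")
  expect_identical(compare_to_references(mix, mono, dimr)$classification,
                   "between")
  expect_identical(compare_to_references(tetra, mono, dimr)$classification,
                   "above dimer")
  expect_error(
    compare_to_references(brightness_distribution(mix_segs), mono, dimr),
    "Bin edges"
  )
})
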