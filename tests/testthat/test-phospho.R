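test_that("kinase ranking matches brute-force arithmetic", {
  tab <- data.frame(kinase = c("a", "b", "c"), signal = c(10, 30, 60))
  r <- rank_kinases(tab)
  expect_identical(r$kinase, c("c", "b", "a"))
  expect_equal(top_k_share(tab, 1), 0.60)
  expect_equal(top_k_share(tab, 2), 0.90)
  expect_equal(r$cumulative_fraction[3], 1)
  # equal signals: top-k share is k/n, ties broken by name
  eq <- data.frame(kinase = c("d", "b", "a", "c"), signal = rep(5, 4))
  re <- rank_kinases(eq)
  expect_identical(re$kinase, c("a", "b", "c", "d"))
  expect_equal(top_k_share(eq, 3), 3 / 4)
  expect_error(rank_kinases(data.frame(kinase = "a", signal = 0)), "zero")
  expect_error(
    rank_kinases(data.frame(kinase = c("a", "b"), signal = c(1, 2),
                            assay = c("radio_33P", "adp_glo"))),
    "Mixed assay"
  )
})

test_that("cumulative fractions are non-decreasing and end at one", {
  for (s in 1:5) {
    set.seed(s)
    tab <- data.frame(kinase = sprintf("k%02d", 1:50),
                      signal = rexp(50, 1 / 1000))
    r <- rank_kinases(tab)
    expect_true(all(diff(r$cumulative_fraction) >= 0))
    expect_equal(r$cumulative_fraction[50], 1, tolerance = 1e-12)
    k <- sample(50, 1)
    expect_equal(top_k_share(tab, k), share_brute(tab$signal, k),
                 tolerance = 1e-14)
  }
})

test_that("threshold counts use strict inequality and are monotone", {
  tab <- data.frame(kinase = c("a", "b", "c"),
                    signal = c(49999, 50000, 50001))
  expect_identical(threshold_count(tab, 50000), 1L)
  expect_identical(threshold_count(tab, 0), 3L)
  set.seed(9)
  tab2 <- data.frame(kinase = sprintf("k%03d", 1:200),
                     signal = rexp(200, 1 / 2e4))
  cuts <- seq(0, 1e5, length.out = 21)
  counts <- vapply(cuts, function(cc) threshold_count(tab2, cc), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], sum(tab2$signal > 0))
})

test_that("site preference classifies availability and priming contrasts", {
  substrates <- tibble::tibble(
    substrate = c("wt", "s892a", "s897p", "s897a_1", "s897a_2"),
    site = c("S892", "S892", "S897", "S897", "S897"),
    status = c("available", "blocked", "primed", "blocked", "blocked"),
    variant_group = c(NA, NA, NA, "s897a", "s897a")
  )
  records <- tibble::tibble(
    kinase = rep(c("PKC1", "CK1a", "NULLK"), each = 5),
    substrate = rep(substrates$substrate, 3),
    signal = c(
      100000, 5000, 20000, 20000, 20000,  # PKC1: needs S892 available
      8000, 8000, 90000, 4000, 6000,      # CK1a: needs S897 primed
      10000, 10000, 10000, 10000, 10000   # indifferent
    )
  )
  prefs <- site_preference(records, substrates)
  pkc <- prefs[prefs$kinase == "PKC1" & prefs$site == "S892" &
                 prefs$substrate_lo == "s892a", ]
  expect_equal(pkc$ratio, 20)
  expect_identical(pkc$label, "mainly phosphorylates S892")
  ck1 <- prefs[prefs$kinase == "CK1a" & prefs$site == "S897" &
                 prefs$substrate_lo == "s897a", ]
  expect_equal(ck1$ratio, 90000 / 5000) # vs averaged last-residue variants
  expect_identical(ck1$label, "requires priming at S897")
  nullk <- prefs[prefs$kinase == "NULLK", ]
  expect_true(all(nullk$label == "indifferent"))
  # identical substrate sets: nothing to compare, flagged
  one_sub <- tibble::tibble(substrate = "wt", site = "S892",
                            status = "available")
  no_inf <- site_preference(records[records$substrate == "wt", ], one_sub)
  expect_true(all(no_inf$label == "no inference"))
})

test_that("multisite fractions count combinations correctly", {
  obs <- data.frame(sites = c("897", "897+901", "892+897+898+899"))
  m <- multisite_fraction(obs)
  expect_equal(m$fraction_multisite, 2 / 3)
  expect_identical(m$max_sites, 4L)
  expect_identical(nrow(m$combinations), 3L)
  expect_equal(sum(m$combinations$frequency), 1)
  single <- multisite_fraction(data.frame(sites = c("897", "892")))
  expect_equal(single$fraction_multisite, 0)
  expect_error(multisite_fraction(data.frame(sites = "")), "at least one site")
  # list-column and count weighting
  obs2 <- tibble::tibble(sites = list("897", c("897", "901")),
                         count = c(30, 70))
  expect_equal(multisite_fraction(obs2)$fraction_multisite, 0.7)
})

test_that("site correlations match brute-force covariance computation", {
  set.seed(13)
  m <- cbind(S892 = rnorm(30), S897 = rnorm(30), S901 = rnorm(30))
  m[, "S901"] <- 0.9 * m[, "S897"] + 0.1 * rnorm(30)
  cc <- site_correlation(m)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 3))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(cc[i, j], cor_brute(m[, i], m[, j]), tolerance = 1e-12)
  }
  # duplicated column correlates perfectly; anti-correlation is exact
  expect_equal(site_correlation(cbind(a = m[, 1], b = m[, 1]))["a", "b"], 1)
  expect_equal(site_correlation(cbind(a = m[, 1], b = -m[, 1]))["a", "b"], -1)
  # independent columns at n = 1000 decorrelate
  set.seed(14)
  big <- cbind(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(site_correlation(big)["x", "y"]), 0.1)
  expect_warning(site_correlation(cbind(a = m[, 1], b = rep(2, 30))),
                 "Constant")
  expect_error(site_correlation(m[1:2, ]), "3 cell lines")
})
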