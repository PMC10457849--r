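# Sieve fraction tables, homogeneity index, fines, PSD quantiles.

test_that("fraction table uses the midpoint diameter convention", {
  s <- sieve_analysis(retained_pct = c(0, 5, 25, 60), pan_pct = 10)
  ft <- fraction_table(s)
  expect_equal(ft$diameter, c(25, 75, 156, 283.5))
  expect_equal(ft$percent, c(10, 60, 25, 5))
  expect_equal(attr(ft, "majority"), 2)
})

test_that("degenerate and tied fraction tables resolve deterministically", {
  all_pan <- fraction_table(sieve_analysis(rep(0, 4), 100))
  expect_equal(nrow(all_pan), 1)
  expect_equal(all_pan$diameter, 25)
  # four-way tie: majority is the smallest-diameter fraction
  tie <- fraction_table(sieve_analysis(c(0, 25, 25, 25), 25))
  expect_equal(attr(tie, "majority"), 1)
  expect_equal(tie$diameter[attr(tie, "majority")], 25)
  expect_error(fraction_table(sieve_analysis(rep(0, 4), 0)), "zero")
})

test_that("the dedicated fines test overrides the pan percentage", {
  s <- sieve_analysis(c(1, 9, 40, 38), pan_pct = 9,
                      fines_direct_pct = 12.15)
  expect_equal(percent_fines(s), 12.15)
  expect_equal(to_radius("Pf", percent_fines(s)), 7.57)
  s2 <- sieve_analysis(c(1, 9, 40, 41), pan_pct = 9)
  expect_equal(percent_fines(s2), 9)
  expect_equal(to_radius("Pf", 0), 10)
  expect_equal(to_radius("Pf", 50), 0)
})

test_that("homogeneity index matches the hand-computed oracle", {
  # majority 60% at 75 um, neighbours at 25/156/283.5 um
  s <- sieve_analysis(retained_pct = c(0, 5, 25, 60), pan_pct = 10)
  it <- homogeneity_index(s)
  expect_equal(it, 60 / (100 + 50 * 10 + 81 * 25 + 208.5 * 5),
               tolerance = 1e-12)
  expect_equal(to_radius("Itheta", it), 8.18, tolerance = 0.005)
  # all mass in one fraction: index = Fm/100 = 1, radius clamps to 10
  one <- homogeneity_index(sieve_analysis(rep(0, 4), 100))
  expect_equal(one, 1)
  expect_equal(suppressWarnings(to_radius("Itheta", one)), 10)
})

test_that("homogeneity index round-trips a published batch radius", {
  # radius 4.18 corresponds to index 0.00836
  expect_equal(from_radius("Itheta", 4.18), 0.00836)
  expect_equal(to_radius("Itheta", 0.00836), 4.18)
})

test_that("homogeneity index is bounded by Fm/100 and falls with spread", {
  set.seed(31)
  for (i in 1:40) {
    pct <- runif(5); pct <- pct / sum(pct) * 100
    s <- sieve_analysis(pct[1:4], pct[5])
    ft <- fraction_table(s)
    it <- homogeneity_index(ft)
    Fm <- max(ft$percent)
    expect_lte(it, Fm / 100 + 1e-12)
    expect_gt(it, 0)
  }
  # moving mass into a distant fraction (holding Fm) strictly lowers it
  base <- homogeneity_index(sieve_analysis(c(0, 0, 60, 20), 20,
                                           loss_tol = 0))
  spread <- homogeneity_index(sieve_analysis(c(10, 0, 60, 10), 20,
                                             loss_tol = 0))
  expect_lt(spread, base)
})

test_that("PSD quantiles recover lognormal quantiles by interpolation", {
  sizes <- exp(seq(log(0.5), log(2000), length.out = 250))
  for (med in c(60, 13)) {
    cv <- plnorm(sizes, log(med), 0.95) * 100
    q <- psd_quantiles(psd_curve(sizes, cv))
    expect_equal(q$D10, qlnorm(0.1, log(med), 0.95), tolerance = 1e-3)
    expect_equal(q$D50, qlnorm(0.5, log(med), 0.95), tolerance = 1e-3)
    expect_equal(q$D90, qlnorm(0.9, log(med), 0.95), tolerance = 1e-3)
    expect_equal(q$Fprime, q$D90 / q$D10)
  }
})

test_that("PSD quantiles are monotone in the level and error off-support", {
  sizes <- exp(seq(log(1), log(500), length.out = 120))
  crv <- psd_curve(sizes, plnorm(sizes, log(30), 0.8) * 100)
  qs <- unlist(psd_quantiles(crv, probs = c(5, 25, 50, 75, 95))[1:5])
  expect_true(all(diff(qs) > 0))
  lo <- psd_curve(c(10, 20, 40), c(50, 80, 100))
  expect_error(psd_quantiles(lo), "outside curve support")
})

test_that("a grid-node crossing needs no interpolation", {
  crv <- psd_curve(c(10, 20, 40), c(0, 50, 100))
  expect_equal(psd_quantiles(crv, probs = 50)$D50, 20)
})
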