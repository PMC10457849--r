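# Radius conversions and the core parameter arithmetic.

test_that("densities follow mass over volume", {
  expect_equal(densities(100, poured_volume = 239.2, tapped_volume = 185.2),
               c(Da = 100 / 239.2, Dc = 100 / 185.2))
  expect_equal(unname(densities(50, poured_volume = 50, tapped_volume = 50)),
               c(1, 1))
  expect_equal(unname(densities(100, poured_volume = 400,
                                tapped_volume = 250)),
               c(0.25, 0.40))
  expect_error(densities(density_measurement(100, 100, 100 - 100)),
               "tapped_volume")
})

test_that("derived ratios are mutually consistent", {
  r <- derived_ratios(0.25, 0.40)
  expect_equal(unname(r), c(1.5, 37.5, 1.6))
  expect_equal(unname(derived_ratios(0.7, 0.7)), c(0, 0, 1))
  # back-converted batch means: Da 0.418, Dc 0.540
  r2 <- derived_ratios(0.418, 0.540)
  expect_equal(r2[["Ie"]], 0.5405, tolerance = 1e-3)
  expect_equal(r2[["IC"]], 22.59, tolerance = 1e-3)
  expect_equal(r2[["IH"]], 1.2919, tolerance = 1e-4)
  # IH = 1 / (1 - IC/100) for random density pairs
  set.seed(11)
  for (i in 1:50) {
    Da <- runif(1, 0.1, 0.9)
    Dc <- runif(1, Da, 1)
    rr <- derived_ratios(Da, Dc)
    expect_equal(rr[["IH"]], 1 / (1 - rr[["IC"]] / 100))
  }
})

test_that("angle of repose uses the mean of four base radii", {
  expect_equal(angle_of_repose(40, base_radii = rep(40, 4)), 45)
  expect_equal(angle_of_repose(0, base_radii = rep(40, 4)), 0)
  a <- angle_of_repose(35.4, base_radii = c(39, 41, 40, 40))
  expect_equal(a, atan(35.4 / 40) * 180 / pi)
  expect_equal(to_radius("alpha", a), 1.70, tolerance = 0.005)
})

test_that("cohesion index is the mean hardness, zero when incompressible", {
  expect_equal(cohesion_index(c(37.1)), 37.1)
  expect_equal(cohesion_index(c(30, 40, 41)), 37)
  inc <- cohesion_measurement(compressible = FALSE)
  expect_equal(cohesion_index(inc), 0)
  expect_equal(to_radius("Icd", cohesion_index(inc)), 0)
  expect_equal(to_radius("Icd", 37), 1.85)
})

test_that("to_radius reproduces the published conversion factors", {
  expect_equal(to_radius("Da", 0.418), 4.18)
  expect_equal(to_radius("IH", 3), 0)
  expect_equal(to_radius("IH", 1), 10)
  expect_equal(to_radius("Itheta", 0.019), 9.5)
  expect_equal(suppressWarnings(to_radius("Itheta", 0.05)), 10) # clamped
  expect_equal(to_radius("t", Inf), 0)   # non-flowing
  expect_equal(suppressWarnings(to_radius("t", 25)), 0)  # beyond 20 s
  expect_equal(to_radius("alpha", 50), 0)
  expect_equal(to_radius("HR", 0), 10)
  expect_equal(to_radius("Pf", 50), 0)
  expect_equal(to_radius("Pf", 0), 10)
  expect_error(to_radius("bogus", 1))
})

test_that("radii are clamped to [0, 10] for any finite input", {
  set.seed(21)
  for (p in sedem_parameters()) {
    v <- c(runif(40, -50, 400), 0, 1e6)
    r <- suppressWarnings(to_radius(p, v))
    expect_true(all(r >= 0 & r <= 10), info = p)
  }
})

test_that("to_radius is monotone in the parameter value", {
  increasing <- c("Da", "Dc", "Ie", "IC", "Icd", "Itheta")
  for (p in sedem_parameters()) {
    v <- seq(0.0001, ifelse(p == "Itheta", 0.019, 9), length.out = 25)
    r <- suppressWarnings(to_radius(p, v, warn = FALSE))
    d <- diff(r)
    if (p %in% increasing) expect_true(all(d >= 0), info = p)
    else expect_true(all(d <= 0), info = p)
  }
})

test_that("from_radius inverts to_radius on the working range", {
  cases <- list(Da = 0.42, Dc = 0.54, Ie = 0.55, IC = 22, Icd = 40,
                IH = 1.3, alpha = 42, t = 8, HR = 0.3, H = 0.1,
                Pf = 12, Itheta = 0.008)
  for (p in names(cases)) {
    expect_equal(from_radius(p, to_radius(p, cases[[p]])), cases[[p]],
                 info = p)
  }
})

test_that("a full parameter set produces the expected reference profile", {
  # back-converted from the GL-1 batch-mean radii
  params <- c(Da = 0.418, Dc = 0.540, Ie = 0.5405, IC = 22.59,
              Icd = 37.0, IH = 1.2919, alpha = 41.6, t = Inf,
              HR = 0.21, H = 0.02, Pf = 12.15, Itheta = 0.00836)
  prof <- radius_profile(params)
  expect_s3_class(prof, "sedem_profile")
  expect_equal(round(unclass(prof), 2),
               c(Da = 4.18, Dc = 5.40, Ie = 4.50, IC = 4.52, Icd = 1.85,
                 IH = 8.54, alpha = 1.68, t = 0.00, HR = 9.79, H = 9.99,
                 Pf = 7.57, Itheta = 4.18))
})

test_that("best-limit values give the all-10 profile", {
  best <- c(Da = 1, Dc = 1, Ie = 1.2, IC = 50, Icd = 200, IH = 1,
            alpha = 0, t = 0, HR = 0, H = 0, Pf = 0, Itheta = 0.02)
  expect_equal(unname(unclass(radius_profile(best))), rep(10, 12))
})

test_that("Da above Dc is flagged but still converts", {
  params <- c(Da = 0.5, Dc = 0.4, Ie = -0.5, IC = -25, Icd = 0, IH = 0.8,
              alpha = 30, t = Inf, HR = 1, H = 1, Pf = 10, Itheta = 0.01)
  expect_warning(radius_profile(params, warn = FALSE), "Da > Dc")
})
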