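# Compressibility indices, incidence factors, verdicts, reliability factor.

test_that("reliability factor conventions", {
  expect_equal(reliability_factor(12), 0.952)
  expect_equal(reliability_factor(12, "polygon"), 3 / pi)
  expect_equal(reliability_factor(1e7, "polygon"), 1, tolerance = 1e-9)
  expect_error(reliability_factor(2), "k >= 3")
})

test_that("indices reproduce the reference replicate columns", {
  # USV pilot: IP constant at 7/12
  usv <- reference_radii("USV", "pilot")
  for (j in seq_len(ncol(usv))) {
    expect_equal(sedem_indices(usv[, j])$IP, 7 / 12)
  }
  # GL-1 first replicate: PP 5.20, IGC 4.95
  gl <- reference_radii("Glenmarck", "pilot")
  ix <- sedem_indices(gl[, "GL-1.R1"])
  expect_equal(round(ix$IPP, 2), 5.20)
  expect_equal(round(ix$GCI, 2), 4.95)
  # maximal profile
  top <- sedem_indices(as_profile(rep(10, 12)))
  expect_equal(top$IP, 1)
  expect_equal(top$IPP, 10)
  expect_equal(top$GCI, 9.52)
})

test_that("GCI is exactly IPP times f and IP is permutation invariant", {
  set.seed(41)
  for (i in 1:25) {
    r <- runif(12, 0, 10)
    ix <- sedem_indices(as_profile(r))
    expect_identical(ix$GCI, ix$IPP * ix$f)
    expect_true(ix$IP %in% ((0:12) / 12))
    ix2 <- sedem_indices(as_profile(setNames(sample(r),
                                             sedem_parameters())))
    expect_equal(ix2$IP, ix$IP)
  }
})

test_that("incidence means recombine to the profile mean", {
  w <- c(2, 3, 3, 2, 2) / 12
  set.seed(42)
  for (i in 1:25) {
    r <- as_profile(runif(12, 0, 10))
    inc <- incidence_summary(r)
    expect_true(all(inc >= 0 & inc <= 10))
    expect_equal(sum(w * inc), mean(unclass(r)))
  }
  expect_equal(unname(incidence_summary(as_profile(rep(0, 12)))),
               rep(0, 5))
})

test_that("incidence means reproduce reference source summaries", {
  # pilot Glenmarck dimensions: (4.18 + 5.46)/2 = 4.82
  gl <- incidence_summary(as_profile(rowMeans(
    reference_radii("Glenmarck", "pilot"))))
  expect_equal(round(gl[["dimensions"]], 2), 4.82)
  us <- incidence_summary(as_profile(rowMeans(
    reference_radii("USV", "industrial"))))
  expect_equal(round(us[["compressibility"]], 2), 5.02)
})

test_that("direct-compression verdict gates on GCI > 5 strictly", {
  suitable <- dc_verdict(sedem_indices(as_profile(rep(5.6, 12))))
  expect_equal(suitable$verdict, "suitable")   # GCI = 5.33
  not <- dc_verdict(sedem_indices(as_profile(rep(3.91, 12))))
  expect_equal(not$verdict, "not_suitable")    # GCI = 3.72
  expect_true("GCI_above_5" %in% not$failing)
  # GCI exactly 5: IPP = 5/0.952
  border <- sedem_indices(as_profile(rep(5 / 0.952, 12)))
  expect_equal(border$GCI, 5)
  expect_equal(dc_verdict(border)$verdict, "not_suitable")
})
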