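# Measurement constructors enforce their physical invariants.

test_that("density measurement invariants", {
  expect_error(density_measurement(0, 100, 90), "sample_mass")
  expect_error(density_measurement(100, 100, 0), "tapped_volume")
  expect_error(density_measurement(100, 90, 100), "poured_volume")
  ok <- density_measurement(100, 240, 185)
  expect_s3_class(ok, "density_measurement")
})

test_that("cohesion measurement invariants", {
  expect_error(cohesion_measurement(c(30, -1)), ">= 0")
  expect_error(cohesion_measurement(c(30), compressible = FALSE),
               "incompressible")
  ok <- cohesion_measurement(compressible = FALSE)
  expect_length(ok$hardness_values, 0)
})

test_that("repose, flow and moisture invariants", {
  expect_error(repose_measurement(10, c(40, 40, 40)), "4 base radii")
  expect_error(repose_measurement(10, c(40, 40, 40, 0)), "> 0")
  expect_error(repose_measurement(-1, rep(40, 4)), ">= 0")
  expect_error(flow_measurement(-2), ">= 0")
  expect_true(flow_measurement(NULL)$non_flowing)
  expect_true(flow_measurement(Inf)$non_flowing)
  expect_error(moisture_measurement(-0.1, 0), ">= 0")
})

test_that("sieve analysis invariants", {
  expect_error(sieve_analysis(c(10, 10, 10), 5), "one entry per sieve")
  expect_error(sieve_analysis(c(10, 10, 10, 10), 5,
                              apertures = c(355, 212, 212, 50)),
               "strictly decreasing")
  expect_error(sieve_analysis(c(200, 0, 0, 0), 5), "\\[0, 100\\]")
  expect_error(sieve_analysis(c(40, 40, 30, 20), 5), "more than 100")
  # mass loss within tolerance is accepted
  ok <- sieve_analysis(c(1, 9, 40, 38), 11)
  expect_s3_class(ok, "sieve_analysis")
})

test_that("psd curve invariants", {
  expect_error(psd_curve(c(1, 2, 2), c(0, 50, 100)), "strictly increasing")
  expect_error(psd_curve(c(1, 2, 3), c(0, 60, 50)), "nondecreasing")
  expect_error(psd_curve(c(1, 2, 3), c(0, 40, 90)), "at least 99")
})

test_that("batch records validate scale and replicate count", {
  expect_error(batch_record("S", "B", "lab", list(make_replicate())))
  expect_error(batch_record("S", "B", "pilot", list()), "length")
  b <- batch_record("S", "B", "industrial", list(make_replicate()))
  expect_equal(b$scale, "industrial")
})
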