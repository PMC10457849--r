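# Synthetic supplier/batch generator.

test_that("same seed gives identical records, different seeds differ", {
  a <- builtin_archetypes()[["glenmarck-like"]]
  b1 <- simulate_batch(a, seed = 42)
  b2 <- simulate_batch(a, seed = 42)
  expect_identical(b1, b2)
  b3 <- simulate_batch(a, seed = 43)
  expect_false(isTRUE(all.equal(b1, b3)))
})

test_that("adding a batch does not perturb another batch's draws", {
  a <- builtin_archetypes()[["usv-like"]]
  alone <- simulate_batch(a, seed = 9, batch_index = 2, batch_id = "B2")
  with_sibling <- {
    simulate_batch(a, seed = 9, batch_index = 1, batch_id = "B1")
    simulate_batch(a, seed = 9, batch_index = 2, batch_id = "B2")
  }
  expect_identical(alone, with_sibling)
})

test_that("noise-free generation recovers the archetype radii exactly", {
  for (a in builtin_archetypes()) {
    a$replicate_cv_pct <- 0
    a$batch_cv_pct <- 0
    b <- simulate_batch(a, seed = 3)
    ch <- characterize_batch(b)
    expect_equal(as.numeric(ch$profile),
                 as.numeric(archetype_profile(a)),
                 tolerance = 1e-12, info = a$name)
    # every replicate identical in the noise-free limit
    expect_equal(ch$replicate_profiles[1, ], ch$replicate_profiles[3, ])
  }
})

test_that("archetype profiles land near the reference source means", {
  inc <- reference_incidence()
  param_rows <- sedem_parameters()
  ref_rows <- c("Da", "Dc", "Ie", "IC", "Icd", "IH", "alpha", "t",
                "HR", "H", "Pf", "Itheta")
  arch <- builtin_archetypes()
  cols <- c("glenmarck-like" = "Glenmarck.average",
            "usv-like" = "USV.average",
            "uquifa-like" = "UQUIFA.average")
  for (nm in names(arch)) {
    prof <- archetype_profile(arch[[nm]])
    ref <- inc[ref_rows, cols[[nm]]]
    expect_true(all(abs(as.numeric(prof) - ref) <= 0.5), info = nm)
  }
  # expected good-compression indices per source
  gci <- vapply(names(arch), function(nm) {
    sedem_indices(archetype_profile(arch[[nm]]))$GCI
  }, numeric(1))
  expect_equal(round(gci[["glenmarck-like"]], 2), 4.94, tolerance = 0.011)
  expect_equal(dc_verdict(sedem_indices(
    archetype_profile(arch[["usv-like"]])))$verdict, "suitable")
  expect_equal(dc_verdict(sedem_indices(
    archetype_profile(arch[["uquifa-like"]])))$verdict, "not_suitable")
  # incompressible sources have a zero cohesion radius
  expect_equal(archetype_profile(arch[["usv-like"]])[["Icd"]], 0)
  # the fine-particle source fails the fines acceptability radius
  expect_lt(archetype_profile(arch[["uquifa-like"]])[["Pf"]], 5)
})

test_that("a full study has the reference design cardinality", {
  st <- simulate_study(seed = 7)
  expect_length(st, 18)
  scales <- vapply(st, `[[`, "", "scale")
  expect_equal(sum(scales == "pilot"), 9)
  srcs <- vapply(st, `[[`, "", "source_id")
  expect_equal(length(unique(srcs)), 3)
  expect_true(all(vapply(st, function(b) length(b$replicates), 0L) == 3))
})

test_that("replicate noise has approximately the requested CV", {
  a <- builtin_archetypes()[["glenmarck-like"]]
  a$replicate_cv_pct <- 5
  b <- simulate_batch(a, n_replicates = 200, seed = 8)
  da <- vapply(b$replicates, function(r) {
    r$density$sample_mass / r$density$poured_volume
  }, numeric(1))
  expect_equal(100 * sd(da) / mean(da), 5, tolerance = 0.15 * 5)
  expect_equal(mean(da), a$bulk_density, tolerance = 0.01 * a$bulk_density)
})

test_that("a unit scale shift preserves the expected profile", {
  a <- builtin_archetypes()[["usv-like"]]
  a$scale_shift <- c(bulk_density = 1)
  expect_equal(as.numeric(archetype_profile(a, "industrial")),
               as.numeric(archetype_profile(a, "pilot")))
  # a real shift moves the density radii
  a$scale_shift <- c(bulk_density = 1.1, tapped_density = 1.1)
  ind <- archetype_profile(a, "industrial")
  expect_equal(ind[["Da"]], archetype_profile(a, "pilot")[["Da"]] * 1.1,
               tolerance = 1e-9)
})

test_that("simulated PSD curves yield the archetype's quantiles", {
  a <- builtin_archetypes()[["glenmarck-like"]]
  a$replicate_cv_pct <- 0
  b <- simulate_batch(a, seed = 12)
  q <- psd_quantiles(b$replicates[[1]]$psd)
  expect_equal(q$D50, a$psd_median, tolerance = 0.01)
  expect_equal(q$Fprime,
               qlnorm(0.9, log(a$psd_median), log(a$psd_gsd)) /
                 qlnorm(0.1, log(a$psd_median), log(a$psd_gsd)),
               tolerance = 0.01)
})
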