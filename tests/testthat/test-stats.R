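# Descriptive statistics, Levene check, one-way ANOVA, validation reports.

test_that("describe matches hand arithmetic and the reference row", {
  d <- describe(c(2, 4))
  expect_equal(d$mean, 3)
  expect_equal(d$variance, 2)
  expect_equal(d$sd, sqrt(2))
  expect_equal(d$cv_pct, 100 * sqrt(2) / 3)
  cst <- describe(c(1, 1, 1))
  expect_equal(c(cst$variance, cst$sd, cst$cv_pct), c(0, 0, 0))
  expect_true(is.na(describe(c(0, 0))$cv_pct))
  expect_error(describe(5), "at least 2")
  # the nine pilot bulk-density radii of the first reference source
  da <- reference_radii("Glenmarck", "pilot")["Da", ]
  d2 <- describe(da)
  expect_equal(round(c(d2$mean, d2$variance, d2$sd, d2$cv_pct), 4),
               c(4.1767, 0.0038, 0.0616, 1.4759))
})

test_that("describe agrees with a brute-force two-pass oracle", {
  two_pass <- function(x) {
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / (length(x) - 1)
    list(mean = m, variance = v, sd = sqrt(v),
         cv_pct = if (m == 0) NA_real_ else 100 * sqrt(v) / m)
  }
  set.seed(51)
  for (i in 1:30) {
    x <- rnorm(sample(2:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0, 3))
    a <- describe(x); b <- two_pass(x)
    for (f in c("mean", "variance", "sd")) {
      expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
    }
  }
})

test_that("Levene check reproduces the reference variance checks", {
  gl <- reference_radii("Glenmarck", "pilot")
  grp <- rep(c("GL-1", "GL-2", "GL-3"), each = 3)
  ic <- split(gl["IC", ], grp)
  expect_equal(levene_check(ic)$p_value, 0.6607, tolerance = 0.02)
  da <- split(gl["Da", ], grp)
  expect_equal(levene_check(da)$p_value, 0.5787, tolerance = 0.02)
  # mean centering is available and differs
  lm_ <- levene_check(ic, config = sedem_config(levene_center = "mean"))
  expect_equal(lm_$center, "mean")
  expect_false(isTRUE(all.equal(lm_$p_value, 0.6607, tolerance = 0.02)))
})

test_that("Levene check flags unequal spread and degenerate input", {
  set.seed(52)
  g1 <- rnorm(50, sd = 1); g2 <- rnorm(50, sd = 10)
  expect_lt(levene_check(list(g1, g2))$p_value, 0.01)
  same <- levene_check(list(c(1, 2, 3), c(2, 1, 3)))
  expect_gt(same$p_value, 0.5)  # identical spread
  flat <- levene_check(list(c(1, 1), c(1, 1)))
  expect_false(flat$testable)
})

test_that("one-way ANOVA reproduces the reference cells", {
  gl <- reference_radii("Glenmarck", "pilot")
  grp <- rep(c("GL-1", "GL-2", "GL-3"), each = 3)
  ic <- one_way_anova(split(gl["IC", ], grp))
  expect_equal(round(ic$F, 2), 3.02)
  expect_equal(round(ic$p_value, 4), 0.1236)
  da <- one_way_anova(split(gl["Da", ], grp))
  expect_equal(round(da$p_value, 4), 0.9934)
  # identical groups (with internal spread): F = 0, p = 1
  id <- one_way_anova(list(c(1, 2), c(1, 2)))
  expect_equal(id$F, 0)
  expect_equal(id$p_value, 1)
  # all values identical: not testable
  expect_false(one_way_anova(list(c(0, 0, 0), c(0, 0, 0)))$testable)
})

test_that("ANOVA F is invariant under affine transformation", {
  set.seed(53)
  groups <- lapply(1:3, function(i) rnorm(6, mean = i * 0.3))
  base <- one_way_anova(groups)
  for (ab in list(c(10, 0), c(-0.2, 5), c(500, -3))) {
    tr <- lapply(groups, function(g) ab[1] * g + ab[2])
    expect_equal(one_way_anova(tr)$F, base$F, tolerance = 1e-9)
  }
})

test_that("validation report groups correctly and self-compare passes", {
  a <- builtin_archetypes()[["glenmarck-like"]]
  b1 <- simulate_batch(a, batch_id = "X1", batch_index = 1, seed = 77)
  # two copies of the same batch (distinct ids): identical groups
  b2 <- b1; b2$batch_id <- "X2"
  v <- validation_report(list(b1, b2), "batches_within_source")
  testable <- v$rows$verdict != "not_testable"
  expect_true(all(v$rows$verdict[testable] == "no_difference"))
  expect_equal(v$overall, "no_difference")
  # t and Icd rows are reported, not dropped
  expect_true(all(c("t", "PP", "IGC") %in% v$rows$parameter))
  expect_equal(v$rows$verdict[v$rows$parameter == "t"], "not_testable")
  expect_error(validation_report(list(b1), "batches_within_source"),
               "at least 2 groups")
})

test_that("injected source differences are detected", {
  a <- builtin_archetypes()[["glenmarck-like"]]
  shifted <- a
  # shift both densities by ~5 replicate CVs
  shifted$bulk_density <- a$bulk_density * 1.10
  shifted$tapped_density <- a$tapped_density * 1.10
  shifted$name <- "shifted"
  b <- lapply(1:3, function(i) simulate_batch(a, batch_index = i,
                                              seed = 60))
  bs <- lapply(1:3, function(i) simulate_batch(shifted, batch_index = i,
                                               seed = 61))
  v <- validation_report(c(b, bs), "source_vs_source")
  expect_equal(v$rows$verdict[v$rows$parameter == "Da"], "difference")
  expect_equal(v$rows$verdict[v$rows$parameter == "Dc"], "difference")
  expect_equal(v$overall, "difference")
})
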