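#' Descriptive statistics with the n-1 divisor
#'
#' @param values Numeric vector of at least 2 values.
#' @return List with `n`, `mean`, `variance` (divisor n-1), `sd` and
#'   `cv_pct` (100 sd / mean; `NA` when the mean is 0).
#' @examples
#' describe(c(2, 4))  # mean 3, var 2, sd 1.414, cv 47.14
#' @export
describe <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("at least 2 values are required")
  m <- mean(values); v <- var(values)
  list(n = length(values), mean = m, variance = v, sd = sqrt(v),
       cv_pct = if (m == 0) NA_real_ else 100 * sqrt(v) / m)
}

all_identical <- function(groups) {
  vals <- unlist(groups)
  max(vals) - min(vals) == 0
}

check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("every group needs at least 2 values")
  }
}

groups_to_df <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(seq_along(groups),
                       vapply(groups, length, integer(1)))))
}

#' Levene variance check across groups
#'
#' Tests homogeneity of variances before the ANOVA.  Centering is
#' median-based (Brown--Forsythe) by default, which reproduces the variance
#' checks of common preformulation statistics software; mean-based
#' centering is available through the configuration.
#'
#' @param groups List of 2 or more numeric vectors, each with at least 2
#'   values.
#' @param config A [sedem_config()]; sets `levene_center`.
#' @return List with `statistic`, `p_value` and `center`; both statistics
#'   are `NA` with `testable = FALSE` when all values are identical.
#' @export
levene_check <- function(groups, config = NULL) {
  cfg <- as_sedem_config(config)
  check_groups(groups)
  if (all_identical(groups)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                center = cfg$levene_center, testable = FALSE))
  }
  df <- groups_to_df(groups)
  centerfun <- if (cfg$levene_center == "median") median else mean
  lt <- car::leveneTest(value ~ group, data = df, center = centerfun)
  list(statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"],
       center = cfg$levene_center, testable = TRUE)
}

#' Classical one-way analysis of variance
#'
#' F statistic on (k-1, N-k) degrees of freedom for equality of group
#' means.
#'
#' @inheritParams levene_check
#' @return List with `F`, `p_value`, `df`, and `testable` (`FALSE` when
#'   every value is identical, as for flow time of a uniformly non-flowing
#'   powder).
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  if (all_identical(groups)) {
    return(list(F = NA_real_, p_value = NA_real_, df = c(NA, NA),
                testable = FALSE))
  }
  df <- groups_to_df(groups)
  a <- anova(lm(value ~ group, data = df))
  if (a["Residuals", "Sum Sq"] == 0) {
    # identical within groups but different between: F degenerate
    return(list(F = Inf, p_value = 0, df = a$Df, testable = TRUE))
  }
  list(F = a["group", "F value"], p_value = a["group", "Pr(>F)"],
       df = a$Df, testable = TRUE)
}

# Collect per-replicate radius values grouped for a validation comparison.
# radii: matrix replicates x 14 (12 params + PP + IGC); group: factor.
radius_groups <- function(values, group) {
  split(values, group)
}

# Build a replicate-level radius table (rows = replicates across batches)
# from a list of characterizations, with PP and IGC appended.
replicate_radius_table <- function(characterizations, config = NULL) {
  cfg <- as_sedem_config(config)
  f <- resolve_f(cfg)
  rows <- do.call(rbind, lapply(characterizations, function(ch) {
    pp <- rowMeans(ch$replicate_profiles)
    cbind(ch$replicate_profiles, PP = pp, IGC = pp * f)
  }))
  meta <- do.call(rbind, lapply(characterizations, function(ch) {
    data.frame(source_id = ch$source_id, batch_id = ch$batch_id,
               scale = ch$scale,
               replicate = seq_len(nrow(ch$replicate_profiles)))
  }))
  list(values = rows, meta = meta)
}

#' Batch-validation report: descriptives, Levene and ANOVA per parameter
#'
#' Implements the statistical layer of the method: per-replicate radius
#' values are grouped according to the chosen comparison and each of the 12
#' parameters, plus the profile indices PP (mean radius) and IGC, is tested
#' with a Levene variance check and a one-way ANOVA.  Groupings:
#'
#' * `"batches_within_source"` -- replicates grouped by batch; verifies
#'   manufacturing reproducibility within one source.
#' * `"pilot_vs_industrial"` -- replicates grouped by production scale;
#'   verifies scale transposition.
#' * `"source_vs_source"` -- replicates grouped by source; detects supplier
#'   differences.
#'
#' Parameters whose values are all identical (flow time of a non-flowing
#' powder; cohesion of uniformly incompressible material) are reported as
#' not testable rather than dropped.  No multiple-testing correction is
#' applied; the report records the number of tests performed.
#'
#' @param batches List of `sedem_batch` records (or of
#'   `sedem_characterization` objects).
#' @param grouping One of the three comparisons above.
#' @param config A [sedem_config()]; `alpha` sets the significance level.
#' @return Object of class `sedem_validation`: `grouping`, `alpha`,
#'   `groups` (group labels), `rows` (data frame with parameter,
#'   per-group means, Levene and ANOVA results, verdict), `n_tests`,
#'   and `overall` (`"no_difference"` if every testable row has
#'   `p > alpha`, else `"difference"`).
#' @examples
#' a <- builtin_archetypes()[["usv-like"]]
#' bs <- lapply(1:3, function(i)
#'   simulate_batch(a, batch_id = paste0("B", i), seed = 100 + i))
#' validation_report(bs, "batches_within_source")$overall
#' @export
validation_report <- function(batches,
                              grouping = c("batches_within_source",
                                           "pilot_vs_industrial",
                                           "source_vs_source"),
                              config = NULL) {
  grouping <- match.arg(grouping)
  cfg <- as_sedem_config(config)
  chars <- lapply(batches, function(b) {
    if (inherits(b, "sedem_characterization")) b else
      characterize_batch(b, config = cfg)
  })
  tab <- replicate_radius_table(chars, config = cfg)
  group <- switch(grouping,
    batches_within_source = tab$meta$batch_id,
    pilot_vs_industrial   = tab$meta$scale,
    source_vs_source      = tab$meta$source_id)
  group <- factor(group)
  if (nlevels(group) < 2) {
    stop("grouping '", grouping, "' needs at least 2 groups, got ",
         nlevels(group))
  }
  params <- colnames(tab$values)
  rows <- lapply(params, function(p) {
    groups <- split(tab$values[, p], group)
    lev <- levene_check(groups, config = cfg)
    av <- one_way_anova(groups)
    verdict <- if (!av$testable) "not_testable" else
      if (av$p_value > cfg$alpha) "no_difference" else "difference"
    means <- vapply(groups, mean, numeric(1))
    data.frame(parameter = p,
               t(setNames(means, paste0("mean.", names(means)))),
               levene_p = lev$p_value, anova_F = av$F,
               anova_p = av$p_value, verdict = verdict,
               check.names = FALSE)
  })
  rows <- do.call(rbind, rows)
  testable <- rows$verdict != "not_testable"
  overall <- if (all(rows$verdict[testable] == "no_difference"))
    "no_difference" else "difference"
  structure(list(grouping = grouping, alpha = cfg$alpha,
                 groups = levels(group), rows = rows,
                 n_tests = sum(testable), overall = overall),
            class = "sedem_validation")
}

#' @export
print.sedem_validation <- function(x, digits = 4, ...) {
  cat(sprintf("SeDeM validation report (%s; alpha = %g)\n",
              x$grouping, x$alpha))
  cat("Groups:", paste(x$groups, collapse = ", "), "\n")
  df <- x$rows
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  cat(sprintf("Overall: %s (%d tests, no correction applied)\n",
              x$overall, x$n_tests))
  invisible(x)
}
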