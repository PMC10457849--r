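#' Run configuration for SeDeM computations
#'
#' Collects the tunable conventions of the method in one object so that every
#' downstream function (radius conversion, indices, statistics, quantiles)
#' resolves them consistently.
#'
#' @param icd_divisor Divisor applied to mean tablet hardness (N) to obtain
#'   the cohesion-index radius.  The default 20 maps the working limit of
#'   0--200 N onto the 0--10 radius scale.
#' @param reliability_f Reliability factor multiplying the mean radius to
#'   give the good-compression index.  The default 0.952 is the constant in
#'   universal use for the 12-parameter diagram; `"polygon"` selects the
#'   geometric ratio of a regular k-gon to its circumscribed circle instead
#'   (see [reliability_factor()]).
#' @param alpha Significance level for the validation verdicts.
#' @param levene_center Centering for the Levene variance check:
#'   `"median"` (Brown--Forsythe, the default) or `"mean"` (classical).
#' @param quantile_interpolation Interpolation for particle-size quantiles:
#'   `"loglinear"` (linear in log10 size, the default for log-spaced
#'   laser-diffraction grids) or `"linear"`.
#' @param sieve_renormalize Whether sieve fractions are renormalized to the
#'   recovered mass before computing the homogeneity index.
#' @param sieve_loss_tol Tolerated mass loss (percentage points) before a
#'   sieve analysis is rejected.
#' @param top_fraction_diameter Mean diameter assigned to the oversize
#'   fraction retained on the coarsest sieve; `NULL` uses that sieve's
#'   aperture itself, a number sets a nominal upper bound whose midpoint
#'   with the aperture is used.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return An object of class `sedem_config` (a named list).
#' @examples
#' cfg <- sedem_config()
#' cfg$icd_divisor
#' @export
sedem_config <- function(icd_divisor = 20,
                         reliability_f = 0.952,
                         alpha = 0.05,
                         levene_center = c("median", "mean"),
                         quantile_interpolation = c("loglinear", "linear"),
                         sieve_renormalize = TRUE,
                         sieve_loss_tol = 2,
                         top_fraction_diameter = NULL,
                         seed = NULL) {
  stopifnot(is.numeric(icd_divisor), icd_divisor > 0)
  if (!identical(reliability_f, "polygon")) {
    stopifnot(is.numeric(reliability_f), reliability_f > 0, reliability_f <= 1)
  }
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  cfg <- list(
    icd_divisor = icd_divisor,
    reliability_f = reliability_f,
    alpha = alpha,
    levene_center = match.arg(levene_center),
    quantile_interpolation = match.arg(quantile_interpolation),
    sieve_renormalize = isTRUE(sieve_renormalize),
    sieve_loss_tol = sieve_loss_tol,
    top_fraction_diameter = top_fraction_diameter,
    seed = seed
  )
  structure(cfg, class = "sedem_config")
}

#' @export
print.sedem_config <- function(x, ...) {
  cat("SeDeM run configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

as_sedem_config <- function(config) {
  if (is.null(config)) return(sedem_config())
  if (inherits(config, "sedem_config")) return(config)
  if (is.list(config)) return(do.call(sedem_config, config))
  stop("`config` must be NULL, a sedem_config, or a list of its arguments")
}
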