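#' Particle-size fraction table from a sieve analysis
#'
#' Turns the retained percentages of a sieve stack into size fractions with
#' mean diameters: one fraction per inter-sieve interval, the pan fraction
#' below the finest sieve, and (when any mass is retained there) the
#' oversize fraction on the coarsest sieve.  Mean diameters are the
#' arithmetic midpoints of the bounding apertures; the pan uses the
#' midpoint of (0, finest aperture); the oversize fraction uses the
#' coarsest aperture itself unless `config$top_fraction_diameter` sets a
#' nominal upper bound.  Fractions with zero mass are dropped; percentages
#' are renormalized to the recovered mass (configurable).
#'
#' @param s A [sieve_analysis()].
#' @param config A [sedem_config()].
#' @return A `fraction_table`: data frame with columns `lower`, `upper`,
#'   `diameter` (um) and `percent`, ordered by ascending diameter, with
#'   attribute `majority` giving the row index of the majority fraction
#'   (ties broken toward the smallest diameter).
#' @examples
#' s <- sieve_analysis(retained_pct = c(0, 5, 25, 60), pan_pct = 10)
#' fraction_table(s)
#' @export
fraction_table <- function(s, config = NULL) {
  cfg <- as_sedem_config(config)
  stopifnot(inherits(s, "sieve_analysis"))
  ap <- s$apertures                      # decreasing
  k <- length(ap)
  lower <- c(ap, 0)                      # oversize, inter-sieve..., pan
  upper <- c(if (is.null(cfg$top_fraction_diameter)) ap[1] else
               cfg$top_fraction_diameter,
             ap[-k], ap[k])
  d <- (lower + upper) / 2
  pct <- c(s$retained_pct, s$pan_pct)
  tot <- sum(pct)
  if (tot <= 0) stop("zero recovered mass in sieve analysis")
  if (cfg$sieve_renormalize) pct <- pct / tot * 100
  tab <- data.frame(lower = lower, upper = upper, diameter = d,
                    percent = pct)
  tab <- tab[tab$percent > 0, , drop = FALSE]
  tab <- tab[order(tab$diameter), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "majority") <- which(tab$percent == max(tab$percent))[1]
  class(tab) <- c("fraction_table", "data.frame")
  tab
}

#' Percentage of fine particles (< 50 um)
#'
#' Returns the dedicated fines-test value when it was measured, otherwise
#' the pan percentage of the full stack test.  The dedicated test takes
#' precedence because fines adhering to coarser particles during the stack
#' test bias the pan fraction low.
#'
#' @param s A [sieve_analysis()].
#' @return Fines percentage in `[0, 100]`.
#' @export
percent_fines <- function(s) {
  stopifnot(inherits(s, "sieve_analysis"))
  if (!is.null(s$fines_direct_pct)) s$fines_direct_pct else s$pan_pct
}

#' Relative homogeneity index of a particle-size distribution
#'
#' The ratio of the majority fraction's percentage to 100 plus the
#' diameter-distance-weighted sum of all other fractions:
#' \deqn{I_\theta = \frac{F_m}{100 + \sum_{n \ge 1} (d_m - d_{m-n}) F_{m-n}
#'   + (d_{m+n} - d_m) F_{m+n}}}
#' with diameters in micrometres and percentages in percent.  A powder
#' concentrated in a single fraction approaches \eqn{F_m / 100}; spreading
#' mass into distant fractions drives the index down.
#'
#' @param t A [fraction_table()] (or a [sieve_analysis()], converted
#'   internally).
#' @param config A [sedem_config()] (used only when converting a sieve
#'   analysis).
#' @return The homogeneity index, in `(0, Fm/100]`.
#' @examples
#' s <- sieve_analysis(retained_pct = c(0, 5, 25, 60), pan_pct = 10)
#' homogeneity_index(s)  # 0.016361
#' @export
homogeneity_index <- function(t, config = NULL) {
  if (inherits(t, "sieve_analysis")) t <- fraction_table(t, config = config)
  stopifnot(inherits(t, "fraction_table"), nrow(t) >= 1)
  m <- attr(t, "majority")
  w <- abs(t$diameter - t$diameter[m])
  t$percent[m] / (100 + sum(w * t$percent))
}

#' Particle-size quantiles and distribution breadth from a PSD curve
#'
#' Interpolates the cumulative undersize curve at 10%, 50% and 90% to give
#' D10, D50 and D90, and reports the breadth ratio `F' = D90 / D10`.
#' Interpolation is linear in log10(size) by default, matching the
#' log-spaced grids of laser-diffraction instruments; set
#' `quantile_interpolation = "linear"` in the configuration for linear
#' interpolation in size.  Note the breadth ratio is computed as D90/D10;
#' this is the definition inferred from published usage.
#'
#' @param c A [psd_curve()].
#' @param probs Quantile levels, percent.
#' @param config A [sedem_config()].
#' @return List with `D10`, `D50`, `D90` (um) and `Fprime`.
#' @examples
#' sz <- exp(seq(log(0.5), log(1000), length.out = 200))
#' cv <- plnorm(sz, log(60), 1) * 100
#' psd_quantiles(psd_curve(sz, cv))
#' @export
psd_quantiles <- function(c, probs = c(10, 50, 90), config = NULL) {
  cfg <- as_sedem_config(config)
  stopifnot(inherits(c, "psd_curve"))
  x <- if (cfg$quantile_interpolation == "loglinear") log10(c$sizes) else
       c$sizes
  q <- vapply(probs, function(p) {
    if (p < min(c$cumulative_pct) || p > max(c$cumulative_pct)) {
      stop(sprintf("quantile %g%% outside curve support", p))
    }
    v <- approx(c$cumulative_pct, x, xout = p, ties = "ordered")$y
    if (cfg$quantile_interpolation == "loglinear") 10^v else v
  }, numeric(1))
  names(q) <- paste0("D", probs)
  out <- as.list(q)
  if (all(c("D10", "D90") %in% names(out))) {
    out$Fprime <- out$D90 / out$D10
  }
  out
}
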