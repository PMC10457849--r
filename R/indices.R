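#' Reliability factor for a k-parameter SeDeM diagram
#'
#' The reliability factor is the area of the diagram's polygon relative to
#' the circumscribed circle.  For the standard 12-parameter diagram the
#' constant 0.952 is in universal use and is the default; the
#' `"polygon"` convention instead returns the exact regular-k-gon ratio
#' \eqn{\frac{k}{2\pi}\sin(2\pi/k)} (0.95493 for k = 12), which tends to 1
#' as k grows.
#'
#' @param k Number of parameters (`>= 3`).
#' @param convention `"constant"` (0.952 when `k = 12`) or `"polygon"`.
#' @return The reliability factor in `(0, 1]`.
#' @examples
#' reliability_factor(12)                          # 0.952
#' reliability_factor(12, "polygon")               # 3/pi
#' @export
reliability_factor <- function(k = 12, convention = c("constant", "polygon")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(k), k >= 3)
  if (convention == "constant" && k == 12) return(0.952)
  k / (2 * pi) * sin(2 * pi / k)
}

resolve_f <- function(cfg, k = 12) {
  if (identical(cfg$reliability_f, "polygon")) {
    reliability_factor(k, "polygon")
  } else {
    cfg$reliability_f
  }
}

#' SeDeM compressibility indices of a radius profile
#'
#' * `IP`, the parametric index: fraction of the 12 radii at or above the
#'   acceptability value 5.
#' * `IPP`, the parametric profile index: arithmetic mean of the 12 radii.
#' * `GCI`, the good-compression index: `IPP` times the reliability factor
#'   `f`.
#'
#' @param profile A 12-radius profile ([radius_profile()] or a named
#'   numeric vector in canonical order).
#' @param config A [sedem_config()]; sets `f`.
#' @return List of class `sedem_indices` with `IP`, `IPP`, `f`, `GCI`.
#' @examples
#' sedem_indices(as_profile(rep(10, 12)))  # IP 1, IPP 10, GCI 9.52
#' @export
sedem_indices <- function(profile, config = NULL) {
  cfg <- as_sedem_config(config)
  r <- as_sedem_profile(profile)
  f <- resolve_f(cfg, length(r))
  ipp <- mean(r)
  structure(list(IP = sum(r >= 5) / length(r), IPP = ipp, f = f,
                 GCI = ipp * f),
            class = "sedem_indices")
}

#' @export
print.sedem_indices <- function(x, ...) {
  cat(sprintf("IP = %.2f  IPP = %.4f  f = %.3f  GCI = %.4f\n",
              x$IP, x$IPP, x$f, x$GCI))
  invisible(x)
}

#' Coerce a bare numeric vector to a radius profile
#'
#' @param r 12 radii in canonical order (named or unnamed).
#' @return A `sedem_profile`.
#' @export
as_profile <- function(r) as_sedem_profile(r)

#' Incidence-factor summary of a radius profile
#'
#' Means of the member radii for the five incidence factors: dimensions
#' (Da, Dc), compressibility (Ie, IC, Icd), flowability (IH, alpha, t),
#' lubricity/stability (HR, H) and lubricity/dosage (Pf, Itheta).
#'
#' @param profile A 12-radius profile.
#' @return Named numeric vector of the five incidence means, each in
#'   `[0, 10]`.
#' @export
incidence_summary <- function(profile) {
  r <- as_sedem_profile(profile)
  vapply(SEDEM_INCIDENCE, function(members) mean(r[members]), numeric(1))
}

#' Direct-compression suitability verdict
#'
#' The decisive criterion is `GCI > 5` (strict); `IPP >= 5` and `IP >= 0.5`
#' are reported as supporting flags but do not gate the verdict.
#'
#' @param ix A [sedem_indices()] result.
#' @return List with `verdict` (`"suitable"` or `"not_suitable"`),
#'   `criteria` (named logical vector) and `failing` (names of unmet
#'   criteria).
#' @export
dc_verdict <- function(ix) {
  stopifnot(inherits(ix, "sedem_indices"))
  crit <- c(GCI_above_5 = ix$GCI > 5,
            IPP_at_least_5 = ix$IPP >= 5,
            IP_at_least_half = ix$IP >= 0.5)
  list(verdict = if (crit[["GCI_above_5"]]) "suitable" else "not_suitable",
       criteria = crit,
       failing = names(crit)[!crit])
}
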