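# The 12 SeDeM parameters in canonical order.  Every radius profile, table
# and diagram in the package uses this order.
SEDEM_PARAMS <- c("Da", "Dc", "Ie", "IC", "Icd", "IH",
                  "alpha", "t", "HR", "H", "Pf", "Itheta")

SEDEM_PARAM_LABELS <- c(
  Da = "Bulk density", Dc = "Tapped density", Ie = "Interparticle porosity",
  IC = "Carr index", Icd = "Cohesion index", IH = "Hausner ratio",
  alpha = "Angle of repose", t = "Flowability", HR = "Loss on drying",
  H = "Hygroscopicity", Pf = "Particles < 50 um", Itheta = "Homogeneity index")

# Incidence-factor grouping: five property groups over the 12 parameters.
SEDEM_INCIDENCE <- list(
  dimensions          = c("Da", "Dc"),
  compressibility     = c("Ie", "IC", "Icd"),
  flowability         = c("IH", "alpha", "t"),
  lubricity_stability = c("HR", "H"),
  lubricity_dosage    = c("Pf", "Itheta"))

#' Canonical SeDeM parameter order
#'
#' @return Character vector of the 12 parameter identifiers in the canonical
#'   order used by every radius profile, table and diagram: bulk density
#'   `Da`, tapped density `Dc`, interparticle porosity `Ie`, Carr index
#'   `IC`, cohesion index `Icd`, Hausner ratio `IH`, angle of repose
#'   `alpha`, flow time `t`, loss on drying `HR`, hygroscopicity `H`,
#'   fines percentage `Pf`, and homogeneity index `Itheta`.
#' @export
sedem_parameters <- function() SEDEM_PARAMS

#' Incidence-factor grouping of the SeDeM parameters
#'
#' @return Named list mapping the five incidence factors (dimensions,
#'   compressibility, flowability, lubricity/stability, lubricity/dosage)
#'   to their member parameters.
#' @export
sedem_incidence_groups <- function() SEDEM_INCIDENCE

clamp01 <- function(r) pmin(10, pmax(0, r))

#' Convert a parameter value to its 0--10 radius
#'
#' Applies the standard SeDeM conversion factor for the given parameter and
#' clamps the result to the 0--10 radius scale.  Increasing-is-better
#' parameters (densities, porosity, Carr index, cohesion, homogeneity) map
#' upward; reversed-scale parameters (Hausner ratio, angle of repose, flow
#' time, loss on drying, hygroscopicity, fines) map downward.  A value of 5
#' is the minimum acceptable radius.
#'
#' @param parameter One of [sedem_parameters()].
#' @param v Numeric value(s) in the parameter's physical units (g/mL,
#'   percent, degrees, seconds, newtons, or dimensionless).  For flow time
#'   `t`, `Inf` (or `NA`) encodes a non-flowing powder and maps to radius 0.
#' @param config A [sedem_config()]; controls the cohesion-index divisor.
#' @param warn Warn when an input lies outside the parameter's working
#'   limits and is clamped.
#'
#' @return Radius value(s) in `[0, 10]`.
#' @examples
#' to_radius("Da", 0.418)   # 4.18
#' to_radius("IH", c(1, 3)) # 10, 0
#' to_radius("t", Inf)      # non-flowing -> 0
#' @export
to_radius <- function(parameter, v, config = NULL, warn = TRUE) {
  cfg <- as_sedem_config(config)
  parameter <- match.arg(parameter, SEDEM_PARAMS)
  v <- as.numeric(v)
  if (parameter == "t") {
    v[is.na(v)] <- Inf  # non-flowing sentinel
  } else if (anyNA(v)) {
    stop("non-finite value for parameter ", parameter)
  }
  r <- switch(parameter,
    Da     = 10 * v,
    Dc     = 10 * v,
    Ie     = 10 * v / 1.2,
    IC     = v / 5,
    Icd    = v / cfg$icd_divisor,
    IH     = 5 * (3 - v),
    alpha  = 10 - v / 5,
    t      = ifelse(is.infinite(v), 0, 10 - v / 2),
    HR     = 10 - v,
    H      = 10 - v / 2,
    Pf     = 10 - v / 5,
    Itheta = 500 * v)
  out <- clamp01(r)
  if (warn && any(r != out & is.finite(r))) {
    warning(sprintf("%s: %d value(s) outside working limits clamped to [0, 10]",
                    parameter, sum(r != out & is.finite(r))))
  }
  out
}

#' Invert a radius back to the parameter's physical value
#'
#' Exact inverse of [to_radius()] on the unclamped range; used to recover
#' physical values from published radius tables.
#'
#' @inheritParams to_radius
#' @param r Radius value(s) in `[0, 10]`.
#' @return Parameter value(s) in physical units.
#' @examples
#' from_radius("Da", 4.18)  # 0.418 g/mL
#' @export
from_radius <- function(parameter, r, config = NULL) {
  cfg <- as_sedem_config(config)
  parameter <- match.arg(parameter, SEDEM_PARAMS)
  r <- as.numeric(r)
  switch(parameter,
    Da     = r / 10,
    Dc     = r / 10,
    Ie     = r * 1.2 / 10,
    IC     = r * 5,
    Icd    = r * cfg$icd_divisor,
    IH     = 3 - r / 5,
    alpha  = (10 - r) * 5,
    t      = (10 - r) * 2,
    HR     = 10 - r,
    H      = (10 - r) * 2,
    Pf     = (10 - r) * 5,
    Itheta = r / 500)
}

#' Build a 12-radius profile from a parameter set
#'
#' @param params Named numeric vector or list holding all 12 parameter
#'   values in physical units (names from [sedem_parameters()]); flow time
#'   `t` may be `Inf` for a non-flowing powder.
#' @param config A [sedem_config()].
#' @param warn Passed to [to_radius()].
#' @return A `sedem_profile`: named numeric vector of 12 radii in canonical
#'   order, each in `[0, 10]`.
#' @examples
#' p <- c(Da = 0.418, Dc = 0.54, Ie = 0.5405, IC = 22.59, Icd = 37,
#'        IH = 1.2919, alpha = 41.6, t = Inf, HR = 0.21, H = 0.02,
#'        Pf = 12.15, Itheta = 0.00836)
#' radius_profile(p)
#' @export
radius_profile <- function(params, config = NULL, warn = TRUE) {
  params <- unlist(params)
  missing <- setdiff(SEDEM_PARAMS, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  if (is.finite(params["Da"]) && is.finite(params["Dc"]) &&
      params["Da"] > params["Dc"]) {
    warning("bulk density exceeds tapped density (Da > Dc)")
  }
  r <- vapply(SEDEM_PARAMS, function(p) {
    to_radius(p, params[[p]], config = config, warn = warn)
  }, numeric(1))
  as_sedem_profile(r)
}

as_sedem_profile <- function(r) {
  r <- unlist(r)
  if (is.null(names(r))) names(r) <- SEDEM_PARAMS
  stopifnot(length(r) == 12, all(SEDEM_PARAMS %in% names(r)))
  r <- r[SEDEM_PARAMS]
  if (any(r < -1e-9 | r > 10 + 1e-9)) stop("radii must lie in [0, 10]")
  structure(clamp01(as.numeric(r)), names = SEDEM_PARAMS,
            class = "sedem_profile")
}

#' @export
print.sedem_profile <- function(x, digits = 2, ...) {
  cat("SeDeM radius profile\n")
  print(round(unclass(x), digits))
  invisible(x)
}
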