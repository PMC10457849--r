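#' Bulk and tapped density from a settling-cylinder measurement
#'
#' Bulk density is the sample mass over the poured volume; tapped density is
#' the mass over the volume after 2500 strokes.
#'
#' @param m A [density_measurement()], or the sample mass in grams if
#'   `poured_volume`/`tapped_volume` are given directly.
#' @param poured_volume,tapped_volume Volumes in mL (used when `m` is a
#'   bare mass).
#' @return Named numeric vector `c(Da =, Dc =)` in g/mL.
#' @examples
#' densities(100, poured_volume = 239.2, tapped_volume = 185.2)
#' @export
densities <- function(m, poured_volume = NULL, tapped_volume = NULL) {
  if (is.numeric(m) && !is.null(poured_volume)) {
    m <- density_measurement(m, poured_volume, tapped_volume)
  }
  stopifnot(inherits(m, "density_measurement"))
  if (m$poured_volume <= 0 || m$tapped_volume <= 0) stop("zero volume")
  c(Da = m$sample_mass / m$poured_volume,
    Dc = m$sample_mass / m$tapped_volume)
}

#' Porosity, Carr index and Hausner ratio from the two densities
#'
#' Interparticle porosity `Ie = (Dc - Da) / (Dc * Da)`, Carr
#' (compressibility) index `IC = 100 (Dc - Da) / Dc`, Hausner ratio
#' `IH = Dc / Da`.  The three are mutually consistent:
#' `IH = 1 / (1 - IC/100)`.
#'
#' @param Da,Dc Bulk and tapped density in g/mL (both `> 0`), or `Da` may be
#'   the named vector returned by [densities()].
#' @return Named numeric vector `c(Ie =, IC =, IH =)`.
#' @examples
#' derived_ratios(0.25, 0.40)  # Ie 1.5, IC 37.5, IH 1.6
#' @export
derived_ratios <- function(Da, Dc = NULL) {
  if (is.null(Dc) && length(Da) == 2) { Dc <- Da[["Dc"]]; Da <- Da[["Da"]] }
  stopifnot(is.numeric(Da), is.numeric(Dc), Da > 0, Dc > 0)
  c(Ie = (Dc - Da) / (Dc * Da),
    IC = 100 * (Dc - Da) / Dc,
    IH = Dc / Da)
}

#' Angle of repose from cone height and base radii
#'
#' The powder cone's angle follows from `tan(alpha) = h / r` with `r` the
#' mean of the four measured base radii.
#'
#' @param m A [repose_measurement()], or the cone height in mm if
#'   `base_radii` is given directly.
#' @param base_radii Four base radii in mm (used when `m` is a bare height).
#' @return Angle in degrees, in `[0, 90)`.
#' @examples
#' angle_of_repose(35.4, base_radii = c(40, 40, 40, 40))
#' @export
angle_of_repose <- function(m, base_radii = NULL) {
  if (is.numeric(m) && !is.null(base_radii)) {
    m <- repose_measurement(m, base_radii)
  }
  stopifnot(inherits(m, "repose_measurement"))
  r <- mean(m$base_radii)
  if (r <= 0) stop("mean base radius must be positive")
  atan(m$cone_height / r) * 180 / pi
}

#' Cohesion index (mean tablet hardness)
#'
#' Mean crushing hardness, in newtons, of tablets compressed directly from
#' the powder (with 3.5% standard lubricant when the powder alone is too
#' abrasive).  A powder that cannot be compressed at all has cohesion index
#' 0, and a cohesion radius of 0.
#'
#' @param m A [cohesion_measurement()], or a numeric vector of hardness
#'   values in newtons.
#' @return Mean hardness in N (0 for an incompressible powder).
#' @examples
#' cohesion_index(c(30, 40, 41))  # 37
#' cohesion_index(cohesion_measurement(compressible = FALSE))
#' @export
cohesion_index <- function(m) {
  if (is.numeric(m)) m <- cohesion_measurement(hardness_values = m)
  stopifnot(inherits(m, "cohesion_measurement"))
  if (!m$compressible || length(m$hardness_values) == 0) return(0)
  mean(m$hardness_values)
}

#' Flow time per 100 g
#'
#' @param m A [flow_measurement()].
#' @return Seconds per 100 g, or `Inf` for a non-flowing powder.
#' @export
flow_time <- function(m) {
  stopifnot(inherits(m, "flow_measurement"))
  if (m$non_flowing) Inf else m$seconds_per_100g
}

#' Compute the full 12-parameter set for one replicate
#'
#' Takes one replicate's raw measurements and derives all 12 SeDeM
#' parameter values in physical units.
#'
#' @param rep A replicate: list with components `density`
#'   ([density_measurement()]), `cohesion` ([cohesion_measurement()]),
#'   `repose` ([repose_measurement()]), `flow` ([flow_measurement()]),
#'   `moisture` ([moisture_measurement()]), and `sieve` ([sieve_analysis()]).
#' @param config A [sedem_config()].
#' @return Named numeric vector of the 12 parameter values (flow time `Inf`
#'   when non-flowing).
#' @export
replicate_parameters <- function(rep, config = NULL) {
  cfg <- as_sedem_config(config)
  d <- densities(rep$density)
  ratios <- derived_ratios(d)
  ft <- fraction_table(rep$sieve, config = cfg)
  c(d,
    ratios,
    Icd = cohesion_index(rep$cohesion),
    alpha = angle_of_repose(rep$repose),
    t = flow_time(rep$flow),
    HR = rep$moisture$loss_on_drying_pct,
    H = rep$moisture$hygroscopicity_pct,
    Pf = percent_fines(rep$sieve),
    Itheta = homogeneity_index(ft))[SEDEM_PARAMS]
}

#' Characterize a batch: per-replicate profiles and batch summary
#'
#' Runs the full SeDeM pipeline on one batch record: each replicate's raw
#' measurements become a 12-parameter set and a radius profile; the batch
#' profile is the per-parameter mean of the replicate radii, from which the
#' indices and the direct-compression verdict follow.
#'
#' @param batch A batch record from [batch_record()] or [read_batches()].
#' @param config A [sedem_config()].
#' @return A list of class `sedem_characterization`: `source_id`,
#'   `batch_id`, `scale`, `parameters` (replicates x 12 matrix),
#'   `replicate_profiles` (replicates x 12 radius matrix), `profile` (mean
#'   radius profile), `incidence`, `indices`, `verdict`.
#' @examples
#' b <- simulate_batch(builtin_archetypes()[["usv-like"]], seed = 1)
#' ch <- characterize_batch(b)
#' round(ch$indices$GCI, 2)
#' @export
characterize_batch <- function(batch, config = NULL) {
  cfg <- as_sedem_config(config)
  stopifnot(inherits(batch, "sedem_batch"))
  pars <- t(vapply(batch$replicates, replicate_parameters,
                   numeric(12), config = cfg))
  colnames(pars) <- SEDEM_PARAMS
  profs <- t(apply(pars, 1, function(p) {
    radius_profile(p, config = cfg, warn = FALSE)
  }))
  colnames(profs) <- SEDEM_PARAMS
  mean_prof <- as_sedem_profile(colMeans(profs))
  ix <- sedem_indices(mean_prof, config = cfg)
  structure(list(
    source_id = batch$source_id,
    batch_id = batch$batch_id,
    scale = batch$scale,
    parameters = pars,
    replicate_profiles = profs,
    profile = mean_prof,
    incidence = incidence_summary(mean_prof),
    indices = ix,
    verdict = dc_verdict(ix)
  ), class = "sedem_characterization")
}

#' @export
print.sedem_characterization <- function(x, ...) {
  cat(sprintf("SeDeM characterization: %s / %s (%s scale, %d replicates)\n",
              x$source_id, x$batch_id, x$scale, nrow(x$parameters)))
  print(x$profile)
  cat(sprintf("IP = %.2f  IPP = %.2f  GCI = %.2f  -> %s\n",
              x$indices$IP, x$indices$IPP, x$indices$GCI, x$verdict$verdict))
  invisible(x)
}
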