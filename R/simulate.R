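# Seeded generator of synthetic supplier/batch datasets.  An archetype
# fixes the "true" powder properties; batches and replicates add
# multiplicative lognormal noise at the stated coefficients of variation.
# Random streams are derived hierarchically (study -> batch -> replicate ->
# quantity) so adding a batch never perturbs the draws of another.

#' Define a supplier archetype for the synthetic generator
#'
#' An archetype is the "true" powder of a supplier: the generator draws
#' batches and replicates around it.  Two size distributions are carried:
#' the laser-diffraction PSD (volume-weighted primary particles; drives
#' the simulated PSD curves and quantiles) and a sieve-effective lognormal
#' (the coarser apparent distribution the sieve test sees for cohesive,
#' agglomerating powders; drives sieve fractions, fines and the
#' homogeneity index).
#'
#' @param name Label.
#' @param bulk_density,tapped_density True densities, g/mL (in `(0, 1]`,
#'   bulk `<=` tapped).
#' @param hardness Mean tablet hardness in N, or `NULL` for an
#'   incompressible powder.
#' @param angle_deg True angle of repose, degrees.
#' @param flow_seconds Flow time per 100 g, or `NULL` for non-flowing.
#' @param lod_pct,hygroscopicity_pct Moisture percentages.
#' @param psd_median,psd_gsd Laser PSD lognormal: median (um) and
#'   geometric standard deviation (`> 1`).
#' @param sieve_median,sieve_gsd Sieve-effective lognormal, same
#'   parameterization.
#' @param replicate_cv_pct Replicate-to-replicate CV% applied to each raw
#'   quantity.
#' @param batch_cv_pct Batch-to-batch CV% applied to the true values.
#'   The default 0 emulates a validated, reproducible manufacturing
#'   process (batches differ only through replicate noise); set it
#'   positive to inject a real between-batch effect.
#' @param scale_shift Named multipliers applied to the true values at
#'   industrial scale (default: none, i.e. perfect scale transposition).
#'   Names from: bulk_density, tapped_density, hardness, angle_deg,
#'   lod_pct, hygroscopicity_pct, psd_median, sieve_median.
#' @return Object of class `supplier_archetype`.
#' @export
supplier_archetype <- function(name,
                               bulk_density, tapped_density,
                               hardness = NULL,
                               angle_deg,
                               flow_seconds = NULL,
                               lod_pct, hygroscopicity_pct,
                               psd_median, psd_gsd,
                               sieve_median, sieve_gsd,
                               replicate_cv_pct = 2,
                               batch_cv_pct = 0,
                               scale_shift = NULL) {
  stopifnot(bulk_density > 0, bulk_density <= 1,
            tapped_density > 0, tapped_density <= 1,
            bulk_density <= tapped_density,
            angle_deg >= 0, angle_deg < 90,
            lod_pct >= 0, hygroscopicity_pct >= 0,
            psd_median > 0, psd_gsd > 1, sieve_median > 0, sieve_gsd > 1,
            replicate_cv_pct >= 0, batch_cv_pct >= 0)
  if (!is.null(hardness)) stopifnot(hardness >= 0)
  if (!is.null(flow_seconds)) stopifnot(flow_seconds >= 0)
  if (!is.null(scale_shift)) stopifnot(!is.null(names(scale_shift)),
                                       all(scale_shift > 0))
  structure(list(name = name, bulk_density = bulk_density,
                 tapped_density = tapped_density, hardness = hardness,
                 angle_deg = angle_deg, flow_seconds = flow_seconds,
                 lod_pct = lod_pct,
                 hygroscopicity_pct = hygroscopicity_pct,
                 psd_median = psd_median, psd_gsd = psd_gsd,
                 sieve_median = sieve_median, sieve_gsd = sieve_gsd,
                 replicate_cv_pct = replicate_cv_pct,
                 batch_cv_pct = batch_cv_pct,
                 scale_shift = scale_shift),
            class = "supplier_archetype")
}

#' Built-in supplier archetypes
#'
#' Three presets patterned on the supplier profiles of the reference
#' Linezolid study: a dense, coarse, compressible source
#' (`"glenmarck-like"`); a low-density source with excellent porosity and
#' granulometry but no compressibility (`"usv-like"`); and a fine,
#' needle-habit source with poor packing and a large fines population
#' (`"uquifa-like"`).  The true values invert the sources' mean radii;
#' the sieve-effective lognormals are calibrated so the expected fines and
#' homogeneity radii land on the corresponding source means.
#'
#' @return Named list of three [supplier_archetype()]s.
#' @examples
#' sapply(builtin_archetypes(), function(a) a$bulk_density)
#' @export
builtin_archetypes <- function() {
  list(
    "glenmarck-like" = supplier_archetype(
      name = "glenmarck-like",
      bulk_density = 0.419, tapped_density = 0.547,
      hardness = 37.4, angle_deg = 42.5, flow_seconds = NULL,
      lod_pct = 0.29, hygroscopicity_pct = 0.02,
      psd_median = 59.635, psd_gsd = 2.68107,
      sieve_median = 93.9775, sieve_gsd = 1.70125),
    "usv-like" = supplier_archetype(
      name = "usv-like",
      bulk_density = 0.255, tapped_density = 0.352,
      hardness = NULL, angle_deg = 45.35, flow_seconds = NULL,
      lod_pct = 0.38, hygroscopicity_pct = 0.02,
      psd_median = 13.396, psd_gsd = 2.53950,
      sieve_median = 90.2070, sieve_gsd = 1.37021),
    "uquifa-like" = supplier_archetype(
      name = "uquifa-like",
      bulk_density = 0.231, tapped_density = 0.263,
      hardness = NULL, angle_deg = 45.15, flow_seconds = NULL,
      lod_pct = 0.51, hygroscopicity_pct = 0.04,
      psd_median = 8.865, psd_gsd = 2.53324,
      sieve_median = 72.487, sieve_gsd = 2.41090))
}

#' Expected (noise-free) radius profile of an archetype
#'
#' The profile a noise-free replicate of this archetype produces; the
#' generator's round-trip identity.
#'
#' @param a A [supplier_archetype()].
#' @param scale Production scale (applies any `scale_shift`).
#' @param config A [sedem_config()].
#' @return A `sedem_profile`.
#' @export
archetype_profile <- function(a, scale = "pilot", config = NULL) {
  radius_profile(archetype_parameters(shifted_archetype(a, scale)),
                 config = config, warn = FALSE)
}

shifted_archetype <- function(a, scale) {
  if (scale == "industrial" && !is.null(a$scale_shift)) {
    for (nm in names(a$scale_shift)) a[[nm]] <- a[[nm]] * a$scale_shift[[nm]]
  }
  a
}

archetype_parameters <- function(a, config = NULL) {
  cfg <- as_sedem_config(config)
  d <- c(Da = a$bulk_density, Dc = a$tapped_density)
  sv <- sieve_from_lognormal(a$sieve_median, log(a$sieve_gsd))
  ft <- fraction_table(sv, config = cfg)
  c(d, derived_ratios(d),
    Icd = if (is.null(a$hardness)) 0 else a$hardness,
    alpha = a$angle_deg,
    t = if (is.null(a$flow_seconds)) Inf else a$flow_seconds,
    HR = a$lod_pct, H = a$hygroscopicity_pct,
    Pf = percent_fines(sv),
    Itheta = homogeneity_index(ft))[SEDEM_PARAMS]
}

# Integrate a lognormal size distribution over the standard sieve cuts.
sieve_from_lognormal <- function(median_um, sdlog,
                                 apertures = c(355, 212, 100, 50)) {
  p <- plnorm(c(Inf, apertures, 0), meanlog = log(median_um), sdlog = sdlog)
  pct <- -diff(p) * 100
  sieve_analysis(retained_pct = pct[-length(pct)],
                 pan_pct = pct[length(pct)],
                 apertures = apertures,
                 fines_direct_pct = pct[length(pct)])
}

# Deterministic derived seed for (batch, replicate, quantity); stays well
# below 2^31.
derive_seed <- function(seed, batch = 0, rep = 0, qty = 0) {
  s <- (as.numeric(seed) %% 1000003)
  as.integer((s * 8191 + batch * 131071 + rep * 8209 + qty * 127 + 17) %%
               2147483629)
}

# One multiplicative lognormal noise factor with the given CV (percent).
noise_factor <- function(cv_pct, seed) {
  if (cv_pct <= 0) return(1)
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  set.seed(seed)
  rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Simulate one batch of raw measurements
#'
#' Draws a full raw-measurement batch record around an archetype:
#' batch-level noise perturbs the true values once, replicate-level noise
#' perturbs each replicate's raw quantities, and the sieve fractions are
#' obtained by integrating the (perturbed) sieve-effective lognormal over
#' the 355/212/100/50 um cuts -- analytic, hence deterministic for a seed.
#'
#' @param a A [supplier_archetype()].
#' @param scale `"pilot"` or `"industrial"`.
#' @param n_replicates Number of replicates (default 3, the compendial
#'   triplicate).
#' @param seed Integer seed; the same seed reproduces the record exactly.
#' @param batch_id,source_id Labels (defaults derived from the archetype).
#' @param batch_index Index used to derive this batch's noise stream.
#' @param n_tablets Tablets crushed for the cohesion test.
#' @return A [batch_record()].
#' @examples
#' b <- simulate_batch(builtin_archetypes()[["glenmarck-like"]], seed = 42)
#' characterize_batch(b)$indices$GCI
#' @export
simulate_batch <- function(a, scale = c("pilot", "industrial"),
                           n_replicates = 3, seed = 1,
                           batch_id = NULL, source_id = NULL,
                           batch_index = 1, n_tablets = 10) {
  scale <- match.arg(scale)
  stopifnot(inherits(a, "supplier_archetype"), n_replicates >= 1)
  a <- shifted_archetype(a, scale)
  if (is.null(source_id)) source_id <- a$name
  if (is.null(batch_id)) {
    batch_id <- paste0(a$name, "-", scale, "-", batch_index)
  }
  # batch-level perturbation of the true values (one factor per quantity)
  bq <- function(q) noise_factor(a$batch_cv_pct,
                                 derive_seed(seed, batch_index, 0, q))
  true <- list(
    Da = a$bulk_density * bq(1), Dc = a$tapped_density * bq(2),
    hardness = if (is.null(a$hardness)) NULL else a$hardness * bq(3),
    angle = a$angle_deg * bq(4),
    lod = a$lod_pct * bq(5), hygro = a$hygroscopicity_pct * bq(6),
    sieve_median = a$sieve_median * bq(7),
    psd_median = a$psd_median * bq(8))
  true$Dc <- max(true$Dc, true$Da)  # tapping cannot decrease density
  reps <- lapply(seq_len(n_replicates), function(ri) {
    rq <- function(q) noise_factor(a$replicate_cv_pct,
                                   derive_seed(seed, batch_index, ri, q))
    Da <- true$Da * rq(1)
    Dc <- max(true$Dc * rq(2), Da)
    mass <- 100
    dens <- density_measurement(mass, mass / Da, mass / Dc)
    coh <- if (is.null(true$hardness)) {
      cohesion_measurement(compressible = FALSE)
    } else {
      set.seed(derive_seed(seed, batch_index, ri, 3))
      cv <- a$replicate_cv_pct / 100
      h <- if (cv > 0) {
        sdl <- sqrt(log(1 + cv^2))
        rlnorm(n_tablets, log(true$hardness) - sdl^2 / 2, sdl)
      } else rep(true$hardness, n_tablets)
      cohesion_measurement(h, lubricated = TRUE)
    }
    base_r <- 40  # mm, typical cone base radius on the compendial funnel
    radii <- base_r * vapply(4:7, function(q) {
      noise_factor(a$replicate_cv_pct, derive_seed(seed, batch_index, ri, q))
    }, numeric(1))
    ang <- min(true$angle * rq(8), 89)
    rep_m <- repose_measurement(mean(radii) * tan(ang * pi / 180), radii)
    fl <- if (is.null(a$flow_seconds)) flow_measurement(non_flowing = TRUE)
          else flow_measurement(a$flow_seconds * rq(9))
    moist <- moisture_measurement(true$lod * rq(10), true$hygro * rq(11))
    sv <- sieve_from_lognormal(true$sieve_median * rq(12), log(a$sieve_gsd))
    psd <- psd_curve_from_lognormal(true$psd_median * rq(13), log(a$psd_gsd))
    replicate_set(dens, coh, rep_m, fl, moist, sv, psd)
  })
  batch_record(source_id, batch_id, scale, reps)
}

# Cumulative PSD curve on a log-spaced grid from a lognormal distribution.
psd_curve_from_lognormal <- function(median_um, sdlog, n = 120) {
  lo <- qlnorm(1e-5, log(median_um), sdlog)
  hi <- qlnorm(1 - 1e-5, log(median_um), sdlog)
  sizes <- exp(seq(log(lo), log(hi), length.out = n))
  psd_curve(sizes, plnorm(sizes, log(median_um), sdlog) * 100)
}

#' Simulate a full multi-supplier study
#'
#' Mirrors the reference study design: for each archetype,
#' `batches_per_scale` batches at pilot and at industrial scale, each with
#' `n_replicates` replicates.
#'
#' @param archetypes List of [supplier_archetype()]s (default: the three
#'   built-ins).
#' @param batches_per_scale Batches per production scale per source.
#' @param n_replicates Replicates per batch.
#' @param seed Integer seed.
#' @return List of [batch_record()]s (length
#'   `2 * batches_per_scale * length(archetypes)`).
#' @examples
#' st <- simulate_study(seed = 7)
#' length(st)  # 18
#' @export
simulate_study <- function(archetypes = builtin_archetypes(),
                           batches_per_scale = 3, n_replicates = 3,
                           seed = 1) {
  stopifnot(length(archetypes) >= 1)
  out <- list()
  for (ai in seq_along(archetypes)) {
    a <- archetypes[[ai]]
    for (scale in c("pilot", "industrial")) {
      for (b in seq_len(batches_per_scale)) {
        idx <- (ai - 1) * 2 * batches_per_scale +
          (scale == "industrial") * batches_per_scale + b
        out[[length(out) + 1]] <- simulate_batch(
          a, scale = scale, n_replicates = n_replicates,
          seed = derive_seed(seed, 0, 0, ai * 1000), batch_index = idx,
          batch_id = sprintf("%s-%s-%d", a$name,
                             substr(scale, 1, 3), b))
      }
    }
  }
  out
}
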