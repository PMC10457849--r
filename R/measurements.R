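# Constructors for the raw-measurement types.  Each enforces its physical
# invariants at construction time; readers funnel everything through these,
# so an invalid file cannot produce a batch record.

#' Settling-cylinder density measurement
#'
#' @param sample_mass Sample mass in grams (`> 0`).
#' @param poured_volume Poured (loose) volume in mL.
#' @param tapped_volume Volume after 2500 strokes in mL; must satisfy
#'   `0 < tapped_volume <= poured_volume`.
#' @return Object of class `density_measurement`.
#' @export
density_measurement <- function(sample_mass, poured_volume, tapped_volume) {
  stopifnot(is.numeric(sample_mass), length(sample_mass) == 1,
            is.numeric(poured_volume), length(poured_volume) == 1,
            is.numeric(tapped_volume), length(tapped_volume) == 1)
  if (!(sample_mass > 0)) stop("sample_mass must be > 0 g")
  if (!(tapped_volume > 0)) stop("tapped_volume must be > 0 mL")
  if (tapped_volume > poured_volume) {
    stop("tapped_volume must not exceed poured_volume")
  }
  structure(list(sample_mass = sample_mass, poured_volume = poured_volume,
                 tapped_volume = tapped_volume),
            class = "density_measurement")
}

#' Tablet-hardness (cohesion) measurement
#'
#' @param hardness_values Crushing hardness per tablet, newtons (all
#'   `>= 0`).  Must be empty when `compressible = FALSE`.
#' @param lubricated Whether 3.5% standard lubricant was added.
#' @param compressible Whether the powder could be compressed at all.
#' @return Object of class `cohesion_measurement`.
#' @export
cohesion_measurement <- function(hardness_values = numeric(),
                                 lubricated = FALSE, compressible = TRUE) {
  stopifnot(is.numeric(hardness_values), is.logical(lubricated),
            is.logical(compressible))
  if (any(hardness_values < 0)) stop("hardness values must be >= 0 N")
  if (!compressible && length(hardness_values) > 0) {
    stop("an incompressible powder cannot have hardness values")
  }
  structure(list(hardness_values = as.numeric(hardness_values),
                 lubricated = isTRUE(lubricated),
                 compressible = isTRUE(compressible)),
            class = "cohesion_measurement")
}

#' Angle-of-repose cone measurement
#'
#' @param cone_height Cone height in mm (`>= 0`).
#' @param base_radii Exactly four base radii in mm, each `> 0`.
#' @return Object of class `repose_measurement`.
#' @export
repose_measurement <- function(cone_height, base_radii) {
  stopifnot(is.numeric(cone_height), length(cone_height) == 1,
            is.numeric(base_radii))
  if (cone_height < 0) stop("cone_height must be >= 0 mm")
  if (length(base_radii) != 4) stop("exactly 4 base radii are required")
  if (any(base_radii <= 0)) stop("base radii must be > 0 mm")
  structure(list(cone_height = cone_height,
                 base_radii = as.numeric(base_radii)),
            class = "repose_measurement")
}

#' Flow-time measurement
#'
#' @param seconds_per_100g Flow time in seconds per 100 g, or `NULL`/`Inf`
#'   for a powder that does not flow.
#' @param non_flowing Explicit non-flowing flag.
#' @return Object of class `flow_measurement`.
#' @export
flow_measurement <- function(seconds_per_100g = NULL, non_flowing = FALSE) {
  if (is.null(seconds_per_100g) || isTRUE(non_flowing) ||
      (length(seconds_per_100g) == 1 && is.infinite(seconds_per_100g))) {
    return(structure(list(seconds_per_100g = NA_real_, non_flowing = TRUE),
                     class = "flow_measurement"))
  }
  stopifnot(is.numeric(seconds_per_100g), length(seconds_per_100g) == 1)
  if (seconds_per_100g < 0) stop("flow time must be >= 0 s")
  structure(list(seconds_per_100g = seconds_per_100g, non_flowing = FALSE),
            class = "flow_measurement")
}

#' Moisture measurements: loss on drying and hygroscopicity
#'
#' @param loss_on_drying_pct Loss on drying (105 degrees C to constant
#'   weight), percent, `>= 0`.
#' @param hygroscopicity_pct Weight gain after 24 h at 76% relative
#'   humidity, percent, `>= 0`.
#' @return Object of class `moisture_measurement`.
#' @export
moisture_measurement <- function(loss_on_drying_pct, hygroscopicity_pct) {
  stopifnot(is.numeric(loss_on_drying_pct), is.numeric(hygroscopicity_pct))
  if (loss_on_drying_pct < 0 || hygroscopicity_pct < 0) {
    stop("moisture percentages must be >= 0")
  }
  structure(list(loss_on_drying_pct = loss_on_drying_pct,
                 hygroscopicity_pct = hygroscopicity_pct),
            class = "moisture_measurement")
}

#' Sieve-stack analysis
#'
#' @param retained_pct Percentage retained on each sieve, top to bottom.
#' @param pan_pct Percentage passing the finest sieve (collected in the
#'   pan).
#' @param apertures Sieve openings in micrometres, strictly decreasing;
#'   default is the standard 355/212/100/50 stack.
#' @param fines_direct_pct Percentage `< 50` um from the dedicated
#'   10-minute vibrated fines test, if performed.  When present it takes
#'   precedence over `pan_pct` as the fines percentage, since fines can
#'   adhere to coarser material during the full stack test.
#' @param loss_tol Tolerated mass loss in percentage points.
#' @return Object of class `sieve_analysis`.
#' @export
sieve_analysis <- function(retained_pct, pan_pct,
                           apertures = c(355, 212, 100, 50),
                           fines_direct_pct = NULL, loss_tol = 2) {
  stopifnot(is.numeric(retained_pct), is.numeric(pan_pct),
            is.numeric(apertures))
  if (length(retained_pct) != length(apertures)) {
    stop("retained_pct must have one entry per sieve aperture")
  }
  if (any(diff(apertures) >= 0)) {
    stop("sieve apertures must be strictly decreasing")
  }
  if (any(retained_pct < 0 | retained_pct > 100) ||
      pan_pct < 0 || pan_pct > 100) {
    stop("sieve percentages must lie in [0, 100]")
  }
  tot <- sum(retained_pct) + pan_pct
  if (tot > 100 + loss_tol) stop("sieve fractions sum to more than 100%")
  if (!is.null(fines_direct_pct)) {
    stopifnot(is.numeric(fines_direct_pct), fines_direct_pct >= 0,
              fines_direct_pct <= 100)
  }
  structure(list(apertures = as.numeric(apertures),
                 retained_pct = as.numeric(retained_pct),
                 pan_pct = as.numeric(pan_pct),
                 fines_direct_pct = fines_direct_pct),
            class = "sieve_analysis")
}

#' Cumulative particle-size-distribution curve
#'
#' @param sizes Ascending size grid in micrometres.
#' @param cumulative_pct Cumulative volume percent undersize at each size;
#'   nondecreasing, reaching at least 99% at the top of the grid.
#' @return Object of class `psd_curve`.
#' @export
psd_curve <- function(sizes, cumulative_pct) {
  stopifnot(is.numeric(sizes), is.numeric(cumulative_pct),
            length(sizes) == length(cumulative_pct))
  if (length(sizes) < 2) stop("a PSD curve needs at least two points")
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  if (any(diff(cumulative_pct) < -1e-9)) {
    stop("cumulative percentages must be nondecreasing")
  }
  if (any(cumulative_pct < -1e-9 | cumulative_pct > 100 + 1e-6)) {
    stop("cumulative percentages must lie in [0, 100]")
  }
  if (max(cumulative_pct) < 99) {
    stop("curve must reach at least 99% at the top of the grid")
  }
  structure(list(sizes = as.numeric(sizes),
                 cumulative_pct = as.numeric(cumulative_pct)),
            class = "psd_curve")
}

#' One replicate's measurement set
#'
#' @param density,cohesion,repose,flow,moisture,sieve The measurement
#'   objects for this replicate (see the respective constructors).
#' @param psd Optional [psd_curve()].
#' @return A named list of validated measurements.
#' @export
replicate_set <- function(density, cohesion, repose, flow, moisture, sieve,
                          psd = NULL) {
  stopifnot(inherits(density, "density_measurement"),
            inherits(cohesion, "cohesion_measurement"),
            inherits(repose, "repose_measurement"),
            inherits(flow, "flow_measurement"),
            inherits(moisture, "moisture_measurement"),
            inherits(sieve, "sieve_analysis"))
  if (!is.null(psd)) stopifnot(inherits(psd, "psd_curve"))
  list(density = density, cohesion = cohesion, repose = repose,
       flow = flow, moisture = moisture, sieve = sieve, psd = psd)
}

#' Raw batch record
#'
#' All raw measurements for one manufactured batch, tagged with its source
#' (supplier) and production scale.
#'
#' @param source_id Supplier/source label.
#' @param batch_id Batch label.
#' @param scale `"pilot"` (around 2 kg) or `"industrial"` (around 25 kg).
#' @param replicates List of one or more [replicate_set()]s.
#' @return Object of class `sedem_batch`.
#' @export
batch_record <- function(source_id, batch_id, scale, replicates) {
  scale <- match.arg(scale, c("pilot", "industrial"))
  stopifnot(is.character(source_id), is.character(batch_id),
            is.list(replicates), length(replicates) >= 1)
  replicates <- lapply(replicates, function(r) do.call(replicate_set, r))
  structure(list(source_id = source_id, batch_id = batch_id, scale = scale,
                 replicates = replicates),
            class = "sedem_batch")
}

#' @export
print.sedem_batch <- function(x, ...) {
  cat(sprintf("<sedem_batch %s/%s, %s scale, %d replicate(s)>\n",
              x$source_id, x$batch_id, x$scale, length(x$replicates)))
  invisible(x)
}
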