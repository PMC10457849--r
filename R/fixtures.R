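#' Reference replicate radius table for one source and scale
#'
#' The package ships the complete replicate-level radius tables of a
#' three-supplier Linezolid characterization study (three sources, three
#' pilot and three industrial batches each, three replicates per batch).
#' They serve as worked reference data for the index and statistics layers.
#'
#' @param source `"Glenmarck"`, `"USV"` or `"UQUIFA"`.
#' @param scale `"pilot"` or `"industrial"`.
#' @return 12 x 9 numeric matrix of radii: rows the canonical parameters,
#'   columns `batch.replicate`.
#' @examples
#' reference_radii("Glenmarck", "pilot")[, "GL-1.R1"]
#' @export
reference_radii <- function(source = c("Glenmarck", "USV", "UQUIFA"),
                            scale = c("pilot", "industrial")) {
  source <- match.arg(source)
  scale <- match.arg(scale)
  REFERENCE_RADII[[paste(source, scale, sep = ".")]]
}

#' Reference pooled summary statistics
#'
#' Published mean/variance/sd/CV% per parameter (plus PP and IGC) pooled
#' over the nine pilot replicates, the nine industrial replicates, or all
#' eighteen replicates of each source.
#'
#' @param scale `"pilot"`, `"industrial"` or `"pooled"`.
#' @return Named list (one matrix per source, 14 x 4).
#' @export
reference_stats <- function(scale = c("pilot", "industrial", "pooled")) {
  REFERENCE_STATS[[match.arg(scale)]]
}

#' Reference laser-diffraction quantiles
#'
#' @return Data frame with `source`, `D10`, `D50`, `D90` (um) and the
#'   breadth ratio `Fprime`.
#' @export
reference_psd_quantiles <- function() REFERENCE_PSD

#' Reference incidence-factor comparison table
#'
#' Source-mean radii, incidence means and indices per source at pilot
#' scale, industrial scale, and averaged.
#'
#' @return 20 x 9 numeric matrix.
#' @export
reference_incidence <- function() REFERENCE_INCIDENCE

#' Reference study as batch mean profiles
#'
#' Convenience accessor: batch-mean radius profiles (mean over the three
#' replicates) for every batch of a source and scale.
#'
#' @inheritParams reference_radii
#' @return Named list of three `sedem_profile`s, one per batch.
#' @export
reference_batch_profiles <- function(source, scale) {
  m <- reference_radii(source, scale)
  batches <- unique(sub("\\.R[0-9]+$", "", colnames(m)))
  setNames(lapply(batches, function(b) {
    as_sedem_profile(rowMeans(m[, grep(paste0("^", b, "\\."),
                                       colnames(m)), drop = FALSE]))
  }), batches)
}

#' Reference printed index rows for one source and scale
#'
#' The published parametric index (IP), parametric profile (PP) and
#' good-compression index (IGC) rows of the replicate radius tables,
#' including the batch-mean columns.
#'
#' @inheritParams reference_radii
#' @return 3 x 12 matrix, rows IP/PP/IGC, columns `batch.R1..R3` and
#'   `batch.mean`.
#' @export
reference_index_rows <- function(source = c("Glenmarck", "USV", "UQUIFA"),
                                 scale = c("pilot", "industrial")) {
  source <- match.arg(source)
  scale <- match.arg(scale)
  REFERENCE_INDEX_ROWS[[paste(source, scale, sep = ".")]]
}
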