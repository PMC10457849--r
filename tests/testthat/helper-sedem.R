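# Shared helpers for the test suite.

# A complete, valid replicate measurement set with adjustable pieces.
make_replicate <- function(Da = 0.42, Dc = 0.54, hardness = c(36, 38, 37),
                           angle = 42, lod = 0.3, hygro = 0.05,
                           retained = c(1, 9, 40, 38), pan = 12,
                           fines = NULL, psd = NULL) {
  replicate_set(
    density = density_measurement(100, 100 / Da, 100 / Dc),
    cohesion = if (is.null(hardness)) {
      cohesion_measurement(compressible = FALSE)
    } else cohesion_measurement(hardness),
    repose = repose_measurement(40 * tan(angle * pi / 180), rep(40, 4)),
    flow = flow_measurement(non_flowing = TRUE),
    moisture = moisture_measurement(lod, hygro),
    sieve = sieve_analysis(retained, pan, fines_direct_pct = fines),
    psd = psd)
}

make_batch <- function(n_replicates = 3, source_id = "SRC",
                       batch_id = "B1", scale = "pilot", ...) {
  batch_record(source_id, batch_id, scale,
               replicates = replicate.list <- lapply(seq_len(n_replicates),
                                                     function(i) make_replicate(...)))
}

# All sources and scales of the reference study.
reference_keys <- function() {
  expand.grid(source = c("Glenmarck", "USV", "UQUIFA"),
              scale = c("pilot", "industrial"),
              stringsAsFactors = FALSE)
}

# Replicate columns of a batch within a reference radius matrix.
batch_cols <- function(m, batch) {
  grep(paste0("^", batch, "\\."), colnames(m))
}
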