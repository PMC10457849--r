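# Readers and writers for batch records.  Two on-disk forms:
#  * JSON: one document per study (schema in inst/extdata/study-schema.json)
#  * CSV:  long format, one row per (batch, replicate, measurement field),
#          columns source_id, batch_id, scale, replicate, kind, field, value.
# Units are fixed by the schema (g, mL, mm, um, s, %); both readers funnel
# every record through the measurement constructors, so invariant
# violations surface as errors naming the offending record and field.

rep_to_list <- function(r) {
  list(
    density = list(sample_mass = r$density$sample_mass,
                   poured_volume = r$density$poured_volume,
                   tapped_volume = r$density$tapped_volume),
    cohesion = list(hardness_values = as.list(r$cohesion$hardness_values),
                    lubricated = r$cohesion$lubricated,
                    compressible = r$cohesion$compressible),
    repose = list(cone_height = r$repose$cone_height,
                  base_radii = as.list(r$repose$base_radii)),
    flow = list(seconds_per_100g = if (r$flow$non_flowing) NULL else
                  r$flow$seconds_per_100g,
                non_flowing = r$flow$non_flowing),
    moisture = list(loss_on_drying_pct = r$moisture$loss_on_drying_pct,
                    hygroscopicity_pct = r$moisture$hygroscopicity_pct),
    sieve = list(apertures = as.list(r$sieve$apertures),
                 retained_pct = as.list(r$sieve$retained_pct),
                 pan_pct = r$sieve$pan_pct,
                 fines_direct_pct = r$sieve$fines_direct_pct),
    psd = if (is.null(r$psd)) NULL else
      list(sizes = as.list(r$psd$sizes),
           cumulative_pct = as.list(r$psd$cumulative_pct))
  )
}

rep_from_list <- function(x, where) {
  need <- c("density", "cohesion", "repose", "flow", "moisture", "sieve")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(where, ": missing measurement(s) ", paste(miss, collapse = ", "))
  }
  wrap <- function(expr, field) {
    tryCatch(expr, error = function(e) {
      stop(where, " [", field, "]: ", conditionMessage(e), call. = FALSE)
    })
  }
  replicate_set(
    density = wrap(density_measurement(x$density$sample_mass,
                                       x$density$poured_volume,
                                       x$density$tapped_volume), "density"),
    cohesion = wrap(cohesion_measurement(
      c(numeric(), unlist(x$cohesion$hardness_values)),
      isTRUE(x$cohesion$lubricated),
      isTRUE(x$cohesion$compressible)), "cohesion"),
    repose = wrap(repose_measurement(x$repose$cone_height,
                                     unlist(x$repose$base_radii)), "repose"),
    flow = wrap(flow_measurement(x$flow$seconds_per_100g,
                                 isTRUE(x$flow$non_flowing)), "flow"),
    moisture = wrap(moisture_measurement(x$moisture$loss_on_drying_pct,
                                         x$moisture$hygroscopicity_pct),
                    "moisture"),
    sieve = wrap(sieve_analysis(unlist(x$sieve$retained_pct),
                                x$sieve$pan_pct,
                                unlist(x$sieve$apertures),
                                x$sieve$fines_direct_pct), "sieve"),
    psd = if (is.null(x$psd)) NULL else
      wrap(psd_curve(unlist(x$psd$sizes), unlist(x$psd$cumulative_pct)),
           "psd"))
}

#' Write batch records to JSON or CSV
#'
#' @param records List of [batch_record()]s (may be empty).
#' @param path Output file path.
#' @param format `"json"` or `"csv"` (default guessed from the extension).
#' @return `path`, invisibly.  [read_batches()] on the written file
#'   restores the records with value equality.
#' @export
write_batches <- function(records, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
      "json"
  }
  stopifnot(is.list(records))
  for (r in records) stopifnot(inherits(r, "sedem_batch"))
  if (format == "json") {
    doc <- list(format = "sedem-study", version = 1L,
                batches = lapply(records, function(b) {
                  list(source_id = b$source_id, batch_id = b$batch_id,
                       scale = b$scale,
                       replicates = lapply(b$replicates, rep_to_list))
                }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    rows <- list()
    for (b in records) {
      for (ri in seq_along(b$replicates)) {
        flat <- unlist(rapply(rep_to_list(b$replicates[[ri]]),
                              function(v) v, how = "replace"))
        flat <- vapply(flat, function(v) {
          if (is.logical(v)) as.numeric(v) else as.numeric(v)
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          source_id = b$source_id, batch_id = b$batch_id, scale = b$scale,
          replicate = ri,
          field = names(flat),
          value = formatC(unname(flat), format = "g", digits = 17))
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(source_id = character(), batch_id = character(),
                 scale = character(), replicate = integer(),
                 field = character(), value = character())
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read batch records from JSON or CSV
#'
#' @param path Input file written by [write_batches()] (or following the
#'   documented schema).
#' @param format `"json"` or `"csv"` (default guessed from the extension).
#' @return List of validated [batch_record()]s.
#' @export
read_batches <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
      "json"
  }
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!identical(doc$format, "sedem-study")) {
      stop("not a sedem study file: ", path)
    }
    lapply(doc$batches, function(b) {
      where <- paste0(b$source_id, "/", b$batch_id)
      if (is.null(b$source_id) || is.null(b$batch_id) || is.null(b$scale)) {
        stop("batch record missing source_id/batch_id/scale")
      }
      reps <- lapply(seq_along(b$replicates), function(i) {
        rep_from_list(b$replicates[[i]],
                      paste0(where, " replicate ", i))
      })
      batch_record(b$source_id, b$batch_id, b$scale, reps)
    })
  } else {
    df <- read.csv(path, colClasses = c(value = "character"))
    need <- c("source_id", "batch_id", "scale", "replicate", "field",
              "value")
    if (!all(need %in% names(df))) {
      stop("CSV schema violation: need columns ",
           paste(need, collapse = ", "))
    }
    if (nrow(df) == 0) return(list())
    key <- paste(df$source_id, df$batch_id, sep = "\r")
    out <- lapply(unique(key), function(k) {
      sub <- df[key == k, ]
      where <- paste0(sub$source_id[1], "/", sub$batch_id[1])
      reps <- lapply(sort(unique(sub$replicate)), function(ri) {
        rs <- sub[sub$replicate == ri, ]
        vals <- as.numeric(rs$value)
        nested <- unflatten_fields(setNames(vals, rs$field))
        rep_from_list(nested, paste0(where, " replicate ", ri))
      })
      batch_record(sub$source_id[1], sub$batch_id[1], sub$scale[1], reps)
    })
    out
  }
}

# Rebuild the nested replicate list from dotted field names
# (e.g. "sieve.retained_pct3" from unlist()).
unflatten_fields <- function(flat) {
  out <- list()
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    kind <- parts[1]
    field <- sub("[0-9]+$", "", parts[2])
    if (is.null(out[[kind]])) out[[kind]] <- list()
    cur <- out[[kind]][[field]]
    out[[kind]][[field]] <- c(cur, unname(flat[[nm]]))
  }
  for (kind in c("cohesion", "flow")) {
    for (lf in c("lubricated", "compressible", "non_flowing")) {
      if (!is.null(out[[kind]][[lf]])) {
        out[[kind]][[lf]] <- out[[kind]][[lf]] != 0
      }
    }
  }
  if (isTRUE(out$flow$non_flowing)) out$flow$seconds_per_100g <- NULL
  if (is.null(out$cohesion$hardness_values)) {
    out$cohesion$hardness_values <- numeric()
  }
  out
}
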