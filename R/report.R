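# Report serialization: JSON carries full precision alongside rounded
# display values (radii 2 dp, statistics 4 dp, matching the conventional
# table layout).

round_display <- function(x, digits) {
  if (is.numeric(x)) round(x, digits) else x
}

#' JSON-ready index report for one characterized batch
#'
#' @param ch A [characterize_batch()] result.
#' @return A list: identification, radii (full precision and 2-dp
#'   display), incidence means, `IP`/`IPP`/`f`/`GCI` and the verdict.
#' @export
characterization_report <- function(ch) {
  stopifnot(inherits(ch, "sedem_characterization"))
  list(source_id = ch$source_id, batch_id = ch$batch_id, scale = ch$scale,
       n_replicates = nrow(ch$parameters),
       radii = as.list(unclass(ch$profile)),
       radii_display = as.list(round(unclass(ch$profile), 2)),
       incidence = as.list(ch$incidence),
       indices = list(IP = ch$indices$IP, IPP = ch$indices$IPP,
                      f = ch$indices$f, GCI = ch$indices$GCI),
       verdict = ch$verdict$verdict,
       failing_criteria = ch$verdict$failing)
}

#' Serialize characterization or validation results to JSON
#'
#' Output ordering is deterministic: identical inputs and configuration
#' give byte-identical files.
#'
#' @param x A `sedem_characterization`, a list of them, or a
#'   `sedem_validation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  body <- if (inherits(x, "sedem_characterization")) {
    characterization_report(x)
  } else if (inherits(x, "sedem_validation")) {
    validation_report_body(x)
  } else if (is.list(x)) {
    lapply(x, function(el) {
      if (inherits(el, "sedem_characterization"))
        characterization_report(el) else validation_report_body(el)
    })
  } else stop("unsupported report object")
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

validation_report_body <- function(v) {
  stopifnot(inherits(v, "sedem_validation"))
  rows <- v$rows
  rows_list <- lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ]))
  list(grouping = v$grouping, alpha = v$alpha, groups = v$groups,
       n_tests = v$n_tests, overall = v$overall, rows = rows_list)
}

#' Markdown table for a validation report
#'
#' Human-readable table mirroring the standard descriptives +
#' variance-check + ANOVA layout.
#'
#' @param v A [validation_report()] result.
#' @return Character vector of markdown lines.
#' @export
validation_markdown <- function(v) {
  stopifnot(inherits(v, "sedem_validation"))
  df <- v$rows
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
  df[df == "NA"] <- "NA"
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                         "|"))
  c(sprintf("## Validation report: %s (alpha = %g)", v$grouping, v$alpha),
    "", sprintf("Groups: %s", paste(v$groups, collapse = ", ")), "",
    hdr, sep, unname(body), "",
    sprintf("Overall: **%s** (%d tests, no multiplicity correction)",
            v$overall, v$n_tests))
}
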