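# Tabular output with a reproducibility manifest.

#' Write a results table with a manifest
#'
#' Writes a data frame as CSV (header, floats at 12 significant digits) or as
#' JSON records, and a sibling `<name>_manifest.json` recording the
#' configuration, the seed and the package version, so a run can be reproduced
#' from its outputs alone.
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @param config Optional configuration list recorded in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return The output path, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "json"),
                        config = NULL, seed = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (format == "csv") {
    printed <- rows
    for (j in seq_along(printed)) {
      if (is.double(printed[[j]])) {
        printed[[j]] <- formatC(printed[[j]], digits = 12, format = "g")
      }
    }
    utils::write.csv(printed, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  # no timestamp: identical runs must produce byte-identical files
  manifest <- list(
    config = strip_classes(config),
    seed = seed,
    package = "collectivelearning",
    version = as.character(utils::packageVersion("collectivelearning")))
  manifest_path <- paste0(tools::file_path_sans_ext(path), "_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# drop S3 classes recursively so configs serialize as plain JSON records
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}
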