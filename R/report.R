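#' Write a stability report to delimited text and JSON
#'
#' Emits the per-gene stability table as TSV (metrics rounded to 3 decimals,
#' consensus to 2, matching the usual reporting precision) and a faithful
#' full-precision JSON companion including the geNorm V series. The JSON
#' round-trips: [read_stability_report()] restores the table to numeric
#' tolerance.
#'
#' @param report a `stability_report` from [stability_report()]
#' @param path output TSV path; the JSON is written next to it with
#'   extension `.json`
#' @param digits rounding for the TSV metrics (default 3)
#' @return invisibly, the paths written
#' @export
write_stability_report <- function(report, path, digits = 3) {
  stopifnot(inherits(report, "stability_report"))
  tab <- report$table
  if (nrow(tab) == 0) stop("empty gene set in report", call. = FALSE)
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) round(v, digits))
  out$consensus_geomean <- round(tab$consensus_geomean, 2)
  .write_delim(out, path)
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  payload <- list(table = tab,
                  v_series = as.list(report$v),
                  recommended_n = report$recommended_n)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(path, json_path))
}

#' Read back the JSON companion of a stability report
#' @param json_path path written by [write_stability_report()]
#' @return list with `table` (data.frame), `v_series`, `recommended_n`
#' @export
read_stability_report <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  payload$v_series <- unlist(payload$v_series)
  payload
}

#' Write the geNorm pairwise-variation series as TSV
#' @param report a `stability_report` or `genorm` object
#' @param path output path
#' @return invisibly, the path
#' @export
write_v_series <- function(report, path) {
  v <- report$v
  if (is.null(v)) stop("no V series in object", call. = FALSE)
  .write_delim(data.frame(comparison = names(v), v = round(unname(v), 4),
                          stringsAsFactors = FALSE), path)
  invisible(path)
}
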