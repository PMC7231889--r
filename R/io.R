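# Range-table and run-manifest file formats.

.known_biomarkers_io <- function() c(.biomarker_names, "AP_peak")

#' Read a biomarker range table from CSV
#'
#' Schema: columns `biomarker`, `protocol` (nonpaced/paced), `lb`, `ub`,
#' `units`. Unknown biomarker names and rows with lb >= ub are rejected.
#'
#' @param path CSV file.
#' @return a `cm_range_table`.
#' @export
read_range_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("biomarker", "protocol", "lb", "ub", "units")
  if (!all(need %in% names(df)))
    stop("range table must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(df$biomarker, .known_biomarkers_io())
  if (length(unknown))
    stop("unknown biomarker name(s): ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(.known_biomarkers_io(), collapse = ", "))
  bad <- which(!is.finite(df$lb) | !is.finite(df$ub))
  if (length(bad)) stop("malformed bounds in row(s): ", paste(bad + 1, collapse = ", "))
  validate_range_table(df)
}

#' Write a biomarker range table to CSV
#'
#' Canonical full-precision formatting: a write -> read -> write cycle is
#' byte-identical.
#'
#' @param table a `cm_range_table`.
#' @param path output file.
#' @export
write_range_table <- function(table, path) {
  stopifnot(inherits(table, "cm_range_table"))
  df <- as.data.frame(table)
  df$lb <- vapply(df$lb, function(x) sprintf("%.15g", x), character(1))
  df$ub <- vapply(df$ub, function(x) sprintf("%.15g", x), character(1))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records enough provenance (seed, configuration, package version, input
#' hashes) to regenerate the deterministic outputs of a stage.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param seed integer seed(s) used.
#' @param config list of stage settings.
#' @export
write_manifest <- function(path, stage, seed = NA, config = list()) {
  jsonlite::write_json(list(
    stage = stage,
    seed = seed,
    config = config,
    package = "ipscpop",
    version = as.character(packageVersion("ipscpop")),
    r_version = R.version.string
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write population results as CSV
#'
#' One row per member: id, the 22 scaling columns, status (and first violated
#' bound, if rejected).
#'
#' @param pop result of [run_population()] (or a list of members plus a
#'   status matrix).
#' @param path output file.
#' @param mode which calibration mode's status column to use.
#' @export
write_population_table <- function(pop, path, mode = "AP_CaTr") {
  sc <- do.call(rbind, lapply(pop$members, `[[`, "scaling"))
  st <- if (mode %in% colnames(pop$status)) pop$status[, mode]
        else vapply(pop$members, `[[`, character(1), "status")
  df <- cbind(data.frame(id = vapply(pop$members, `[[`, character(1), "id")),
              as.data.frame(sc), data.frame(status = st))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
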