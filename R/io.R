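#' Write index reports as JSON
#'
#' Serialises one report or a full [consensus_indices()] set as a JSON
#' array of `{index, per_item, study_wide}` objects.
#'
#' @param reports an `index_report` or `index_report_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reports_json <- function(reports, path) {
  if (inherits(reports, "index_report")) reports <- list(reports)
  out <- lapply(unname(reports), function(rep)
    list(index = rep$index, per_item = rep$per_item,
         study_wide = rep$study_wide))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a dependency table as CSV and JSON
#'
#' The CSV holds the ranked table (columns `index`, `dependency`, `rank`);
#' the JSON additionally carries the per-condition medians and the grid so
#' the table can be re-plotted without re-simulation.
#'
#' @param tab a `"dependency_table"` from [run_sweep()].
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_dependency_table <- function(tab, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(tab), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    med <- attr(tab, "medians")
    payload <- list(
      param = attr(tab, "param"),
      grid = attr(tab, "grid"),
      replicates = attr(tab, "replicates"),
      table = as.data.frame(tab),
      medians = lapply(seq_len(ncol(med)), function(j) unname(med[, j])))
    names(payload$medians) <- colnames(med)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}

#' Write a run manifest
#'
#' Every output directory gets a manifest sufficient to regenerate its
#' contents bit-for-bit: the configuration echo, the master seed, the
#' package version, a timestamp, and the paths written.
#'
#' @param dir output directory.
#' @param config a list (or `simulation_config`/`sweep_spec`) echoing the
#'   run configuration.
#' @param seed the master seed used.
#' @param outputs character vector of files written.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed, outputs) {
  cfg <- unclass(config)
  cfg$clustering <- if (!is.null(cfg$clustering)) unclass(cfg$clustering)
  cfg$baseline <- if (!is.null(cfg$baseline)) {
    b <- unclass(cfg$baseline); b$clustering <- unclass(b$clustering); b
  }
  man <- list(tool = "delphisim",
              version = as.character(packageVersion("delphisim")),
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
              master_seed = seed,
              config = cfg,
              outputs = basename(outputs))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Serialise a study result to JSON
#'
#' @param res a `"study_result"` from [run_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(res, path) {
  payload <- list(
    config = {
      cfg <- unclass(res$config); cfg$clustering <- unclass(cfg$clustering)
      cfg
    },
    study_wide = as.list(res$study_wide),
    per_item = lapply(unname(res$reports), function(r) r$per_item),
    clusters = lapply(res$cluster_sets, function(cs)
      as.data.frame(cs)))
  names(payload$per_item) <- names(res$reports)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
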