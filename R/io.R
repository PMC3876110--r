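# Configuration files, time-series serialization and run manifests.

.config_sections <- function() unique(.param_table()$section)

#' Load a model configuration file
#'
#' Reads a hierarchical YAML configuration holding the parameter sections
#' (`physical`, `geometry`, `bulk`, `fractions`, `exchange`, `currents`,
#' `sr`, `buffers`, `stimulus`, `clamp`) plus optional `protocol` and
#' `clamp_mode` blocks. Unknown keys anywhere are errors reported with
#' their full key path; all parameters are validated on load.
#'
#' @param path path to a YAML configuration.
#' @return list with `params` (`ttmyo_params`), `protocol`
#'   (`ttmyo_protocol` or `NULL`) and `clamp` (`ttmyo_clamp`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  tab <- .param_table()
  known_sections <- c(unique(tab$section), "protocol", "clamp_mode", "meta")
  bad <- setdiff(names(cfg), known_sections)
  if (length(bad))
    abort(paste0("unknown config section(s): ", paste(bad, collapse = ", ")))
  p <- list()
  for (sec in intersect(names(cfg), unique(tab$section))) {
    entries <- cfg[[sec]]
    bad <- setdiff(names(entries), tab$name[tab$section == sec])
    if (length(bad))
      abort(paste0("unknown config key(s): ",
                   paste(paste0(sec, ".", bad), collapse = ", ")))
    p[names(entries)] <- entries
  }
  missing <- setdiff(tab$name, names(p))
  if (length(missing))
    abort(paste0("config incomplete, missing: ",
                 paste(missing, collapse = ", ")))
  params <- validate_parameters(structure(p[tab$name], class = "ttmyo_params"))
  clamp <- clamp_config(cfg$clamp_mode %||% "free")
  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    segs <- purrr::map_dfr(cfg$protocol$segments, as_tibble)
    protocol <- pacing_protocol(segs, clamp = clamp,
                                stim_amp = cfg$protocol$stim_amp %||% NULL)
  }
  list(params = params, protocol = protocol, clamp = clamp)
}

#' Write a model configuration file
#'
#' @param params a `ttmyo_params` object.
#' @param path output YAML path.
#' @param clamp_mode clamp mode string stored alongside the parameters.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, clamp_mode = "free") {
  params <- validate_parameters(params)
  tab <- .param_table()
  cfg <- lapply(split(tab$name, tab$section)[unique(tab$section)],
                function(nm) as.list(unclass(params)[nm]))
  cfg$clamp_mode <- clamp_mode
  cfg$meta <- list(
    calibrated = as.list(attr(params, "calibrated")),
    layout_version = state_layout()$version
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write a simulation trace as CSV
#'
#' Canonical interchange format: a CSV whose first column is `time` (ms)
#' followed by the requested trace columns; units are recorded in a
#' `# units:` comment line above the header.
#'
#' @param sim a `ttmyo_sim` with a dense trace.
#' @param path output file.
#' @param traces character vector of trace columns to keep (defaults to
#'   every recorded column); an empty selection writes a header-only file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(sim, path, traces = NULL) {
  stopifnot(inherits(sim, "ttmyo_sim"))
  if (is.null(sim$trace)) abort("simulation holds no dense trace")
  tr <- sim$trace
  if (is.null(traces)) traces <- setdiff(names(tr), "time")
  bad <- setdiff(traces, names(tr))
  if (length(bad))
    abort(paste0("unknown trace column(s): ", paste(bad, collapse = ", ")))
  out <- tr[, c("time", traces), drop = FALSE]
  units <- c(time = "ms", v = "mV")
  ucol <- ifelse(names(out) %in% names(units), units[names(out)],
                 ifelse(grepl("^i_", names(out)), "pA",
                        ifelse(grepl("^j_", names(out)), "fmol/ms",
                               ifelse(grepl("^int_", names(out)), "pA*ms", "mM"))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(ucol, collapse = ",")), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read back a CSV trace written by [write_timeseries()]
#'
#' @param path CSV path.
#' @return tibble with the stored columns; units attribute attached.
#' @export
read_timeseries <- function(path) {
  first <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#")
  out <- as_tibble(df)
  if (startsWith(first, "# units:"))
    attr(out, "units") <- strsplit(sub("^# units: ", "", first), ",")[[1]]
  out
}

#' Run manifest for a simulation
#'
#' @param sim a `ttmyo_sim` object.
#' @param outputs named character vector of files produced from this run.
#' @return list with parameter hash, protocol description, solver settings,
#'   package version and output paths; write it with
#'   [jsonlite::write_json()].
#' @export
run_manifest <- function(sim, outputs = character()) {
  stopifnot(inherits(sim, "ttmyo_sim"))
  list(
    package = "ttmyo",
    version = as.character(utils::packageVersion("ttmyo")),
    params_hash = sim$params_hash,
    layout_version = sim$layout$version,
    n_state = sim$layout$n_state,
    protocol = list(
      segments = as.data.frame(sim$protocol$segments),
      clamp = sim$protocol$clamp$mode
    ),
    solver = sim$solver,
    n_cycles = nrow(sim$cycles),
    outputs = as.list(outputs)
  )
}
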