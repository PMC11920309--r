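#' Serialize a power report to JSON
#'
#' Writes the power estimates together with the fully resolved configuration
#' (all defaults materialized), so a report file alone suffices to reproduce
#' the run.
#'
#' @param report a `power_report` from [run_power()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string, or the path invisibly when writing to file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "power_report"))
  x <- list(
    power = list(
      nhst = report$power_nhst,
      met = report$power_met,
      eq = report$power_eq
    ),
    mc_se = as.list(report$mc_se),
    n_sims = report$n_sims,
    n_degenerate = report$n_degenerate,
    seed = report$seed,
    config = .config_list(report$config),
    package_version = as.character(packageVersion("aucpower"))
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(path)
}

# fully resolved config as a plain list (for reports and manifests)
.config_list <- function(config) {
  spec_list <- function(s) {
    if (is.null(s)) {
      return(NULL)
    }
    s <- unclass(s)
    s[!vapply(s, is.null, logical(1))]
  }
  out <- list(
    design = config$design,
    spec1 = spec_list(config$spec1),
    spec2 = spec_list(config$spec2),
    sesoi = config$sesoi,
    alpha = config$alpha,
    n_sims = config$n_sims,
    seed = config$seed,
    fpr_range = config$fpr_range,
    n_boot = config$n_boot
  )
  out[!vapply(out, is.null, logical(1))]
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a command-line run byte-for-byte:
#' the command, the fully resolved configuration (defaults written out, so a
#' silent default can never desynchronize a report), the seed, the package
#' version, a timestamp, and the output paths.
#'
#' @param command the command name.
#' @param config a [power_config()] or a plain list of resolved settings.
#' @param seed the seed the run used.
#' @param outputs character vector of files the run wrote.
#' @param path where to write the manifest JSON.
#' @return The path, invisibly.
#' @export
write_manifest <- function(command, config, seed, outputs, path) {
  cfg <- if (inherits(config, "power_config")) .config_list(config) else config
  x <- list(
    command = command,
    config = cfg,
    seed = seed,
    package_version = as.character(packageVersion("aucpower")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  writeLines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
    path
  )
  invisible(path)
}
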